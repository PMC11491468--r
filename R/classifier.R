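#' Platform-specific called-segment cutoff
#'
#' SNP-array and low-coverage WGS pipelines produce systematically
#' different segment counts, so the CNA-quiet segment cutoff is
#' platform-calibrated: 20 called segments on SNP arrays, 6 on lcWGS.
#'
#' @param platform `"snp_array"` or `"lcwgs"`.
#' @return integer cutoff.
#' @export
platform_segment_cutoff <- function(platform = c("snp_array", "lcwgs")) {
  switch(match.arg(platform), snp_array = 20L, lcwgs = 6L)
}

#' Classify a tumor as CNA-quiet or CNA-other
#'
#' The core decision rule: a tumor is CNA-quiet iff its (purity-corrected)
#' FGA is below 0.20 AND fewer than the platform cutoff of segments were
#' called; otherwise (FGA >= 0.20 and/or segment count at or above the
#' cutoff) it is CNA-other. With `casp8_override = TRUE`, a CASP8-mutated
#' tumor is additionally classified CNA-quiet regardless of its
#' copy-number profile — an opt-in extension of the rule motivated by the
#' strong enrichment of CASP8 mutations in quiet tumors.
#'
#' @param fga fraction genome altered, in \[0, 1\].
#' @param n_called number of called segments (>= 0).
#' @param platform `"snp_array"` or `"lcwgs"`.
#' @param fga_cutoff FGA threshold (default 0.20).
#' @param casp8_mutated optional logical; required when
#'   `casp8_override = TRUE`.
#' @param casp8_override enable the CASP8-mutated shortcut (default off;
#'   the main classification is defined without it).
#' @return list with `label` (`"CNA_quiet"` or `"CNA_other"`),
#'   `rule_fired` (the single decision branch that produced the label) and
#'   `cutoffs_used` (`fga_cutoff`, `segment_cutoff`).
#' @export
classify_cna <- function(fga, n_called, platform = c("snp_array", "lcwgs"),
                         fga_cutoff = 0.20, casp8_mutated = NULL,
                         casp8_override = FALSE) {
  platform <- match.arg(platform)
  if (!is.finite(fga) || fga < 0 || fga > 1)
    stop("fga must be in [0, 1]")
  if (!is.finite(n_called) || n_called < 0)
    stop("n_called must be >= 0")
  seg_cutoff <- platform_segment_cutoff(platform)
  base_quiet <- fga < fga_cutoff && n_called < seg_cutoff
  if (casp8_override) {
    if (is.null(casp8_mutated) || is.na(casp8_mutated))
      stop("casp8_override requires casp8_mutated")
    if (isTRUE(casp8_mutated)) {
      label <- "CNA_quiet"; rule <- "casp8_override"
    } else if (base_quiet) {
      label <- "CNA_quiet"; rule <- "fga_and_segments_below_cutoff"
    } else {
      label <- "CNA_other"; rule <- "fga_or_segments_at_cutoff"
    }
  } else if (base_quiet) {
    label <- "CNA_quiet"; rule <- "fga_and_segments_below_cutoff"
  } else {
    label <- "CNA_other"; rule <- "fga_or_segments_at_cutoff"
  }
  list(label = label, rule_fired = rule,
       cutoffs_used = c(fga_cutoff = fga_cutoff,
                        segment_cutoff = seg_cutoff))
}

#' Classify a table of samples
#'
#' Vectorized convenience over [classify_cna()] for cohort tables.
#'
#' @param samples data.frame with columns `fga`, `n_called`, `platform`,
#'   and optionally `casp8_mutated`.
#' @inheritParams classify_cna
#' @return the input with a `label` column appended.
#' @export
classify_cohort <- function(samples, casp8_override = FALSE) {
  stopifnot(is.data.frame(samples),
            all(c("fga", "n_called", "platform") %in% names(samples)))
  samples$label <- vapply(seq_len(nrow(samples)), function(i) {
    classify_cna(samples$fga[i], samples$n_called[i], samples$platform[i],
                 casp8_mutated = samples$casp8_mutated[i] %||% NULL,
                 casp8_override = casp8_override)$label
  }, character(1))
  samples
}

#' FGA quartile-style category
#'
#' Bins the fraction genome altered into the four categories used to
#' explore mutation enrichment across the FGA distribution. Category edges
#' are \[0, 0.08), \[0.08, 0.20), \[0.20, 0.46\], (0.46, 1\]: the boundary
#' between the middle categories sits at 0.20 (consistent with the 0.20
#' classification cutoff) and 0.46 belongs to the third category.
#'
#' @param fga fraction(s) in \[0, 1\].
#' @return factor with levels `Q1`-`Q4`.
#' @export
fga_category <- function(fga) {
  if (any(!is.finite(fga) | fga < 0 | fga > 1))
    stop("fga must be in [0, 1]")
  cut(fga, breaks = c(-Inf, 0.08, 0.20, 0.46 + 1e-12, Inf),
      labels = c("Q1", "Q2", "Q3", "Q4"), right = FALSE)
}

#' Calibrate the segment-count cutoff to a new platform
#'
#' Rescales a reference platform's called-segment cutoff by the ratio of
#' mean called-segment counts observed on the two platforms, with half-up
#' rounding. With the SNP-array cutoff of 20 and mean counts of 48.3
#' (SNP array) versus 13.4 (lcWGS), this yields the lcWGS cutoff of 6.
#'
#' @param mean_ref mean called segments on the reference platform (> 0).
#' @param mean_new mean called segments on the new platform (> 0).
#' @param ref_cutoff reference cutoff (> 0).
#' @return integer cutoff for the new platform.
#' @export
calibrate_segment_cutoff <- function(mean_ref, mean_new, ref_cutoff) {
  if (any(c(mean_ref, mean_new, ref_cutoff) <= 0))
    stop("all inputs must be > 0")
  as.integer(floor(ref_cutoff * mean_new / mean_ref + 0.5))
}
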