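#' Run the copy-number pipeline on one sample
#'
#' Chains the per-sample stages: background subtraction against the panel
#' of normals, recursive binary segmentation, panel-based segment calling,
#' purity/ploidy fitting (grid fit, optionally blended with an external
#' estimate via [consensus_fit()], with a VAF fallback for profiles whose
#' copy-number signal cannot constrain the fit), conversion to absolute
#' copy numbers, altered-segment calling against the modal state, FGA, and
#' the final quiet/other classification.
#'
#' @param bins a [bin_profile()].
#' @param panel a [normal_panel()] on the same layout.
#' @param external_fit optional [purity_fit()] from an external tool.
#' @param variants optional [variant_table()] of filtered somatic variants
#'   used for the VAF purity fallback on copy-number-flat profiles.
#' @param grid a [fit_grid_spec()].
#' @param platform classification platform (default `"lcwgs"`).
#' @param abs_cutoff,alpha segment-calling rule (see
#'   [call_segments_pon()]).
#' @param min_size,threshold segmentation controls (see [segment_bins()]).
#' @return list with `segments` (called/altered [segment_profile()] with
#'   `abs_cn`), `fit`, `modal`, `n_called`, `fga_called`, `fga_altered`,
#'   and `classification` (from [classify_cna()], using the called-segment
#'   FGA as is standard for low-coverage WGS).
#' @export
run_sample_pipeline <- function(bins, panel, external_fit = NULL,
                                variants = NULL, grid = fit_grid_spec(),
                                platform = "lcwgs", abs_cutoff = 0.02,
                                alpha = 0.001, min_size = 3,
                                threshold = 5) {
  corrected <- subtract_background(bins, panel)
  segs <- segment_bins(corrected, min_size = min_size,
                       threshold = threshold)
  segs <- call_segments_pon(segs, panel, abs_cutoff = abs_cutoff,
                            alpha = alpha)
  fits <- fit_grid(segs, grid)
  fit <- if (isTRUE(attr(fits, "degenerate")) && !is.null(variants) &&
             nrow(variants) > 0) {
    purity_from_vaf(variants)
  } else if (!is.null(external_fit)) {
    consensus_fit(fits, external_fit)
  } else {
    best_fit(fits)
  }
  segs$segments$abs_cn <- absolute_cn(segs$segments$value, fit)
  modal <- modal_cn(segs, ploidy = fit$ploidy)
  segs <- call_altered(segs, modal)
  n_called <- sum(segs$segments$called)
  fga_called <- fga(segs, "called")
  fga_altered <- fga(segs, "altered")
  list(segments = segs, fit = fit, modal = modal, n_called = n_called,
       fga_called = fga_called, fga_altered = fga_altered,
       classification = classify_cna(fga_called, n_called,
                                     platform = platform))
}
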