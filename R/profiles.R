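#' Bin-level read-ratio profile
#'
#' Container for one sample's normalized read-depth track on a genome
#' layout. Ratios are linear and dimensionless (1 = the sample's typical
#' depth); `usable` marks bins that enter downstream analysis.
#'
#' @param sample_id sample identifier.
#' @param layout the `genome_layout` the bins tile.
#' @param bins data.frame with columns `chrom`, `start`, `end`, `ratio`
#'   and optionally `usable` (default all `TRUE`).
#' @return object of class `bin_profile`.
#' @export
bin_profile <- function(sample_id, layout, bins) {
  stopifnot(inherits(layout, "genome_layout"),
            is.data.frame(bins),
            all(c("chrom", "start", "end", "ratio") %in% names(bins)))
  if (is.null(bins$usable)) bins$usable <- TRUE
  bins$chrom <- as.character(bins$chrom)
  bins <- bins[order(match(bins$chrom, layout$chromosomes$name), bins$start), ]
  rownames(bins) <- NULL
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (any(b$end < b$start)) stop("bin with end < start on chromosome ", ch)
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)]))
      stop("overlapping bins on chromosome ", ch)
  }
  if (any(b_len <- (bins$end - bins$start + 1) > layout$bin_size))
    stop("bin wider than layout bin_size")
  bad <- bins$usable & (!is.finite(bins$ratio) | bins$ratio < 0)
  if (any(bad)) stop("usable bins must have finite ratio >= 0")
  structure(list(sample_id = as.character(sample_id),
                 layout = layout, bins = bins),
            class = "bin_profile")
}

#' @export
print.bin_profile <- function(x, ...) {
  cat(sprintf("<bin_profile> %s: %d bins (%d usable), median ratio %.3f\n",
              x$sample_id, nrow(x$bins), sum(x$bins$usable),
              stats::median(x$bins$ratio[x$bins$usable])))
  invisible(x)
}

#' Segment-level copy-number profile
#'
#' Segments partition the analyzed genome per chromosome; each carries a
#' mean relative signal (`value`, linear scale, 1 = sample average), the
#' number of supporting bins, a `called` flag (significant deviation from
#' the normal panel), and once purity/ploidy are known an absolute copy
#' number `abs_cn` and an `altered` flag (deviates from the modal state).
#'
#' @param sample_id sample identifier.
#' @param segments data.frame with columns `chrom`, `start`, `end`, `value`
#'   and optionally `n_bins`, `called`, `abs_cn`, `altered`. Extra columns
#'   are preserved.
#' @return object of class `segment_profile`.
#' @export
segment_profile <- function(sample_id, segments) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end", "value") %in% names(segments)))
  segments$chrom <- as.character(segments$chrom)
  n <- nrow(segments)
  if (is.null(segments$n_bins)) segments$n_bins <- rep(NA_integer_, n)
  if (is.null(segments$called)) segments$called <- rep(NA, n)
  if (is.null(segments$abs_cn)) segments$abs_cn <- rep(NA_real_, n)
  if (is.null(segments$altered)) segments$altered <- rep(NA, n)
  segments <- segments[order(match(segments$chrom, unique(segments$chrom)),
                             segments$start), ]
  rownames(segments) <- NULL
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (any(s$end < s$start))
      stop("segment with end < start on chromosome ", ch)
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments on chromosome ", ch)
  }
  structure(list(sample_id = as.character(sample_id), segments = segments),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  s <- x$segments
  cat(sprintf(
    "<segment_profile> %s: %d segments on %d chromosomes, %.3g Gb%s%s\n",
    x$sample_id, nrow(s), length(unique(s$chrom)),
    sum(segment_lengths(x)) / 1e9,
    if (!all(is.na(s$called))) sprintf(", %d called", sum(s$called, na.rm = TRUE)) else "",
    if (!all(is.na(s$altered))) sprintf(", %d altered", sum(s$altered, na.rm = TRUE)) else ""))
  invisible(x)
}

#' Genomic lengths of the segments of a profile
#' @param profile a `segment_profile`.
#' @return numeric vector of lengths in bp (1-based inclusive coordinates).
#' @export
segment_lengths <- function(profile) {
  stopifnot(inherits(profile, "segment_profile"))
  with(profile$segments, end - start + 1)
}

#' Purity/ploidy candidate solution
#'
#' @param purity tumor-cell fraction in (0, 1].
#' @param ploidy average tumor copy number, in \[1, 8\].
#' @param error non-negative fit score (0 for externally supplied fits).
#' @param source one of `"grid"` (in-package grid fit), `"external"`
#'   (e.g. an ABSOLUTE-style estimate supplied from outside), `"vaf"`
#'   (variant-allele-frequency based).
#' @return object of class `purity_fit`.
#' @export
purity_fit <- function(purity, ploidy, error = 0, source = "external") {
  stopifnot(length(purity) == 1, length(ploidy) == 1)
  if (!(is.finite(purity) && purity > 0 && purity <= 1))
    stop("purity must be in (0, 1]")
  if (!(is.finite(ploidy) && ploidy >= 1 && ploidy <= 8))
    stop("ploidy must be in [1, 8]")
  if (!(is.finite(error) && error >= 0)) stop("error must be >= 0")
  source <- match.arg(source, c("grid", "external", "vaf"))
  structure(list(purity = purity, ploidy = ploidy,
                 error = error, source = source),
            class = "purity_fit")
}

#' @export
print.purity_fit <- function(x, ...) {
  cat(sprintf("<purity_fit> purity %.2f, ploidy %.2f (error %.4g, %s)\n",
              x$purity, x$ploidy, x$error, x$source))
  invisible(x)
}
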