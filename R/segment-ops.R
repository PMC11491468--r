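#' Panel of normals for background modeling and segment calling
#'
#' Summarizes a set of normal-control bin profiles (e.g. FFPE-derived
#' normals) on a shared layout: per-bin mean and standard deviation of the
#' linear ratios, plus the two leading principal-component loadings of the
#' median-centered ratio matrix. The components capture recurrent
#' platform/FFPE background waves; their contribution is removed from tumor
#' profiles by [subtract_background()], and the per-bin spread drives
#' significance in [call_segments_pon()] and [segment_power()].
#'
#' @param ratios numeric matrix, samples in rows, bins in columns, matching
#'   `layout_bins(layout)` column order.
#' @param layout the shared [genome_layout()].
#' @return object of class `normal_panel` with elements `layout`, `bins`
#'   (data.frame `chrom`, `start`, `end`, `mean`, `sd`) and `components`
#'   (bins x 2 matrix, unit-norm columns).
#' @export
normal_panel <- function(ratios, layout) {
  stopifnot(is.matrix(ratios), inherits(layout, "genome_layout"))
  grid <- layout_bins(layout)
  if (ncol(ratios) != nrow(grid))
    stop("ratio matrix has ", ncol(ratios), " bins; layout tiles into ",
         nrow(grid))
  if (nrow(ratios) < 3) stop("need at least 3 normal samples")
  centered <- ratios - apply(ratios, 1, stats::median)
  pc <- stats::prcomp(centered, center = TRUE, scale. = FALSE)
  comp <- pc$rotation[, 1:2, drop = FALSE]
  comp <- sweep(comp, 2, sqrt(colSums(comp^2)), "/")
  sds <- apply(ratios, 2, stats::sd)
  if (any(sds <= 0)) sds[sds <= 0] <- max(sds, 1e-6)
  structure(list(layout = layout,
                 bins = cbind(grid, mean = colMeans(ratios), sd = sds),
                 components = comp,
                 n_samples = nrow(ratios)),
            class = "normal_panel")
}

#' @export
print.normal_panel <- function(x, ...) {
  cat(sprintf("<normal_panel> %d normals, %d bins, median SD %.4f\n",
              x$n_samples, nrow(x$bins), stats::median(x$bins$sd)))
  invisible(x)
}

#' Remove panel background components from a bin profile
#'
#' Projects the sample's median-centered ratios onto the panel's two
#' leading principal components and subtracts the projection, then
#' re-centers the profile to median 1. The projection coefficients are
#' fitted robustly, excluding bins deviating by more than 3 MADs from the
#' center: without this, a strong copy-number alteration (e.g. a
#' homozygous deletion in a high-purity tumor) leaks into the background
#' fit and smears component-shaped artifacts across the whole genome.
#' Signal orthogonal to the components is left untouched.
#'
#' @param bins a [bin_profile()] on the panel's layout.
#' @param panel a [normal_panel()].
#' @return a corrected [bin_profile()].
#' @export
subtract_background <- function(bins, panel) {
  stopifnot(inherits(bins, "bin_profile"), inherits(panel, "normal_panel"))
  if (!identical(bins$layout$chromosomes, panel$layout$chromosomes) ||
      bins$layout$bin_size != panel$layout$bin_size)
    stop("bin profile and panel are on different layouts")
  key <- function(d) paste(d$chrom, d$start)
  idx <- match(key(bins$bins), key(panel$bins))
  if (anyNA(idx)) stop("bin profile and panel bins do not align")
  r <- bins$bins$ratio
  x <- r - stats::median(r[bins$bins$usable])
  V <- panel$components[idx, , drop = FALSE]
  keep <- bins$bins$usable &
    abs(x) <= 3 * max(stats::mad(x[bins$bins$usable]), 1e-8)
  if (sum(keep) < 2 * ncol(V)) keep <- bins$bins$usable
  coef <- qr.coef(qr(V[keep, , drop = FALSE]), x[keep])
  coef[is.na(coef)] <- 0
  x <- x - as.numeric(V %*% coef)
  out <- bins
  out$bins$ratio <- x - stats::median(x[bins$bins$usable]) + 1
  out
}

#' Segment a bin profile by recursive change-point detection
#'
#' A deterministic change-point segmentation adequate at 500-kbp
#' resolution, in the style of circular binary segmentation: per
#' chromosome, every interior window is tested against its complement with
#' a two-sample mean difference normalized by the pooled standard
#' deviation; the strongest window is accepted as a segment when the
#' statistic exceeds `threshold` and all resulting pieces retain at least
#' `min_size` bins, and the pieces are scanned recursively. Testing
#' windows rather than single split points keeps chromosomes with several
#' alternating gains and losses segmentable (a single best split would
#' average them away). Segment value is the mean ratio of member bins.
#'
#' @param bins a [bin_profile()].
#' @param min_size minimum bins per segment (default 3).
#' @param threshold z-like statistic required to accept a change point
#'   (default 5).
#' @return a [segment_profile()] with `value` and `n_bins` set.
#' @export
segment_bins <- function(bins, min_size = 3, threshold = 5) {
  stopifnot(inherits(bins, "bin_profile"))
  b <- bins$bins[bins$bins$usable, , drop = FALSE]
  if (nrow(b) == 0) stop("no usable bins")
  # best interior window (a, b]: returns c(stat, a, b) or NULL
  best_window <- function(v) {
    n <- length(v)
    if (n < 2 * min_size) return(NULL)
    S <- c(0, cumsum(v)); S2 <- c(0, cumsum(v^2))
    a <- rep(0:(n - min_size), each = n)
    bnd <- rep(seq_len(n), n - min_size + 1)
    keep <- (bnd - a) >= min_size & (n - (bnd - a)) >= min_size &
      (a == 0 | a >= min_size) & (bnd == n | (n - bnd) >= min_size)
    a <- a[keep]; bnd <- bnd[keep]
    if (!length(a)) return(NULL)
    n_in <- bnd - a
    sum_in <- S[bnd + 1] - S[a + 1]
    m_in <- sum_in / n_in
    ss_in <- (S2[bnd + 1] - S2[a + 1]) - n_in * m_in^2
    n_out <- n - n_in
    m_out <- (S[n + 1] - sum_in) / n_out
    ss_out <- (S2[n + 1] - (S2[bnd + 1] - S2[a + 1])) - n_out * m_out^2
    # prefix-sum cancellation can leave tiny negative sums of squares
    sp2 <- pmax((ss_in + ss_out) / pmax(n - 2, 1), 0)
    d <- abs(m_in - m_out)
    stat <- ifelse(sp2 > 0, d / sqrt(sp2 * (1 / n_in + 1 / n_out)),
                   ifelse(d > 0, Inf, 0))
    i <- which.max(stat)
    c(stat[i], a[i], bnd[i])
  }
  # returns run lengths of the segmentation of v
  recurse <- function(v) {
    n <- length(v)
    w <- best_window(v)
    if (is.null(w) || w[1] <= threshold) return(n)
    a <- w[2]; bnd <- w[3]
    out <- integer(0)
    if (a > 0) out <- c(out, recurse(v[seq_len(a)]))
    out <- c(out, recurse(v[(a + 1):bnd]))
    if (bnd < n) out <- c(out, recurse(v[(bnd + 1):n]))
    out
  }
  pieces <- lapply(unique(b$chrom), function(ch) {
    cb <- b[b$chrom == ch, , drop = FALSE]
    sizes <- recurse(cb$ratio)
    stops <- cumsum(sizes)
    starts <- c(1, utils::head(stops, -1) + 1)
    data.frame(chrom = ch,
               start = cb$start[starts],
               end = cb$end[stops],
               value = vapply(seq_along(sizes), function(k)
                 mean(cb$ratio[starts[k]:stops[k]]), numeric(1)),
               n_bins = sizes)
  })
  segment_profile(bins$sample_id, do.call(rbind, pieces))
}

#' Call segments against a panel of normals
#'
#' A segment is called when it deviates from the panel both practically and
#' statistically: `|value - panel mean over its bins| > abs_cutoff` AND a
#' two-sided z-test of the segment mean against the panel distribution
#' (standard error = pooled panel SD / sqrt(n_bins)) rejects at `alpha`.
#' Segments with no panel coverage are excluded with a warning.
#'
#' @param segments a [segment_profile()].
#' @param panel a [normal_panel()].
#' @param abs_cutoff minimum absolute deviation on the linear ratio scale
#'   (default 0.02).
#' @param alpha significance level of the z-test (default 0.001,
#'   conservative so that flat profiles stay sparsely called).
#' @return the profile with `called` flags set (and panel deviation in
#'   column `panel_dev`).
#' @export
call_segments_pon <- function(segments, panel, abs_cutoff = 0.02,
                              alpha = 0.001) {
  stopifnot(inherits(segments, "segment_profile"),
            inherits(panel, "normal_panel"))
  s <- segments$segments
  dev <- se <- rep(NA_real_, nrow(s))
  for (i in seq_len(nrow(s))) {
    in_seg <- panel$bins$chrom == s$chrom[i] &
      panel$bins$start >= s$start[i] & panel$bins$end <= s$end[i]
    n <- sum(in_seg)
    if (n == 0) next
    dev[i] <- s$value[i] - mean(panel$bins$mean[in_seg])
    se[i] <- sqrt(mean(panel$bins$sd[in_seg]^2)) / sqrt(n)
  }
  uncovered <- is.na(dev)
  if (any(uncovered)) {
    warning(sum(uncovered), " segment(s) without panel coverage excluded")
    s <- s[!uncovered, , drop = FALSE]
    dev <- dev[!uncovered]; se <- se[!uncovered]
  }
  z <- dev / se
  s$called <- abs(dev) > abs_cutoff & 2 * stats::pnorm(-abs(z)) < alpha
  s$panel_dev <- dev
  segment_profile(segments$sample_id, s)
}

#' Absolute copy number implied by a relative signal
#'
#' Inverts the stromal dilution of the copy-number signal. The observed
#' linear relative value of a locus in a tumor of purity `p` and ploidy
#' `psi` mixed with diploid stroma is
#' `value = (p * cn + 2 * (1 - p)) / (p * psi + 2 * (1 - p))`, so
#' `cn = (value * (p * psi + 2 * (1 - p)) - 2 * (1 - p)) / p`. A value of 1
#' (the sample average) always maps to the ploidy. The mapping is affine
#' and strictly increasing in `value`; lower purity steepens the slope,
#' which is exactly why uncorrected low-purity profiles understate their
#' alterations.
#'
#' @param value linear relative signal(s), >= 0.
#' @param fit a [purity_fit()].
#' @return real-valued copy number(s).
#' @export
absolute_cn <- function(value, fit) {
  stopifnot(inherits(fit, "purity_fit"))
  p <- fit$purity
  if (p <= 0) stop("purity must be > 0")
  denom <- p * fit$ploidy + 2 * (1 - p)
  (value * denom - 2 * (1 - p)) / p
}

#' Expected relative signal of a copy-number state
#'
#' Inverse of [absolute_cn()]: the linear relative value at which a locus
#' of `cn` tumor copies is observed given a purity/ploidy fit.
#'
#' @param cn tumor copy number(s).
#' @param fit a [purity_fit()].
#' @return linear relative value(s).
#' @export
expected_value <- function(cn, fit) {
  stopifnot(inherits(fit, "purity_fit"))
  p <- fit$purity
  (p * cn + 2 * (1 - p)) / (p * fit$ploidy + 2 * (1 - p))
}

#' Modal copy number of a profile
#'
#' The integer copy state occupying the greatest total genomic length after
#' rounding each segment's absolute copy number to the nearest integer.
#' Ties are broken toward the state nearest the ploidy, defaulting the
#' modal state to the genome's average state when ambiguous.
#'
#' @param segments a [segment_profile()] with `abs_cn` set.
#' @param ploidy tie-break anchor (default 2).
#' @return integer copy number.
#' @export
modal_cn <- function(segments, ploidy = 2) {
  stopifnot(inherits(segments, "segment_profile"))
  s <- segments$segments
  if (nrow(s) == 0 || all(is.na(s$abs_cn)))
    stop("abs_cn must be set on the profile")
  cn <- pmax(0, round(s$abs_cn))
  tot <- tapply(segment_lengths(segments), cn, sum)
  states <- as.integer(names(tot))
  best <- states[tot == max(tot)]
  best[order(abs(best - ploidy), best)][1]
}

#' Flag altered segments
#'
#' A segment is altered when its purity/ploidy-adjusted copy number differs
#' by strictly more than 0.5 copies from the modal copy number of the
#' tumor. The boundary case (exactly 0.5 away) is not altered.
#'
#' @param segments a [segment_profile()] with `abs_cn` set.
#' @param modal modal copy number, e.g. from [modal_cn()].
#' @return the profile with `altered` flags set.
#' @export
call_altered <- function(segments, modal) {
  stopifnot(inherits(segments, "segment_profile"))
  segments$segments$altered <- abs(segments$segments$abs_cn - modal) > 0.5
  segments
}

#' Fraction genome altered
#'
#' Total genomic length of altered (or called) segments divided by the
#' total genomic length of all segments. `which = "altered"` is the
#' modal-state definition used when recalculating SNP-array FGA after
#' purity correction; `which = "called"` is the panel-of-normals definition
#' used for low-coverage WGS profiles.
#'
#' @param segments a [segment_profile()] with the relevant flags set.
#' @param which `"altered"` or `"called"`.
#' @return fraction in \[0, 1\].
#' @export
fga <- function(segments, which = c("altered", "called")) {
  which <- match.arg(which)
  stopifnot(inherits(segments, "segment_profile"))
  w <- segment_lengths(segments)
  if (sum(w) == 0) stop("profile has zero total length")
  flag <- segments$segments[[which]]
  if (all(is.na(flag))) stop(which, " flags not set")
  sum(w[flag %in% TRUE]) / sum(w)
}
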