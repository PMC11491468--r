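#' Purity/ploidy search grid
#'
#' @param purity_values ascending purity grid; default 0.05 to 1 in steps
#'   of 0.01.
#' @param ploidy_values ascending ploidy grid; default 1.5 to 5.5 in steps
#'   of 0.05, wide enough to cover whole-genome-doubled tumors.
#' @param penalty_weight reserved non-negative weight for pluggable error
#'   penalties (unused by the default RMS error).
#' @return object of class `fit_grid_spec`.
#' @export
fit_grid_spec <- function(purity_values = seq(0.05, 1, by = 0.01),
                          ploidy_values = seq(1.5, 5.5, by = 0.05),
                          penalty_weight = 0) {
  if (!length(purity_values) || !length(ploidy_values))
    stop("grids must be non-empty")
  if (is.unsorted(purity_values, strictly = TRUE) ||
      is.unsorted(ploidy_values, strictly = TRUE))
    stop("grid values must be strictly ascending")
  if (any(purity_values <= 0 | purity_values > 1))
    stop("purity grid must lie in (0, 1]")
  if (penalty_weight < 0) stop("penalty_weight must be >= 0")
  structure(list(purity_values = purity_values,
                 ploidy_values = ploidy_values,
                 penalty_weight = penalty_weight),
            class = "fit_grid_spec")
}

#' Goodness-of-fit error of a purity/ploidy hypothesis
#'
#' Converts each segment's linear relative value to the absolute copy
#' number implied by `(purity, ploidy)` (see [absolute_cn()]) and scores
#' the hypothesis by the length-weighted root-mean-square distance of those
#' copy numbers to their nearest non-negative integers. A perfect fit — all
#' segments landing on integer copies — scores 0.
#'
#' @param segments a [segment_profile()] with linear-scale values.
#' @param purity tumor-cell fraction in (0, 1].
#' @param ploidy average tumor copy number.
#' @return non-negative fit error.
#' @export
fit_error <- function(segments, purity, ploidy) {
  stopifnot(inherits(segments, "segment_profile"))
  if (nrow(segments$segments) == 0) stop("empty segment profile")
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  cn <- absolute_cn(segments$segments$value,
                    purity_fit(purity, ploidy, source = "grid"))
  d <- cn - pmax(0, round(cn))
  w <- segment_lengths(segments)
  sqrt(sum(w * d^2) / sum(w))
}

#' Exhaustive grid fit of purity and ploidy
#'
#' Evaluates [fit_error()] on every grid point and returns all candidates
#' ranked by error, ties broken toward higher purity then lower ploidy
#' (favoring the most parsimonious explanation of a diluted profile). A
#' profile with essentially no copy-number variation cannot constrain the
#' fit; such results carry `attr(, "degenerate") = TRUE` and purity should
#' then come from [purity_from_vaf()].
#'
#' @param segments a [segment_profile()] with linear-scale values.
#' @param grid a [fit_grid_spec()].
#' @return data.frame of class `fit_grid_result` with columns `purity`,
#'   `ploidy`, `error`, sorted best-first.
#' @export
fit_grid <- function(segments, grid = fit_grid_spec()) {
  stopifnot(inherits(grid, "fit_grid_spec"))
  pts <- expand.grid(purity = grid$purity_values,
                     ploidy = grid$ploidy_values)
  # vectorized evaluation of fit_error over the whole grid
  stopifnot(inherits(segments, "segment_profile"))
  if (nrow(segments$segments) == 0) stop("empty segment profile")
  w <- segment_lengths(segments)
  w <- w / sum(w)
  v <- segments$segments$value
  denom <- pts$purity * pts$ploidy + 2 * (1 - pts$purity)
  cn <- outer(denom, v) - 2 * (1 - pts$purity)   # points x segments
  cn <- cn / pts$purity
  d <- cn - pmax(0, round(cn))
  pts$error <- sqrt(as.numeric(d^2 %*% w))
  pts <- pts[order(pts$error, -pts$purity, pts$ploidy), ]
  rownames(pts) <- NULL
  w <- segment_lengths(segments)
  v <- segments$segments$value
  m <- sum(w * v) / sum(w)
  spread <- sqrt(sum(w * (v - m)^2) / sum(w))
  attr(pts, "degenerate") <- spread < 1e-8
  class(pts) <- c("fit_grid_result", class(pts))
  pts
}

#' Top candidate of a grid fit as a purity_fit
#' @param fits a `fit_grid_result` from [fit_grid()].
#' @return a [purity_fit()] with `source = "grid"`.
#' @export
best_fit <- function(fits) {
  purity_fit(fits$purity[1], fits$ploidy[1], fits$error[1], source = "grid")
}

#' Distance between two purity/ploidy fits
#'
#' The consensus distance is the Euclidean distance in the
#' (purity, ploidy / sqrt(5)) plane:
#' `sqrt((purity_a - purity_b)^2 + (ploidy_a - ploidy_b)^2 / 5)`.
#' The division by 5 down-weights the ploidy difference so that its
#' contribution is in balance with the purity difference.
#'
#' @param fit_a,fit_b [purity_fit()] objects.
#' @return non-negative distance.
#' @export
consensus_distance <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "purity_fit"), inherits(fit_b, "purity_fit"))
  sqrt((fit_a$purity - fit_b$purity)^2 +
         (fit_a$ploidy - fit_b$ploidy)^2 / 5)
}

#' Consensus fit between grid candidates and an external estimate
#'
#' Re-ranks grid candidates by a corrected error
#' `error * (1 + consensus_distance(candidate, external))` and returns the
#' minimizer (ties as in [fit_grid()]). The external fit is typically an
#' ABSOLUTE-style purity/ploidy estimate supplied from outside the package.
#' The multiplicative `1 + distance` correction is monotone in the distance
#' and leaves the ranking untouched when a candidate agrees exactly with
#' the external estimate.
#'
#' @param candidates a `fit_grid_result` (or data.frame with `purity`,
#'   `ploidy`, `error`).
#' @param external a [purity_fit()].
#' @return the selected candidate as a [purity_fit()] with
#'   `source = "grid"`; its `error` is the corrected error.
#' @export
consensus_fit <- function(candidates, external) {
  stopifnot(inherits(external, "purity_fit"))
  if (is.null(nrow(candidates)) || nrow(candidates) == 0)
    stop("no candidates")
  d <- sqrt((candidates$purity - external$purity)^2 +
              (candidates$ploidy - external$ploidy)^2 / 5)
  corrected <- candidates$error * (1 + d)
  ord <- order(corrected, -candidates$purity, candidates$ploidy)
  i <- ord[1]
  purity_fit(candidates$purity[i], candidates$ploidy[i], corrected[i],
             source = "grid")
}

#' Purity from somatic variant allele frequencies
#'
#' For tumors without usable copy-number signal, purity is estimated from
#' somatic VAFs under the assumption of heterozygous single-copy variants
#' in a diploid genome: a clonal variant then has VAF = purity / 2. The
#' 90th-percentile VAF is used rather than the maximum, which is robust to
#' subclonal variants while not being inflated by sampling noise at the
#' highest-VAF site.
#'
#' @param variants a data.frame of variant calls with columns `vaf` and
#'   `depth` (see [filter_variants()]), or a bare numeric vector of VAFs.
#' @param quantile_level quantile of the VAF distribution used; default 0.9.
#' @return a [purity_fit()] with `ploidy = 2` and `source = "vaf"`.
#' @export
purity_from_vaf <- function(variants, quantile_level = 0.9) {
  vaf <- if (is.data.frame(variants)) {
    if (!is.null(variants$depth) && any(variants$depth <= 0))
      stop("variants must have depth > 0")
    variants$vaf
  } else {
    as.numeric(variants)
  }
  if (length(vaf) == 0 || all(is.na(vaf)))
    stop("purity indeterminate: no somatic variants")
  p <- min(1, 2 * stats::quantile(vaf, quantile_level, names = FALSE,
                                  na.rm = TRUE))
  purity_fit(p, 2, 0, source = "vaf")
}
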