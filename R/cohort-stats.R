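#' Pearson chi-squared test on a contingency table
#'
#' Thin, explicit wrapper around [stats::chisq.test()] for cohort
#' characteristic tables. Continuity (Yates) correction applies to 2x2
#' tables only and defaults to on for those; for larger tables it is off
#' and ignored. Unknown categories are expected to be excluded upstream.
#'
#' @param counts matrix of non-negative counts, at least 2x2.
#' @param yates apply the continuity correction (2x2 only)? Default `TRUE`
#'   for 2x2 tables. Always reported explicitly in the result.
#' @return list with `statistic`, `df`, `p`, `yates`.
#' @export
chi_squared <- function(counts, yates = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("table must be at least 2x2")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in table")
  is2x2 <- nrow(counts) == 2 && ncol(counts) == 2
  if (is.null(yates)) yates <- is2x2
  res <- suppressWarnings(
    stats::chisq.test(counts, correct = yates && is2x2))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, yates = yates && is2x2)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!(nrow(counts) == 2 && ncol(counts) == 2))
    stop("fisher_exact requires a 2x2 table")
  stats::fisher.test(counts, alternative = "two.sided")$p.value
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values (step-up procedure), elementwise >= raw.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration is used for small samples (both sizes <= 8, no ties);
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U` statistic (for `x` versus `y`) and two-sided `p`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  use_exact <- length(x) <= 8 && length(y) <= 8 &&
    !any(duplicated(c(x, y)))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(U = unname(res$statistic), p = res$p.value)
}

#' Kaplan-Meier curves with log-rank test and hazard ratio
#'
#' Fits product-limit survival curves for two groups with follow-up
#' administratively censored at `horizon` (e.g. 60 months for a 5-year
#' analysis), tests the difference by the log-rank test, and reports the
#' hazard ratio of the first group versus the second from the log-rank
#' observed/expected events: `HR = (O1/E1) / (O2/E2)`.
#'
#' @param data data.frame with columns `time` (months, >= 0), `event`
#'   (logical or 0/1) and `group` (two levels; the first factor level is
#'   the HR numerator).
#' @param horizon truncation time in months (default 60).
#' @return list with `fit` (a [survival::survfit()] object), `logrank_p`,
#'   `hazard_ratio`, `observed`, `expected`.
#' @export
km_logrank <- function(data, horizon = 60) {
  stopifnot(is.data.frame(data),
            all(c("time", "event", "group") %in% names(data)))
  if (any(data$time < 0)) stop("negative survival time")
  grp <- factor(data$group)
  if (nlevels(grp) != 2) stop("exactly two groups required")
  if (any(table(grp) == 0)) stop("empty group")
  over <- data$time > horizon
  data$event[over] <- FALSE
  data$time[over] <- horizon
  if (!any(data$event)) stop("no events within the horizon")
  sv <- survival::Surv(data$time, as.integer(data$event))
  fit <- survival::survfit(sv ~ grp)
  sd <- survival::survdiff(sv ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  hr <- (sd$obs[1] / sd$exp[1]) / (sd$obs[2] / sd$exp[2])
  list(fit = fit, logrank_p = p, hazard_ratio = unname(hr),
       observed = unname(sd$obs), expected = unname(sd$exp))
}
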