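#' MLPA probe set definition
#'
#' @param probes data.frame with columns `probe_id`, `region_id`, `role`
#'   (`"classification"` or `"reference"`).
#' @param region_threshold named integer vector mapping region to the
#'   minimum number of same-direction aberrant probes required to score the
#'   region as changed (>= 2).
#' @return object of class `mlpa_probeset`.
#' @export
mlpa_probeset <- function(probes, region_threshold) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "region_id", "role") %in% names(probes)))
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe ids")
  if (!all(probes$role %in% c("classification", "reference")))
    stop("role must be classification or reference")
  regions <- unique(probes$region_id[probes$role == "classification"])
  if (!all(regions %in% names(region_threshold)))
    stop("missing region threshold(s): ",
         paste(setdiff(regions, names(region_threshold)), collapse = ", "))
  if (any(region_threshold < 2)) stop("region thresholds must be >= 2")
  structure(list(probes = probes,
                 region_threshold = region_threshold[regions]),
            class = "mlpa_probeset")
}

#' Default head-and-neck MLPA probe set
#'
#' Ten classification regions in loci most frequently gained or lost in
#' HPV-negative head and neck squamous cell carcinoma — 2q36 (CUL3), 3q26
#' (PIK3CA/SOX2), 4q35 (FAT1), 5q15 (KIAA0825), 7p11 (EGFR), 8q11 (SNAI2),
#' 9p22 (NFIB), 11q13 (CCND1/FADD), 18p11 (TGIF1), 20q11 (BCL2L1) —
#' covered by 36 classification probes, plus 13 reference probes in
#' regions least frequently copy-number changed. 3q26 and 11q13 carry four
#' probes and require three aberrant probes to score; every other region
#' requires two. The exact probe-to-region multiplicities within the 36 are
#' a bundled convention (4 or 3 probes per region).
#'
#' @return an [mlpa_probeset()].
#' @export
default_mlpa_probeset <- function() {
  n_probes <- c("2q36" = 4, "3q26" = 4, "4q35" = 4, "5q15" = 3,
                "7p11" = 4, "8q11" = 3, "9p22" = 4, "11q13" = 4,
                "18p11" = 3, "20q11" = 3)
  stopifnot(sum(n_probes) == 36)
  cls <- do.call(rbind, lapply(names(n_probes), function(r) {
    data.frame(probe_id = sprintf("%s_p%d", r, seq_len(n_probes[[r]])),
               region_id = r, role = "classification")
  }))
  ref <- data.frame(probe_id = sprintf("ref_p%02d", 1:13),
                    region_id = "reference", role = "reference")
  thresholds <- ifelse(names(n_probes) %in% c("3q26", "11q13"), 3L, 2L)
  names(thresholds) <- names(n_probes)
  mlpa_probeset(rbind(cls, ref), thresholds)
}

#' Read a probe-set definition file
#'
#' Tab-separated file with columns `probe_id`, `region_id`, `role` and
#' optionally `threshold` (per classification region; default 2).
#'
#' @param path path to the TSV.
#' @return an [mlpa_probeset()].
#' @export
read_mlpa_probeset <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  cls <- raw[raw$role == "classification", ]
  thr <- if ("threshold" %in% names(raw)) {
    vapply(split(cls$threshold, cls$region_id), function(x)
      as.integer(x[1]), integer(1))
  } else {
    regions <- unique(cls$region_id)
    stats::setNames(rep(2L, length(regions)), regions)
  }
  mlpa_probeset(raw[, c("probe_id", "region_id", "role")], thr)
}

#' MLPA sample with normalized probe ratios
#'
#' @param sample_id sample identifier.
#' @param probe_ratios named numeric vector of normalized probe ratios
#'   (1.0 = diploid); must be finite and > 0.
#' @return object of class `mlpa_sample`.
#' @export
mlpa_sample <- function(sample_id, probe_ratios) {
  if (is.null(names(probe_ratios)) || any(!nzchar(names(probe_ratios))))
    stop("probe_ratios must be named by probe id")
  if (any(!is.finite(probe_ratios) | probe_ratios <= 0))
    stop("probe ratios must be finite and > 0")
  structure(list(sample_id = as.character(sample_id),
                 probe_ratios = probe_ratios),
            class = "mlpa_sample")
}

#' Normalize raw MLPA peak intensities
#'
#' Intra-sample normalization divides each probe's intensity by the
#' geometric mean of the sample's reference probes; inter-sample
#' normalization divides by the median of the same quantity across the
#' reference (healthy control) samples, so a copy-neutral probe lands at
#' ratio 1.
#'
#' @param raw named numeric vector of peak intensities for one sample.
#' @param reference_samples list of named intensity vectors from normal
#'   reference samples (>= 1).
#' @param probeset an [mlpa_probeset()].
#' @param sample_id sample name.
#' @return an [mlpa_sample()] with ratios for all probes in the set.
#' @export
normalize_probes <- function(raw, reference_samples, probeset,
                             sample_id = "sample") {
  stopifnot(inherits(probeset, "mlpa_probeset"), length(reference_samples) >= 1)
  ref_ids <- probeset$probes$probe_id[probeset$probes$role == "reference"]
  all_ids <- probeset$probes$probe_id
  check <- function(x, who) {
    if (!all(ref_ids %in% names(x)))
      stop("missing reference probe(s) in ", who, ": ",
           paste(setdiff(ref_ids, names(x)), collapse = ", "))
    if (any(x[names(x) %in% all_ids] <= 0))
      stop("zero or negative intensity in ", who)
  }
  check(raw, "sample")
  for (i in seq_along(reference_samples))
    check(reference_samples[[i]], paste0("reference sample ", i))
  geo <- function(x) exp(mean(log(x)))
  intra <- function(x) x[all_ids[all_ids %in% names(x)]] / geo(x[ref_ids])
  sample_q <- intra(raw)
  ref_q <- vapply(reference_samples, function(x) intra(x)[names(sample_q)],
                  numeric(length(sample_q)))
  ref_med <- if (is.matrix(ref_q)) apply(ref_q, 1, stats::median) else ref_q
  mlpa_sample(sample_id, sample_q / ref_med)
}

#' Score one MLPA region
#'
#' A probe is aberrant when its ratio falls strictly outside the normal
#' range 0.7-1.3 (boundary values count as normal). A region scores as
#' gained (lost) when at least `threshold` probes are increased
#' (decreased); whenever at least one aberrant probe points the opposite
#' way, one extra same-direction probe is required, applied symmetrically
#' to gains and losses. If both directions still qualify, the direction
#' with more aberrant probes wins; an exact tie scores normal.
#'
#' @param ratios numeric vector of probe ratios for the region.
#' @param threshold minimum aberrant probes (default 2).
#' @return `"gain"`, `"loss"` or `"normal"`.
#' @export
score_region <- function(ratios, threshold = 2) {
  if (length(ratios) == 0) stop("empty ratio list")
  g <- sum(ratios > 1.3)
  l <- sum(ratios < 0.7)
  t_gain <- threshold + (l >= 1)
  t_loss <- threshold + (g >= 1)
  gain_ok <- g >= t_gain
  loss_ok <- l >= t_loss
  if (gain_ok && loss_ok) {
    if (g > l) "gain" else if (l > g) "loss" else "normal"
  } else if (gain_ok) "gain" else if (loss_ok) "loss" else "normal"
}

#' MLPA pre-screen decision
#'
#' Scores every classification region of the probe set and counts regions
#' called gained or lost. More than two changed regions yields
#' `definitive_other` — such samples need no further copy-number workup;
#' two or fewer yields `quiet_candidate`, to be resolved by genome-wide
#' profiling (changes may lie outside the probed regions, or purity may be
#' too low for probes to leave the normal range).
#'
#' @param sample an [mlpa_sample()] covering all probes of the set.
#' @param probeset an [mlpa_probeset()].
#' @return list with `call` (`"definitive_other"` or `"quiet_candidate"`),
#'   `n_changed`, and `regions` (data.frame `region_id`, `call`).
#' @export
prescreen <- function(sample, probeset) {
  stopifnot(inherits(sample, "mlpa_sample"),
            inherits(probeset, "mlpa_probeset"))
  cls <- probeset$probes[probeset$probes$role == "classification", ]
  missing_p <- setdiff(cls$probe_id, names(sample$probe_ratios))
  if (length(missing_p))
    stop("missing probe(s): ", paste(missing_p, collapse = ", "))
  regions <- names(probeset$region_threshold)
  calls <- vapply(regions, function(r) {
    ids <- cls$probe_id[cls$region_id == r]
    score_region(sample$probe_ratios[ids], probeset$region_threshold[[r]])
  }, character(1))
  n_changed <- sum(calls != "normal")
  list(call = if (n_changed > 2) "definitive_other" else "quiet_candidate",
       n_changed = n_changed,
       regions = data.frame(region_id = regions, call = unname(calls)))
}
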