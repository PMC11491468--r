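#' Construct a somatic-variant call table
#'
#' Builds (and validates) the annotated variant table the filtering, copy
#' linkage and power machinery operates on. One row per candidate variant.
#'
#' @param df data.frame with columns `gene`, `chrom`, `pos`, `ref`, `alt`,
#'   `vaf`, `depth`, `alt_reads`, `caller_a`, `caller_b`, `consequence`
#'   (one of missense, truncating, silent, intronic, utr, promoter,
#'   splice, inframe), and optionally `population_af`, `dbsnp_common`,
#'   `pon_count`, `cosmic_confirmed_somatic` (defaulted to benign values
#'   when absent).
#' @return validated data.frame of class `variant_table`.
#' @export
variant_table <- function(df) {
  need <- c("gene", "chrom", "pos", "ref", "alt", "vaf", "depth",
            "alt_reads", "caller_a", "caller_b", "consequence")
  stopifnot(is.data.frame(df))
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$population_af)) df$population_af <- NA_real_
  if (is.null(df$dbsnp_common)) df$dbsnp_common <- FALSE
  if (is.null(df$pon_count)) df$pon_count <- 0L
  if (is.null(df$cosmic_confirmed_somatic)) df$cosmic_confirmed_somatic <- FALSE
  ok <- c("missense", "truncating", "silent", "intronic", "utr",
          "promoter", "splice", "inframe")
  if (!all(df$consequence %in% ok))
    stop("unknown consequence value(s): ",
         paste(setdiff(df$consequence, ok), collapse = ", "))
  if (any(df$alt_reads > df$depth)) stop("alt_reads exceeds depth")
  class(df) <- c("variant_table", class(df))
  df
}

#' Filter candidate somatic variants
#'
#' Applies the somatic-variant retention rules: a variant must be called
#' by both callers, have VAF >= 0.02 and at least 3 supporting reads;
#' likely germline variants (population allele frequency >= 0.01, flagged
#' common in dbSNP, or seen in more than 5 panel-of-normals cases) are
#' removed unless previously confirmed somatic in COSMIC; intronic, silent
#' and UTR variants are removed, with the exception of TERT promoter and
#' TP53 5'-UTR records. Output is always a subset of the input and the
#' filter is idempotent.
#'
#' @param variants a [variant_table()] (or coercible data.frame).
#' @param min_vaf minimum VAF (default 0.02).
#' @param min_alt_reads minimum supporting reads (default 3).
#' @return the retained rows.
#' @export
filter_variants <- function(variants, min_vaf = 0.02, min_alt_reads = 3) {
  v <- variant_table(as.data.frame(variants))
  keep_call <- v$caller_a & v$caller_b &
    v$vaf >= min_vaf & v$alt_reads >= min_alt_reads
  germline <- (ifelse(is.na(v$population_af), 0, v$population_af) >= 0.01) |
    v$dbsnp_common | (v$pon_count > 5)
  keep_germ <- !germline | v$cosmic_confirmed_somatic
  noncoding <- v$consequence %in% c("intronic", "silent", "utr")
  rescue <- (v$gene == "TERT" & v$consequence == "promoter") |
    (v$gene == "TP53" & v$consequence == "utr")
  keep_cons <- !noncoding | rescue
  out <- v[keep_call & keep_germ & keep_cons, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected variant allele frequency
#'
#' VAF expected for a variant on `variant_copies` of the
#' `tumor_total_copies` at its locus in a tumor of the given purity, with
#' diploid stroma. Somatic variants contribute only tumor alleles:
#' `p*m / (p*C + 2*(1-p))`. Germline variants additionally carry
#' `m_stroma` stromal allele(s) (1 for a heterozygous carrier):
#' `(p*m + m_stroma*(1-p)) / (p*C + 2*(1-p))`.
#'
#' @param purity tumor-cell fraction in (0, 1].
#' @param variant_copies tumor copies carrying the variant (m >= 0).
#' @param tumor_total_copies total tumor copies at the locus (C >= m).
#' @param germline logical; is the variant present in the stroma?
#' @param m_stroma stromal variant alleles per cell for germline variants
#'   (1 = heterozygous, 2 = homozygous).
#' @return expected VAF.
#' @export
expected_vaf <- function(purity, variant_copies, tumor_total_copies,
                         germline = FALSE, m_stroma = 1) {
  if (any(purity <= 0)) stop("purity must be > 0")
  if (any(tumor_total_copies < variant_copies))
    stop("variant_copies cannot exceed tumor_total_copies")
  denom <- purity * tumor_total_copies + 2 * (1 - purity)
  num <- purity * variant_copies +
    ifelse(germline, m_stroma * (1 - purity), 0)
  num / denom
}

#' Link a variant to its most likely copy configuration
#'
#' Enumerates variant copy counts m in 0..round(local_cn) under somatic
#' and germline (heterozygous and homozygous stroma) models, scoring each
#' by the distance between expected and observed VAF in units of the
#' binomial standard deviation at the variant's depth. Exact ties are
#' broken toward m = 1 (the single-copy clonal model) and then toward the
#' somatic model.
#'
#' @param vaf observed variant allele frequency.
#' @param depth sequencing depth (> 0).
#' @param local_cn total tumor copy number at the locus.
#' @param fit a [purity_fit()].
#' @return list with `m` (best variant copy count), `model` (`"somatic"`
#'   or `"germline"`), `m_stroma` (0, 1 or 2) and `residual`
#'   (`|expected - observed|` VAF).
#' @export
link_variant_copies <- function(vaf, depth, local_cn, fit) {
  stopifnot(inherits(fit, "purity_fit"))
  if (depth <= 0) stop("depth must be > 0")
  cand <- expand.grid(m = 0:max(0, round(local_cn)),
                      m_stroma = c(0, 1, 2))
  cand$evaf <- expected_vaf(fit$purity, cand$m, max(local_cn, cand$m),
                            germline = cand$m_stroma > 0,
                            m_stroma = cand$m_stroma)
  sd <- pmax(sqrt(cand$evaf * (1 - cand$evaf) / depth), 1e-9)
  cand$score <- abs(cand$evaf - vaf) / sd
  # ties -> m = 1 first, then somatic (m_stroma 0) over germline
  ord <- order(round(cand$score, 9), abs(cand$m - 1), cand$m_stroma)
  i <- ord[1]
  list(m = cand$m[i],
       model = if (cand$m_stroma[i] > 0) "germline" else "somatic",
       m_stroma = cand$m_stroma[i],
       residual = abs(cand$evaf[i] - vaf))
}

#' Power to call a single-copy gain or loss on a segment
#'
#' Under the panel-of-normals call rule (absolute deviation above
#' `abs_cutoff` AND two-sided z-test at `alpha` with standard error
#' `panel_sd / sqrt(n_bins)`), computes the probability that a segment
#' carrying one extra (or one fewer) copy in all tumor cells is called.
#' The expected deviation of a single-copy event on the linear relative
#' scale is `p / (p * ploidy + 2 * (1 - p))`; the observed segment mean is
#' modeled as normal around it. The minimum of the gain and loss powers is
#' returned (conservative; the two coincide under the symmetric normal
#' model).
#'
#' @param purity tumor-cell fraction in (0, 1].
#' @param ploidy average tumor copy number (default 2).
#' @param panel_sd per-bin panel standard deviation over the segment.
#' @param n_bins bins supporting the segment.
#' @param abs_cutoff,alpha the segment-calling rule (defaults as in
#'   [call_segments_pon()]).
#' @return power in \[0, 1\].
#' @export
segment_power <- function(purity, ploidy = 2, panel_sd, n_bins,
                          abs_cutoff = 0.02, alpha = 0.001) {
  stopifnot(purity > 0, purity <= 1, panel_sd > 0, n_bins > 0)
  d <- purity / (purity * ploidy + 2 * (1 - purity))
  se <- panel_sd / sqrt(n_bins)
  zcrit <- stats::qnorm(1 - alpha / 2)
  thr <- max(abs_cutoff, zcrit * se)
  p_gain <- stats::pnorm((d - thr) / se)
  p_loss <- stats::pnorm((d - thr) / se)  # symmetric single-copy loss
  min(p_gain, p_loss)
}

#' Length-weighted fraction of the genome with adequate calling power
#'
#' @param per_segment_power numeric vector of per-segment powers.
#' @param segment_lengths matching vector of genomic lengths.
#' @param power_threshold per-segment power required (default 0.8).
#' @return fraction of total genomic length with power above threshold.
#' @export
genome_power_fraction <- function(per_segment_power, segment_lengths,
                                  power_threshold = 0.8) {
  if (length(per_segment_power) != length(segment_lengths))
    stop("power and length vectors differ in length")
  sum(segment_lengths[per_segment_power > power_threshold]) /
    sum(segment_lengths)
}

#' Power to call a variant at a locus
#'
#' The calling threshold in supporting reads is the largest of (i) the
#' smallest read count whose probability under the sequencing-error
#' binomial falls below `alpha_noise`, (ii) the 3-read minimum, and
#' (iii) the 2% minimum VAF at the local depth. Power is the binomial
#' upper-tail probability of reaching that threshold at the expected VAF.
#'
#' @param depth local sequencing depth (>= 0).
#' @param expected_vaf expected variant allele frequency
#'   (see [expected_vaf()]).
#' @param error_rate per-base sequencing error rate (default 0.001).
#' @param alpha_noise per-locus false-call probability allowed under the
#'   error model (default 1e-4).
#' @return power in \[0, 1\].
#' @export
variant_power <- function(depth, expected_vaf, error_rate = 0.001,
                          alpha_noise = 1e-4) {
  stopifnot(depth >= 0, expected_vaf >= 0, expected_vaf <= 1,
            error_rate >= 0, error_rate <= 1)
  if (depth == 0) return(0)
  # smallest k with P(Binom(depth, error_rate) >= k) < alpha_noise
  k_noise <- stats::qbinom(alpha_noise, depth, error_rate,
                           lower.tail = FALSE) + 1
  while (k_noise > 1 &&
         stats::pbinom(k_noise - 2, depth, error_rate,
                       lower.tail = FALSE) < alpha_noise)
    k_noise <- k_noise - 1
  k_call <- max(k_noise, 3, ceiling(0.02 * depth))
  stats::pbinom(k_call - 1, depth, expected_vaf, lower.tail = FALSE)
}

#' Sample-level QC decision
#'
#' A sample passes QC when its purity is at least 0.10 and more than 80%
#' of the genome has over 80% power to call a single-copy event.
#'
#' @param fit a [purity_fit()].
#' @param genome_power_fraction fraction of the genome with per-segment
#'   power above 0.8 (see [genome_power_fraction()]).
#' @param min_purity purity gate (default 0.10).
#' @param min_genome_fraction required powered genome fraction
#'   (default 0.80; the gate is strict: the fraction must exceed it).
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed gates, empty when passing).
#' @export
qc_sample <- function(fit, genome_power_fraction, min_purity = 0.10,
                      min_genome_fraction = 0.80) {
  stopifnot(inherits(fit, "purity_fit"))
  reasons <- character(0)
  if (fit$purity < min_purity) reasons <- c(reasons, "purity")
  if (genome_power_fraction <= min_genome_fraction)
    reasons <- c(reasons, "power")
  list(pass = length(reasons) == 0, reasons = reasons)
}
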