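#' Simulation configuration
#'
#' One object that fixes every knob of the synthetic-data generators. The
#' same configuration (including seed) always produces identical output.
#' The generators emulate the statistical structure of the pipeline's real
#' inputs: an integer-copy tumor clone mixed with diploid stroma at the
#' given purity, multiplicative lognormal bin noise, an additive FFPE-like
#' background built from two fixed genome-wide sinusoidal components,
#' MLPA probe ratios from the same mixture algebra, binomial variant read
#' counts at purity-determined expected VAFs, and cohort tables with
#' group-dependent covariate distributions and exponential survival.
#'
#' @param seed integer random seed.
#' @param layout a [genome_layout()] (default [toy_layout()]).
#' @param purity tumor-cell fraction in (0, 1].
#' @param ploidy average tumor copy number (the unaltered state).
#' @param n_events number of copy-number events in the clone.
#' @param event_size_range event genomic size range in bp.
#' @param event_bias list with `gain_chrom` / `loss_chrom` chromosome
#'   names that attract gains/losses at triple weight, echoing the
#'   characteristic 3q/8q gain and 3p/8p loss pattern of HPV-negative
#'   head and neck tumors.
#' @param bin_noise_sd lognormal sigma of per-bin multiplicative noise.
#' @param ffpe_wave_amplitude SD of the per-sample coefficients on the two
#'   background components.
#' @param mlpa_noise_sd lognormal sigma of MLPA probe noise.
#' @param depth sequencing depth for simulated variants.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, layout = toy_layout(), purity = 0.6,
                       ploidy = 2, n_events = 8,
                       event_size_range = c(2e6, 1e7),
                       event_bias = list(gain_chrom = c("3", "8"),
                                         loss_chrom = c("3", "8")),
                       bin_noise_sd = 0.05, ffpe_wave_amplitude = 0.02,
                       mlpa_noise_sd = 0.05, depth = 500) {
  stopifnot(inherits(layout, "genome_layout"),
            purity > 0, purity <= 1, ploidy >= 1,
            n_events >= 0, bin_noise_sd >= 0, mlpa_noise_sd >= 0)
  structure(list(seed = as.integer(seed), layout = layout, purity = purity,
                 ploidy = ploidy, n_events = n_events,
                 event_size_range = event_size_range,
                 event_bias = event_bias, bin_noise_sd = bin_noise_sd,
                 ffpe_wave_amplitude = ffpe_wave_amplitude,
                 mlpa_noise_sd = mlpa_noise_sd, depth = depth),
            class = "sim_config")
}

# two fixed genome-wide background components (unit-norm over the bins)
ffpe_wave_components <- function(n_bins) {
  i <- seq_len(n_bins)
  w <- cbind(sin(2 * pi * i / 47), cos(2 * pi * i / 31))
  sweep(w, 2, sqrt(colSums(w^2)), "/") * sqrt(n_bins)  # ~unit amplitude
}

#' Simulate a tumor bin profile with known truth
#'
#' Draws an integer-copy clone (baseline state `round(ploidy)` plus
#' `n_events` non-overlapping gain/loss events), dilutes it with diploid
#' stroma at the configured purity, and observes each 500-kb bin with
#' multiplicative lognormal noise plus the additive FFPE background wave.
#' The generating segment profile is returned alongside for oracle
#' testing; its `abs_cn` holds the true clone copy numbers and its
#' `altered` flags mark deviation from the modal state, so
#' `fga(truth)` is the generating FGA.
#'
#' @param config a [sim_config()].
#' @return list with `bins` (a [bin_profile()]) and `truth`
#'   (a [segment_profile()]).
#' @export
simulate_tumor_bins <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  grid <- layout_bins(config$layout)
  n <- nrow(grid)
  baseline <- max(1, round(config$ploidy))
  cn <- rep(baseline, n)
  taken <- rep(FALSE, n)
  bin_size <- config$layout$bin_size
  chroms <- config$layout$chromosomes$name
  if (config$n_events > 0) {
    for (e in seq_len(config$n_events)) {
      is_gain <- stats::runif(1) < 0.5
      wt <- rep(1, length(chroms))
      fav <- if (is_gain) config$event_bias$gain_chrom else
        config$event_bias$loss_chrom
      wt[chroms %in% fav] <- 3
      placed <- FALSE
      for (try in 1:200) {
        ch <- sample(chroms, 1, prob = wt)
        on_ch <- which(grid$chrom == ch)
        size_bins <- max(1, round(stats::runif(
          1, config$event_size_range[1], config$event_size_range[2]) /
            bin_size))
        if (size_bins > length(on_ch)) next
        s <- sample(length(on_ch) - size_bins + 1, 1)
        idx <- on_ch[s:(s + size_bins - 1)]
        if (any(taken[idx])) next
        cn[idx] <- if (is_gain) baseline + sample(1:2, 1, prob = c(0.7, 0.3))
          else max(0, baseline - sample(1:2, 1, prob = c(0.8, 0.2)))
        taken[idx] <- TRUE
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place event ", e,
                        ": events overflow the genome")
    }
  }
  fit <- purity_fit(config$purity, config$ploidy, source = "external")
  clean <- expected_value(cn, fit)
  wave <- ffpe_wave_components(n)
  coefs <- stats::rnorm(2, 0, config$ffpe_wave_amplitude)
  ratio <- clean * exp(stats::rnorm(n, 0, config$bin_noise_sd)) +
    as.numeric(wave %*% coefs)
  bins <- bin_profile("sim_tumor", config$layout,
                      cbind(grid, ratio = pmax(ratio, 0)))
  # collapse constant-CN runs into truth segments
  runs <- rle(paste(grid$chrom, cn))
  stops <- cumsum(runs$lengths)
  starts <- c(1, utils::head(stops, -1) + 1)
  truth <- data.frame(chrom = grid$chrom[starts],
                      start = grid$start[starts],
                      end = grid$end[stops],
                      value = clean[starts],
                      n_bins = runs$lengths,
                      abs_cn = cn[starts])
  tp <- segment_profile("sim_tumor", truth)
  modal <- modal_cn(tp, ploidy = config$ploidy)
  tp <- call_altered(tp, modal)
  tp$segments$called <- tp$segments$altered
  list(bins = bins, truth = tp)
}

#' Simulate a panel of FFPE-like normal controls
#'
#' Each normal sample is flat copy-neutral signal with multiplicative
#' lognormal noise plus the shared background wave components at random
#' per-sample coefficients, mimicking FFPE-derived normal controls whose
#' leading principal components carry the recurrent background.
#'
#' @param config a [sim_config()].
#' @param n_samples number of normals (default 42, >= 3).
#' @return a [normal_panel()].
#' @export
simulate_normal_panel <- function(config, n_samples = 42) {
  stopifnot(inherits(config, "sim_config"), n_samples >= 3)
  set.seed(config$seed)
  n <- n_layout_bins(config$layout)
  wave <- ffpe_wave_components(n)
  ratios <- t(vapply(seq_len(n_samples), function(s) {
    coefs <- stats::rnorm(2, 0, config$ffpe_wave_amplitude)
    exp(stats::rnorm(n, 0, config$bin_noise_sd)) +
      as.numeric(wave %*% coefs)
  }, numeric(n)))
  normal_panel(ratios, config$layout)
}

#' Simulate an MLPA sample from region copy numbers
#'
#' Classification-probe ratios follow the purity mixture
#' `(p * CN + 2 * (1 - p)) / 2` with multiplicative lognormal noise;
#' reference probes sit at copy number 2.
#'
#' @param config a [sim_config()].
#' @param region_cn named integer vector mapping region ids of the default
#'   probe set to clone copy numbers; unlisted regions stay at 2.
#' @param probeset the probe set (default [default_mlpa_probeset()]).
#' @return an [mlpa_sample()].
#' @export
simulate_mlpa <- function(config, region_cn = integer(0),
                          probeset = default_mlpa_probeset()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  unknown <- setdiff(names(region_cn), names(probeset$region_threshold))
  if (length(unknown))
    stop("unknown region(s): ", paste(unknown, collapse = ", "))
  p <- config$purity
  probes <- probeset$probes
  cn <- ifelse(probes$role == "reference", 2,
               ifelse(probes$region_id %in% names(region_cn),
                      region_cn[probes$region_id], 2))
  ratio <- (p * cn + 2 * (1 - p)) / 2 *
    exp(stats::rnorm(nrow(probes), 0, config$mlpa_noise_sd))
  mlpa_sample("sim_mlpa", stats::setNames(ratio, probes$probe_id))
}

#' Simulate an annotated somatic-variant table
#'
#' Draws supporting reads binomially at the expected VAF of each specified
#' variant given the configured purity. With `include_decoys = TRUE`,
#' appends records that the somatic filter must remove (germline SNPs,
#' sub-threshold VAF, single-caller, silent) and records it must keep
#' despite their consequence class (TERT promoter, TP53 5'-UTR).
#'
#' @param config a [sim_config()].
#' @param variant_spec data.frame with columns `gene`, `m` (variant
#'   copies), `C` (total copies), `germline`; default: three clonal
#'   single-copy somatic drivers.
#' @param include_decoys append filter-test records (default TRUE).
#' @return a [variant_table()].
#' @export
simulate_variants <- function(config,
                              variant_spec = data.frame(
                                gene = c("TP53", "CASP8", "HRAS"),
                                m = 1, C = 2, germline = FALSE),
                              include_decoys = TRUE) {
  stopifnot(inherits(config, "sim_config"), config$depth > 0)
  set.seed(config$seed)
  evaf <- expected_vaf(config$purity, variant_spec$m, variant_spec$C,
                       germline = variant_spec$germline)
  alt <- stats::rbinom(nrow(variant_spec), config$depth, evaf)
  main <- data.frame(
    gene = variant_spec$gene, chrom = "1",
    pos = seq_len(nrow(variant_spec)) * 1e6,
    ref = "C", alt = "T", vaf = alt / config$depth, depth = config$depth,
    alt_reads = alt, caller_a = TRUE, caller_b = TRUE,
    consequence = "missense", population_af = 0, dbsnp_common = FALSE,
    pon_count = 0L, cosmic_confirmed_somatic = FALSE)
  if (include_decoys) {
    mk <- function(gene, vaf, cons, caller_b = TRUE, pop = 0,
                   dbsnp = FALSE, pon = 0L, cosmic = FALSE) {
      data.frame(gene = gene, chrom = "2", pos = stats::runif(1, 1e6, 4e7),
                 ref = "G", alt = "A", vaf = vaf,
                 depth = config$depth,
                 alt_reads = round(vaf * config$depth), caller_a = TRUE,
                 caller_b = caller_b, consequence = cons,
                 population_af = pop, dbsnp_common = dbsnp,
                 pon_count = pon, cosmic_confirmed_somatic = cosmic)
    }
    decoys <- rbind(
      mk("NOTCH1", 0.5, "missense", pop = 0.3, dbsnp = TRUE),   # germline SNP
      mk("FAT1", 0.48, "missense", pon = 20L),                  # PON germline
      mk("KMT2D", 0.01, "missense"),                            # below min VAF
      mk("PIK3CA", 0.2, "missense", caller_b = FALSE),          # one caller
      mk("NSD1", 0.2, "silent"),                                # silent
      mk("CDKN2A", 0.2, "intronic"),                            # intronic
      mk("TERT", 0.2, "promoter"),                              # kept
      mk("TP53", 0.2, "utr"),                                   # kept
      mk("PIK3CA", 0.3, "missense", pop = 0.02, cosmic = TRUE)  # COSMIC rescue
    )
    main <- rbind(main, decoys)
  }
  variant_table(main)
}

#' Simulate a two-group clinical cohort with survival
#'
#' Categorical covariates are drawn per group from configurable frequency
#' tables (defaults echo the contrast between quiet and other tumors:
#' quiet patients more often female and never-smokers). Survival times are
#' exponential with the group hazard set by `hazard_ratio` (quiet versus
#' other) around a baseline calibrated to roughly 50% 5-year survival in
#' the other group; censoring is uniform on (0, 120) months.
#'
#' @param config a [sim_config()].
#' @param n_quiet,n_other group sizes (> 0).
#' @param hazard_ratio quiet-versus-other hazard ratio (default 0.44).
#' @param base_hazard monthly hazard of the "other" group
#'   (default `-log(0.5)/60`).
#' @param covariates named list of per-group probability tables; each
#'   element is a list with `levels`, `quiet`, `other`.
#' @return list with `clinical` (data.frame) and `survival` (data.frame
#'   `time`, `event`, `group` with `"CNA_quiet"` as first level).
#' @export
simulate_cohort <- function(config, n_quiet, n_other, hazard_ratio = 0.44,
                            base_hazard = -log(0.5) / 60,
                            covariates = list(
                              sex = list(levels = c("Female", "Male"),
                                         quiet = c(0.60, 0.40),
                                         other = c(0.40, 0.60)),
                              tobacco = list(
                                levels = c("Never", "Former", "Current"),
                                quiet = c(0.43, 0.36, 0.21),
                                other = c(0.21, 0.28, 0.51)))) {
  stopifnot(inherits(config, "sim_config"), n_quiet > 0, n_other > 0)
  set.seed(config$seed)
  group <- factor(rep(c("CNA_quiet", "CNA_other"), c(n_quiet, n_other)),
                  levels = c("CNA_quiet", "CNA_other"))
  clinical <- data.frame(sample_id = sprintf("S%04d", seq_along(group)),
                         group = group)
  for (cv in names(covariates)) {
    spec <- covariates[[cv]]
    clinical[[cv]] <- c(
      sample(spec$levels, n_quiet, replace = TRUE, prob = spec$quiet),
      sample(spec$levels, n_other, replace = TRUE, prob = spec$other))
  }
  hazard <- ifelse(group == "CNA_quiet", base_hazard * hazard_ratio,
                   base_hazard)
  t_event <- stats::rexp(length(group), hazard)
  t_cens <- stats::runif(length(group), 0, 120)
  survival <- data.frame(time = pmin(t_event, t_cens),
                         event = t_event <= t_cens,
                         group = group)
  list(clinical = clinical, survival = survival)
}
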