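#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the inputs of a CNA-quiet classification study: a panel of
# FFPE-like normal controls, low-coverage WGS bin profiles for a cohort of
# tumors with known quiet/other ground truth, MLPA probe-ratio samples,
# and an annotated somatic-variant table. Everything is seeded, so the
# downstream stages are reproducible.
#
# Outputs (results/):
#   cohort_manifest.tsv   per-sample ground truth (label, purity, events)
#   bins/<sample>.tsv     bin-level ratio tracks
#   mlpa_calls.tsv        MLPA pre-screen region calls per sample
#   variants.tsv          simulated annotated variant table (one sample)

library(cnaquiet)

seed <- 20260923
n_quiet <- 30
n_other <- 30

dir.create("results/bins", recursive = TRUE, showWarnings = FALSE)

manifest <- do.call(rbind, lapply(seq_len(n_quiet + n_other), function(i) {
  set.seed(seed + i)
  quiet <- i <= n_quiet
  data.frame(sample_id = sprintf("S%03d", i),
             true_label = if (quiet) "CNA_quiet" else "CNA_other",
             purity = round(runif(1, 0.3, 0.9), 2),
             n_events = if (quiet) sample(0:3, 1) else sample(8:12, 1))
}))

for (i in seq_len(nrow(manifest))) {
  cfg <- sim_config(seed = seed + 1000 + i, purity = manifest$purity[i],
                    ploidy = 2, n_events = manifest$n_events[i])
  sim <- simulate_tumor_bins(cfg)
  manifest$true_fga[i] <- round(fga(sim$truth), 4)
  write_bins(sim$bins, file.path("results/bins",
                                 paste0(manifest$sample_id[i], ".tsv")))
}
write.table(manifest, "results/cohort_manifest.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("wrote %d bin profiles (%d quiet, %d other); true FGA %0.2f-%0.2f\n",
            nrow(manifest), n_quiet, n_other,
            min(manifest$true_fga), max(manifest$true_fga)))

# MLPA pre-screen inputs: region copy numbers per sample
ps <- default_mlpa_probeset()
regions <- names(ps$region_threshold)
mlpa <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
  set.seed(seed + 2000 + i)
  quiet <- manifest$true_label[i] == "CNA_quiet"
  nreg <- if (quiet) sample(0:2, 1) else sample(3:6, 1)
  cn <- stats::setNames(sample(c(1, 3, 4), nreg, replace = TRUE),
                        sample(regions, nreg))
  s <- simulate_mlpa(sim_config(seed = seed + 3000 + i,
                                purity = manifest$purity[i]), cn)
  pre <- prescreen(s, ps)
  data.frame(sample_id = manifest$sample_id[i],
             true_label = manifest$true_label[i],
             regions_changed_truth = nreg,
             n_changed_called = pre$n_changed,
             prescreen_call = pre$call)
}))
write.table(mlpa, "results/mlpa_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("MLPA pre-screen: %d definitive_other, %d quiet_candidate\n",
            sum(mlpa$prescreen_call == "definitive_other"),
            sum(mlpa$prescreen_call == "quiet_candidate")))

# one deep-sequencing variant table with decoys for the filter stage
v <- simulate_variants(sim_config(seed = seed + 4000, purity = 0.5,
                                  depth = 800))
write.table(v, "results/variants.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("variant table: %d records (incl. filter decoys)\n", nrow(v)))
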