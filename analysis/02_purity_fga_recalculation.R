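#!/usr/bin/env Rscript
# Stage 2: purity/ploidy fitting and stromal-contamination-corrected FGA.
#
# Demonstrates the central correction of the pipeline: on low-purity
# tumors, the uncorrected fraction genome altered (computed as if the
# sample were pure) collapses toward zero, producing false CNA-quiet
# calls; recalculating absolute copy numbers with the consensus
# purity/ploidy fit restores the true alteration burden.
#
# Outputs (results/):
#   fga_recalculation.tsv  per-sample naive vs corrected FGA and the fit

library(cnaquiet)

seed <- 20260923
lay <- hg19_layout()
panel <- simulate_normal_panel(sim_config(seed = seed, layout = lay))

rows <- lapply(1:40, function(i) {
  set.seed(seed + 100 + i)
  p <- runif(1, 0.1, 0.6)           # spans the problematic low-purity range
  sim <- simulate_tumor_bins(sim_config(
    seed = seed + 200 + i, layout = lay, purity = p, ploidy = 2,
    n_events = 15, event_size_range = c(2e7, 8e7)))
  # external purity/ploidy estimate, as supplied by an orthogonal tool
  ext <- purity_fit(min(1, max(0.05, p + rnorm(1, 0, 0.03))),
                    max(1, 2 + rnorm(1, 0, 0.1)))
  res <- run_sample_pipeline(sim$bins, panel, external_fit = ext)
  naive <- res$segments
  naive$segments$abs_cn <- absolute_cn(naive$segments$value,
                                       purity_fit(1, 2))
  naive <- call_altered(naive, modal_cn(naive, 2))
  data.frame(sample = sprintf("R%03d", i), purity_true = round(p, 3),
             purity_fit = res$fit$purity, ploidy_fit = res$fit$ploidy,
             fga_true = round(fga(sim$truth), 3),
             fga_naive = round(fga(naive), 3),
             fga_corrected = round(res$fga_altered, 3))
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(tab, "results/fga_recalculation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

low <- tab[tab$purity_true <= 0.2, ]
cat(sprintf("%d samples; purity recovery median |error| = %.3f\n",
            nrow(tab), median(abs(tab$purity_fit - tab$purity_true))))
cat(sprintf("FGA correlation (corrected vs true): %.3f; naive vs true: %.3f\n",
            cor(tab$fga_corrected, tab$fga_true),
            cor(tab$fga_naive, tab$fga_true)))
cat(sprintf("low-purity (<=0.2) samples: %d/%d look falsely quiet uncorrected, %d/%d stay CNA-other corrected\n",
            sum(low$fga_naive < 0.2), nrow(low),
            sum(low$fga_corrected >= 0.2), nrow(low)))
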