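# shared fixtures, built in code at test time

toy_segments <- function(values = c(1, 1.25, 0.75, 1),
                         n_per_chrom = 2, sample_id = "s1") {
  k <- length(values)
  chrom <- rep(as.character(seq_len(ceiling(k / n_per_chrom))),
               each = n_per_chrom)[seq_len(k)]
  start <- rep(seq(1, by = 1e7, length.out = n_per_chrom), length.out = k)
  segment_profile(sample_id,
                  data.frame(chrom = chrom, start = start,
                             end = start + 1e7 - 1, value = values,
                             n_bins = 20))
}

# deterministic flat panel used where panel content is irrelevant
flat_panel <- function(layout = toy_layout(), sd = 0.05, seed = 424242,
                       n_samples = 12) {
  set.seed(seed)
  n <- n_layout_bins(layout)
  ratios <- t(vapply(seq_len(n_samples),
                     function(i) exp(stats::rnorm(n, 0, sd)),
                     numeric(n)))
  normal_panel(ratios, layout)
}
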