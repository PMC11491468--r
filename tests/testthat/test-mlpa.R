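test_that("the bundled probe set has the expected composition", {
  ps <- default_mlpa_probeset()
  expect_equal(sum(ps$probes$role == "classification"), 36)
  expect_equal(sum(ps$probes$role == "reference"), 13)
  expect_equal(length(ps$region_threshold), 10)
  expect_equal(unname(ps$region_threshold[c("3q26", "11q13")]), c(3L, 3L))
  expect_true(all(ps$region_threshold[setdiff(names(ps$region_threshold),
                                              c("3q26", "11q13"))] == 2L))
  # the shipped TSV parses to the same set
  f <- system.file("extdata", "mlpa_probeset_hnscc.tsv",
                   package = "cnaquiet")
  ps2 <- read_mlpa_probeset(f)
  expect_equal(ps2$region_threshold, ps$region_threshold)
})

test_that("probe normalization anchors copy-neutral probes at 1", {
  ps <- default_mlpa_probeset()
  ids <- ps$probes$probe_id
  set.seed(4)
  base <- stats::setNames(runif(length(ids), 500, 2000), ids)
  refs <- list(base * 1.7, base * 0.6, base)  # scale differences only
  # identical to references -> all ratios 1
  got <- normalize_probes(base * 3, refs, ps)
  expect_equal(unname(got$probe_ratios), rep(1, length(ids)),
               tolerance = 1e-10)
  # one probe doubled -> ratio 2
  doubled <- base; doubled["3q26_p1"] <- doubled["3q26_p1"] * 2
  got2 <- normalize_probes(doubled, refs, ps)
  expect_equal(unname(got2$probe_ratios["3q26_p1"]), 2, tolerance = 1e-10)
  # purity mixture: region at CN 3 in a purity-p tumor
  p <- 0.6
  mixed <- base
  r3 <- ps$probes$probe_id[ps$probes$region_id == "3q26"]
  mixed[r3] <- mixed[r3] * (p * 3 + 2 * (1 - p)) / 2
  got3 <- normalize_probes(mixed, refs, ps)
  expect_equal(unname(got3$probe_ratios[r3]),
               rep((p * 3 + 2 * (1 - p)) / 2, length(r3)),
               tolerance = 1e-10)
  # errors
  expect_error(normalize_probes(base[names(base) != "ref_p01"], refs, ps),
               "missing reference")
  zero <- base; zero[1] <- 0
  expect_error(normalize_probes(zero, refs, ps), "zero")
})

test_that("region scoring follows the aberrant-probe counting rules", {
  expect_equal(score_region(c(1.4, 1.35, 1.0), 2), "gain")
  # mixed directions raise the requirement to three
  expect_equal(score_region(c(1.4, 0.6, 1.35), 2), "normal")
  expect_equal(score_region(c(0.65, 0.6, 0.55), 3), "loss")
  # boundary values 0.7 / 1.3 are normal
  expect_equal(score_region(c(1.29, 1.25, 1.28), 2), "normal")
  expect_equal(score_region(c(0.7, 0.7, 1.3), 2), "normal")
  # symmetric extra-probe rule: gains with one opposing loss
  expect_equal(score_region(c(1.4, 1.35, 1.45, 0.6), 2), "gain")
  expect_equal(score_region(c(0.6, 0.65, 0.5, 1.4), 2), "loss")
  expect_error(score_region(numeric(0), 2), "empty")
})

test_that("region scoring is invariant under probe order", {
  set.seed(6)
  for (rep in 1:20) {
    r <- runif(sample(3:6, 1), 0.4, 1.8)
    expect_equal(score_region(r, 2), score_region(sample(r), 2))
  }
})

test_that("prescreen counts changed regions against the two-region rule", {
  ps <- default_mlpa_probeset()
  flat <- mlpa_sample("s", stats::setNames(rep(1, nrow(ps$probes)),
                                           ps$probes$probe_id))
  got <- prescreen(flat, ps)
  expect_equal(got$call, "quiet_candidate")
  expect_equal(got$n_changed, 0)
  raise <- function(sample, regions, ratio = 1.6) {
    r <- sample$probe_ratios
    ids <- ps$probes$probe_id[ps$probes$region_id %in% regions]
    r[ids] <- ratio
    mlpa_sample("s", r)
  }
  # exactly two changed regions stays a quiet candidate (boundary)
  expect_equal(prescreen(raise(flat, c("2q36", "4q35")), ps)$call,
               "quiet_candidate")
  # three changed regions -> definitive CNA-other
  expect_equal(prescreen(raise(flat, c("2q36", "4q35", "7p11")), ps)$call,
               "definitive_other")
  # missing probes are reported
  short <- mlpa_sample("s", flat$probe_ratios[-1])
  expect_error(prescreen(short, ps), "missing probe")
})

test_that("low purity drives all region calls toward normal", {
  ps <- default_mlpa_probeset()
  regions <- names(ps$region_threshold)[1:5]
  cn <- stats::setNames(rep(4, 5), regions)
  n_changed <- vapply(c(0.8, 0.4, 0.15, 0.05), function(p) {
    s <- simulate_mlpa(sim_config(seed = 88, purity = p,
                                  mlpa_noise_sd = 0.03), cn)
    prescreen(s, ps)$n_changed
  }, numeric(1))
  expect_true(all(diff(n_changed) <= 0))
  expect_equal(n_changed[4], 0)
})

test_that("definitive_other pre-screen calls are reliably true others", {
  ps <- default_mlpa_probeset()
  regions <- names(ps$region_threshold)
  tp <- 0; n_other_calls <- 0
  for (i in 1:300) {
    set.seed(60000 + i)
    is_other <- i %% 2 == 0
    p <- runif(1, 0.4, 0.9)
    nreg <- if (is_other) sample(3:6, 1) else sample(0:2, 1)
    cn <- stats::setNames(sample(c(1, 3, 4), nreg, replace = TRUE),
                          sample(regions, nreg))
    s <- simulate_mlpa(sim_config(seed = 61000 + i, purity = p), cn)
    if (prescreen(s, ps)$call == "definitive_other") {
      n_other_calls <- n_other_calls + 1
      if (is_other) tp <- tp + 1
    }
  }
  expect_gt(n_other_calls, 50)
  expect_gte(tp / n_other_calls, 0.99)
})
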