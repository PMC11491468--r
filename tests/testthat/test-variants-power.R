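make_variant <- function(gene = "TP53", vaf = 0.2, depth = 500,
                         caller_a = TRUE, caller_b = TRUE,
                         consequence = "missense", population_af = 0,
                         dbsnp_common = FALSE, pon_count = 0L,
                         cosmic = FALSE) {
  data.frame(gene = gene, chrom = "1", pos = 1e6, ref = "C", alt = "T",
             vaf = vaf, depth = depth, alt_reads = round(vaf * depth),
             caller_a = caller_a, caller_b = caller_b,
             consequence = consequence, population_af = population_af,
             dbsnp_common = dbsnp_common, pon_count = pon_count,
             cosmic_confirmed_somatic = cosmic)
}

test_that("variant filtering applies every retention rule", {
  v <- rbind(
    make_variant("PIK3CA"),                                   # kept
    make_variant("NOTCH1", caller_b = FALSE),                 # one caller
    make_variant("KMT2D", vaf = 0.01),                        # below VAF
    make_variant("FAT1", vaf = 0.005, depth = 200),           # < 3 reads
    make_variant("NSD1", population_af = 0.05),               # gnomAD
    make_variant("RB1", dbsnp_common = TRUE),                 # dbSNP
    make_variant("KEAP1", pon_count = 20L),                   # PON
    make_variant("HRAS", population_af = 0.05, cosmic = TRUE),# rescued
    make_variant("CDKN2A", consequence = "silent"),           # silent
    make_variant("NOTCH2", consequence = "intronic"),         # intronic
    make_variant("EPHA2", consequence = "utr"),               # UTR
    make_variant("TERT", consequence = "promoter"),           # kept
    make_variant("TP53", consequence = "utr"))                # kept (5'UTR)
  got <- filter_variants(v)
  expect_setequal(paste(got$gene, got$consequence),
                  c("PIK3CA missense", "HRAS missense", "TERT promoter",
                    "TP53 utr"))
})

test_that("variant filtering matches a rule-by-rule reference filter", {
  set.seed(17)
  pool <- c("missense", "truncating", "silent", "intronic", "utr",
            "promoter", "splice", "inframe")
  for (rep in 1:10) {
    n <- 40
    v <- do.call(rbind, lapply(seq_len(n), function(i) {
      make_variant(gene = sample(c("TP53", "TERT", "CASP8", "HRAS"), 1),
                   vaf = round(runif(1, 0, 0.6), 3),
                   depth = sample(c(100, 500), 1),
                   caller_a = runif(1) < 0.9, caller_b = runif(1) < 0.9,
                   consequence = sample(pool, 1),
                   population_af = sample(c(0, 0.005, 0.05), 1),
                   dbsnp_common = runif(1) < 0.1,
                   pon_count = sample(c(0L, 2L, 10L), 1),
                   cosmic = runif(1) < 0.1)
    }))
    got <- filter_variants(v)
    # independent reference: literal per-row rule evaluation
    keep <- vapply(seq_len(nrow(v)), function(i) {
      r <- v[i, ]
      if (!(r$caller_a && r$caller_b)) return(FALSE)
      if (r$vaf < 0.02 || r$alt_reads < 3) return(FALSE)
      if ((r$population_af >= 0.01 || r$dbsnp_common || r$pon_count > 5) &&
          !r$cosmic_confirmed_somatic) return(FALSE)
      if (r$consequence %in% c("intronic", "silent", "utr") &&
          !(r$gene == "TERT" && r$consequence == "promoter") &&
          !(r$gene == "TP53" && r$consequence == "utr")) return(FALSE)
      TRUE
    }, logical(1))
    expect_equal(nrow(got), sum(keep))
    # subset of input and idempotent
    expect_true(all(paste(got$gene, got$vaf) %in% paste(v$gene, v$vaf)))
    expect_equal(nrow(filter_variants(got)), nrow(got))
  }
})

test_that("expected VAF follows the purity mixture closed forms", {
  expect_equal(expected_vaf(0.5, 1, 2), 0.25)
  expect_equal(expected_vaf(1.0, 1, 2), 0.5)
  expect_equal(expected_vaf(0.5, 1, 2, germline = TRUE), 0.5)
  # germline heterozygous at C = 2 is purity-independent
  for (p in c(0.1, 0.4, 0.9))
    expect_equal(expected_vaf(p, 1, 2, germline = TRUE), 0.5)
  # somatic <= germline at equal (p, m, C)
  set.seed(2)
  for (rep in 1:20) {
    p <- runif(1, 0.05, 1); C <- sample(1:6, 1); m <- sample(0:C, 1)
    s <- expected_vaf(p, m, C); g <- expected_vaf(p, m, C, germline = TRUE)
    expect_lte(s, g)
    expect_gte(s, 0); expect_lte(g, 1)
  }
  expect_error(expected_vaf(0.5, 3, 2), "exceed")
})

test_that("variant-copy linkage resolves the canonical configurations", {
  fit <- purity_fit(0.5, 2)
  got <- link_variant_copies(0.25, 1000, 2, fit)
  expect_equal(got$m, 1)
  expect_equal(got$model, "somatic")
  got2 <- link_variant_copies(0.50, 1000, 2, fit)
  expect_equal(got2$m, 1)
  expect_equal(got2$model, "germline")
  expect_error(link_variant_copies(0.25, 0, 2, fit), "depth")
})

test_that("variant-copy linkage recovers simulated configurations", {
  set.seed(23)
  hits <- 0; n <- 60
  for (i in 1:n) {
    p <- runif(1, 0.3, 0.9)
    C <- sample(2:4, 1)
    m <- sample(1:C, 1)
    germ <- runif(1) < 0.3
    fit <- purity_fit(p, 2)
    ev <- expected_vaf(p, m, C, germline = germ)
    vaf <- rbinom(1, 500, ev) / 500
    got <- link_variant_copies(vaf, 500, C, fit)
    if (got$m == m &&
        got$model == (if (germ) "germline" else "somatic")) hits <- hits + 1
  }
  expect_gte(hits / n, 0.8)
})

test_that("variant power equals brute-force binomial tail sums", {
  expect_equal(variant_power(0, 0.25), 0)
  expect_gt(variant_power(1000, 0.25, 0.001), 0.999)
  # brute-force oracle: explicit dbinom sums for threshold and power
  brute <- function(depth, evaf, err, alpha_noise = 1e-4) {
    upper_tail <- function(k, p) sum(stats::dbinom(k:depth, depth, p))
    k_noise <- depth + 1
    for (k in 1:(depth + 1)) {
      if (k > depth || upper_tail(k, err) < alpha_noise) {
        k_noise <- k; break
      }
    }
    k_call <- max(k_noise, 3, ceiling(0.02 * depth))
    if (k_call > depth) return(0)
    upper_tail(k_call, evaf)
  }
  for (depth in c(10, 50, 200, 800)) {
    for (evaf in c(0.01, 0.05, 0.25)) {
      expect_equal(variant_power(depth, evaf, 0.001),
                   brute(depth, evaf, 0.001), tolerance = 1e-12,
                   info = sprintf("depth=%d evaf=%g", depth, evaf))
    }
  }
})

test_that("segment power matches Monte-Carlo estimates of the call rule", {
  set.seed(41)
  for (case in list(c(0.6, 2, 0.05, 40), c(0.3, 2, 0.05, 20),
                    c(0.2, 3, 0.08, 60), c(0.07, 2, 0.05, 25))) {
    p <- case[1]; q <- case[2]; sdv <- case[3]; nb <- case[4]
    pw <- segment_power(p, q, sdv, nb)
    d <- p / (p * q + 2 * (1 - p))
    se <- sdv / sqrt(nb)
    draws <- rnorm(1e5, d, se)
    zcrit <- qnorm(1 - 0.001 / 2)
    mc <- mean(abs(draws) > 0.02 & abs(draws) / se > zcrit)
    expect_lt(abs(pw - mc), 0.011)
  }
  # limits
  expect_gt(segment_power(1, 2, 1e-4, 50), 0.999)
  expect_lt(segment_power(0.01, 2, 0.05, 20), 0.01)
})

test_that("power is monotone in purity, depth and bin support", {
  purities <- seq(0.1, 0.9, by = 0.1)
  sp <- vapply(purities, function(p) segment_power(p, 2, 0.05, 30),
               numeric(1))
  expect_true(all(diff(sp) >= -1e-12))
  nbins <- c(5, 10, 20, 40, 80)
  sp2 <- vapply(nbins, function(nb) segment_power(0.3, 2, 0.05, nb),
                numeric(1))
  expect_true(all(diff(sp2) >= -1e-12))
  depths <- c(50, 100, 200, 400, 800)
  vp <- vapply(depths, function(d) variant_power(d, 0.15), numeric(1))
  expect_true(all(diff(vp) >= -1e-12))
  vafs <- seq(0.02, 0.5, by = 0.04)
  vp2 <- vapply(vafs, function(v) variant_power(300, v), numeric(1))
  expect_true(all(diff(vp2) >= -1e-12))
})

test_that("genome power fraction is the length-weighted tally", {
  expect_equal(genome_power_fraction(c(1, 1), c(5, 5)), 1)
  expect_equal(genome_power_fraction(c(0.9, 0.1), c(7, 7)), 0.5)
  set.seed(3)
  for (rep in 1:10) {
    k <- sample(2:30, 1)
    pw <- runif(k); len <- runif(k, 1, 100)
    expect_equal(genome_power_fraction(pw, len),
                 sum(len[pw > 0.8]) / sum(len))
  }
  expect_error(genome_power_fraction(c(1, 1), 1), "length")
})

test_that("sample QC gates on purity and powered genome fraction", {
  expect_false(qc_sample(purity_fit(0.09, 2), 0.95)$pass)
  expect_equal(qc_sample(purity_fit(0.09, 2), 0.95)$reasons, "purity")
  expect_true(qc_sample(purity_fit(0.5, 2), 0.95)$pass)
  got <- qc_sample(purity_fit(0.5, 2), 0.5)
  expect_false(got$pass)
  expect_equal(got$reasons, "power")
  expect_setequal(qc_sample(purity_fit(0.05, 2), 0.2)$reasons,
                  c("purity", "power"))
})
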