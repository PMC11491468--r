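test_that("absolute_cn matches its closed form and inverts expected_value", {
  expect_equal(absolute_cn(1, purity_fit(0.37, 3.2)), 3.2)
  expect_equal(absolute_cn(1.5, purity_fit(0.5, 2)), 4)
  set.seed(5)
  for (rep in 1:20) {
    fit <- purity_fit(runif(1, 0.1, 1), runif(1, 1, 6))
    cn <- runif(1, 0, 8)
    expect_equal(absolute_cn(expected_value(cn, fit), fit), cn)
  }
})

test_that("decreasing purity steepens the value-to-copy-number slope", {
  slope <- function(p) {
    fit <- purity_fit(p, 2)
    absolute_cn(1.1, fit) - absolute_cn(1.0, fit)
  }
  expect_true(all(diff(sapply(c(0.9, 0.6, 0.3, 0.1), slope)) > 0))
})

test_that("modal_cn is the length-weighted mode with ploidy tie-break", {
  prof <- toy_segments(values = rep(1, 4))
  prof$segments$abs_cn <- c(2, 2, 2, 2)
  expect_equal(modal_cn(prof), 2)
  # 60% of length CN 2, 40% CN 3
  prof$segments$abs_cn <- c(2, 2, 2, 3)
  prof$segments$end[4] <- prof$segments$start[4] + 2e7
  expect_equal(modal_cn(prof), 2)
  # exact tie broken toward ploidy
  tie <- toy_segments(values = c(1, 1))
  tie$segments$abs_cn <- c(2, 4)
  expect_equal(modal_cn(tie, ploidy = 2), 2)
  expect_equal(modal_cn(tie, ploidy = 4), 4)
  # randomized profiles vs brute-force length tally
  set.seed(9)
  for (rep in 1:15) {
    k <- sample(3:10, 1)
    prof <- toy_segments(values = rep(1, k))
    prof$segments$abs_cn <- runif(k, 0, 5)
    prof$segments$end <- prof$segments$start +
      sample(1:50, k, replace = TRUE) * 1e5
    lens <- segment_lengths(prof)
    tally <- tapply(lens, pmax(0, round(prof$segments$abs_cn)), sum)
    expect_true(modal_cn(prof, 2) %in%
                  as.integer(names(tally)[tally == max(tally)]))
  }
})

test_that("altered calls use a strict 0.5-copy rule around the modal state", {
  prof <- toy_segments(values = rep(1, 3))
  prof$segments$abs_cn <- c(2.5, 2.51, 1.2)
  got <- call_altered(prof, 2)$segments$altered
  expect_equal(got, c(FALSE, TRUE, TRUE))
})

test_that("fga is the altered length fraction and is monotone", {
  prof <- toy_segments(values = rep(1, 4))
  prof$segments$abs_cn <- c(2, 2, 2, 2)
  prof <- call_altered(prof, 2)
  expect_equal(fga(prof), 0)
  prof$segments$altered <- rep(TRUE, 4)
  expect_equal(fga(prof), 1)
  prof$segments$altered <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(fga(prof), 0.5)
  # flagging one more segment never decreases fga
  f0 <- fga(prof)
  prof$segments$altered[3] <- TRUE
  expect_gte(fga(prof), f0)
})

test_that("background subtraction removes panel components and re-centers", {
  lay <- toy_layout()
  panel <- flat_panel(lay)
  n <- n_layout_bins(lay)
  grid <- layout_bins(lay)
  # profile equal to a multiple of a panel component -> flat 1
  v1 <- panel$components[, 1]
  bp <- bin_profile("s", lay, cbind(grid, ratio = 1 + 0.3 * v1))
  out <- subtract_background(bp, panel)
  expect_lt(max(abs(out$bins$ratio - 1)), 0.02)
  # profile orthogonal to both components -> unchanged up to re-centering
  set.seed(3)
  x <- rnorm(n, 0, 0.1)
  for (j in 1:2) {
    v <- panel$components[, j]
    x <- x - sum(x * v) / sum(v * v) * v
  }
  bp2 <- bin_profile("s", lay, cbind(grid, ratio = pmax(1 + x, 0)))
  out2 <- subtract_background(bp2, panel)
  # small residue allowed: re-centering by the median is not exactly
  # orthogonal to the components
  expect_lt(max(abs((out2$bins$ratio - median(out2$bins$ratio)) -
                      (bp2$bins$ratio - median(bp2$bins$ratio)))), 0.005)
  # construct-and-remove: truth + alpha * component recovered within noise
  truth <- pmax(1 + rnorm(n, 0, 0.02), 0)
  bp3 <- bin_profile("s", lay, cbind(grid, ratio = truth + 0.25 * v1))
  out3 <- subtract_background(bp3, panel)
  expect_lt(sd(out3$bins$ratio - truth), sd(bp3$bins$ratio - truth))
  expect_lt(max(abs(out3$bins$ratio - truth)), 0.1)
  # layout mismatch errors
  expect_error(subtract_background(
    bin_profile("s", hg19_layout(),
                cbind(layout_bins(hg19_layout()), ratio = 1)), panel),
    "layout")
})

test_that("segmentation finds a clean step and respects the size guard", {
  lay <- genome_layout(data.frame(name = "1", length = 2e7), bin_size = 5e5)
  grid <- layout_bins(lay)
  # flat noiseless profile -> one segment
  flatp <- segment_bins(bin_profile("s", lay, cbind(grid, ratio = 1)))
  expect_equal(nrow(flatp$segments), 1)
  # 5-SD step mid-chromosome -> two segments, breakpoint within 1 bin
  set.seed(21)
  x <- rnorm(40, 1, 0.05)
  x[21:40] <- x[21:40] + 0.25
  segp <- segment_bins(bin_profile("s", lay, cbind(grid, ratio = x)))
  expect_equal(nrow(segp$segments), 2)
  expect_lt(abs(segp$segments$start[2] - grid$start[21]), 2 * lay$bin_size)
  # two-bin chromosome with min_size 3 stays one segment
  lay2 <- genome_layout(data.frame(name = "1", length = 1e6), bin_size = 5e5)
  two <- segment_bins(bin_profile("s", lay2,
                                  cbind(layout_bins(lay2),
                                        ratio = c(0.5, 1.5))),
                      min_size = 3)
  expect_equal(nrow(two$segments), 1)
  expect_error(segment_bins(bin_profile("s", lay2, data.frame(
    chrom = "1", start = 1, end = 5e5, ratio = 1, usable = FALSE))),
    "no usable")
})

test_that("segmentation resolves several alternating events per chromosome", {
  lay <- genome_layout(data.frame(name = "1", length = 5e7), bin_size = 5e5)
  grid <- layout_bins(lay)
  cn <- rep(2, 100)
  cn[11:25] <- 3; cn[41:55] <- 1; cn[71:85] <- 3
  set.seed(8)
  x <- expected_value(cn, purity_fit(0.6, 2)) * exp(rnorm(100, 0, 0.04))
  segp <- segment_bins(bin_profile("s", lay, cbind(grid, ratio = x)))
  expect_gte(nrow(segp$segments), 6)
  expect_lte(nrow(segp$segments), 8)
})

test_that("panel-based calling gates on both deviation and significance", {
  lay <- toy_layout()
  panel <- flat_panel(lay, sd = 0.05)
  mk <- function(values) {
    k <- length(values)
    segment_profile("s", data.frame(
      chrom = "1", start = seq(1, by = 1e7, length.out = k),
      end = seq(1, by = 1e7, length.out = k) + 1e7 - 1,
      value = values, n_bins = 20))
  }
  pm <- mean(panel$bins$mean)
  # equal to panel mean -> not called
  got <- call_segments_pon(mk(rep(pm, 3)), panel)
  expect_false(any(got$segments$called))
  # significant z but deviation below the absolute cutoff -> not called
  got2 <- call_segments_pon(mk(c(pm + 0.015, pm, pm)), panel,
                            abs_cutoff = 0.02, alpha = 0.5)
  expect_false(got2$segments$called[1])
  # clear gain -> called
  got3 <- call_segments_pon(mk(c(pm + 0.3, pm, pm)), panel)
  expect_true(got3$segments$called[1])
  # no panel coverage -> excluded with warning
  off <- segment_profile("s", data.frame(chrom = "99", start = 1,
                                         end = 1e6, value = 1.5,
                                         n_bins = 2))
  expect_warning(got4 <- call_segments_pon(off, panel), "coverage")
  expect_equal(nrow(got4$segments), 0)
})

test_that("false-call rate of panel calling respects alpha", {
  lay <- toy_layout()
  panel <- flat_panel(lay, sd = 0.05)
  # null segments drawn from the panel distribution itself
  set.seed(77)
  n_reps <- 400
  vals <- 1 + rnorm(n_reps, 0, 0.05 / sqrt(20))
  calls <- vapply(vals, function(v) {
    p <- segment_profile("s", data.frame(chrom = "1", start = 1,
                                         end = 1e7, value = v,
                                         n_bins = 20))
    call_segments_pon(p, panel, alpha = 0.001)$segments$called
  }, logical(1))
  expect_lte(mean(calls), 0.02)
})
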