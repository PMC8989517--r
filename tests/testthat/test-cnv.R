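# Binned CNV differencing, region calling, and correlations.

neutral_counts <- function(lens, bin, depth, seed, id = "s") {
  grid <- bin_grid(lens, bin)
  grid$copy <- 1
  simulate_binned_counts(grid, depth, sample_id = id, seed = seed)
}

test_that("cnv_difference identities, antisymmetry and normalisation", {
  lens <- c(chr1 = 1e6, chr2 = 1e6)
  a <- neutral_counts(lens, 5e4, 100, seed = 1, id = "a")
  expect_true(all(cnv_difference(a, a)$value == 0))

  b <- neutral_counts(lens, 5e4, 100, seed = 2, id = "b")
  d_ab <- cnv_difference(a, b, normalization = "none")
  d_ba <- cnv_difference(b, a, normalization = "none")
  expect_equal(d_ab$value, -d_ba$value)

  # doubling the rearranged sample's library is absorbed by total-count
  # normalisation (the control scale is the reference)
  a2 <- a; a2$count <- a2$count * 2L
  expect_equal(cnv_difference(a2, b)$value, cnv_difference(a, b)$value)

  bad <- b[-1, ]
  expect_error(cnv_difference(a, bad), "grid")
})

test_that("a gained bin shows the expected count difference", {
  lens <- c(chr1 = 1e6)
  grid <- bin_grid(lens, 5e4)
  grid$copy <- 1
  grid$copy[7] <- 2
  diffs <- vapply(1:300, function(s) {
    gcr <- simulate_binned_counts(grid, 100, seed = s)
    nc <- neutral_counts(lens, 5e4, 100, seed = 10000 + s)
    cnv_difference(gcr, nc, normalization = "none")$value[7]
  }, numeric(1))
  expect_gt(mean(diffs), 90)
  expect_lt(mean(diffs), 110)
})

test_that("high-CNV region calling matches a rank oracle and merges", {
  lens <- c(chr1 = 1e6)
  profile <- bin_grid(lens, 5e4)
  profile$value <- 0
  expect_error(high_cnv_regions(profile[0, ]), "empty")
  expect_identical(nrow(high_cnv_regions(profile, "abs_z", t = 2)), 0L)

  profile$value <- stats::rnorm(20)
  profile$value[11] <- 50
  got <- high_cnv_regions(profile, "abs_quantile", q = 0.95)
  expect_equal(got$start, profile$start[11])
  expect_equal(got$end, profile$end[11])

  profile$value[12] <- 60 # adjacent extreme bins merge
  got2 <- high_cnv_regions(profile, "abs_quantile", q = 0.9)
  expect_identical(nrow(got2), 1L)
  expect_equal(got2$start, profile$start[11])
  expect_equal(got2$end, profile$end[12])

  expect_error(high_cnv_regions(profile, "abs_quantile", q = 1.2), "q")
  expect_error(high_cnv_regions(profile, "abs_z", t = -1), "t")
})

test_that("common_regions equals a per-base bitmap on a toy genome", {
  lens <- c(chr1 = 1e5)
  expect_identical(nrow(common_regions(
    data.frame(chrom = "chr1", start = 0L, end = 10L),
    data.frame(chrom = "chr1", start = 50L, end = 60L))), 0L)
  a <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(50L, 200L))
  expect_equal(common_regions(a, a), gcrsim:::merge_bins(a),
               ignore_attr = TRUE)
  set.seed(5)
  for (rep in 1:5) {
    mk <- function(n) {
      st <- sort(sample.int(99000, n))
      data.frame(chrom = "chr1", start = st,
                 end = st + sample.int(3000, n, replace = TRUE))
    }
    x <- mk(20); y <- mk(20)
    expect_equal(common_regions(x, y), bitmap_intersect(x, y, lens),
                 ignore_attr = TRUE)
  }
})

test_that("cnv_correlation recovers exact and noisy linear relations", {
  lens <- c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6)
  p1 <- bin_grid(lens, 2000) # 3000 bins
  set.seed(9)
  p1$value <- stats::rnorm(nrow(p1))
  p2 <- p1
  p2$value <- 2 * p1$value
  # lm warns about the deliberately perfect fit
  r <- suppressWarnings(cnv_correlation(p1, p2))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)

  p3 <- p1
  p3$value <- stats::rnorm(nrow(p1))
  expect_lt(cnv_correlation(p1, p3)$r_squared, 0.05)

  # SNR 1 construction: R^2 concentrates near 1/2
  p4 <- p1
  p4$value <- p1$value + stats::rnorm(nrow(p1))
  r4 <- cnv_correlation(p1, p4)$r_squared
  expect_gt(r4, 0.4); expect_lt(r4, 0.6)

  # per-chromosome fit computed two ways is identical
  rc <- cnv_correlation(p1, p4, "per_chromosome")
  sums1 <- tapply(p1$value, p1$chrom, sum)
  sums4 <- tapply(p4$value, p4$chrom, sum)
  fit <- stats::lm(sums4 ~ sums1)
  expect_equal(rc$r_squared, summary(fit)$r.squared)
  expect_equal(rc$slope, unname(stats::coef(fit)[2]))
  expect_identical(rc$n_points, 3L)
})

test_that("interval coverage ratios behave on uniform and depleted data", {
  counts <- data.frame(chrom = "cas", start = seq(0, 900, 100),
                       end = seq(100, 1000, 100), count = 50L)
  iv <- function(s, e) list(chrom = "cas", start = s, end = e)
  expect_equal(interval_coverage_ratio(counts, iv(0, 500), iv(500, 1000)),
               1.0)
  counts2 <- counts
  counts2$count[1:5] <- 25L
  expect_equal(interval_coverage_ratio(counts2, iv(0, 500), iv(500, 1000)),
               0.5)
  # central cassette deletion: numerator nearly empty vs intact control
  counts3 <- counts
  counts3$count[3:8] <- 2L
  expect_lt(interval_coverage_ratio(counts3, iv(200, 800), iv(800, 1000)),
            0.2)
  counts4 <- counts
  counts4$count[6:10] <- 0L
  expect_error(
    interval_coverage_ratio(counts4, iv(0, 500), iv(500, 1000)), "zero")
  expect_error(
    interval_coverage_ratio(counts, iv(0, 500), list(chrom = "x",
                                                     start = 0, end = 10)),
    "not covered")
})

test_that("simulator gains and losses are recovered from binned counts", {
  # parameter recovery on simulator-style truth: 200 bins, 10 changed
  lens <- c(chr1 = 5e6, chr2 = 5e6)
  grid <- bin_grid(lens, 5e4)
  sens <- fdr <- numeric(5)
  for (s in 1:5) {
    set.seed(s)
    truth <- grid
    truth$copy <- 1
    changed <- sample(nrow(grid), 10)
    truth$copy[changed] <- sample(c(0, 2, 3), 10, replace = TRUE)
    gcr <- simulate_binned_counts(truth, 100, seed = 100 + s)
    nc <- neutral_counts(lens, 5e4, 100, seed = 200 + s)
    prof <- cnv_difference(gcr, nc)
    called <- high_cnv_regions(prof, "abs_quantile", q = 0.95)
    called_bins <- which(points_in <- gcrsim:::points_in_regions(
      grid$chrom, grid$start, called))
    sens[s] <- length(intersect(called_bins, changed)) / length(changed)
    fdr[s] <- if (length(called_bins) == 0) 0 else
      length(setdiff(called_bins, changed)) / length(called_bins)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdr), 0.1)
})
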