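# Permutation enrichment, Monte-Carlo intra/inter null, nearest-element
# distances, and genome linearisation.

random_junctions <- function(n, lens, seed) {
  set.seed(seed)
  nm <- names(lens)
  p <- lens / sum(lens)
  ca <- sample(nm, n, TRUE, p); cb <- sample(nm, n, TRUE, p)
  data.frame(chrom_a = ca, pos_a = as.integer(floor(runif(n) * lens[ca])),
             chrom_b = cb, pos_b = as.integer(floor(runif(n) * lens[cb])),
             strand_a = "+", strand_b = "-", class = "translocation_intra",
             support = 0L, stringsAsFactors = FALSE)
}

test_that("breakpoint-in-region counts equal the double-loop oracle", {
  lens <- c(chr1 = 1e5, chr2 = 1e5)
  regions0 <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0))
  j <- random_junctions(40, lens, seed = 1)
  expect_identical(count_breakpoints_in_regions(j, regions0), 0L)
  all_reg <- data.frame(chrom = names(lens), start = 0L, end = 1e5)
  expect_identical(count_breakpoints_in_regions(j, all_reg), 80L)
  expect_identical(
    count_breakpoints_in_regions(j, all_reg, "per_junction"), 40L)
  set.seed(2)
  for (rep in 1:5) {
    st <- sort(sample.int(90000, 15))
    regions <- data.frame(chrom = sample(names(lens), 15, TRUE),
                          start = st, end = st + 4000L)
    for (counting in c("per_breakpoint", "per_junction")) {
      expect_identical(
        count_breakpoints_in_regions(j, regions, counting),
        as.integer(naive_count_in_regions(j, regions, counting)))
    }
  }
})

test_that("region shuffling preserves lengths, bounds and disjointness", {
  lens <- c(chr1 = 2e5, chr2 = 1e5, chr3 = 5e4)
  regions <- data.frame(chrom = "chr1",
                        start = seq(0, 90000, 10000),
                        end = seq(0, 90000, 10000) + c(3000, 8000))
  set.seed(3)
  for (rep in 1:20) {
    sh <- shuffle_regions(regions, lens)
    expect_setequal(sh$end - sh$start, regions$end - regions$start)
    expect_true(all(sh$start >= 0))
    expect_true(all(sh$end <= lens[sh$chrom]))
    sh <- sh[order(sh$chrom, sh$start), ]
    same <- sh$chrom[-1] == sh$chrom[-nrow(sh)]
    expect_true(all(sh$start[-1][same] >= sh$end[-nrow(sh)][same]))
  }
  # same-chromosome variant keeps every interval on its chromosome
  for (rep in 1:5) {
    sh <- shuffle_regions(regions, lens, same_chrom = TRUE)
    expect_true(all(sh$chrom == "chr1"))
    expect_setequal(sh$end - sh$start, regions$end - regions$start)
    expect_true(all(sh$end <= lens["chr1"]))
  }
})

test_that("permutation null mean matches the binomial expectation", {
  lens <- c(chr1 = 5e5, chr2 = 5e5)
  set.seed(4)
  st <- sort(sample.int(450000, 10))
  regions <- data.frame(chrom = sample(names(lens), 10, TRUE),
                        start = st, end = st + 10000L) # 10% of genome
  j <- random_junctions(100, lens, seed = 5)
  res <- permutation_enrichment(j, regions, lens, n_perm = 500, seed = 6)
  # null mean ~ 200 breakpoints x 10% within 3 sigma of binomial
  expect_lt(abs(res$null_mean - 20), 3 * sqrt(200 * 0.1 * 0.9))
  expect_false(res$degenerate)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("extreme enrichment and degenerate inputs are handled", {
  lens <- c(chr1 = 1e6)
  regions <- data.frame(chrom = "chr1", start = 0L, end = 50000L) # 5%
  set.seed(7)
  j <- data.frame(chrom_a = "chr1", pos_a = sample.int(49000, 60),
                  chrom_b = "chr1", pos_b = sample.int(49000, 60),
                  strand_a = "+", strand_b = "-",
                  class = "translocation_intra", support = 0L)
  res <- permutation_enrichment(j, regions, lens, n_perm = 300, seed = 8)
  expect_lt(res$p_value, 0.001)
  res0 <- permutation_enrichment(j[0, ], regions, lens, n_perm = 100,
                                 seed = 9)
  expect_true(res0$degenerate)
  expect_identical(res0$observed, 0L)
  expect_identical(res0$p_value, 1)
})

test_that("p-value decreases as breakpoints move into the regions", {
  lens <- c(chr1 = 1e6)
  regions <- data.frame(chrom = "chr1", start = 0L, end = 100000L)
  ps <- vapply(c(0.1, 0.4, 0.7), function(f) {
    set.seed(round(f * 100))
    n <- 80
    inside <- round(f * n)
    pos_a <- c(sample.int(99000, inside),
               100000 + sample.int(890000, n - inside))
    j <- data.frame(chrom_a = "chr1", pos_a = pos_a, chrom_b = "chr1",
                    pos_b = 100000 + sample.int(890000, n),
                    strand_a = "+", strand_b = "-",
                    class = "translocation_intra", support = 0L)
    permutation_enrichment(j, regions, lens, n_perm = 300,
                           seed = 10)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("MC closed forms are exact for degenerate genomes", {
  j <- random_junctions(50, c(chr1 = 1e5), seed = 11)
  res1 <- mc_intra_inter(j, c(chr1 = 1e5), seed = 12)
  expect_identical(res1$closed_form_intra_fraction, 1)
  expect_identical(res1$expected_intra_mean, 50)
  lens2 <- c(chr1 = 1e5, chr2 = 1e5)
  res2 <- mc_intra_inter(random_junctions(50, lens2, seed = 13), lens2,
                         seed = 14)
  expect_identical(res2$closed_form_intra_fraction, 0.5)
})

test_that("MC intra fraction matches the closed form on uneven genomes", {
  # human-like length profile (scaled): 23 decreasing chromosome sizes
  lens <- stats::setNames(
    round(seq(2.5e6, 5e5, length.out = 23)),
    paste0("chr", 1:23))
  j <- random_junctions(10, lens, seed = 15)
  res <- mc_intra_inter(j, lens, n_runs = 1, seed = 16)
  # estimator check at scale: one run of 1e5 pairs via n_events trick
  big <- random_junctions(1e5, lens, seed = 17)
  resb <- mc_intra_inter(big, lens, n_runs = 1, seed = 18)
  p <- resb$closed_form_intra_fraction
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(resb$expected_intra_mean / 1e5 - p), 3 * se)
  # unbiasedness over seeds at moderate n
  fr <- vapply(1:200, function(s) {
    mc_intra_inter(j, lens, n_runs = 1, seed = s)$expected_intra_mean / 10
  }, numeric(1))
  se10 <- sqrt(p * (1 - p) / 10) / sqrt(200)
  expect_lt(abs(mean(fr) - p), 2 * se10 * 1.5)
})

test_that("chi-square flags a strongly intra-biased junction set", {
  lens <- c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6, chr4 = 1e6)
  set.seed(19)
  j <- data.frame(chrom_a = "chr1", pos_a = sample.int(1e6, 100),
                  chrom_b = "chr1", pos_b = sample.int(1e6, 100),
                  strand_a = "+", strand_b = "-",
                  class = "translocation_intra", support = 0L)
  res <- mc_intra_inter(j, lens, seed = 20)
  expect_identical(res$observed_intra, 100L)
  expect_lt(res$p_value, 1e-6)
  expect_error(mc_intra_inter(j[0, ], lens), "at least one")
})

test_that("nearest-element distances equal the exhaustive scan", {
  set.seed(21)
  ann <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                    start = sample.int(999000, 300))
  ann$end <- ann$start + sample(c(300L, 6000L), 300, TRUE)
  ann$element_class <- sample(c("L1_like", "Alu_like"), 300, TRUE)
  ann$strand <- "+"
  ann$copy_id <- sprintf("c%03d", 1:300)
  j <- random_junctions(200, c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                        seed = 22)
  got <- nearest_element_distance(j, ann)
  expect_identical(
    got$distance,
    vapply(seq_len(nrow(got)), function(i) {
      as.integer(naive_nearest_distance(got$chrom[i], got$pos[i], ann))
    }, integer(1)))
  # chr3 carries no elements at all
  expect_true(all(got$category[got$chrom == "chr3"] ==
                    "no_element_on_chrom"))
})

test_that("distance categories follow the documented breaks", {
  ann <- data.frame(chrom = "chr1", start = 10000L, end = 10300L,
                    element_class = "Alu_like", strand = "+",
                    copy_id = "c1")
  j <- data.frame(chrom_a = "chr1",
                  pos_a = c(10100L, 9500L, 8000L, 300L),
                  chrom_b = "chr1",
                  pos_b = c(10299L, 10300L, 150000L, 500000L),
                  strand_a = "+", strand_b = "-", class = "x",
                  support = 0L)
  got <- nearest_element_distance(j, ann)
  expect_identical(got$distance, c(0L, 500L, 2000L, 9700L, 0L, 1L,
                                   139701L, 489701L))
  expect_identical(got$category,
                   c("in_element", "lt_1kb", "kb_1_10", "kb_1_10",
                     "in_element", "lt_1kb", "gt_100kb", "gt_100kb"))
})

test_that("linearisation uses cumulative offsets with canonical end order", {
  lens <- c(chr1 = 1000, chr2 = 2000, chr3 = 500)
  j <- data.frame(chrom_a = c("chr1", "chr2", "chr3"),
                  pos_a = c(0L, 100L, 10L),
                  chrom_b = c("chr1", "chr1", "chr2"),
                  pos_b = c(0L, 900L, 1999L),
                  strand_a = "+", strand_b = "-", class = "x",
                  support = 0L)
  xy <- linearize_breakpoints(j, lens)
  # cumulative-offset oracle: chr1 at 0, chr2 at 1000, chr3 at 3000
  expect_identical(xy$x, c(0, 900, 1000 + 1999))
  expect_identical(xy$y, c(0, 1000 + 100, 3000 + 10))
  expect_true(all(xy$x <= xy$y))
  intra <- xy[1, ]
  expect_lt(abs(intra$x - intra$y), 1000)
})

test_that("statistics are invariant to junction input order", {
  lens <- c(chr1 = 1e6, chr2 = 1e6)
  j <- random_junctions(60, lens, seed = 23)
  perm <- j[sample(nrow(j)), ]
  regions <- data.frame(chrom = "chr1", start = 0L, end = 2e5)
  expect_identical(
    count_breakpoints_in_regions(j, regions),
    count_breakpoints_in_regions(perm, regions))
  r1 <- permutation_enrichment(j, regions, lens, n_perm = 100, seed = 24)
  r2 <- permutation_enrichment(perm, regions, lens, n_perm = 100,
                               seed = 24)
  expect_identical(r1$null_counts, r2$null_counts)
  expect_identical(r1$observed, r2$observed)
  m1 <- mc_intra_inter(j, lens, seed = 25)
  m2 <- mc_intra_inter(perm, lens, seed = 25)
  expect_identical(m1$chi_square, m2$chi_square)
})
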