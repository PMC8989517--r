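# Cut selection and NHEJ rejoining: identities, conservation accounting,
# forced reassemblies, and the stochastic invariants.

test_that("cut selection follows the cut model", {
  matches <- data.frame(chrom = "chr1", start = seq(0, 4900, by = 100),
                        strand = rep(c("+", "-"), 25), mismatch = 0L)
  expect_identical(nrow(select_cut_sites(matches, cut_model(0))), 0L)
  all_cuts <- select_cut_sites(matches, cut_model(1))
  expect_identical(nrow(all_cuts), 50L)
  # forward cut at start + 17, reverse at start + 3
  expect_true(all(all_cuts$pos[all_cuts$strand == "+"] %% 100 == 17))
  expect_true(all(all_cuts$pos[all_cuts$strand == "-"] %% 100 == 3))
  capped <- select_cut_sites(matches, cut_model(1, max_cuts = 10, seed = 1))
  expect_identical(nrow(capped), 10L)
  # binomial concentration of the selected count over 1000 distinct sites
  many <- data.frame(chrom = "chr1", start = seq(0, 99900, by = 100),
                     strand = "+", mismatch = 0L)
  n <- vapply(1:100, function(s) {
    nrow(select_cut_sites(many, cut_model(0.3, seed = s)))
  }, numeric(1))
  expect_gt(mean(n), 280)
  expect_lt(mean(n), 320)
})

test_that("zero cuts reproduce the genome unchanged", {
  g <- generate_genome(genome_spec(2, 5e4, seed = 1))
  rr <- rejoin(g, data.frame(chrom = character(0), pos = integer(0)),
               rejoin_model(seed = 2), bin_size = 1e4)
  expect_identical(nrow(rr$junctions), 0L)
  expect_identical(unclass(render_derivative(rr, g))[1:2],
                   stats::setNames(unclass(g), c("der1", "der2"))[1:2])
  expect_true(all(rr$copy_truth$copy == 1))
})

test_that("a forced middle-segment flip yields two inversion junctions", {
  lens <- c(chr1 = 30000L)
  segs <- data.frame(
    der_chrom = "der1", order = 1:3, chrom = "chr1",
    start = c(0L, 10000L, 20000L), end = c(10000L, 20000L, 30000L),
    strand = c("+", "-", "+"))
  rr <- derivative_from_segments(segs, lens, bin_size = 5000)
  expect_identical(nrow(rr$junctions), 2L)
  expect_identical(unique(rr$junctions$class), "inversion")
  # enumerated by hand: A+ joined to flipped B gives (+,+) at 10 kb; B to
  # C gives (-,-) at 20 kb
  expect_setequal(rr$junctions$pos_a, c(10000L, 10000L))
  expect_setequal(rr$junctions$pos_b, c(20000L, 20000L))
  expect_true(all(rr$copy_truth$copy == 1))
})

test_that("base conservation holds with loss and duplication", {
  scene <- make_scene(seed = 21, loss = 0.15, dup = 0.15)
  rr <- scene$rr
  der_bases <- sum(rr$segments$end - rr$segments$start)
  lost_bases <- sum(rr$lost$end - rr$lost$start)
  dup_bases <- sum(rr$duplicated$end - rr$duplicated$start)
  src_bases <- sum(scene$lens)
  expect_identical(der_bases + lost_bases, src_bases + dup_bases)
  # per-bin copy truth equals the naive per-base tabulation
  naive <- naive_bin_copy(rr$segments, scene$lens, 25000)
  expect_equal(rr$copy_truth$copy,
               naive$bases / (naive$end - naive$start))
})

test_that("pure reshuffles conserve total length exactly", {
  for (seed in c(31, 32)) {
    scene <- make_scene(seed = seed, loss = 0, dup = 0)
    expect_identical(
      sum(nchar(render_derivative(scene$rr, scene$genome))),
      sum(scene$lens))
  }
})

test_that("every junction end coincides with a cut (up to resection)", {
  res_max <- 10L
  scene <- make_scene(seed = 41, loss = 0.1, dup = 0.1,
                      resection = res_max)
  rr <- scene$rr
  cuts <- scene$cuts
  for (i in seq_len(nrow(rr$junctions))) {
    for (side in c("a", "b")) {
      cm <- rr$junctions[[paste0("chrom_", side)]][i]
      p <- rr$junctions[[paste0("pos_", side)]][i]
      d <- min(abs(cuts$pos[cuts$chrom == cm] - p))
      expect_lte(d, res_max)
    }
  }
})

test_that("derivative chromosomes keep two telomeres; parity never breaks", {
  for (seed in 51:56) {
    scene <- make_scene(seed = seed, loss = 0.2, dup = 0.2)
    seg <- scene$rr$segments
    for (dc in unique(seg$der_chrom)) {
      s <- seg[seg$der_chrom == dc, ]
      s <- s[order(s$order), ]
      first <- s[1, ]; last <- s[nrow(s), ]
      # first segment begins at a source 5' telomere in forward
      # orientation; last ends at a source 3' telomere
      expect_identical(first$start, 0L)
      expect_identical(first$strand, "+")
      expect_identical(last$end, unname(scene$lens[[last$chrom]]))
      expect_identical(last$strand, "+")
    }
  }
})

test_that("raising intra_bias raises the intra-chromosomal fraction", {
  frac <- function(bias) {
    f <- vapply(1:8, function(s) {
      scene <- make_scene(seed = 100 + s, intra_bias = bias)
      j <- scene$rr$junctions
      if (nrow(j) == 0) return(NA_real_)
      mean(j$chrom_a == j$chrom_b)
    }, numeric(1))
    mean(f, na.rm = TRUE)
  }
  expect_gt(frac(0.95), frac(0.05))
})

test_that("junction tables round-trip through BEDPE byte-identically", {
  scene <- make_scene(seed = 61)
  f1 <- tempfile(fileext = ".bedpe")
  f2 <- tempfile(fileext = ".bedpe")
  write_junctions_bedpe(scene$rr$junctions, f1)
  j2 <- read_junctions_bedpe(f1)
  write_junctions_bedpe(j2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(j2, scene$rr$junctions, ignore_attr = TRUE)
  # empty table: header-only file
  f3 <- tempfile(fileext = ".bedpe")
  write_junctions_bedpe(scene$rr$junctions[0, ], f3)
  expect_identical(length(readLines(f3)), 1L)
  expect_identical(nrow(read_junctions_bedpe(f3)), 0L)
})

test_that("cuts outside chromosome bounds are rejected", {
  g <- generate_genome(genome_spec(1, 1e4, seed = 1))
  expect_error(rejoin(g, data.frame(chrom = "chr1", pos = 20000L),
                      rejoin_model(seed = 1)), "inside")
  expect_error(rejoin(g, data.frame(chrom = "chrX", pos = 100L),
                      rejoin_model(seed = 1)), "inside")
})
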