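# Repeat-anchored long-read translocation calling: element detection,
# flank mapping, calling, evaluation, and PAF interoperability.

longread_scene <- function(seed = 301) {
  make_scene(seed = seed, n_chrom = 3, chrom_len = 4e5, copies = 25,
             cut_prob = 0.6, intra_bias = 0.3)
}

test_that("the banded alignment kernel agrees with pairwiseAlignment", {
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                      mismatch = -1)
  set.seed(411)
  for (rep in 1:5) {
    x <- gcrsim:::random_dna(400)
    y <- paste0(gcrsim:::random_dna(80),
                gcrsim:::apply_read_errors(x, 0.08),
                gcrsim:::random_dna(80))
    mine <- gcrsim:::.sw_banded_cpp(x, y, 1L, -1L, -2L, -300L, 300L)
    ref <- Biostrings::pairwiseAlignment(
      x, y, type = "local", substitutionMatrix = sub_mat,
      gapOpening = 0, gapExtension = 2)
    expect_identical(mine$score, as.integer(Biostrings::score(ref)))
    expect_identical(mine$n_match, Biostrings::nmatch(ref))
  }
})

test_that("element hits are found on consensus-bearing reads only", {
  scene <- longread_scene()
  cons <- scene$consensi[["Alu_like"]]
  backbone <- gcrsim:::random_dna(4000)
  read_seq <- paste0(substr(backbone, 1, 2000), cons,
                     substr(backbone, 2001, 4000))
  reads <- structure(list(
    reads = data.frame(read_id = c("r_cons", "r_plain", "r_rc"),
                       sequence = c(read_seq, backbone,
                                    gcrsim::revcomp(read_seq)),
                       length = c(nchar(read_seq), 4000L,
                                  nchar(read_seq)),
                       error_rate = 0, stringsAsFactors = FALSE),
    origin = data.frame()), class = "gcr_reads")
  hits <- find_element_reads(reads, scene$consensi["Alu_like"])
  expect_setequal(hits$read_id, c("r_cons", "r_rc"))
  h <- hits[hits$read_id == "r_cons", ]
  expect_identical(h$strand, "+")
  expect_lt(abs(h$read_start - 2000), 25)
  expect_lt(abs(h$read_end - 2300), 25)
  expect_gt(h$identity, 0.95)
  expect_identical(hits$strand[hits$read_id == "r_rc"], "-")
})

test_that("a pure consensus read is hit over nearly its whole length", {
  scene <- longread_scene()
  cons <- scene$consensi[["Alu_like"]]
  reads <- structure(list(
    reads = data.frame(read_id = "r", sequence = cons,
                       length = nchar(cons), error_rate = 0),
    origin = data.frame()), class = "gcr_reads")
  hits <- find_element_reads(reads, scene$consensi["Alu_like"],
                             min_span = 100)
  expect_identical(nrow(hits), 1L)
  expect_gt(hits$read_end - hits$read_start, 0.95 * nchar(cons))
})

test_that("10% element divergence still clears the identity threshold", {
  scene <- longread_scene()
  cons <- scene$consensi[["Alu_like"]]
  set.seed(5)
  noisy <- gcrsim:::apply_read_errors(cons, 0.1)
  reads <- structure(list(
    reads = data.frame(read_id = "r",
                       sequence = paste0(gcrsim:::random_dna(1000), noisy,
                                         gcrsim:::random_dna(1000)),
                       length = 2000L + nchar(noisy), error_rate = 0),
    origin = data.frame()), class = "gcr_reads")
  hits <- find_element_reads(reads, scene$consensi["Alu_like"])
  expect_identical(nrow(hits), 1L)
  expect_gte(hits$identity, 0.8)
})

test_that("random megabase-scale sequence yields no element hits", {
  scene <- longread_scene()
  set.seed(6)
  reads <- structure(list(
    reads = data.frame(read_id = sprintf("r%03d", 1:125),
                       sequence = vapply(1:125, function(i)
                         gcrsim:::random_dna(8000), character(1)),
                       length = 8000L, error_rate = 0),
    origin = data.frame()), class = "gcr_reads")
  hits <- find_element_reads(reads, scene$consensi["Alu_like"],
                             min_span = 100)
  expect_identical(nrow(hits), 0L)
})

test_that("flanks copied from the reference map back to their locus", {
  scene <- longread_scene()
  idx <- build_reference_index(scene$genome)
  flank <- substr(scene$genome[["chr2"]], 50001, 53000)
  aln <- map_sequence(flank, idx, "q1")
  expect_gte(nrow(aln), 1L)
  best <- aln[which.max(aln$n_anchors), ]
  expect_identical(best$chrom, "chr2")
  expect_identical(best$strand, "+")
  expect_gt(best$read_end - best$read_start, 0.95 * 3000)
  expect_lt(abs(best$r_start - 50000), 20)
  # reverse-complemented query maps to the same locus on the minus strand
  aln_rc <- map_sequence(gcrsim::revcomp(flank), idx, "q2")
  best_rc <- aln_rc[which.max(aln_rc$n_anchors), ]
  expect_identical(best_rc$chrom, "chr2")
  expect_identical(best_rc$strand, "-")
  expect_lt(abs(best_rc$r_start - 50000), 20)
  # random queries produce no confident chain
  set.seed(7)
  expect_identical(nrow(map_sequence(gcrsim:::random_dna(3000), idx,
                                     "q3")), 0L)
  expect_error(build_reference_index(
    structure(c(chr1 = "ACGT"), class = "gcr_genome")), "smaller than k")
})

test_that("an intact element locus produces no call (negative control)", {
  scene <- longread_scene()
  idx <- build_reference_index(scene$genome)
  ann <- scene$annotation
  cand <- ann[is.na(ann$guide_mismatch) & ann$start > 3000 &
                ann$end < scene$lens[ann$chrom] - 3000, ]
  copy <- cand[1, ] # an uncut copy away from the chromosome ends
  lo <- copy$start - 2000L
  read_seq <- substr(scene$genome[[copy$chrom]], lo + 1L,
                     copy$end + 2000L)
  reads <- structure(list(
    reads = data.frame(read_id = "r", sequence = read_seq,
                       length = nchar(read_seq), error_rate = 0),
    origin = data.frame()), class = "gcr_reads")
  hits <- find_element_reads(reads, scene$consensi["Alu_like"])
  expect_identical(nrow(hits), 1L)
  aln <- map_flanks(read_seq, "r", hits[1, ], idx)
  expect_gte(nrow(aln), 2L)
  calls <- call_translocations(hits, aln)
  expect_identical(nrow(calls), 0L)
})

test_that("junction-spanning reads cluster into one supported call", {
  scene <- longread_scene()
  idx <- build_reference_index(scene$genome)
  tri <- scene$rr$junctions[
    scene$rr$junctions$chrom_a != scene$rr$junctions$chrom_b, ]
  expect_gt(nrow(tri), 0L)
  # simulate many reads and keep those whose origin spans the first
  # inter-chromosomal junction
  reads <- simulate_long_reads(scene$rr, scene$genome, n_reads = 1500,
                               mean_length = 6000, error_rate = 0.05,
                               seed = 302)
  hits <- find_element_reads(reads, scene$consensi)
  aln <- do.call(rbind, lapply(
    which(reads$reads$read_id %in% hits$read_id), function(i) {
      h <- hits[hits$read_id == reads$reads$read_id[i], , drop = FALSE]
      map_flanks(reads$reads$sequence[i], reads$reads$read_id[i],
                 h[which.max(h$score), ], idx)
    }))
  calls <- call_translocations(hits, aln,
                               chrom_order = names(scene$lens))
  ci <- calls[calls$chrom_a != calls$chrom_b, ]
  ev <- evaluate_calls(ci, tri)
  expect_gte(ev$precision, 0.95)
  expect_gte(ev$recall, 0.7)
  # clustered support: called junctions aggregate multiple reads
  expect_gt(max(calls$support), 3L)
})

test_that("evaluation matching is greedy, 1-1 and boundary-inclusive", {
  truth <- data.frame(chrom_a = "chr1", pos_a = c(1000L, 50000L),
                      chrom_b = "chr2", pos_b = c(2000L, 60000L))
  ev_same <- evaluate_calls(truth, truth)
  expect_identical(ev_same$precision, 1)
  expect_identical(ev_same$recall, 1)
  ev_none <- evaluate_calls(truth[0, ], truth)
  expect_identical(ev_none$recall, 0)
  shifted <- truth
  shifted$pos_a <- shifted$pos_a + 499L
  shifted$pos_b <- shifted$pos_b - 499L
  expect_identical(evaluate_calls(shifted, truth, 500)$recall, 1)
  too_far <- truth
  too_far$pos_a <- too_far$pos_a + 501L
  expect_identical(evaluate_calls(too_far, truth, 500)$recall, 0)
})

test_that("PAF writer and reader round-trip and import cleanly", {
  scene <- longread_scene()
  idx <- build_reference_index(scene$genome)
  flank <- substr(scene$genome[["chr1"]], 100001, 103000)
  aln <- map_sequence(flank, idx, "q1")
  paf <- tempfile(fileext = ".paf")
  write_paf(aln, c(q1 = 3000L), scene$lens, paf)
  back <- read_paf(paf)
  expect_identical(back$qname, aln$read_id)
  expect_identical(back$qstart, aln$read_start)
  expect_identical(back$tstart, aln$r_start)
  sa <- paf_to_split_alignments(back)
  expect_identical(sa$read_start, aln$read_start)
  expect_identical(sa$chrom, aln$chrom)
  expect_identical(unique(sa$source), "paf_import")
  # empty file round-trip
  paf0 <- tempfile(fileext = ".paf")
  write_paf(aln[0, ], integer(0), scene$lens, paf0)
  expect_identical(nrow(read_paf(paf0)), 0L)
})

test_that("builtin-mapper and minimap2 PAF pipelines agree on calls", {
  scene <- longread_scene()
  idx <- build_reference_index(scene$genome)
  reads <- simulate_long_reads(scene$rr, scene$genome, n_reads = 400,
                               mean_length = 6000, error_rate = 0,
                               seed = 303)
  hits <- find_element_reads(reads, scene$consensi)
  aln_builtin <- do.call(rbind, lapply(
    which(reads$reads$read_id %in% hits$read_id), function(i) {
      h <- hits[hits$read_id == reads$reads$read_id[i], , drop = FALSE]
      map_flanks(reads$reads$sequence[i], reads$reads$read_id[i],
                 h[which.max(h$score), ], idx)
    }))
  calls_builtin <- call_translocations(hits, aln_builtin,
                                       chrom_order = names(scene$lens))

  dir <- tempfile(); dir.create(dir)
  ref_fa <- file.path(dir, "ref.fa"); rd_fa <- file.path(dir, "reads.fa")
  write_genome_fasta(scene$genome, ref_fa)
  write_reads_fasta(reads, rd_fa)
  paf_file <- file.path(dir, "aln.paf")
  status <- system2("minimap2",
                    c("-x", "map-ont", "-t", "1", ref_fa, rd_fa),
                    stdout = paf_file, stderr = FALSE)
  expect_identical(status, 0L)
  paf <- read_paf(paf_file)
  calls_paf <- call_translocations(hits, paf_to_split_alignments(paf),
                                   chrom_order = names(scene$lens))
  ev <- evaluate_calls(
    calls_paf[calls_paf$chrom_a != calls_paf$chrom_b, ],
    calls_builtin[calls_builtin$chrom_a != calls_builtin$chrom_b, ])
  expect_gte(ev$precision, 0.9)
  expect_gte(ev$recall, 0.9)
})
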