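# Independent brute-force oracles and small scene builders shared across
# the suite. The oracles deliberately use naive algorithms (per-window
# loops, per-base bitmaps, double loops) so they share no code path with
# the production implementations they check.

# Naive per-window Hamming scan on both strands; only usable on small
# genomes. `require_pam` checks the motif base by base.
naive_guide_scan <- function(genome, guide, max_mm, require_pam = FALSE,
                             pam = "NGG") {
  glen <- nchar(guide)
  gchars <- strsplit(guide, "")[[1]]
  rchars <- strsplit(gcrsim::revcomp(guide), "")[[1]]
  pam_chars <- strsplit(pam, "")[[1]]
  pam_rc <- strsplit(gcrsim::revcomp(pam), "")[[1]]
  res <- list()
  for (cm in names(genome)) {
    chars <- strsplit(genome[[cm]], "")[[1]]
    L <- length(chars)
    for (p in seq_len(L - glen + 1L)) {
      win <- chars[p:(p + glen - 1L)]
      for (strand in c("+", "-")) {
        ref <- if (strand == "+") gchars else rchars
        mm <- sum(win != ref | !(win %in% c("A", "C", "G", "T")))
        if (mm > max_mm) next
        if (require_pam) {
          if (strand == "+") {
            idx <- (p + glen):(p + glen + length(pam_chars) - 1L)
            if (max(idx) > L) next
            ok <- all(mapply(function(b, q) {
              b %in% c("A", "C", "G", "T") && (q == "N" || b == q)
            }, chars[idx], pam_chars))
          } else {
            idx <- (p - length(pam_chars)):(p - 1L)
            if (min(idx) < 1L) next
            ok <- all(mapply(function(b, q) {
              b %in% c("A", "C", "G", "T") && (q == "N" || b == q)
            }, chars[idx], pam_rc))
          }
          if (!ok) next
        }
        res[[length(res) + 1L]] <- data.frame(
          chrom = cm, start = p - 1L, strand = strand, mismatch = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), mismatch = integer(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# Exhaustive same-chromosome scan for the nearest element.
naive_nearest_distance <- function(chrom, pos, annotation) {
  ann <- annotation[annotation$chrom == chrom, , drop = FALSE]
  if (nrow(ann) == 0L) return(NA_integer_)
  d <- integer(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    d[i] <- if (pos >= ann$start[i] && pos < ann$end[i]) 0L
            else if (pos < ann$start[i]) ann$start[i] - pos
            else pos - ann$end[i] + 1L
  }
  min(d)
}

# O(n * m) double loop breakpoint-in-region count.
naive_count_in_regions <- function(junctions, regions,
                                   counting = "per_breakpoint") {
  bp <- data.frame(chrom = c(junctions$chrom_a, junctions$chrom_b),
                   pos = c(junctions$pos_a, junctions$pos_b),
                   j = rep(seq_len(nrow(junctions)), 2L))
  inside <- logical(nrow(bp))
  for (i in seq_len(nrow(bp))) {
    for (r in seq_len(nrow(regions))) {
      if (bp$chrom[i] == regions$chrom[r] &&
          bp$pos[i] >= regions$start[r] && bp$pos[i] < regions$end[r]) {
        inside[i] <- TRUE
      }
    }
  }
  if (counting == "per_breakpoint") sum(inside)
  else length(unique(bp$j[inside]))
}

# Per-base bitmap intersection of two region sets on a small genome.
bitmap_intersect <- function(a, b, chrom_lengths) {
  out <- list()
  for (cm in names(chrom_lengths)) {
    va <- logical(chrom_lengths[[cm]])
    vb <- logical(chrom_lengths[[cm]])
    for (r in which(a$chrom == cm)) va[(a$start[r] + 1L):a$end[r]] <- TRUE
    for (r in which(b$chrom == cm)) vb[(b$start[r] + 1L):b$end[r]] <- TRUE
    v <- va & vb
    if (!any(v)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths
    keep <- rl$values
    out[[cm]] <- data.frame(chrom = cm, start = starts[keep],
                            end = ends[keep], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

# Per-base copy counts of a derivative segment map, tabulated directly.
naive_bin_copy <- function(segments, chrom_lengths, bin_size) {
  grid <- gcrsim::bin_grid(chrom_lengths, bin_size)
  grid$bases <- 0
  for (cm in names(chrom_lengths)) {
    cover <- integer(chrom_lengths[[cm]])
    seg <- segments[segments$chrom == cm, , drop = FALSE]
    for (i in seq_len(nrow(seg))) {
      idx <- (seg$start[i] + 1L):seg$end[i]
      cover[idx] <- cover[idx] + 1L
    }
    sel <- which(grid$chrom == cm)
    for (s in sel) {
      grid$bases[s] <- sum(cover[(grid$start[s] + 1L):grid$end[s]])
    }
  }
  grid
}

# A small rearranged scene reused by several tests.
make_scene <- function(seed = 1, n_chrom = 3, chrom_len = 3e5,
                       copies = 25, cut_prob = 0.6, intra_bias = 0.5,
                       loss = 0, dup = 0, resection = 0) {
  g <- generate_genome(genome_spec(n_chrom, chrom_len, seed = seed))
  emb <- embed_repeats(
    g, repeat_spec("Alu_like", copy_number = copies,
                   guide_exact_fraction = 0.8,
                   mismatch_profile = c(0.1, 0.05)),
    gcr_guides[["sgAlu"]], seed = seed + 1)
  m <- find_guide_matches(emb$genome, gcr_guides[["sgAlu"]], 0)
  cuts <- select_cut_sites(m, cut_model(cut_probability = cut_prob,
                                        seed = seed + 2))
  rr <- rejoin(emb$genome, cuts,
               rejoin_model(intra_bias = intra_bias,
                            distance_scale = 2e5,
                            segment_loss_probability = loss,
                            segment_duplication_probability = dup,
                            end_resection_max = resection,
                            seed = seed + 3),
               bin_size = 25000)
  list(genome = emb$genome, annotation = emb$annotation,
       consensi = emb$consensi, matches = m, cuts = cuts, rr = rr,
       lens = chrom_lengths(emb$genome))
}
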