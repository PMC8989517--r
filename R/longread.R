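# Repeat-anchored long-read translocation calling.
#
# The pipeline mirrors the classic long-read workflow: filter reads, find
# reads containing a repeat-element consensus, map the element-flanking
# sequence to the reference, and call a translocation when the two flanks
# land on different chromosomal parts. The builtin mapper is a deliberately
# minimal unique-k-mer anchor chainer adequate for desk-scale synthetic
# references; alignments from a production long-read aligner can be
# imported as PAF and substituted for it.

# --- k-mer machinery -------------------------------------------------------

# Integer k-mer codes of a code vector (base 4); NA bases poison their
# windows. k <= 15 so codes stay within the integer range.
kmer_codes <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1L) return(integer(0))
  km <- codes[seq_len(n)]
  for (j in 2:k) {
    km <- km * 4L + codes[j:(n + j - 1L)]
  }
  km
}

#' Build a unique k-mer index over a reference genome
#'
#' Indexes every k-mer that occurs exactly once in the reference; repeated
#' k-mers are dropped, so anchors are unambiguous by construction.
#'
#' @param genome a `gcr_genome`.
#' @param k k-mer size (<= 15, default 14).
#' @return a `gcr_ref_index` list.
#' @export
build_reference_index <- function(genome, k = 14L) {
  k <- as.integer(k)
  if (k < 8L || k > 15L) stopf("k must lie in [8, 15]")
  if (sum(nchar(genome)) < k) stopf("reference smaller than k")
  kms <- list(); cms <- list(); pss <- list()
  for (ci in seq_along(genome)) {
    codes <- seq_codes(genome[[ci]])
    km <- kmer_codes(codes, k)
    ok <- which(!is.na(km))
    kms[[ci]] <- km[ok]
    cms[[ci]] <- rep.int(ci, length(ok))
    pss[[ci]] <- ok - 1L
  }
  km <- unlist(kms, use.names = FALSE)
  cm <- unlist(cms, use.names = FALSE)
  ps <- unlist(pss, use.names = FALSE)
  o <- order(km)
  km <- km[o]; cm <- cm[o]; ps <- ps[o]
  n <- length(km)
  dup <- c(FALSE, km[-1] == km[-n]) | c(km[-1] == km[-n], FALSE)
  keep <- !dup
  # stored as double so repeated findInterval lookups avoid re-coercion
  structure(list(k = k, kmer = as.numeric(km[keep]), chrom = cm[keep],
                 pos = ps[keep],
                 chrom_names = names(genome),
                 chrom_lengths = chrom_lengths(genome)),
            class = "gcr_ref_index")
}

# Anchors of a query code vector against the index: data.frame(qpos, chrom
# index, rpos), all 0-based.
lookup_anchors <- function(codes, index) {
  qk <- kmer_codes(codes, index$k)
  valid <- which(!is.na(qk))
  if (length(valid) == 0L) {
    return(data.frame(qpos = integer(0), chrom = integer(0),
                      rpos = integer(0)))
  }
  qv <- qk[valid]
  i <- findInterval(qv, index$kmer)
  hit <- i > 0L & index$kmer[pmax(i, 1L)] == qv
  data.frame(qpos = valid[hit] - 1L, chrom = index$chrom[i[hit]],
             rpos = index$pos[i[hit]])
}

# Cluster anchors of one orientation into collinear chains by diagonal.
# Returns one row per chain with >= min_anchors anchors.
chain_anchors <- function(anchors, k, band, min_anchors) {
  if (nrow(anchors) == 0L) return(NULL)
  out <- list()
  for (cm in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == cm, , drop = FALSE]
    diag <- a$rpos - a$qpos
    o <- order(diag, a$qpos)
    a <- a[o, ]; diag <- diag[o]
    grp <- cumsum(c(TRUE, diff(diag) > band))
    for (g in unique(grp)) {
      sel <- grp == g
      if (sum(sel) < min_anchors) next
      q <- a$qpos[sel]; r <- a$rpos[sel]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cm, q_start = min(q), q_end = max(q) + k,
        r_start = min(r), r_end = max(r) + k,
        n_anchors = sum(sel), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

empty_split_alignments <- function() {
  data.frame(read_id = character(0), read_start = integer(0),
             read_end = integer(0), chrom = character(0),
             r_start = integer(0), r_end = integer(0),
             strand = character(0), n_anchors = integer(0),
             identity = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Map a sequence to the reference with the builtin unique-k-mer mapper
#'
#' Finds unique-k-mer anchors on both strands, chains collinear anchors
#' (same chromosome and strand, consistent diagonal within a band), and
#' reports every chain with at least `min_anchors` anchors. Identity is
#' estimated from anchor density as `(matched / possible)^(1/k)`.
#'
#' @param seq query sequence (one flank or read).
#' @param index a [build_reference_index()].
#' @param read_id id stored on the result.
#' @param offset 0-based offset of `seq` within its read (so read
#'   coordinates refer to the full read).
#' @param band diagonal tolerance in bp (default scales with query length).
#' @param min_anchors minimum anchors per reported chain.
#' @param min_identity drop chains below this anchor-density identity.
#' @return SplitAlignment data.frame (possibly 0 rows).
#' @export
map_sequence <- function(seq, index, read_id = "query", offset = 0L,
                         band = NULL, min_anchors = 4L,
                         min_identity = 0.5) {
  len <- nchar(seq)
  if (len < index$k) return(empty_split_alignments())
  if (is.null(band)) band <- max(100L, as.integer(0.1 * len))
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    anc <- lookup_anchors(seq_codes(s), index)
    ch <- chain_anchors(anc, index$k, band, min_anchors)
    if (is.null(ch)) next
    if (strand == "-") {
      q_start <- len - ch$q_end
      ch$q_end <- len - ch$q_start
      ch$q_start <- q_start
    }
    n_possible <- pmax((ch$q_end - ch$q_start) - index$k + 1L, 1L)
    ch$identity <- pmin(1, (ch$n_anchors / n_possible)^(1 / index$k))
    ch$strand <- strand
    res[[length(res) + 1L]] <- ch
  }
  if (length(res) == 0L) return(empty_split_alignments())
  ch <- do.call(rbind, res)
  ch <- ch[ch$identity >= min_identity, , drop = FALSE]
  if (nrow(ch) == 0L) return(empty_split_alignments())
  data.frame(read_id = read_id, read_start = offset + ch$q_start,
             read_end = offset + ch$q_end,
             chrom = index$chrom_names[ch$chrom],
             r_start = ch$r_start, r_end = ch$r_end, strand = ch$strand,
             n_anchors = ch$n_anchors, identity = ch$identity,
             source = "builtin_mapper", stringsAsFactors = FALSE)
}

# --- element detection -----------------------------------------------------

# Precompute per-class seed tables: sorted k-mer codes with consensus
# positions, for both orientations.
consensus_seed_tables <- function(consensi, k) {
  lapply(consensi, function(cons) {
    lapply(c(`+` = cons, `-` = revcomp(cons)), function(s) {
      km <- kmer_codes(seq_codes(s), k)
      ok <- which(!is.na(km))
      o <- order(km[ok])
      list(kmer = km[ok][o], pos = (ok - 1L)[o])
    })
  })
}

#' Find reads containing a repeat-element consensus
#'
#' Reads are screened with k-mer seeds against each element consensus
#' (both orientations); candidates are refined by banded local alignment
#' (match +1, mismatch -1, gap -2) of the consensus against the seeded read
#' window. The best hit per (read, class) is kept when its identity over
#' the aligned span reaches `min_identity` and the aligned read span
#' reaches `min_span`.
#'
#' @param reads a `gcr_reads` object.
#' @param consensi named character vector (or list) of element consensus
#'   sequences, e.g. from [embed_repeats()].
#' @param k seed k-mer size (default 12).
#' @param min_identity minimum identity over the aligned span.
#' @param min_span minimum aligned span on the read, bp.
#' @param min_seed_kmers seed matches required to trigger alignment; the
#'   effective threshold additionally adapts to the chance-match rate of
#'   the read against each seed table (a long consensus shares k-mers
#'   with a long read by chance alone), so random reads rarely reach the
#'   alignment stage.
#' @return data.frame of element hits: read_id, read_start, read_end,
#'   element_class, strand, identity.
#' @export
find_element_reads <- function(reads, consensi, k = 12L,
                               min_identity = 0.8, min_span = 100L,
                               min_seed_kmers = 3L) {
  stopifnot(inherits(reads, "gcr_reads"))
  k <- as.integer(k)
  seeds <- consensus_seed_tables(as.list(consensi), k)
  hits <- list()
  for (i in seq_len(nrow(reads$reads))) {
    rseq <- reads$reads$sequence[i]
    rlen <- nchar(rseq)
    if (rlen < k) next
    rcodes <- seq_codes(rseq)
    rk <- kmer_codes(rcodes, k)
    valid <- which(!is.na(rk))
    if (length(valid) == 0L) next
    rkv <- rk[valid]
    for (cls in names(seeds)) {
      best <- NULL
      for (strand in c("+", "-")) {
        tab <- seeds[[cls]][[strand]]
        chance <- length(rkv) * length(tab$kmer) / 4^k
        thr <- max(min_seed_kmers,
                   stats::qpois(1 - 1e-4, chance) + 1L)
        ii <- findInterval(rkv, tab$kmer)
        mhit <- ii > 0L & tab$kmer[pmax(ii, 1L)] == rkv
        if (sum(mhit) < thr) next
        qpos <- valid[mhit] - 1L
        cpos <- tab$pos[ii[mhit]]
        cons <- as.list(consensi)[[cls]]
        if (strand == "-") cons <- revcomp(cons)
        clen <- nchar(cons)
        # keep only the dominant diagonal cluster of seeds: spurious
        # off-diagonal matches would otherwise inflate the DP band
        drift <- as.integer(30L + 0.05 * clen)
        dg <- qpos - cpos
        o <- order(dg)
        grp <- cumsum(c(TRUE, diff(dg[o]) > drift))
        gbest <- which.max(tabulate(grp))
        sel <- o[grp == gbest]
        if (length(sel) < thr) next
        qpos <- qpos[sel]; cpos <- cpos[sel]
        margin <- drift + 20L
        # trim both sequences to the seeded overlap so the DP cost scales
        # with the shared region, not the full consensus length
        c0 <- max(0L, min(cpos) - margin)
        c1 <- min(clen, max(cpos) + k + margin)
        cpart <- substr(cons, c0 + 1L, c1)
        w0 <- max(0L, min(qpos) - (min(cpos) - c0) - margin)
        w1 <- min(rlen, max(qpos) + (c1 - max(cpos)) + margin)
        window <- substr(rseq, w0 + 1L, w1)
        # diagonals of trimmed consensus (a) vs window (b): b_pos - a_pos
        d <- (qpos - w0) - (cpos - c0)
        aln <- .sw_banded_cpp(cpart, window, 1L, -1L, -2L,
                              min(d) - margin, max(d) + margin)
        if (aln$aln_len == 0L) next
        identity <- aln$n_match / aln$aln_len
        span <- aln$b_end - aln$b_start
        if (identity < min_identity || span < min_span) next
        cand <- data.frame(
          read_id = reads$reads$read_id[i],
          read_start = w0 + aln$b_start, read_end = w0 + aln$b_end,
          element_class = cls, strand = strand,
          identity = identity, score = aln$score,
          stringsAsFactors = FALSE)
        if (is.null(best) || cand$score > best$score) best <- cand
      }
      if (!is.null(best)) hits[[length(hits) + 1L]] <- best
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(read_id = character(0), read_start = integer(0),
                      read_end = integer(0), element_class = character(0),
                      strand = character(0), identity = numeric(0),
                      score = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Map the two element-flanking sequences of a read
#'
#' Extracts the read sequence on either side of an element hit and maps
#' each flank with the builtin mapper; flanks shorter than `min_flank` are
#' skipped. Among a flank's chains, the caller later selects the
#' element-proximal one.
#'
#' @param read_seq full read sequence.
#' @param read_id read identifier.
#' @param element_hit one row of [find_element_reads()] output.
#' @param index reference index.
#' @param min_flank minimum flank length to attempt mapping.
#' @param min_anchors minimum anchors per chain.
#' @param min_identity drop chains below this anchor-density identity.
#' @return SplitAlignment data.frame for both flanks (possibly 0 rows).
#' @export
map_flanks <- function(read_seq, read_id, element_hit, index,
                       min_flank = 200L, min_anchors = 4L,
                       min_identity = 0.5) {
  len <- nchar(read_seq)
  flanks <- list()
  if (element_hit$read_start >= min_flank) {
    flanks[[length(flanks) + 1L]] <-
      list(seq = substr(read_seq, 1L, element_hit$read_start), offset = 0L)
  }
  if (len - element_hit$read_end >= min_flank) {
    flanks[[length(flanks) + 1L]] <-
      list(seq = substr(read_seq, element_hit$read_end + 1L, len),
           offset = element_hit$read_end)
  }
  if (length(flanks) == 0L) return(empty_split_alignments())
  # one batched index lookup for all flanks x strands: pieces are
  # concatenated with an NA separator so no k-mer spans a boundary
  pieces <- list()
  for (fi in seq_along(flanks)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") flanks[[fi]]$seq else revcomp(flanks[[fi]]$seq)
      pieces[[length(pieces) + 1L]] <-
        list(codes = seq_codes(s), flank = fi, strand = strand,
             len = nchar(s))
    }
  }
  sep <- rep(NA_integer_, index$k)
  cat_codes <- unlist(lapply(pieces, function(p) c(p$codes, sep)),
                      use.names = FALSE)
  anc <- lookup_anchors(cat_codes, index)
  starts <- cumsum(c(0L, vapply(pieces, function(p) p$len + index$k,
                                integer(1))))
  out <- list()
  for (pi in seq_along(pieces)) {
    p <- pieces[[pi]]
    sel <- anc$qpos >= starts[pi] & anc$qpos < starts[pi] + p$len
    if (!any(sel)) next
    a <- anc[sel, , drop = FALSE]
    a$qpos <- a$qpos - starts[pi]
    ch <- chain_anchors(a, index$k, max(100L, as.integer(0.1 * p$len)),
                        min_anchors)
    if (is.null(ch)) next
    if (p$strand == "-") {
      q_start <- p$len - ch$q_end
      ch$q_end <- p$len - ch$q_start
      ch$q_start <- q_start
    }
    n_possible <- pmax((ch$q_end - ch$q_start) - index$k + 1L, 1L)
    ch$identity <- pmin(1, (ch$n_anchors / n_possible)^(1 / index$k))
    ch$strand <- p$strand
    ch$offset <- flanks[[p$flank]]$offset
    out[[length(out) + 1L]] <- ch
  }
  if (length(out) == 0L) return(empty_split_alignments())
  ch <- do.call(rbind, out)
  ch <- ch[ch$identity >= min_identity, , drop = FALSE]
  if (nrow(ch) == 0L) return(empty_split_alignments())
  data.frame(read_id = read_id, read_start = ch$offset + ch$q_start,
             read_end = ch$offset + ch$q_end,
             chrom = index$chrom_names[ch$chrom],
             r_start = ch$r_start, r_end = ch$r_end, strand = ch$strand,
             n_anchors = ch$n_anchors, identity = ch$identity,
             source = "builtin_mapper", stringsAsFactors = FALSE)
}

# --- translocation calling -------------------------------------------------

#' Call translocations from element hits and flank alignments
#'
#' For every read carrying an element hit with mapped flanks on both sides,
#' a rearrangement is called when the flanks map to different chromosomes,
#' to the same chromosome more than `min_distance` apart, or with
#' incompatible orientation (inversion type). Breakpoint coordinates are
#' the element-proximal ends of the two flank alignments. Per-read calls
#' are clustered across reads within `cluster_window` bp on both ends and
#' support accumulated.
#'
#' @param element_hits output of [find_element_reads()].
#' @param split_alignments SplitAlignment table covering the element
#'   flanks, from [map_flanks()] or [paf_to_split_alignments()].
#' @param min_flank minimum mapped flank span, bp.
#' @param min_distance same-chromosome distance beyond which flanks count
#'   as different chromosomal parts (default 100 kb, safely larger than an
#'   intact element locus).
#' @param min_support minimum supporting reads per reported call.
#' @param cluster_window clustering tolerance, bp.
#' @param prox_slack maximum gap, bp, between a selected flank alignment
#'   and the element boundary; reads whose flank chain does not reach the
#'   element are not used (their element-adjacent locus is unresolved).
#' @param min_identity minimum flank-alignment identity used for calling
#'   (alignments with unknown identity pass).
#' @param chrom_order chromosome order for canonical output.
#' @return data.frame of translocation calls: chrom_a, pos_a, strand_a,
#'   chrom_b, pos_b, strand_b, class, support, element_class, read_ids.
#' @export
call_translocations <- function(element_hits, split_alignments,
                                min_flank = 200L, min_distance = 1e5,
                                min_support = 1L, cluster_window = 500L,
                                prox_slack = 150L, min_identity = 0.8,
                                chrom_order = NULL) {
  per_read <- list()
  slack <- 60L
  # sparse chance anchor clusters produce low-identity chains; only
  # well-supported flank alignments may anchor a call
  split_alignments <- split_alignments[
    is.na(split_alignments$identity) |
      split_alignments$identity >= min_identity, , drop = FALSE]
  for (i in seq_len(nrow(element_hits))) {
    hit <- element_hits[i, ]
    aln <- split_alignments[split_alignments$read_id == hit$read_id, ,
                            drop = FALSE]
    if (nrow(aln) == 0L) next
    span <- aln$read_end - aln$read_start
    left <- aln[aln$read_start + min_flank <= hit$read_start &
                  aln$read_end <= hit$read_end + slack &
                  span >= min_flank, , drop = FALSE]
    right <- aln[aln$read_end - min_flank >= hit$read_end &
                   aln$read_start >= hit$read_start - slack &
                   span >= min_flank, , drop = FALSE]
    if (nrow(left) == 0L || nrow(right) == 0L) next
    left <- left[which.max(left$read_end), ]
    right <- right[which.min(right$read_start), ]
    # the selected chains must reach the element boundary: a gap means the
    # read continues through an unmapped (or differently mapped) piece and
    # the element-adjacent locus is unknown -- calling would misplace the
    # breakpoint
    if (hit$read_start - left$read_end > prox_slack ||
        right$read_start - hit$read_end > prox_slack) next
    # element-proximal breakpoints; strand "+" = joined piece lies below
    # the breakpoint, "-" = above (same convention as junction truth)
    if (left$strand == "+") {
      pa <- left$r_end; sa <- "+"
    } else {
      pa <- left$r_start; sa <- "-"
    }
    if (right$strand == "+") {
      pb <- right$r_start; sb <- "-"
    } else {
      pb <- right$r_end; sb <- "+"
    }
    normal <- left$chrom == right$chrom && sa != sb && {
      plus <- if (sa == "+") pa else pb
      minus <- if (sa == "+") pb else pa
      plus <= minus && (minus - plus) <= min_distance
    }
    if (normal) next
    cls <- classify_junction(left$chrom, pa, sa, right$chrom, pb, sb,
                             adjacent = FALSE)
    if (cls %in% c("deletion", "duplication", "religation")) {
      cls <- "translocation_intra"
    }
    per_read[[length(per_read) + 1L]] <- data.frame(
      chrom_a = left$chrom, pos_a = as.integer(pa), strand_a = sa,
      chrom_b = right$chrom, pos_b = as.integer(pb), strand_b = sb,
      class = cls, read_id = hit$read_id,
      element_class = hit$element_class, stringsAsFactors = FALSE)
  }
  if (length(per_read) == 0L) return(empty_calls())
  ev <- do.call(rbind, per_read)
  if (is.null(chrom_order)) {
    chrom_order <- sort(unique(c(ev$chrom_a, ev$chrom_b)))
  }
  ev <- canonicalize_events(ev, chrom_order)
  # cluster within (chrom pair, strand pair)
  key <- paste(ev$chrom_a, ev$chrom_b, ev$strand_a, ev$strand_b)
  out <- list()
  for (kk in unique(key)) {
    e <- ev[key == kk, , drop = FALSE]
    e <- e[order(e$pos_a, e$pos_b), , drop = FALSE]
    cl <- integer(nrow(e))
    ref_a <- ref_b <- NULL
    cur <- 0L
    for (j in seq_len(nrow(e))) {
      if (cur == 0L || abs(e$pos_a[j] - ref_a) > cluster_window ||
          abs(e$pos_b[j] - ref_b) > cluster_window) {
        cur <- cur + 1L
        ref_a <- e$pos_a[j]; ref_b <- e$pos_b[j]
      }
      cl[j] <- cur
    }
    for (g in unique(cl)) {
      sel <- which(cl == g)
      ids <- unique(e$read_id[sel])
      if (length(ids) < min_support) next
      out[[length(out) + 1L]] <- data.frame(
        chrom_a = e$chrom_a[sel[1]],
        pos_a = as.integer(round(stats::median(e$pos_a[sel]))),
        strand_a = e$strand_a[sel[1]],
        chrom_b = e$chrom_b[sel[1]],
        pos_b = as.integer(round(stats::median(e$pos_b[sel]))),
        strand_b = e$strand_b[sel[1]],
        class = e$class[sel[1]], support = length(ids),
        element_class = e$element_class[sel[1]],
        read_ids = paste(ids, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) return(empty_calls())
  calls <- calls[order(match(calls$chrom_a, chrom_order), calls$pos_a), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(chrom_a = character(0), pos_a = integer(0),
             strand_a = character(0), chrom_b = character(0),
             pos_b = integer(0), strand_b = character(0),
             class = character(0), support = integer(0),
             element_class = character(0), read_ids = character(0),
             stringsAsFactors = FALSE)
}

# canonicalize per-read events (same as junctions but extra columns ride
# along)
canonicalize_events <- function(ev, chrom_order) {
  ia <- match(ev$chrom_a, chrom_order)
  ib <- match(ev$chrom_b, chrom_order)
  swap <- ib < ia | (ib == ia & ev$pos_b < ev$pos_a)
  if (any(swap)) {
    tmp <- ev[swap, c("chrom_a", "pos_a", "strand_a")]
    ev[swap, c("chrom_a", "pos_a", "strand_a")] <-
      ev[swap, c("chrom_b", "pos_b", "strand_b")]
    ev[swap, c("chrom_b", "pos_b", "strand_b")] <- tmp
  }
  ev
}

#' Evaluate translocation calls against simulated truth
#'
#' Greedy 1-1 matching: call/truth pairs on the same chromosome pair whose
#' two breakpoints both lie within `tolerance` bp are matched in order of
#' increasing distance.
#'
#' @param calls call table (chrom_a/pos_a/chrom_b/pos_b).
#' @param truth truth junction table (same columns).
#' @param tolerance matching tolerance, bp.
#' @return list: precision, recall, n_calls, n_truth, matches (per-pair
#'   table with distances), unmatched_truth indices.
#' @export
evaluate_calls <- function(calls, truth, tolerance = 500L) {
  chrom_order <- sort(unique(c(calls$chrom_a, calls$chrom_b,
                               truth$chrom_a, truth$chrom_b)))
  n_calls <- nrow(calls); n_truth <- nrow(truth)
  if (n_calls == 0L || n_truth == 0L) {
    return(list(precision = if (n_calls == 0L) NA_real_ else 0,
                recall = if (n_truth == 0L) NA_real_ else 0,
                n_calls = n_calls, n_truth = n_truth,
                matches = data.frame(), unmatched_truth = seq_len(n_truth)))
  }
  calls <- canonicalize_junctions(
    data.frame(chrom_a = calls$chrom_a, pos_a = calls$pos_a,
               strand_a = ".", chrom_b = calls$chrom_b,
               pos_b = calls$pos_b, strand_b = ".",
               class = ".", support = 0L, stringsAsFactors = FALSE),
    chrom_order)
  truth <- canonicalize_junctions(
    data.frame(chrom_a = truth$chrom_a, pos_a = truth$pos_a,
               strand_a = ".", chrom_b = truth$chrom_b,
               pos_b = truth$pos_b, strand_b = ".",
               class = ".", support = 0L, stringsAsFactors = FALSE),
    chrom_order)
  pairs <- list()
  for (i in seq_len(n_calls)) {
    same <- which(truth$chrom_a == calls$chrom_a[i] &
                    truth$chrom_b == calls$chrom_b[i])
    if (length(same) == 0L) next
    da <- abs(truth$pos_a[same] - calls$pos_a[i])
    db <- abs(truth$pos_b[same] - calls$pos_b[i])
    ok <- which(da <= tolerance & db <= tolerance)
    if (length(ok) == 0L) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      call = i, truth = same[ok], dist = pmax(da[ok], db[ok]))
  }
  matched_call <- logical(n_calls)
  matched_truth <- logical(n_truth)
  matches <- data.frame(call = integer(0), truth = integer(0),
                        dist = integer(0))
  if (length(pairs) > 0L) {
    pr <- do.call(rbind, pairs)
    pr <- pr[order(pr$dist), , drop = FALSE]
    for (j in seq_len(nrow(pr))) {
      if (!matched_call[pr$call[j]] && !matched_truth[pr$truth[j]]) {
        matched_call[pr$call[j]] <- TRUE
        matched_truth[pr$truth[j]] <- TRUE
        matches <- rbind(matches, pr[j, ])
      }
    }
  }
  list(precision = sum(matched_call) / n_calls,
       recall = sum(matched_truth) / n_truth,
       n_calls = n_calls, n_truth = n_truth, matches = matches,
       unmatched_truth = which(!matched_truth))
}
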