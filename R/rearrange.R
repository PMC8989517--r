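# Cut-and-rejoin rearrangement simulator.
#
# Multiple double-strand breaks at guide target sites are rejoined
# NHEJ-style: chromosomes are split at the selected cuts, internal segments
# may be lost or duplicated, and free ends are paired sequentially with a
# bias towards same-chromosome, nearby partners. The result is a derivative
# genome (an ordered segment map over source coordinates), the full junction
# list, and binned copy-number ground truth -- everything downstream
# statistics are validated against.

#' Cas9 cut model
#'
#' @param cut_probability per-matching-site probability of cleavage.
#' @param cut_offset bp from the protospacer start to the blunt cut on the
#'   protospacer strand; the default 17 encodes the canonical cut 3 bp 5' of
#'   the PAM.
#' @param max_cuts optional cap on the number of cuts (uniform subsample).
#' @param seed RNG seed.
#' @return a `gcr_cut_model` list.
#' @export
cut_model <- function(cut_probability = 1, cut_offset = 17L,
                      max_cuts = NULL, seed = NULL) {
  if (cut_probability < 0 || cut_probability > 1) {
    stopf("cut_probability must lie in [0, 1]")
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > 20L) {
    stopf("cut_offset must lie in [0, 20]")
  }
  structure(list(cut_probability = cut_probability, cut_offset = cut_offset,
                 max_cuts = max_cuts, seed = seed),
            class = "gcr_cut_model")
}

#' NHEJ rejoining model
#'
#' @param intra_bias weight favouring rejoining ends from the same source
#'   chromosome (see Details).
#' @param distance_scale bp scale of the exponential proximity kernel for
#'   same-chromosome ends.
#' @param segment_loss_probability chance an internal free segment is
#'   discarded (producing a deletion).
#' @param segment_duplication_probability chance an internal segment is
#'   copied before reassembly (producing a gain).
#' @param end_resection_max maximum bp trimmed per free end
#'   (uniform on 0..max).
#' @param seed RNG seed.
#' @details During sequential end pairing a candidate partner end on the
#'   same source chromosome at distance d is drawn with weight
#'   `intra_bias * exp(-d / distance_scale)`; ends on other chromosomes are
#'   drawn with uniform weight `1 - intra_bias`. Telomeric segments are
#'   never lost or duplicated, so every derivative chromosome ends in two
#'   original telomeres.
#' @return a `gcr_rejoin_model` list.
#' @export
rejoin_model <- function(intra_bias = 0.95, distance_scale = 1e6,
                         segment_loss_probability = 0.05,
                         segment_duplication_probability = 0.05,
                         end_resection_max = 0L, seed = NULL) {
  for (p in c(intra_bias, segment_loss_probability,
              segment_duplication_probability)) {
    if (p < 0 || p > 1) stopf("probabilities must lie in [0, 1]")
  }
  if (distance_scale <= 0) stopf("distance_scale must be > 0")
  if (end_resection_max < 0) stopf("end_resection_max must be >= 0")
  structure(list(intra_bias = intra_bias, distance_scale = distance_scale,
                 segment_loss_probability = segment_loss_probability,
                 segment_duplication_probability =
                   segment_duplication_probability,
                 end_resection_max = as.integer(end_resection_max),
                 seed = seed),
            class = "gcr_rejoin_model")
}

#' Select cut sites from a guide-match table
#'
#' Each match is cleaved independently with `cut_probability`. The cut
#' coordinate is `start + cut_offset` for forward-strand protospacers and
#' `start + (20 - cut_offset)` for reverse-strand ones, reported in
#' forward-strand coordinates. With `max_cuts` the selected set is uniformly
#' subsampled.
#'
#' @param matches data.frame as returned by [find_guide_matches()].
#' @param model a [cut_model()].
#' @return data.frame: chrom, pos, strand, mismatch; sorted by (chrom, pos).
#' @export
select_cut_sites <- function(matches, model = cut_model()) {
  stopifnot(inherits(model, "gcr_cut_model"))
  with_seed(model$seed, {
    keep <- stats::runif(nrow(matches)) < model$cut_probability
    sel <- matches[keep, , drop = FALSE]
    if (!is.null(model$max_cuts) && nrow(sel) > model$max_cuts) {
      sel <- sel[sort(sample.int(nrow(sel), model$max_cuts)), , drop = FALSE]
    }
  })
  pos <- ifelse(sel$strand == "+",
                sel$start + model$cut_offset,
                sel$start + (20L - model$cut_offset))
  out <- data.frame(chrom = sel$chrom, pos = as.integer(pos),
                    strand = sel$strand,
                    mismatch = sel$mismatch, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out <- out[!duplicated(out[c("chrom", "pos")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Classify one junction from its two oriented breakpoints. Strand "+" means
# the joined piece occupies coordinates below the breakpoint, "-" above.
# `adjacent` says whether the two ends derive from the same or neighbouring
# cuts on one chromosome (NA when unknown).
classify_junction <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                              adjacent = NA) {
  if (chrom1 != chrom2) return("translocation_inter")
  if (strand1 == strand2) return("inversion")
  pos_plus <- if (strand1 == "+") pos1 else pos2
  pos_minus <- if (strand1 == "+") pos2 else pos1
  if (pos_plus == pos_minus) return("religation")
  if (pos_plus < pos_minus) {
    if (is.na(adjacent) || adjacent) "deletion" else "translocation_intra"
  } else {
    "duplication"
  }
}

# Fraction of [lo, hi) on `chrom` covered by the intervals in `segs`.
interval_covered_frac <- function(chrom, lo, hi, segs) {
  if (hi <= lo || is.null(segs) || nrow(segs) == 0L) return(0)
  s <- segs[segs$chrom == chrom, , drop = FALSE]
  if (nrow(s) == 0L) return(0)
  ov <- pmin(s$end, hi) - pmax(s$start, lo)
  sum(pmax(ov, 0)) / (hi - lo)
}

empty_junctions <- function() {
  data.frame(chrom_a = character(0), pos_a = integer(0),
             strand_a = character(0), chrom_b = character(0),
             pos_b = integer(0), strand_b = character(0),
             class = character(0), support = integer(0),
             stringsAsFactors = FALSE)
}

# Canonical orientation: end A is the lexicographically smaller
# (chromosome-order index, position).
canonicalize_junctions <- function(junc, chrom_order) {
  if (nrow(junc) == 0L) return(junc)
  ia <- match(junc$chrom_a, chrom_order)
  ib <- match(junc$chrom_b, chrom_order)
  swap <- ib < ia | (ib == ia & junc$pos_b < junc$pos_a)
  if (any(swap)) {
    tmp <- junc[swap, c("chrom_a", "pos_a", "strand_a")]
    junc[swap, c("chrom_a", "pos_a", "strand_a")] <-
      junc[swap, c("chrom_b", "pos_b", "strand_b")]
    junc[swap, c("chrom_b", "pos_b", "strand_b")] <- tmp
  }
  ord <- order(match(junc$chrom_a, chrom_order), junc$pos_a,
               match(junc$chrom_b, chrom_order), junc$pos_b)
  junc <- junc[ord, , drop = FALSE]
  rownames(junc) <- NULL
  junc
}

#' Assemble a derivative genome from an explicit segment plan
#'
#' Lower-level constructor used by [rejoin()] and directly useful for
#' deterministic tests: given ordered source segments per derivative
#' chromosome, derives the junction list (from consecutive segment ends) and
#' binned copy-number truth.
#'
#' @param segments data.frame: der_chrom, order, chrom, start, end, strand
#'   (0-based half-open source coordinates).
#' @param chrom_lengths named lengths of the source genome.
#' @param bin_size bin size for the copy-number truth.
#' @return a `gcr_rearrangement` list (see [rejoin()]).
#' @export
derivative_from_segments <- function(segments, chrom_lengths,
                                     bin_size = 50000L) {
  stopifnot(all(c("der_chrom", "order", "chrom", "start", "end", "strand")
                %in% names(segments)))
  if (any(segments$start < 0L) ||
      any(segments$end > chrom_lengths[segments$chrom])) {
    stopf("segment coordinates outside source chromosome bounds")
  }
  junc <- empty_junctions()
  for (dc in unique(segments$der_chrom)) {
    seg <- segments[segments$der_chrom == dc, , drop = FALSE]
    seg <- seg[order(seg$order), , drop = FALSE]
    if (nrow(seg) < 2L) next
    for (i in seq_len(nrow(seg) - 1L)) {
      up <- seg[i, ]; dn <- seg[i + 1L, ]
      p1 <- if (up$strand == "+") up$end else up$start
      s1 <- if (up$strand == "+") "+" else "-"
      p2 <- if (dn$strand == "+") dn$start else dn$end
      s2 <- if (dn$strand == "+") "-" else "+"
      cls <- classify_junction(up$chrom, p1, s1, dn$chrom, p2, s2)
      if (cls == "religation") next
      junc <- rbind(junc, data.frame(
        chrom_a = up$chrom, pos_a = as.integer(p1), strand_a = s1,
        chrom_b = dn$chrom, pos_b = as.integer(p2), strand_b = s2,
        class = cls, support = 0L, stringsAsFactors = FALSE))
    }
  }
  junc <- canonicalize_junctions(junc, names(chrom_lengths))
  structure(list(
    segments = segments,
    junctions = junc,
    copy_truth = copy_number_truth(segments, chrom_lengths, bin_size),
    lost = NULL, duplicated = NULL, cuts = NULL,
    chrom_lengths = chrom_lengths
  ), class = "gcr_rearrangement")
}

#' Binned copy-number truth implied by a derivative segment map
#'
#' For every bin of the source genome, the mean per-base copy count over the
#' bin (sum of segment overlaps divided by bin width). A value of 1 is
#' copy-neutral; the last bin of each chromosome may be short.
#'
#' @param segments derivative segment map (data.frame with chrom/start/end).
#' @param chrom_lengths named source chromosome lengths.
#' @param bin_size bin size in bp.
#' @return data.frame: chrom, start, end, copy.
#' @export
copy_number_truth <- function(segments, chrom_lengths, bin_size = 50000L) {
  bin_size <- as.integer(bin_size)
  grid <- bin_grid(chrom_lengths, bin_size)
  cov <- numeric(nrow(grid))
  first_bin <- match(unique(grid$chrom), grid$chrom)
  names(first_bin) <- unique(grid$chrom)
  for (i in seq_len(nrow(segments))) {
    cm <- segments$chrom[i]
    st <- segments$start[i]; en <- segments$end[i]
    if (en <= st) next
    b0 <- st %/% bin_size
    b1 <- (en - 1L) %/% bin_size
    idx <- first_bin[[cm]] + b0:b1
    ov <- pmin(grid$end[idx], en) - pmax(grid$start[idx], st)
    cov[idx] <- cov[idx] + ov
  }
  grid$copy <- cov / (grid$end - grid$start)
  grid
}

#' Bin grid tiling a genome
#'
#' @param chrom_lengths named chromosome lengths.
#' @param bin_size bin size in bp; the last bin of a chromosome may be
#'   short.
#' @return data.frame: chrom, start, end (0-based half-open).
#' @export
bin_grid <- function(chrom_lengths, bin_size) {
  bin_size <- as.integer(bin_size)
  if (bin_size <= 0L) stopf("bin_size must be > 0")
  out <- lapply(names(chrom_lengths), function(cm) {
    L <- chrom_lengths[[cm]]
    starts <- seq.int(0L, L - 1L, by = bin_size)
    data.frame(chrom = cm, start = starts,
               end = pmin(starts + bin_size, L), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate NHEJ rejoining of cut chromosomes
#'
#' Splits each chromosome at its cut positions, discards or duplicates
#' internal segments per the model, optionally resects free ends, and pairs
#' the remaining free ends sequentially (intra-chromosomal proximity biased,
#' see [rejoin_model()]). Perfect religations of an uncut-apart pair with no
#' trimmed bases restore the original sequence and are not recorded as
#' junctions. Every derivative chromosome starts and ends with an original
#' telomeric segment.
#'
#' @param genome a `gcr_genome`, or a named vector of chromosome lengths
#'   (sequence is only needed later, for rendering).
#' @param cuts data.frame with columns chrom, pos (0-based), e.g. from
#'   [select_cut_sites()].
#' @param model a [rejoin_model()].
#' @param bin_size bin size of the copy-number truth.
#' @return `gcr_rearrangement` list: `segments` (derivative map:
#'   der_chrom, order, chrom, start, end, strand), `junctions`,
#'   `copy_truth`, `lost`, `duplicated`, `cuts`, `chrom_lengths`.
#' @export
rejoin <- function(genome, cuts, model = rejoin_model(),
                   bin_size = 50000L) {
  stopifnot(inherits(model, "gcr_rejoin_model"))
  lens <- if (inherits(genome, "gcr_genome")) chrom_lengths(genome)
          else unlist(genome)
  if (nrow(cuts) > 0L) {
    bad <- cuts$pos <= 0L | cuts$pos >= lens[cuts$chrom]
    if (any(is.na(bad)) || any(bad)) {
      stopf("every cut must fall strictly inside a known chromosome")
    }
  }
  cuts <- cuts[order(match(cuts$chrom, names(lens)), cuts$pos), ,
               drop = FALSE]
  cuts <- cuts[!duplicated(cuts[c("chrom", "pos")]), , drop = FALSE]

  with_seed(model$seed, {
    # --- split into segments -------------------------------------------
    seg <- list()
    for (cm in names(lens)) {
      p <- cuts$pos[cuts$chrom == cm]
      bounds <- c(0L, p, lens[[cm]])
      k <- length(p)
      for (j in seq_len(k + 1L)) {
        seg[[length(seg) + 1L]] <- list(
          chrom = cm, start = bounds[j], end = bounds[j + 1L],
          left_telo = j == 1L, right_telo = j == k + 1L,
          # per-chromosome cut indices; 0 / k+1 stand for telomeres
          left_cut = j - 1L, right_cut = j)
      }
    }
    segdf <- do.call(rbind, lapply(seg, as.data.frame))
    segdf$internal <- !segdf$left_telo & !segdf$right_telo

    # --- loss and duplication of internal segments ---------------------
    lost <- segdf[0, ]
    dup_extra <- segdf[0, ]
    if (any(segdf$internal)) {
      ii <- which(segdf$internal)
      drop <- ii[stats::runif(length(ii)) < model$segment_loss_probability]
      keep_ii <- setdiff(ii, drop)
      dup <- keep_ii[stats::runif(length(keep_ii)) <
                       model$segment_duplication_probability]
      lost <- segdf[drop, , drop = FALSE]
      dup_extra <- segdf[dup, , drop = FALSE]
      if (length(drop) > 0L) segdf <- segdf[-drop, , drop = FALSE]
      segdf <- rbind(segdf, dup_extra)
    }
    rownames(segdf) <- NULL

    # --- end resection --------------------------------------------------
    if (model$end_resection_max > 0L) {
      for (i in seq_len(nrow(segdf))) {
        if (!segdf$left_telo[i]) {
          r <- sample.int(model$end_resection_max + 1L, 1L) - 1L
          segdf$start[i] <- min(segdf$start[i] + r, segdf$end[i] - 1L)
        }
        if (!segdf$right_telo[i]) {
          r <- sample.int(model$end_resection_max + 1L, 1L) - 1L
          segdf$end[i] <- max(segdf$end[i] - r, segdf$start[i] + 1L)
        }
      }
    }

    # --- free-end parity check (internal invariant) ---------------------
    n_free <- sum(!segdf$left_telo) + sum(!segdf$right_telo)
    if (n_free %% 2L != 0L) {
      stop("internal invariant violation: odd free-end parity")
    }

    # --- sequential assembly --------------------------------------------
    left_idx <- which(segdf$left_telo)
    right_idx <- which(segdf$right_telo)
    pool <- setdiff(seq_len(nrow(segdf)), c(left_idx, right_idx))
    # uncut chromosomes carry both telomeres and are complete already
    pool_rt <- setdiff(right_idx, left_idx)

    der <- lapply(left_idx, function(i) {
      data.frame(idx = i, strand = "+", stringsAsFactors = FALSE)
    })
    open <- which(!segdf$right_telo[left_idx]) # derivatives needing an end
    junc <- empty_junctions()

    end_of <- function(d) {
      last <- d[nrow(d), ]
      s <- segdf[last$idx, ]
      if (last$strand == "+") {
        list(chrom = s$chrom, pos = s$end, strand = "+", cut = s$right_cut)
      } else {
        list(chrom = s$chrom, pos = s$start, strand = "-", cut = s$left_cut)
      }
    }

    while (length(open) > 0L) {
      di <- if (length(open) == 1L) open else sample(open, 1L)
      E <- end_of(der[[di]])
      # candidate ends: (segment index, attach orientation, is_closing)
      cand <- data.frame(idx = integer(0), orient = character(0),
                         closing = logical(0), stringsAsFactors = FALSE)
      if (length(pool) > 0L) {
        cand <- rbind(cand,
          data.frame(idx = pool, orient = "+", closing = FALSE,
                     stringsAsFactors = FALSE),
          data.frame(idx = pool, orient = "-", closing = FALSE,
                     stringsAsFactors = FALSE))
      }
      allow_close <- length(open) > 1L || length(pool) == 0L
      if (allow_close && length(pool_rt) > 0L) {
        cand <- rbind(cand,
          data.frame(idx = pool_rt, orient = "+", closing = TRUE,
                     stringsAsFactors = FALSE))
      }
      stopifnot(nrow(cand) > 0L)
      cpos <- ifelse(cand$orient == "+", segdf$start[cand$idx],
                     segdf$end[cand$idx])
      cchrom <- segdf$chrom[cand$idx]
      same <- cchrom == E$chrom
      w <- ifelse(same,
                  model$intra_bias *
                    exp(-abs(cpos - E$pos) / model$distance_scale),
                  1 - model$intra_bias)
      if (sum(w) <= 0) w <- rep(1, length(w))
      pick <- sample.int(nrow(cand), 1L, prob = w)
      idx <- cand$idx[pick]; orient <- cand$orient[pick]
      s2 <- segdf[idx, ]
      p2 <- if (orient == "+") s2$start else s2$end
      str2 <- if (orient == "+") "-" else "+"
      cut2 <- if (orient == "+") s2$left_cut else s2$right_cut
      cls <- classify_junction(E$chrom, E$pos, E$strand,
                               s2$chrom, p2, str2)
      # deletion/duplication labels require the skipped (or re-covered)
      # interval to really be absent from (or doubled in) the derivative;
      # otherwise the join is an intra-chromosomal translocation.
      if (cls == "deletion" && E$cut != cut2) {
        plus <- if (E$strand == "+") E$pos else p2
        minus <- if (E$strand == "+") p2 else E$pos
        if (interval_covered_frac(E$chrom, plus, minus, lost) < 0.9) {
          cls <- "translocation_intra"
        }
      } else if (cls == "duplication") {
        plus <- if (E$strand == "+") E$pos else p2
        minus <- if (E$strand == "+") p2 else E$pos
        if (interval_covered_frac(E$chrom, minus, plus, dup_extra) < 0.9) {
          cls <- "translocation_intra"
        }
      }
      if (cls != "religation") {
        junc <- rbind(junc, data.frame(
          chrom_a = E$chrom, pos_a = as.integer(E$pos), strand_a = E$strand,
          chrom_b = s2$chrom, pos_b = as.integer(p2), strand_b = str2,
          class = cls, support = 0L, stringsAsFactors = FALSE))
      }
      der[[di]] <- rbind(der[[di]],
                         data.frame(idx = idx, strand = orient,
                                    stringsAsFactors = FALSE))
      if (cand$closing[pick]) {
        pool_rt <- setdiff(pool_rt, idx)
        open <- setdiff(open, di)
      } else {
        pool <- pool[-match(idx, pool)]
      }
    }
  })

  segments <- do.call(rbind, lapply(seq_along(der), function(i) {
    d <- der[[i]]
    data.frame(der_chrom = sprintf("der%d", i), order = seq_len(nrow(d)),
               chrom = segdf$chrom[d$idx], start = segdf$start[d$idx],
               end = segdf$end[d$idx], strand = d$strand,
               stringsAsFactors = FALSE)
  }))
  rownames(segments) <- NULL
  junc <- canonicalize_junctions(junc, names(lens))
  structure(list(
    segments = segments,
    junctions = junc,
    copy_truth = copy_number_truth(segments, lens, bin_size),
    lost = lost[, c("chrom", "start", "end"), drop = FALSE],
    duplicated = dup_extra[, c("chrom", "start", "end"), drop = FALSE],
    cuts = cuts,
    chrom_lengths = lens
  ), class = "gcr_rearrangement")
}

#' @export
print.gcr_rearrangement <- function(x, ...) {
  cat(sprintf(paste0("<gcr_rearrangement> %d derivative chromosome(s), ",
                     "%d segment(s), %d junction(s)\n"),
              length(unique(x$segments$der_chrom)), nrow(x$segments),
              nrow(x$junctions)))
  if (nrow(x$junctions) > 0L) {
    print(table(x$junctions$class))
  }
  invisible(x)
}

#' Render the nucleotide sequence of a derivative genome
#'
#' @param rearrangement a `gcr_rearrangement`.
#' @param genome the source `gcr_genome` the segment coordinates refer to.
#' @return named character vector of derivative chromosome sequences
#'   (class `gcr_genome`).
#' @export
render_derivative <- function(rearrangement, genome) {
  stopifnot(inherits(rearrangement, "gcr_rearrangement"))
  seg <- rearrangement$segments
  out <- vapply(unique(seg$der_chrom), function(dc) {
    s <- seg[seg$der_chrom == dc, , drop = FALSE]
    s <- s[order(s$order), , drop = FALSE]
    parts <- vapply(seq_len(nrow(s)), function(i) {
      piece <- substr(genome[[s$chrom[i]]], s$start[i] + 1L, s$end[i])
      if (s$strand[i] == "-") revcomp(piece) else piece
    }, character(1))
    paste0(parts, collapse = "")
  }, character(1))
  structure(out, class = "gcr_genome")
}
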