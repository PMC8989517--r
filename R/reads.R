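# Read-level simulators: binned short-read counts drawn directly from
# copy-number truth (Poisson sampling proportional to copy state -- no
# alignment stage, since the downstream CNV statistic consumes per-bin
# counts), and long reads drawn from the derivative genome with full origin
# bookkeeping.

#' Simulate binned short-read counts from a copy-number truth
#'
#' Each bin's count is drawn from
#' `Poisson(depth * copy / baseline_ploidy * width_fraction)`, where
#' `width_fraction` accounts for a short terminal bin.
#'
#' @param copy_truth data.frame chrom, start, end, copy (e.g. from
#'   [copy_number_truth()] or a neutral [bin_grid()] with `copy = 1`).
#' @param depth expected reads per full-width copy-neutral bin.
#' @param baseline_ploidy copy value considered neutral (default 1, the
#'   haploid simulation baseline).
#' @param sample_id label stored on the result.
#' @param seed RNG seed.
#' @return data.frame chrom, start, end, count with attributes `sample_id`,
#'   `bin_size`, `total_count`.
#' @export
simulate_binned_counts <- function(copy_truth, depth, baseline_ploidy = 1,
                                   sample_id = "sample", seed = NULL) {
  if (depth <= 0) stopf("depth must be > 0")
  if (any(copy_truth$copy < 0)) stopf("copy numbers must be >= 0")
  width <- copy_truth$end - copy_truth$start
  bin_size <- max(width)
  lambda <- depth * copy_truth$copy / baseline_ploidy * (width / bin_size)
  with_seed(seed, {
    counts <- stats::rpois(length(lambda), lambda)
  })
  out <- data.frame(chrom = copy_truth$chrom, start = copy_truth$start,
                    end = copy_truth$end, count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  attr(out, "bin_size") <- bin_size
  attr(out, "total_count") <- sum(counts)
  out
}

# Map a derivative-coordinate interval [s, e) on one derivative chromosome
# back to source-genome parts via the segment map.
derivative_interval_origin <- function(seg, s, e) {
  # seg: ordered segments of one derivative chromosome with cumulative
  # offsets precomputed in seg$doff (start of each segment in derivative
  # coordinates). Returns a list of parallel vectors, one element per
  # overlapped segment, in read order.
  ds <- seg$doff
  de <- ds + (seg$end - seg$start)
  lo <- pmax(s, ds); hi <- pmin(e, de)
  keep <- which(hi > lo)
  fwd <- seg$strand[keep] == "+"
  list(chrom = seg$chrom[keep],
       start = ifelse(fwd, seg$start[keep] + (lo[keep] - ds[keep]),
                      seg$end[keep] - (hi[keep] - ds[keep])),
       end = ifelse(fwd, seg$start[keep] + (hi[keep] - ds[keep]),
                    seg$end[keep] - (lo[keep] - ds[keep])),
       strand = ifelse(fwd, "+", "-"))
}

# Apply substitution/insertion/deletion errors to one sequence.
# error_rate is the total per-base error probability, split 3:1:1 between
# substitutions, insertions and deletions.
apply_read_errors <- function(s, error_rate) {
  n <- nchar(s)
  if (error_rate <= 0 || n == 0L) return(s)
  n_err <- stats::rbinom(1L, n, error_rate)
  if (n_err == 0L) return(s)
  codes <- seq_codes(s)
  pos <- sample.int(n, n_err)
  type <- sample.int(3L, n_err, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  sub_pos <- pos[type == 1L]
  if (length(sub_pos) > 0L) {
    codes[sub_pos] <- (codes[sub_pos] +
      sample.int(3L, length(sub_pos), replace = TRUE)) %% 4L
  }
  reps <- rep(1L, n)
  reps[pos[type == 3L]] <- 0L # deletions
  ins_pos <- pos[type == 2L]
  reps[ins_pos] <- 2L # insertion after the original base
  out <- rep.int(codes, reps)
  if (length(ins_pos) > 0L) {
    out[cumsum(reps)[ins_pos]] <- sample.int(4L, length(ins_pos),
                                             replace = TRUE) - 1L
  }
  codes_to_seq(out)
}

#' Simulate long reads from a (derivative) genome
#'
#' Read start positions are uniform over the genome; lengths are log-normal
#' with the requested mean, truncated at `min_length` and clipped at the
#' chromosome end. When a `gcr_rearrangement` is supplied, each read's true
#' origin is recorded as source-genome intervals via the derivative segment
#' map, so reads spanning junctions carry >= 2 origin parts. Substitution,
#' insertion and deletion errors (3:1:1) are applied at `error_rate`.
#'
#' @param x a `gcr_rearrangement`, or a `gcr_genome` to read directly from.
#' @param genome the source `gcr_genome` (required when `x` is a
#'   rearrangement; ignored otherwise).
#' @param n_reads number of reads.
#' @param mean_length target mean read length in bp.
#' @param min_length minimum read length (reads are redrawn, mirroring the
#'   standard >= 500 bp long-read length filter).
#' @param sdlog log-scale standard deviation of the length distribution.
#' @param error_rate total per-base error probability in `[0, 0.2]`.
#' @param seed RNG seed.
#' @return list of class `gcr_reads`: `reads` (data.frame read_id,
#'   sequence, length, error_rate) and `origin` (data.frame read_id,
#'   part_index, chrom, start, end, strand in source coordinates).
#' @export
simulate_long_reads <- function(x, genome = NULL, n_reads,
                                mean_length = 8000, min_length = 500L,
                                sdlog = 0.5, error_rate = 0, seed = NULL) {
  if (n_reads < 0) stopf("n_reads must be >= 0")
  if (error_rate < 0 || error_rate > 0.2) {
    stopf("error_rate must lie in [0, 0.2]")
  }
  if (inherits(x, "gcr_rearrangement")) {
    if (is.null(genome)) stopf("genome required to render the derivative")
    der_seq <- render_derivative(x, genome)
    seg_all <- x$segments
  } else if (inherits(x, "gcr_genome") || is.character(x)) {
    der_seq <- x
    if (is.null(names(der_seq))) {
      names(der_seq) <- paste0("chr", seq_along(der_seq))
    }
    seg_all <- data.frame(der_chrom = names(der_seq), order = 1L,
                          chrom = names(der_seq), start = 0L,
                          end = nchar(der_seq), strand = "+",
                          stringsAsFactors = FALSE)
  } else {
    stopf("x must be a gcr_rearrangement or a gcr_genome")
  }
  if (sum(nchar(der_seq)) == 0L) stopf("derivative genome is empty")
  # per-derivative-chromosome segment tables with derivative offsets
  seg_by_chrom <- lapply(unique(seg_all$der_chrom), function(dc) {
    s <- seg_all[seg_all$der_chrom == dc, , drop = FALSE]
    s <- s[order(s$order), , drop = FALSE]
    w <- s$end - s$start
    s$doff <- cumsum(c(0L, w[-length(w)]))
    s
  })
  names(seg_by_chrom) <- unique(seg_all$der_chrom)
  lens <- nchar(der_seq)
  names(lens) <- names(der_seq)
  mu <- log(mean_length) - sdlog^2 / 2

  seqs <- character(n_reads)
  org_parts <- vector("list", n_reads)
  with_seed(seed, {
    for (i in seq_len(n_reads)) {
      repeat {
        len <- as.integer(round(stats::rlnorm(1L, mu, sdlog)))
        if (len >= min_length && len <= max(lens)) break
      }
      cm <- sample(names(lens), 1L, prob = pmax(lens - len + 1L, 0L))
      st <- runif_int(1L, lens[[cm]] - len + 1L)
      raw_seq <- substr(der_seq[[cm]], st + 1L, st + len)
      org_parts[[i]] <- derivative_interval_origin(seg_by_chrom[[cm]],
                                                   st, st + len)
      seqs[i] <- apply_read_errors(raw_seq, error_rate)
    }
  })
  ids <- sprintf("read_%06d", seq_len(n_reads))
  reads_df <- data.frame(read_id = ids, sequence = seqs,
                         length = nchar(seqs),
                         error_rate = rep(error_rate, n_reads),
                         stringsAsFactors = FALSE)
  n_parts <- vapply(org_parts, function(o) length(o$chrom), integer(1))
  origin_df <- data.frame(
    read_id = rep(ids, n_parts),
    part_index = unlist(lapply(n_parts, seq_len), use.names = FALSE) %||%
      integer(0),
    chrom = unlist(lapply(org_parts, `[[`, "chrom"), use.names = FALSE) %||%
      character(0),
    start = as.integer(unlist(lapply(org_parts, `[[`, "start"),
                              use.names = FALSE) %||% integer(0)),
    end = as.integer(unlist(lapply(org_parts, `[[`, "end"),
                            use.names = FALSE) %||% integer(0)),
    strand = unlist(lapply(org_parts, `[[`, "strand"),
                    use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE)
  structure(list(reads = reads_df, origin = origin_df),
            class = "gcr_reads")
}

#' @export
print.gcr_reads <- function(x, ...) {
  cat(sprintf("<gcr_reads> %d read(s), %s bases, mean length %.0f bp\n",
              nrow(x$reads), format(sum(x$reads$length), big.mark = ","),
              mean(x$reads$length)))
  invisible(x)
}

#' Filter long reads by length and error-rate proxy
#'
#' Synthetic reads carry their injected error rate, which stands in for a
#' mean base-quality filter; reads without a usable quality proxy pass.
#'
#' @param reads a `gcr_reads` object.
#' @param min_length minimum length in bp (reads shorter are removed).
#' @param max_error optional maximum per-read error-rate proxy.
#' @return filtered `gcr_reads`.
#' @export
filter_reads <- function(reads, min_length = 500L, max_error = NULL) {
  stopifnot(inherits(reads, "gcr_reads"))
  keep <- reads$reads$length >= min_length
  if (!is.null(max_error)) {
    er <- reads$reads$error_rate
    keep <- keep & (is.na(er) | er <= max_error)
  }
  ids <- reads$reads$read_id[keep]
  structure(list(reads = reads$reads[keep, , drop = FALSE],
                 origin = reads$origin[reads$origin$read_id %in% ids, ,
                                       drop = FALSE]),
            class = "gcr_reads")
}

#' Reconstruct a read from its recorded origin intervals
#'
#' Concatenates the source-genome intervals (reverse complementing minus
#' parts); for error-free reads this reproduces the read sequence exactly.
#'
#' @param origin origin rows of a single read, in part order.
#' @param genome source `gcr_genome`.
#' @return character scalar.
#' @export
reconstruct_from_origin <- function(origin, genome) {
  origin <- origin[order(origin$part_index), , drop = FALSE]
  parts <- vapply(seq_len(nrow(origin)), function(i) {
    piece <- substr(genome[[origin$chrom[i]]], origin$start[i] + 1L,
                    origin$end[i])
    if (origin$strand[i] == "-") revcomp(piece) else piece
  }, character(1))
  paste0(parts, collapse = "")
}
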