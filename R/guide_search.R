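# Exhaustive enumeration of guide target sites with up to two mismatches.
#
# Every 20-bp window on either strand whose Hamming distance to the guide is
# <= max_mismatch is reported once, in the spirit of an all-alignments
# (`bowtie -a -v k`) census. The scan is vectorised: per guide position j,
# one whole-chromosome comparison of the shifted base-code vector against the
# j-th guide base, accumulating per-window mismatch counts in 20 vector
# operations per strand. Ambiguous bases never match.

# Per-window mismatch counts of `guide_codes` against chromosome codes.
window_mismatches <- function(codes, guide_codes) {
  n <- length(codes)
  k <- length(guide_codes)
  w <- n - k + 1L
  if (w < 1L) return(integer(0))
  mism <- integer(w)
  for (j in seq_len(k)) {
    cmp <- codes[j:(w + j - 1L)] != guide_codes[j]
    cmp[is.na(cmp)] <- TRUE # N never matches
    mism <- mism + cmp
  }
  mism
}

# PAM check for window starts `p` (0-based): pattern over {A,C,G,T,N}
# immediately 3' of the protospacer, strand-aware.
pam_ok <- function(codes, p, strand, pam_codes) {
  k <- 20L
  m <- length(pam_codes)
  n <- length(codes)
  ok <- rep(TRUE, length(p))
  for (j in seq_len(m)) {
    pc <- pam_codes[j]
    if (is.na(pc)) next # N matches anything unambiguous
    idx <- if (strand == "+") p + k + j - 1L else p - j
    # 0-based idx -> 1-based subscript; out-of-range fails the PAM
    inb <- idx >= 0L & idx < n
    base <- rep(NA_integer_, length(p))
    base[inb] <- codes[idx[inb] + 1L]
    want <- if (strand == "+") pc else 3L - pc # complement on minus strand
    ok <- ok & !is.na(base) & base == want
  }
  if (any(is.na(pam_codes))) {
    # N in the pattern still requires an unambiguous genome base in range
    for (j in which(is.na(pam_codes))) {
      idx <- if (strand == "+") p + k + j - 1L else p - j
      inb <- idx >= 0L & idx < n
      base <- rep(NA_integer_, length(p))
      base[inb] <- codes[idx[inb] + 1L]
      ok <- ok & !is.na(base)
    }
  }
  ok
}

#' Find all genomic matches of a guide with up to two mismatches
#'
#' Scans both strands of every chromosome for 20-bp windows within
#' `max_mismatch` Hamming distance of the guide. A reverse-strand match at
#' forward position p is reported with `start = p` (leftmost base of the
#' window) and strand `"-"`; `sequence` is the protospacer as read on its
#' own strand. Overlapping matches are all reported. With `require_pam` the
#' window must be followed (3', strand-aware) by `pam_pattern` (`N` is a
#' wildcard); PAM filtering is off by default, matching a raw sequence
#' census.
#'
#' @param genome a `gcr_genome` (named character vector of chromosomes).
#' @param guide 20-nt guide over A/C/G/T.
#' @param max_mismatch 0, 1 or 2.
#' @param require_pam require an adjacent PAM motif.
#' @param pam_pattern PAM motif, default `"NGG"`.
#' @return data.frame: chrom, start (0-based), end, strand, mismatch,
#'   sequence; sorted by (chrom, start, strand).
#' @export
#' @examples
#' g <- generate_genome(genome_spec(1, 1e4, seed = 3))
#' guide <- substr(g[[1]], 501, 520)
#' find_guide_matches(g, guide, max_mismatch = 0)[1, ]
find_guide_matches <- function(genome, guide, max_mismatch = 2L,
                               require_pam = FALSE, pam_pattern = "NGG") {
  check_guide(guide)
  max_mismatch <- as.integer(max_mismatch)
  if (!max_mismatch %in% 0:2) stopf("max_mismatch must be 0, 1 or 2")
  g_fwd <- seq_codes(guide)
  g_rev <- seq_codes(revcomp(guide))
  pam_codes <- if (require_pam) {
    .base_lut[as.integer(charToRaw(pam_pattern)) + 1L]
  } else NULL
  out <- vector("list", 2L * length(genome))
  k <- 1L
  for (cm in names(genome)) {
    codes <- seq_codes(genome[[cm]])
    for (strand in c("+", "-")) {
      gc_ <- if (strand == "+") g_fwd else g_rev
      mism <- window_mismatches(codes, gc_)
      hit <- which(mism <= max_mismatch)
      if (length(hit) > 0L && require_pam) {
        keep <- pam_ok(codes, hit - 1L, strand, pam_codes)
        hit <- hit[keep]
      }
      if (length(hit) == 0L) next
      p0 <- hit - 1L
      seqs <- substring(genome[[cm]], hit, hit + 19L)
      if (strand == "-") seqs <- revcomp(seqs)
      out[[k]] <- data.frame(chrom = cm, start = p0, end = p0 + 20L,
                             strand = strand, mismatch = mism[hit],
                             sequence = seqs, stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  res <- do.call(rbind, out[seq_len(k - 1L)])
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatch = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(match(res$chrom, names(genome)), res$start, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
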