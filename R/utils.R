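# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' perturb the caller's RNG stream. A `NULL` seed evaluates the expression
#' against the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stopf("seed must be a single integer, got %s", deparse(seed))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Byte lookup table mapping A/C/G/T (either case) to codes 0:3; all other
# bytes (including N) map to NA so they never match anything.
.base_lut <- local({
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A") + 1L] <- 0L; lut[utf8ToInt("a") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L; lut[utf8ToInt("c") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L; lut[utf8ToInt("g") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L; lut[utf8ToInt("t") + 1L] <- 3L
  lut
})

.code_to_base <- c("A", "C", "G", "T")

#' Encode a nucleotide string as integer codes 0:3 (NA for ambiguous bases)
#' @noRd
seq_codes <- function(s) {
  .base_lut[as.integer(charToRaw(s)) + 1L]
}

codes_to_seq <- function(codes) {
  rawToChar(as.raw(c(65L, 67L, 71L, 84L)[codes + 1L]))
}

#' Reverse complement of DNA strings
#'
#' Vectorised over its argument; ambiguous bases (`N`) are preserved.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACCGT")
revcomp <- function(x) {
  vapply(x, function(s) {
    rawToChar(rev(charToRaw(chartr("ACGTacgtn", "TGCAtgcaN", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA string with a given GC fraction
#' @noRd
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- sample.int(4L, n, replace = TRUE, prob = p) - 1L
  codes_to_seq(codes)
}

#' Count G+C bases in a sequence
#' @noRd
gc_count <- function(s) {
  codes <- seq_codes(s)
  sum(codes == 1L | codes == 2L, na.rm = TRUE)
}

check_guide <- function(guide) {
  if (!is.character(guide) || length(guide) != 1 || is.na(guide)) {
    stopf("guide must be a single character string")
  }
  if (nchar(guide) != 20L) {
    stopf("guide must be exactly 20 nt, got %d", nchar(guide))
  }
  if (grepl("[^ACGT]", guide)) {
    stopf("guide must contain only A/C/G/T: %s", guide)
  }
  invisible(guide)
}

#' Chromosome lengths of a genome
#'
#' @param genome a named character vector of chromosome sequences
#'   (a `gcr_genome`).
#' @return named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

# Draw n integer positions uniformly from [0, max_excl)
runif_int <- function(n, max_excl) {
  as.integer(floor(stats::runif(n) * max_excl))
}
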