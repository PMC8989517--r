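# Synthetic genome and repeat-embedding module.
#
# The generator stands in for a reference assembly at desk scale: a handful
# of megabase chromosomes seeded with long (L1-like, ~6 kb) and short
# (Alu-like, ~300 bp) repeat copies. A 20-nt guide is written into a declared
# fraction of copies at a fixed offset, so guide target sites -- and hence
# Cas9 cut positions -- are computable from the annotation alone.

#' Specification of a synthetic genome
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param chrom_lengths integer vector of chromosome lengths in bp, recycled
#'   to `n_chromosomes`; every length must be >= 10000.
#' @param gc_fraction genome-wide GC proportion in `[0, 1]`.
#' @param seed RNG seed for reproducible generation.
#' @return a `gcr_genome_spec` list.
#' @export
#' @examples
#' genome_spec(2, 5e4, gc_fraction = 0.41, seed = 1)
genome_spec <- function(n_chromosomes, chrom_lengths, gc_fraction = 0.41,
                        seed = NULL) {
  if (!is.numeric(n_chromosomes) || n_chromosomes < 1) {
    stopf("n_chromosomes must be >= 1")
  }
  n_chromosomes <- as.integer(n_chromosomes)
  chrom_lengths <- as.integer(rep_len(chrom_lengths, n_chromosomes))
  if (any(chrom_lengths < 10000L)) {
    stopf("every chromosome length must be >= 10000 bp")
  }
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1) {
    stopf("gc_fraction must lie in [0, 1]")
  }
  structure(
    list(n_chromosomes = n_chromosomes, chrom_lengths = chrom_lengths,
         gc_fraction = gc_fraction, seed = seed),
    class = "gcr_genome_spec"
  )
}

#' Generate a synthetic genome
#'
#' Chromosomes are i.i.d. base draws at the requested GC fraction, named
#' `chr1..chrN`. Output is bit-identical for identical specs (including
#' seed).
#'
#' @param spec a [genome_spec()].
#' @return named character vector of chromosome sequences, class
#'   `gcr_genome`.
#' @export
#' @examples
#' g <- generate_genome(genome_spec(1, 1e4, seed = 1))
#' nchar(g)
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "gcr_genome_spec"))
  with_seed(spec$seed, {
    seqs <- vapply(spec$chrom_lengths, random_dna, character(1),
                   gc = spec$gc_fraction)
  })
  names(seqs) <- paste0("chr", seq_len(spec$n_chromosomes))
  structure(seqs, class = "gcr_genome")
}

#' @export
print.gcr_genome <- function(x, ...) {
  cat(sprintf("<gcr_genome> %d chromosome(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in names(x)) cat(sprintf("  %s  %s bp\n", nm,
                                   format(nchar(x[[nm]]), big.mark = ",")))
  invisible(x)
}

#' Specification of a repeat-element family to embed
#'
#' Copies of a family consensus are written into the genome; a declared
#' fraction carries the exact guide protospacer (plus an NGG PAM) at a fixed
#' offset inside the consensus, further fractions carry 1- or 2-mismatch
#' variants, and the remainder carry a heavily mutated (non-targetable)
#' guide region. Non-guide positions of each copy are diverged from the
#' consensus at `divergence_rate`.
#'
#' @param element_class `"L1_like"` or `"Alu_like"`.
#' @param consensus_length consensus length in bp (default 6000 for L1-like,
#'   300 for Alu-like).
#' @param copy_number number of copies to place.
#' @param guide_exact_fraction fraction of copies with the exact guide.
#' @param mismatch_profile numeric length-2: fractions with a 1- and
#'   2-mismatch guide variant. `guide_exact_fraction + sum(mismatch_profile)`
#'   must be <= 1.
#' @param divergence_rate per-base substitution probability applied to
#'   non-guide positions of each copy.
#' @param guide_offset 0-based offset of the protospacer within the
#'   consensus.
#' @return a `gcr_repeat_spec` list.
#' @export
repeat_spec <- function(element_class = c("L1_like", "Alu_like"),
                        consensus_length = NULL,
                        copy_number = 0L,
                        guide_exact_fraction = 0.5,
                        mismatch_profile = c(0.2, 0.1),
                        divergence_rate = 0.05,
                        guide_offset = 100L) {
  element_class <- match.arg(element_class)
  if (is.null(consensus_length)) {
    consensus_length <- if (element_class == "L1_like") 6000L else 300L
  }
  consensus_length <- as.integer(consensus_length)
  copy_number <- as.integer(copy_number)
  if (copy_number < 0L) stopf("copy_number must be >= 0")
  if (length(mismatch_profile) != 2L || any(mismatch_profile < 0)) {
    stopf("mismatch_profile must be two non-negative fractions")
  }
  if (guide_exact_fraction < 0 ||
      guide_exact_fraction + sum(mismatch_profile) > 1 + 1e-9) {
    stopf("guide fractions must be >= 0 and sum to <= 1")
  }
  if (divergence_rate < 0 || divergence_rate > 1) {
    stopf("divergence_rate must lie in [0, 1]")
  }
  if (guide_offset < 0 || guide_offset + 23L > consensus_length) {
    stopf("guide_offset + 23 must fit inside the consensus")
  }
  structure(
    list(element_class = element_class, consensus_length = consensus_length,
         copy_number = copy_number,
         guide_exact_fraction = guide_exact_fraction,
         mismatch_profile = as.numeric(mismatch_profile),
         divergence_rate = divergence_rate,
         guide_offset = as.integer(guide_offset)),
    class = "gcr_repeat_spec"
  )
}

# Mutate `n_mm` distinct positions of a 20-nt guide to different bases.
mutate_guide <- function(guide, n_mm) {
  if (n_mm == 0L) return(guide)
  chars <- strsplit(guide, "")[[1]]
  pos <- sample.int(20L, n_mm)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste0(chars, collapse = "")
}

# Deterministic per-category copy counts: exact fractions rounded, never
# exceeding copy_number.
copy_categories <- function(n, exact_frac, mm_profile) {
  n_exact <- min(n, round(exact_frac * n))
  n_mm1 <- min(n - n_exact, round(mm_profile[1] * n))
  n_mm2 <- min(n - n_exact - n_mm1, round(mm_profile[2] * n))
  mm <- c(rep(0L, n_exact), rep(1L, n_mm1), rep(2L, n_mm2),
          rep(NA_integer_, n - n_exact - n_mm1 - n_mm2))
  sample(mm) # shuffle category assignment across copies
}

#' Embed repeat-element copies carrying guide target sites
#'
#' Places non-overlapping copies of each repeat family at uniformly drawn
#' positions on random strands and writes them into the genome. The
#' annotation records every copy with the mismatch count of its embedded
#' guide (`NA` for copies whose guide region was ablated).
#'
#' @param genome a `gcr_genome`.
#' @param repeat_specs list of [repeat_spec()] objects (or a single one).
#' @param guide 20-nt guide protospacer(s) to embed, recycled to one per
#'   repeat family (e.g. an L1-targeting guide for the L1-like family and
#'   an Alu-targeting guide for the Alu-like family).
#' @param seed RNG seed.
#' @param max_tries placement attempts per copy before a capacity error.
#' @return list with elements `genome` (modified `gcr_genome`), `annotation`
#'   (data.frame: chrom, start, end, element_class, strand, copy_id,
#'   guide_mismatch; 0-based half-open), and `consensi` (named character
#'   vector of family consensus sequences).
#' @export
embed_repeats <- function(genome, repeat_specs, guide, seed = NULL,
                          max_tries = 200L) {
  stopifnot(inherits(genome, "gcr_genome"))
  if (inherits(repeat_specs, "gcr_repeat_spec")) {
    repeat_specs <- list(repeat_specs)
  }
  guides <- rep_len(guide, length(repeat_specs))
  for (g in guides) check_guide(g)
  lens <- chrom_lengths(genome)
  with_seed(seed, {
    placed <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), element_class = character(0),
                         strand = character(0), copy_id = character(0),
                         guide_mismatch = integer(0),
                         stringsAsFactors = FALSE)
    copy_seqs <- character(0)
    consensi <- character(0)
    for (si in seq_along(repeat_specs)) {
      spec <- repeat_specs[[si]]
      guide <- guides[[si]]
      stopifnot(inherits(spec, "gcr_repeat_spec"))
      L <- spec$consensus_length
      # Family consensus: random backbone with guide + TGG PAM written in.
      cons <- random_dna(L, gc = 0.45)
      substr(cons, spec$guide_offset + 1L, spec$guide_offset + 20L) <- guide
      substr(cons, spec$guide_offset + 21L, spec$guide_offset + 23L) <- "TGG"
      consensi[[spec$element_class]] <- cons
      if (spec$copy_number == 0L) next
      mm_cat <- copy_categories(spec$copy_number, spec$guide_exact_fraction,
                                spec$mismatch_profile)
      ok_chrom <- names(lens)[lens >= L]
      if (length(ok_chrom) == 0L) {
        stopf("capacity error: no chromosome can hold a %d bp copy", L)
      }
      w <- (lens[ok_chrom] - L + 1)
      for (i in seq_len(spec$copy_number)) {
        hit <- FALSE
        for (try in seq_len(max_tries)) {
          cm <- sample(ok_chrom, 1L, prob = w)
          st <- runif_int(1L, lens[[cm]] - L + 1L)
          en <- st + L
          same <- placed$chrom == cm
          if (!any(same & placed$start < en & placed$end > st)) {
            hit <- TRUE
            break
          }
        }
        if (!hit) {
          stopf(paste0("capacity error: could not place copy %d/%d of %s ",
                       "(%d bp) after %d tries; %d copies placed so far"),
                i, spec$copy_number, spec$element_class, L, max_tries,
                nrow(placed))
        }
        # Per-copy sequence: diverge non-guide positions, then install the
        # guide variant for this copy's category.
        s <- cons
        n_sub <- stats::rbinom(1L, L, spec$divergence_rate)
        if (n_sub > 0L) {
          pos <- sample.int(L, n_sub)
          pos <- pos[pos <= spec$guide_offset | pos > spec$guide_offset + 23L]
          for (p in pos) {
            substr(s, p, p) <- sample(
              setdiff(c("A", "C", "G", "T"), substr(s, p, p)), 1L)
          }
        }
        mm <- mm_cat[i]
        gvar <- if (is.na(mm)) mutate_guide(guide, 6L) else
          mutate_guide(guide, mm)
        substr(s, spec$guide_offset + 1L, spec$guide_offset + 20L) <- gvar
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") s <- revcomp(s)
        copy_id <- sprintf("%s_%04d", sub("_like$", "", spec$element_class),
                           i)
        placed <- rbind(placed, data.frame(
          chrom = cm, start = st, end = en,
          element_class = spec$element_class, strand = strand,
          copy_id = copy_id, guide_mismatch = mm, stringsAsFactors = FALSE))
        copy_seqs <- c(copy_seqs, s)
      }
    }
    # Write all copies into each chromosome in one pass.
    if (nrow(placed) > 0L) {
      for (cm in unique(placed$chrom)) {
        idx <- which(placed$chrom == cm)
        idx <- idx[order(placed$start[idx])]
        starts <- placed$start[idx]
        ends <- placed$end[idx]
        src <- genome[[cm]]
        parts <- character(2L * length(idx) + 1L)
        prev <- 0L
        for (j in seq_along(idx)) {
          parts[2L * j - 1L] <- substr(src, prev + 1L, starts[j])
          parts[2L * j] <- copy_seqs[idx[j]]
          prev <- ends[j]
        }
        parts[2L * length(idx) + 1L] <- substr(src, prev + 1L, nchar(src))
        genome[[cm]] <- paste0(parts, collapse = "")
      }
    }
  })
  ord <- order(match(placed$chrom, names(genome)), placed$start)
  placed <- placed[ord, , drop = FALSE]
  rownames(placed) <- NULL
  list(genome = genome, annotation = placed, consensi = consensi)
}

#' Cut position of a guide within an annotated repeat copy
#'
#' For a copy on the forward strand the protospacer starts at
#' `start + guide_offset`; on the reverse strand the consensus is reverse
#' complemented, so the protospacer window ends at `end - guide_offset`.
#' The blunt cut falls `cut_offset` bases into the protospacer on its own
#' strand (default 17, i.e. 3 bp 5' of the PAM).
#' @noRd
annotation_cut_positions <- function(annotation, guide_offset,
                                     cut_offset = 17L) {
  fwd <- annotation$strand == "+"
  proto_start <- ifelse(fwd,
                        annotation$start + guide_offset,
                        annotation$end - guide_offset - 20L)
  ifelse(fwd, proto_start + cut_offset, proto_start + (20L - cut_offset))
}
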