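# Breakpoint statistics: permutation (shuffle) enrichment of
# translocation/inversion sites in region sets, the Monte-Carlo
# intra/inter-chromosomal null, nearest-repeat distances, and genome
# linearisation for 2D breakpoint plots.

#' Breakpoints of a junction table
#'
#' @param junctions junction data.frame (chrom_a/pos_a/chrom_b/pos_b).
#' @return data.frame chrom, pos with two rows per junction (end A then
#'   end B).
#' @export
junction_breakpoints <- function(junctions) {
  data.frame(chrom = c(junctions$chrom_a, junctions$chrom_b),
             pos = c(junctions$pos_a, junctions$pos_b),
             junction = rep(seq_len(nrow(junctions)), 2L),
             stringsAsFactors = FALSE)
}

# Vectorised point-in-regions test; regions need not be sorted.
points_in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(pos))
  for (cm in unique(regions$chrom)) {
    r <- regions[regions$chrom == cm, , drop = FALSE]
    o <- order(r$start)
    st <- r$start[o]; en <- r$end[o]
    sel <- which(chrom == cm)
    if (length(sel) == 0L) next
    idx <- findInterval(pos[sel], st)
    hit[sel] <- idx > 0L & pos[sel] < en[pmax(idx, 1L)]
  }
  hit
}

#' Count breakpoints falling inside a region set
#'
#' @param junctions junction data.frame.
#' @param regions region set (chrom, start, end; 0-based half-open).
#' @param counting `"per_breakpoint"` counts each junction end
#'   independently; `"per_junction"` counts a junction once if either end
#'   falls in a region.
#' @return integer count.
#' @export
count_breakpoints_in_regions <- function(junctions, regions,
                                         counting = c("per_breakpoint",
                                                      "per_junction")) {
  counting <- match.arg(counting)
  if (nrow(junctions) == 0L || nrow(regions) == 0L) return(0L)
  bp <- junction_breakpoints(junctions)
  hit <- points_in_regions(bp$chrom, bp$pos, regions)
  if (counting == "per_breakpoint") {
    sum(hit)
  } else {
    length(unique(bp$junction[hit]))
  }
}

#' Length-preserving random re-placement of a region set
#'
#' Every interval is re-placed uniformly at random genome-wide (any
#' chromosome), keeping its length, without overlap among the placed
#' intervals -- the shuffle underlying the permutation enrichment test.
#' Placement uses the classical gap-insertion construction: starts are
#' drawn uniformly in the genome shrunk by the total interval length and
#' re-expanded, which yields an exact uniform draw of non-overlapping
#' intervals; draws crossing a chromosome boundary are retried.
#'
#' @param regions region set to shuffle.
#' @param chrom_lengths named chromosome lengths.
#' @param same_chrom keep every interval on its own chromosome instead of
#'   re-placing genome-wide.
#' @return shuffled region set (unsorted lengths correspond to permuted
#'   input intervals).
#' @export
shuffle_regions <- function(regions, chrom_lengths, same_chrom = FALSE) {
  lens <- regions$end - regions$start
  n <- length(lens)
  if (n == 0L) return(regions[0, ])
  if (same_chrom) {
    out <- lapply(unique(regions$chrom), function(cm) {
      r <- regions[regions$chrom == cm, , drop = FALSE]
      shuffle_regions(r, chrom_lengths[cm], same_chrom = FALSE)
    })
    return(do.call(rbind, out))
  }
  total <- sum(as.numeric(chrom_lengths))
  if (sum(lens) >= total) stopf("regions do not fit in the genome")
  offs <- cumsum(c(0, as.numeric(chrom_lengths)))
  names(offs) <- NULL
  lens <- lens[sample.int(n)] # random interval order along the genome
  free <- total - sum(lens)
  for (attempt in 1:200) {
    s <- sort(floor(stats::runif(n) * free))
    starts <- s + cumsum(c(0, lens[-n]))
    ci <- findInterval(starts, offs)
    ok <- (starts + lens) <= offs[ci + 1L]
    if (all(ok)) {
      return(data.frame(chrom = names(chrom_lengths)[ci],
                        start = as.integer(starts - offs[ci]),
                        end = as.integer(starts - offs[ci] + lens),
                        stringsAsFactors = FALSE))
    }
    # keep the valid ones' relative draw and retry wholesale (cheap)
  }
  stopf("could not place shuffled regions without crossing boundaries")
}

#' Permutation enrichment of breakpoints in a region set
#'
#' The observed count of breakpoints in the regions is compared with a null
#' built by re-placing the regions at random (length preserved, genome-wide)
#' `n_perm` times while holding breakpoints fixed. A one-sided upper-tail P
#' is computed from the normal approximation to the null, alongside an
#' empirical P.
#'
#' @param junctions junction data.frame.
#' @param regions region set (e.g. high-CNV regions).
#' @param chrom_lengths named chromosome lengths.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param counting see [count_breakpoints_in_regions()].
#' @param same_chrom shuffle each region within its own chromosome
#'   instead of genome-wide (see [shuffle_regions()]).
#' @return object of class `gcr_permtest`: observed, null_mean, null_sd, z,
#'   p_value (normal), p_empirical, n_perm, degenerate flag, and the raw
#'   null counts.
#' @export
permutation_enrichment <- function(junctions, regions, chrom_lengths,
                                   n_perm = 1000L, seed = NULL,
                                   counting = c("per_breakpoint",
                                                "per_junction"),
                                   same_chrom = FALSE) {
  counting <- match.arg(counting)
  region_len <- sum(as.numeric(regions$end - regions$start))
  if (region_len > 0.5 * sum(as.numeric(chrom_lengths))) {
    warning("regions cover more than half the genome; ",
            "shuffle space is constrained")
  }
  obs <- count_breakpoints_in_regions(junctions, regions, counting)
  null <- integer(n_perm)
  if (nrow(junctions) > 0L && nrow(regions) > 0L) {
    bp <- junction_breakpoints(junctions)
    with_seed(seed, {
      for (i in seq_len(n_perm)) {
        shuf <- shuffle_regions(regions, chrom_lengths, same_chrom)
        hit <- points_in_regions(bp$chrom, bp$pos, shuf)
        null[i] <- if (counting == "per_breakpoint") sum(hit) else
          length(unique(bp$junction[hit]))
      }
    })
  }
  mu <- mean(null)
  sdv <- stats::sd(null)
  degenerate <- nrow(junctions) == 0L || is.na(sdv) || sdv == 0
  z <- if (degenerate) NA_real_ else (obs - mu) / sdv
  p <- if (degenerate) 1 else stats::pnorm(z, lower.tail = FALSE)
  p_emp <- (1 + sum(null >= obs)) / (n_perm + 1)
  structure(list(observed = obs, null_mean = mu, null_sd = sdv, z = z,
                 p_value = p, p_empirical = p_emp, n_perm = n_perm,
                 counting = counting, degenerate = degenerate,
                 null_counts = null, seed = seed),
            class = "gcr_permtest")
}

#' @export
print.gcr_permtest <- function(x, ...) {
  cat(sprintf(paste0("<gcr_permtest> observed = %d, null = %.1f +/- %.2f ",
                     "(%d perms)\n"),
              x$observed, x$null_mean, x$null_sd, x$n_perm))
  if (x$degenerate) {
    cat("  degenerate null (no breakpoints or zero variance); p = 1\n")
  } else {
    cat(sprintf("  z = %.2f, normal p = %.3g, empirical p = %.3g\n",
                x$z, x$p_value, x$p_empirical))
  }
  invisible(x)
}

#' Monte-Carlo null for intra- versus inter-chromosomal translocations
#'
#' Draws `n_events` random breakpoint pairs (each endpoint uniform over the
#' genome, chromosome chosen proportional to length) per run, averages
#' intra/inter counts over `n_runs` runs, and compares the observed
#' intra/inter split with the expectation by a 1-df chi-square
#' goodness-of-fit test. The exact closed-form intra fraction
#' `sum((L_i/L)^2)` is reported alongside.
#'
#' @param junctions junction data.frame; every same-chromosome junction
#'   (inversions included) counts as intra.
#' @param chrom_lengths named chromosome lengths.
#' @param n_runs number of Monte-Carlo runs averaged (default 10).
#' @param seed RNG seed.
#' @return object of class `gcr_mctest`.
#' @export
mc_intra_inter <- function(junctions, chrom_lengths, n_runs = 10L,
                           seed = NULL) {
  n_events <- nrow(junctions)
  if (n_events < 1L) stopf("need at least one junction")
  obs_intra <- sum(junctions$chrom_a == junctions$chrom_b)
  obs_inter <- n_events - obs_intra
  L <- as.numeric(chrom_lengths)
  pL <- L / sum(L)
  closed_form <- sum(pL^2)
  nm <- names(chrom_lengths)
  sim_intra <- numeric(n_runs)
  pairs1 <- NULL
  with_seed(seed, {
    for (r in seq_len(n_runs)) {
      ca <- sample.int(length(L), n_events, replace = TRUE, prob = pL)
      cb <- sample.int(length(L), n_events, replace = TRUE, prob = pL)
      sim_intra[r] <- sum(ca == cb)
      if (r == 1L) {
        # retain one run's positions for 2D plotting
        pairs1 <- data.frame(
          chrom_a = nm[ca], pos_a = runif_int(n_events, L[ca]),
          chrom_b = nm[cb], pos_b = runif_int(n_events, L[cb]),
          stringsAsFactors = FALSE)
      }
    }
  })
  exp_intra <- mean(sim_intra)
  exp_inter <- n_events - exp_intra
  if (exp_intra <= 0 || exp_inter <= 0) {
    chi2 <- NA_real_
    p <- NA_real_
  } else {
    chi2 <- (obs_intra - exp_intra)^2 / exp_intra +
      (obs_inter - exp_inter)^2 / exp_inter
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(n_events = n_events, observed_intra = obs_intra,
                 observed_inter = obs_inter,
                 expected_intra_mean = exp_intra,
                 expected_inter_mean = exp_inter,
                 sim_intra = sim_intra, n_runs = n_runs,
                 chi_square = chi2, p_value = p,
                 closed_form_intra_fraction = closed_form,
                 mc_pairs = pairs1, seed = seed),
            class = "gcr_mctest")
}

#' @export
print.gcr_mctest <- function(x, ...) {
  cat(sprintf("<gcr_mctest> %d events: intra %d / inter %d\n",
              x$n_events, x$observed_intra, x$observed_inter))
  cat(sprintf("  MC expectation (%d runs): intra %.1f / inter %.1f\n",
              x$n_runs, x$expected_intra_mean, x$expected_inter_mean))
  cat(sprintf("  closed-form intra fraction = %.4f\n",
              x$closed_form_intra_fraction))
  cat(sprintf("  chi-square (1 df) = %.2f, p = %.3g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Distance from each breakpoint to the nearest repeat element
#'
#' For every junction end, elements of the requested class on the same
#' chromosome are scanned; distance is 0 inside an element, otherwise the
#' gap to the closest element boundary. Chromosomes lacking the class yield
#' `no_element_on_chrom`.
#'
#' @param junctions junction data.frame.
#' @param annotation repeat annotation (chrom, start, end, element_class,
#'   copy_id).
#' @param element_class optional class filter (`"L1_like"`/`"Alu_like"`).
#' @return data.frame: chrom, pos, nearest_copy_id, element_class,
#'   distance, category.
#' @export
nearest_element_distance <- function(junctions, annotation,
                                     element_class = NULL) {
  if (!is.null(element_class)) {
    annotation <- annotation[annotation$element_class %in% element_class, ,
                             drop = FALSE]
  }
  bp <- junction_breakpoints(junctions)
  n <- nrow(bp)
  dist <- rep(NA_integer_, n)
  copy <- rep(NA_character_, n)
  ecls <- rep(NA_character_, n)
  for (cm in unique(bp$chrom)) {
    sel <- which(bp$chrom == cm)
    ann <- annotation[annotation$chrom == cm, , drop = FALSE]
    if (nrow(ann) == 0L) next
    ann <- ann[order(ann$start), , drop = FALSE]
    pos <- as.numeric(bp$pos[sel])
    # elements may overlap/nest (as in real repeat annotations): among
    # elements starting at/before pos, the relevant one is the one with
    # the largest end (running maximum with its achieving index)
    cmax_end <- cummax(ann$end)
    cmax_idx <- cummax(seq_len(nrow(ann)) * (ann$end == cmax_end))
    idx <- findInterval(pos, ann$start) # last element starting at/before
    left_end <- ifelse(idx > 0L, cmax_end[pmax(idx, 1L)], NA_real_)
    left_idx <- ifelse(idx > 0L, cmax_idx[pmax(idx, 1L)], NA_integer_)
    inside <- !is.na(left_end) & pos < left_end
    d_left <- ifelse(!is.na(left_end), pos - left_end + 1, NA_real_)
    d_right <- ifelse(idx < nrow(ann),
                      ann$start[pmin(idx + 1L, nrow(ann))] - pos,
                      NA_real_)
    d <- ifelse(inside, 0, pmin(d_left, d_right, na.rm = TRUE))
    best <- ifelse(inside, left_idx,
                   ifelse(!is.na(d_left) & (is.na(d_right) |
                                              d_left <= d_right),
                          left_idx, pmin(idx + 1L, nrow(ann))))
    dist[sel] <- as.integer(d)
    copy[sel] <- ann$copy_id[best]
    ecls[sel] <- ann$element_class[best]
  }
  category <- cut(dist, breaks = c(-1, 0, 999, 9999, 99999, Inf),
                  labels = c("in_element", "lt_1kb", "kb_1_10",
                             "kb_10_100", "gt_100kb"))
  category <- as.character(category)
  category[is.na(dist)] <- "no_element_on_chrom"
  data.frame(chrom = bp$chrom, pos = bp$pos, nearest_copy_id = copy,
             element_class = ecls, distance = dist, category = category,
             stringsAsFactors = FALSE)
}

#' Linearise junctions onto a concatenated genome axis
#'
#' Maps each junction to a single (x, y) point on the linearly arranged
#' genome (chromosomes concatenated in `chrom_order`), with end A defined
#' as the lexicographically smaller (chromosome index, position) -- one
#' point per junction, no symmetric duplication.
#'
#' @param junctions junction data.frame.
#' @param chrom_lengths named chromosome lengths defining offsets and the
#'   default order.
#' @param chrom_order optional explicit chromosome order.
#' @return data.frame x, y (plus chrom/pos columns for both ends).
#' @export
linearize_breakpoints <- function(junctions, chrom_lengths,
                                  chrom_order = names(chrom_lengths)) {
  offs <- cumsum(c(0, as.numeric(chrom_lengths[chrom_order])))
  names(offs) <- c(chrom_order, "_end")
  junc <- canonicalize_junctions(junctions, chrom_order)
  if (nrow(junc) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  data.frame(x = offs[junc$chrom_a] + junc$pos_a,
             y = offs[junc$chrom_b] + junc$pos_b,
             chrom_a = junc$chrom_a, pos_a = junc$pos_a,
             chrom_b = junc$chrom_b, pos_b = junc$pos_b,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' 2D breakpoint plot on the linearised genome
#'
#' Scatter of junction endpoint pairs on the concatenated genome axes, with
#' chromosome boundaries drawn; intra-chromosomal junctions cluster around
#' the diagonal.
#'
#' @param junctions junction data.frame.
#' @param chrom_lengths named chromosome lengths.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the linearised coordinates.
#' @export
plot_breakpoints_2d <- function(junctions, chrom_lengths, ...) {
  xy <- linearize_breakpoints(junctions, chrom_lengths)
  total <- sum(as.numeric(chrom_lengths))
  graphics::plot(xy$x, xy$y, xlim = c(0, total), ylim = c(0, total),
                 xlab = "genome position (end A)",
                 ylab = "genome position (end B)", pch = 20, ...)
  offs <- cumsum(as.numeric(chrom_lengths))
  graphics::abline(v = offs, h = offs, col = "grey80", lty = 3)
  graphics::abline(0, 1, col = "grey60")
  invisible(xy)
}
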