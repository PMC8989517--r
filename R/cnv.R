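# Binned copy-number differencing and region statistics.
#
# The CNV signal is defined exactly as a per-bin difference of (optionally
# library-size normalised) read counts between a rearranged sample and the
# negative control, on a fixed bin grid (500 kb at genome scale; scaled down
# proportionally for synthetic genomes).

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !all(a$chrom == b$chrom) ||
      !all(a$start == b$start) ||
      !all(a$end == b$end)) {
    stopf("count tables are not on the same bin grid")
  }
}

#' Per-bin copy-number difference between a rearranged sample and control
#'
#' With `normalization = "total_count"` each sample's counts are scaled to
#' the control library size before subtraction, so the profile is
#' expressed on the control's depth scale and is invariant to the
#' rearranged sample's sequencing depth; `"none"` subtracts raw counts.
#'
#' @param counts_gcr,counts_nc binned count tables on the same grid
#'   (see [simulate_binned_counts()]).
#' @param normalization `"total_count"` (default) or `"none"`.
#' @return data.frame chrom, start, end, value with attributes `pair` and
#'   `bin_size` (a CNV profile).
#' @export
cnv_difference <- function(counts_gcr, counts_nc,
                           normalization = c("total_count", "none")) {
  normalization <- match.arg(normalization)
  check_same_grid(counts_gcr, counts_nc)
  g <- counts_gcr$count
  n <- counts_nc$count
  if (normalization == "total_count") {
    libs <- c(sum(g), sum(n))
    if (any(libs == 0)) stopf("cannot normalise a zero-count library")
    g <- g * libs[2] / libs[1] # control library as the reference scale
  }
  out <- data.frame(chrom = counts_gcr$chrom, start = counts_gcr$start,
                    end = counts_gcr$end, value = g - n,
                    stringsAsFactors = FALSE)
  attr(out, "pair") <- paste(attr(counts_gcr, "sample_id") %||% "gcr",
                             attr(counts_nc, "sample_id") %||% "nc",
                             sep = "_vs_")
  attr(out, "bin_size") <- attr(counts_gcr, "bin_size") %||%
    max(out$end - out$start)
  out
}

#' Call high-CNV regions from a profile
#'
#' Bins whose `|value|` exceeds the rule threshold are selected and adjacent
#' qualifying bins are merged. `abs_quantile(q)` thresholds at the q-th
#' quantile of `|value|` (scale-free); `abs_z(t)` at `t` standard deviations
#' of the profile.
#'
#' @param profile a CNV profile from [cnv_difference()].
#' @param rule `"abs_quantile"` or `"abs_z"`.
#' @param q quantile in (0, 1) for `abs_quantile`.
#' @param t z threshold (> 0) for `abs_z`.
#' @return data.frame chrom, start, end (a merged, sorted region set).
#' @export
high_cnv_regions <- function(profile, rule = c("abs_quantile", "abs_z"),
                             q = 0.95, t = 2) {
  rule <- match.arg(rule)
  if (nrow(profile) == 0L) stopf("profile is empty")
  v <- profile$value
  if (rule == "abs_quantile") {
    if (q <= 0 || q >= 1) stopf("q must lie in (0, 1)")
    thr <- stats::quantile(abs(v), q, names = FALSE)
    keep <- abs(v) > thr
  } else {
    if (t <= 0) stopf("t must be > 0")
    s <- stats::sd(v)
    keep <- if (s == 0) rep(FALSE, length(v)) else
      abs(v - mean(v)) / s > t
  }
  merge_bins(profile[keep, c("chrom", "start", "end"), drop = FALSE])
}

# Merge bookended/overlapping intervals, sorted output.
merge_bins <- function(regions) {
  if (nrow(regions) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- lapply(split(regions, regions$chrom), function(r) {
    ir <- IRanges::reduce(IRanges::IRanges(start = r$start + 1L,
                                           end = r$end))
    data.frame(chrom = r$chrom[1],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Base-pair intersection of two region sets
#'
#' @param a,b region sets (data.frames chrom, start, end; 0-based
#'   half-open).
#' @return merged intersection as a region set.
#' @export
common_regions <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- lapply(chroms, function(cm) {
    ra <- a[a$chrom == cm, ]; rb <- b[b$chrom == cm, ]
    ia <- IRanges::reduce(IRanges::IRanges(ra$start + 1L, ra$end))
    ib <- IRanges::reduce(IRanges::IRanges(rb$start + 1L, rb$end))
    ov <- IRanges::intersect(ia, ib)
    if (length(ov) == 0L) return(NULL)
    data.frame(chrom = cm, start = IRanges::start(ov) - 1L,
               end = IRanges::end(ov), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation between two CNV profiles
#'
#' Ordinary least-squares fit of profile 2 on profile 1, either per bin or
#' on per-chromosome sums of the per-bin values (genomic gain/loss at the
#' chromosome level).
#'
#' @param p1,p2 CNV profiles on the same grid.
#' @param level `"per_bin"` or `"per_chromosome"`.
#' @return list of class `gcr_correlation`: r_squared, slope, intercept,
#'   n_points, level.
#' @export
cnv_correlation <- function(p1, p2, level = c("per_bin",
                                              "per_chromosome")) {
  level <- match.arg(level)
  check_same_grid(p1, p2)
  if (level == "per_bin") {
    x <- p1$value; y <- p2$value
  } else {
    x <- tapply(p1$value, p1$chrom, sum)
    y <- tapply(p2$value, p2$chrom, sum)[names(x)]
  }
  if (length(x) < 3L) stopf("need at least 3 points for a correlation")
  fit <- stats::lm(y ~ x)
  structure(list(level = level,
                 r_squared = summary(fit)$r.squared,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_points = length(x)),
            class = "gcr_correlation")
}

#' @export
print.gcr_correlation <- function(x, ...) {
  cat(sprintf("<gcr_correlation> %s: R^2 = %.4f, slope = %.3f (n = %d)\n",
              x$level, x$r_squared, x$slope, x$n_points))
  invisible(x)
}

#' Mean-coverage ratio between two intervals
#'
#' Ratio of mean per-base depth over a numerator interval to that over a
#' denominator interval, e.g. an integrated nuclease cassette relative to a
#' selection-marker cassette retained in all samples.
#'
#' @param counts binned (or base-resolution) count table: chrom, start,
#'   end, count.
#' @param numerator,denominator intervals as `list(chrom=, start=, end=)`.
#' @return numeric ratio.
#' @export
interval_coverage_ratio <- function(counts, numerator, denominator) {
  mean_depth <- function(iv) {
    sel <- counts$chrom == iv$chrom & counts$start < iv$end &
      counts$end > iv$start
    if (!any(sel)) stopf("interval %s:%d-%d not covered by the count table",
                         iv$chrom, iv$start, iv$end)
    b <- counts[sel, ]
    ov <- pmin(b$end, iv$end) - pmax(b$start, iv$start)
    depth <- b$count / (b$end - b$start)
    sum(depth * ov) / (iv$end - iv$start)
  }
  den <- mean_depth(denominator)
  if (den <= 0) stopf("denominator interval has zero coverage")
  mean_depth(numerator) / den
}
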