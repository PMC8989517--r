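# End-to-end pipeline: wires the simulator and every analysis stage into a
# single reproducible run with per-stage seeds and a structured report.

#' Guide sequences used throughout the package
#'
#' The L1- and Alu-targeting guides and the no-target negative control
#' guide (20-nt protospacers).
#' @format named character vector.
#' @export
gcr_guides <- c(
  sgL1 = "TTCCAATCAATAGAAAAAGA",
  sgAlu = "TGTAATCCCAGCACTTTGGG",
  sgNC = "CGCTTCCGCGGCCCGTTCAA"
)

#' Build a pipeline run configuration
#'
#' All tunables of the end-to-end run with documented defaults: a 4 x
#' 2.5 Mb genome (one-300th of a human-scale genome) with L1-like and
#' Alu-like repeat families, 50 kb CNV bins (500 kb scaled by the same
#' factor), depth 100 reads per copy-neutral bin, 1000 region
#' permutations, 10 Monte-Carlo runs, and an optional long-read arm.
#' Every stochastic stage derives its own seed from `seed`, so single
#' stages can be re-run without disturbing the others.
#'
#' @param seed base seed; per-stage seeds are derived as small fixed
#'   offsets.
#' @param n_chromosomes,chrom_length,gc_fraction genome shape.
#' @param l1_copies,alu_copies repeat copy numbers.
#' @param guides named guide vector (subset of [gcr_guides] or custom); one
#'   pipeline arm is run per guide. The L1-like family carries the guide
#'   named `sgL1`, the Alu-like family the guide named `sgAlu`, when
#'   present.
#' @param cut_probability,max_cuts,match_max_mismatch cut-stage settings.
#' @param intra_bias,distance_scale,segment_loss_probability,segment_duplication_probability,end_resection_max
#'   rejoining-stage settings (see [rejoin_model()]).
#' @param bin_size,depth CNV-stage settings.
#' @param high_cnv_q quantile for [high_cnv_regions()].
#' @param n_perm,mc_runs statistics settings.
#' @param longread_enabled,longread_n_reads,longread_mean_length,longread_error_rate,longread_min_support
#'   long-read-arm settings.
#' @return a `gcr_config` list.
#' @export
run_config <- function(seed = 1L,
                       n_chromosomes = 4L, chrom_length = 2500000L,
                       gc_fraction = 0.41,
                       l1_copies = 40L, alu_copies = 200L,
                       guides = gcr_guides,
                       cut_probability = 0.8, max_cuts = 60L,
                       match_max_mismatch = 1L,
                       intra_bias = 0.95, distance_scale = 1e6,
                       segment_loss_probability = 0.05,
                       segment_duplication_probability = 0.05,
                       end_resection_max = 0L,
                       bin_size = 50000L, depth = 100,
                       high_cnv_q = 0.95,
                       n_perm = 1000L, mc_runs = 10L,
                       longread_enabled = TRUE,
                       longread_n_reads = 2000L,
                       longread_mean_length = 8000,
                       longread_error_rate = 0.05,
                       longread_min_support = 1L) {
  cfg <- as.list(environment())
  cfg$guides <- unlist(cfg$guides)
  structure(cfg, class = "gcr_config")
}

#' Write / read a run configuration as YAML
#' @param config a `gcr_config`.
#' @param path YAML file path.
#' @return invisibly `path`; the reader returns the `gcr_config`.
#' @export
write_run_config <- function(config, path) {
  raw <- unclass(config)
  raw$guides <- as.list(raw$guides) # keep guide names in the YAML map
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[setdiff(names(raw), "guides")])
  cfg$guides <- unlist(raw$guides)
  cfg
}

stage_seed <- function(config, offset) {
  (as.integer(config$seed) * 131L + offset) %% 2000000000L
}

json_log <- function(con, stage, ...) {
  if (is.null(con)) return(invisible())
  rec <- c(list(stage = stage, wall_time = unclass(Sys.time())), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 6), con)
}

#' Run the full synthetic pipeline
#'
#' Generates the genome with repeat-embedded guide sites, then for every
#' guide in the configuration: enumerates its target sites, cuts and
#' rejoins the genome, simulates binned counts for the rearranged sample
#' and the control, computes the CNV profile and high-CNV regions, runs the
#' permutation enrichment and Monte-Carlo intra/inter tests, profiles
#' breakpoint-to-repeat distances, and (optionally) simulates long reads
#' and calls translocations back, evaluated against the junction truth.
#' The negative-control guide has no target sites, so its arm yields zero
#' cuts, zero junctions and a null CNV profile.
#'
#' @param config a [run_config()].
#' @param outdir optional output directory; when given, all intermediates
#'   are written in their standard formats plus a `report.json`, and a
#'   `run_log.jsonl` records stages, seeds and wall times (wall times are
#'   informational only and never enter the report).
#' @return the run report (nested list, class `gcr_report`).
#' @export
run_all <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "gcr_config"))
  log_con <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    log_con <- file(file.path(outdir, "run_log.jsonl"), "w")
    on.exit(close(log_con))
  }
  opath <- function(...) file.path(outdir, paste0(...))

  gspec <- genome_spec(config$n_chromosomes, config$chrom_length,
                       config$gc_fraction, seed = stage_seed(config, 1L))
  base_genome <- generate_genome(gspec)
  rep_specs <- list(
    repeat_spec("L1_like", copy_number = config$l1_copies),
    repeat_spec("Alu_like", copy_number = config$alu_copies)
  )
  pick_guide <- function(nm) {
    if (nm %in% names(config$guides)) config$guides[[nm]] else
      gcr_guides[[nm]]
  }
  rep_guides <- c(pick_guide("sgL1"), pick_guide("sgAlu"))
  emb <- embed_repeats(base_genome, rep_specs, rep_guides,
                       seed = stage_seed(config, 2L))
  genome <- emb$genome
  annotation <- emb$annotation
  lens <- chrom_lengths(genome)
  json_log(log_con, "simulate-genome", seed = stage_seed(config, 1L),
           total_bp = sum(lens), repeats = nrow(annotation))
  if (!is.null(outdir)) {
    write_genome_fasta(genome, opath("genome.fa"))
    write_annotation_bed(annotation, opath("repeats.bed"))
  }

  grid <- bin_grid(lens, config$bin_size)
  neutral <- grid
  neutral$copy <- 1
  ref_index <- NULL

  arms <- list()
  for (gi in seq_along(config$guides)) {
    gname <- names(config$guides)[gi]
    guide <- config$guides[[gi]]
    arm_off <- 10L * gi

    matches <- find_guide_matches(genome, guide,
                                  max_mismatch = config$match_max_mismatch)
    cuts <- select_cut_sites(matches, cut_model(
      cut_probability = config$cut_probability, max_cuts = config$max_cuts,
      seed = stage_seed(config, arm_off + 1L)))
    rr <- rejoin(genome, cuts, rejoin_model(
      intra_bias = config$intra_bias,
      distance_scale = config$distance_scale,
      segment_loss_probability = config$segment_loss_probability,
      segment_duplication_probability =
        config$segment_duplication_probability,
      end_resection_max = config$end_resection_max,
      seed = stage_seed(config, arm_off + 2L)),
      bin_size = config$bin_size)
    json_log(log_con, "simulate-gcr", guide = gname,
             n_matches = nrow(matches), n_cuts = nrow(cuts),
             n_junctions = nrow(rr$junctions))

    counts_gcr <- simulate_binned_counts(
      rr$copy_truth, config$depth, sample_id = paste0("GCR-", gname),
      seed = stage_seed(config, arm_off + 3L))
    counts_nc <- simulate_binned_counts(
      neutral, config$depth, sample_id = "NC",
      seed = stage_seed(config, arm_off + 4L))
    profile <- cnv_difference(counts_gcr, counts_nc)
    regions <- high_cnv_regions(profile, "abs_quantile", q = config$high_cnv_q)

    perm <- permutation_enrichment(rr$junctions, regions, lens,
                                   n_perm = config$n_perm,
                                   seed = stage_seed(config, arm_off + 5L))
    mc <- if (nrow(rr$junctions) >= 1L) {
      mc_intra_inter(rr$junctions, lens, n_runs = config$mc_runs,
                     seed = stage_seed(config, arm_off + 6L))
    } else NULL
    dists <- nearest_element_distance(rr$junctions, annotation)

    longread <- NULL
    if (isTRUE(config$longread_enabled) && nrow(rr$junctions) > 0L) {
      reads <- simulate_long_reads(
        rr, genome, n_reads = config$longread_n_reads,
        mean_length = config$longread_mean_length,
        error_rate = config$longread_error_rate,
        seed = stage_seed(config, arm_off + 7L))
      reads <- filter_reads(reads, min_length = 500L)
      hits <- find_element_reads(reads, emb$consensi)
      if (is.null(ref_index)) ref_index <- build_reference_index(genome)
      aln <- do.call(rbind, lapply(seq_len(nrow(reads$reads)), function(i) {
        h <- hits[hits$read_id == reads$reads$read_id[i], , drop = FALSE]
        if (nrow(h) == 0L) return(NULL)
        map_flanks(reads$reads$sequence[i], reads$reads$read_id[i],
                   h[which.max(h$score), ], ref_index)
      }))
      if (is.null(aln)) aln <- empty_split_alignments()
      calls <- call_translocations(
        hits, aln, min_support = config$longread_min_support,
        chrom_order = names(lens))
      truth_inter <- rr$junctions[
        rr$junctions$chrom_a != rr$junctions$chrom_b, , drop = FALSE]
      calls_inter <- calls[calls$chrom_a != calls$chrom_b, , drop = FALSE]
      ev <- evaluate_calls(calls_inter, truth_inter)
      longread <- list(n_reads = nrow(reads$reads),
                       n_element_reads = length(unique(hits$read_id)),
                       n_calls = nrow(calls),
                       n_calls_inter = nrow(calls_inter),
                       n_truth_inter = nrow(truth_inter),
                       precision_inter = ev$precision,
                       recall_inter = ev$recall)
      if (!is.null(outdir)) {
        write_reads_fasta(reads, opath(gname, "_reads.fa"),
                          opath(gname, "_reads_truth.tsv"))
        write_junctions_bedpe(calls, opath(gname, "_calls.bedpe"))
      }
      json_log(log_con, "longread-sv", guide = gname,
               n_calls = nrow(calls))
    }

    if (!is.null(outdir)) {
      write_matches_tsv(matches, opath(gname, "_matches.tsv"))
      write_junctions_bedpe(rr$junctions, opath(gname, "_junctions.bedpe"))
      write_segments_tsv(rr, opath(gname, "_segments.tsv"))
      write_bins_tsv(profile, opath(gname, "_cnv.tsv"))
      write_regions_bed(regions, opath(gname, "_high_cnv.bed"))
    }

    arms[[gname]] <- list(
      guide = guide,
      n_matches = nrow(matches),
      n_cuts = nrow(cuts),
      n_junctions = nrow(rr$junctions),
      n_intra = sum(rr$junctions$chrom_a == rr$junctions$chrom_b),
      n_inter = sum(rr$junctions$chrom_a != rr$junctions$chrom_b),
      cnv_sd = stats::sd(profile$value),
      cnv_mean = mean(profile$value),
      permutation = list(observed = perm$observed,
                         null_mean = perm$null_mean,
                         null_sd = perm$null_sd, z = perm$z,
                         p_value = perm$p_value,
                         p_empirical = perm$p_empirical,
                         degenerate = perm$degenerate),
      mc = if (is.null(mc)) NULL else list(
        observed_intra = mc$observed_intra,
        observed_inter = mc$observed_inter,
        expected_intra_mean = mc$expected_intra_mean,
        chi_square = mc$chi_square, p_value = mc$p_value,
        closed_form_intra_fraction = mc$closed_form_intra_fraction),
      distance_categories = as.list(table(dists$category)),
      longread = longread,
      profile = profile
    )
  }

  cross <- NULL
  if (all(c("sgL1", "sgAlu") %in% names(arms))) {
    cb <- cnv_correlation(arms$sgL1$profile, arms$sgAlu$profile, "per_bin")
    cc <- cnv_correlation(arms$sgL1$profile, arms$sgAlu$profile,
                          "per_chromosome")
    cross <- list(
      cnv_r_squared_per_bin = cb$r_squared,
      cnv_slope_per_bin = cb$slope,
      cnv_r_squared_per_chromosome = cc$r_squared,
      cnv_slope_per_chromosome = cc$slope)
  }

  for (gname in names(arms)) arms[[gname]]$profile <- NULL
  report <- structure(list(
    schema = "gcrsim_report/1",
    seed = config$seed,
    genome = list(n_chromosomes = config$n_chromosomes,
                  total_bp = sum(lens),
                  n_repeat_copies = nrow(annotation)),
    arms = arms,
    cross = cross
  ), class = "gcr_report")
  if (!is.null(outdir)) {
    writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                digits = 10, pretty = TRUE, null = "null"),
               opath("report.json"))
  }
  json_log(log_con, "done")
  report
}

#' @export
print.gcr_report <- function(x, ...) {
  cat("<gcr_report>", x$schema, "\n")
  for (gname in names(x$arms)) {
    a <- x$arms[[gname]]
    cat(sprintf("  %s: %d matches, %d cuts, %d junctions (%d intra/%d inter)\n",
                gname, a$n_matches, a$n_cuts, a$n_junctions, a$n_intra,
                a$n_inter))
  }
  if (!is.null(x$cross)) {
    cat(sprintf("  CNV R^2 (per bin) between arms: %.3f\n",
                x$cross$cnv_r_squared_per_bin))
  }
  invisible(x)
}

#' Validate a run report against the expected schema
#'
#' Checks the presence and types of every field the report contract
#' promises; used by the pipeline tests and by downstream consumers of
#' `report.json`.
#'
#' @param report a `gcr_report` (or a list parsed from `report.json`).
#' @return TRUE invisibly; errors describe the first violation.
#' @export
validate_run_report <- function(report) {
  need <- function(cond, what) if (!cond) stopf("invalid report: %s", what)
  need(identical(report$schema, "gcrsim_report/1"), "schema tag")
  need(is.numeric(report$seed), "seed")
  need(all(c("n_chromosomes", "total_bp", "n_repeat_copies") %in%
             names(report$genome)), "genome block")
  need(length(report$arms) >= 1L, "at least one arm")
  for (a in report$arms) {
    need(all(c("guide", "n_matches", "n_cuts", "n_junctions", "n_intra",
               "n_inter", "permutation", "distance_categories") %in%
               names(a)), "arm fields")
    need(all(c("observed", "null_mean", "p_value", "degenerate") %in%
               names(a$permutation)), "permutation fields")
  }
  invisible(TRUE)
}
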