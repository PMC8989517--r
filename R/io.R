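# Readers and writers for the standard interchange formats. FASTA goes
# through Biostrings; the line-oriented tabular formats (BED, BEDPE, PAF,
# TSV) are plain read/write with fixed column contracts so that every
# writer round-trips through its reader.

#' Write a genome to FASTA (60-column wrap)
#' @param genome a `gcr_genome` or named character vector.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return a `gcr_genome`.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  structure(out, class = "gcr_genome")
}

#' Write a repeat annotation as BED6
#'
#' Columns: chrom, start, end, name (copy_id), score (mismatch count of the
#' embedded guide; -1 when the copy carries no target site), strand.
#' @param annotation repeat annotation data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_annotation_bed <- function(annotation, path) {
  score <- ifelse(is.na(annotation$guide_mismatch), -1L,
                  annotation$guide_mismatch)
  df <- data.frame(annotation$chrom, annotation$start, annotation$end,
                   paste(annotation$copy_id, annotation$element_class,
                         sep = "|"),
                   score, annotation$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 repeat annotation
#' @param path BED file written by [write_annotation_bed()] (or any BED6
#'   whose name field is `copy_id|element_class`).
#' @return repeat annotation data.frame.
#' @export
read_annotation_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  parts <- strsplit(df$name, "|", fixed = TRUE)
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             element_class = vapply(parts, function(p) p[2] %||% NA_character_,
                                    character(1)),
             strand = df$strand,
             copy_id = vapply(parts, `[[`, character(1), 1L),
             guide_mismatch = ifelse(df$score < 0, NA_integer_,
                                     as.integer(df$score)),
             stringsAsFactors = FALSE)
}

.bedpe_header <- paste("#chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                       "end_b", "name", "score", "strand_a", "strand_b",
                       sep = "\t")

#' Write junctions as BEDPE
#'
#' Standard ten-column BEDPE (0-based half-open single-base intervals per
#' breakpoint); name carries the junction class, score the read support.
#' @param junctions junction data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_junctions_bedpe <- function(junctions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.bedpe_header, con)
  if (nrow(junctions) > 0L) {
    df <- data.frame(junctions$chrom_a, junctions$pos_a,
                     junctions$pos_a + 1L, junctions$chrom_b,
                     junctions$pos_b, junctions$pos_b + 1L,
                     junctions$class, junctions$support,
                     junctions$strand_a, junctions$strand_b)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read junctions from BEDPE
#' @param path BEDPE file.
#' @return junction data.frame.
#' @export
read_junctions_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_junctions())
  df <- utils::read.table(text = lines, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(chrom_a = df[[1]], pos_a = df[[2]], strand_a = df[[9]],
             chrom_b = df[[4]], pos_b = df[[5]], strand_b = df[[10]],
             class = df[[7]], support = df[[8]], stringsAsFactors = FALSE)
}

#' Write/read a binned table (counts, CNV profile, copy truth) as TSV
#'
#' Four columns: chrom, start, end and the value column (its name recorded
#' in the header).
#' @param x data.frame chrom, start, end, plus one value column.
#' @param path file path.
#' @return invisibly `path` for the writer; the data.frame for the reader.
#' @export
write_bins_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins_tsv
#' @export
read_bins_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a region set as BED3
#' @param regions data.frame chrom, start, end.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED3 region set
#' @param path BED file.
#' @return data.frame chrom, start, end.
#' @export
read_regions_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end"))
}

#' Write long reads as FASTA plus an origin-truth TSV
#' @param reads a `gcr_reads`.
#' @param fasta_path FASTA output path.
#' @param truth_path optional TSV path for the origin truth (read_id,
#'   part_index, chrom, start, end, strand).
#' @return invisibly, `fasta_path`.
#' @export
write_reads_fasta <- function(reads, fasta_path, truth_path = NULL) {
  x <- Biostrings::DNAStringSet(
    stats::setNames(reads$reads$sequence, reads$reads$read_id))
  Biostrings::writeXStringSet(x, filepath = fasta_path, width = 60L)
  if (!is.null(truth_path)) {
    utils::write.table(reads$origin, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Read long reads from FASTA (optionally with origin truth)
#' @param fasta_path FASTA file.
#' @param truth_path optional origin-truth TSV.
#' @return a `gcr_reads` (error_rate NA when unknown).
#' @export
read_reads_fasta <- function(fasta_path, truth_path = NULL) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  reads <- data.frame(read_id = sub("\\s.*$", "", names(x)),
                      sequence = as.character(unname(x)),
                      length = Biostrings::width(x),
                      error_rate = NA_real_, stringsAsFactors = FALSE)
  origin <- if (!is.null(truth_path)) {
    utils::read.table(truth_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    data.frame(read_id = character(0), part_index = integer(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  }
  structure(list(reads = reads, origin = origin), class = "gcr_reads")
}

#' Write split alignments as PAF (12 mandatory columns)
#'
#' Minimap2-dialect PAF: query name/length/start/end, strand, target
#' name/length/start/end, matching bases, alignment block length, mapping
#' quality.
#' @param aln SplitAlignment data.frame.
#' @param read_lengths named read lengths.
#' @param chrom_lengths named reference chromosome lengths.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_paf <- function(aln, read_lengths, chrom_lengths, path) {
  if (nrow(aln) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  blk <- pmax(aln$read_end - aln$read_start, aln$r_end - aln$r_start)
  nmatch <- as.integer(round(aln$identity * blk))
  df <- data.frame(aln$read_id, read_lengths[aln$read_id],
                   aln$read_start, aln$read_end, aln$strand, aln$chrom,
                   chrom_lengths[aln$chrom], aln$r_start, aln$r_end,
                   nmatch, blk, 60L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PAF file (mandatory columns only)
#' @param path PAF file (tags beyond column 12 are ignored).
#' @return data.frame with the 12 mandatory columns.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(qname = character(0), qlen = integer(0),
                      qstart = integer(0), qend = integer(0),
                      strand = character(0), tname = character(0),
                      tlen = integer(0), tstart = integer(0),
                      tend = integer(0), nmatch = integer(0),
                      alen = integer(0), mapq = integer(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  data.frame(qname = get(1), qlen = as.integer(get(2)),
             qstart = as.integer(get(3)), qend = as.integer(get(4)),
             strand = get(5), tname = get(6), tlen = as.integer(get(7)),
             tstart = as.integer(get(8)), tend = as.integer(get(9)),
             nmatch = as.integer(get(10)), alen = as.integer(get(11)),
             mapq = as.integer(get(12)), stringsAsFactors = FALSE)
}

#' Convert imported PAF records to the SplitAlignment contract
#'
#' Alignments from a long-read aligner (e.g. chimeric/supplementary pieces)
#' become flank alignments for [call_translocations()], bypassing the
#' builtin mapper.
#' @param paf data.frame from [read_paf()].
#' @return SplitAlignment data.frame.
#' @export
paf_to_split_alignments <- function(paf) {
  if (nrow(paf) == 0L) return(empty_split_alignments())
  data.frame(read_id = paf$qname, read_start = paf$qstart,
             read_end = paf$qend, chrom = paf$tname,
             r_start = paf$tstart, r_end = paf$tend, strand = paf$strand,
             n_anchors = NA_integer_,
             identity = ifelse(paf$alen > 0, paf$nmatch / paf$alen, 0),
             source = "paf_import", stringsAsFactors = FALSE)
}

#' Write a derivative segment map as TSV
#' @param rearrangement a `gcr_rearrangement` (or its `segments`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_segments_tsv <- function(rearrangement, path) {
  seg <- if (inherits(rearrangement, "gcr_rearrangement")) {
    rearrangement$segments
  } else rearrangement
  utils::write.table(seg, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a derivative segment map from TSV
#' @param path TSV written by [write_segments_tsv()].
#' @return segments data.frame.
#' @export
read_segments_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write guide matches as a BED6-compatible TSV
#' @param matches data.frame from [find_guide_matches()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_matches_tsv <- function(matches, path) {
  df <- matches[, c("chrom", "start", "end", "strand", "mismatch",
                    "sequence")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
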