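write_tsv0 <- function(df, path, col.names = TRUE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names)
}

#' Write hits as 12-column BLAST tabular
#'
#' Inverse of [parse_hits()]: internal 0-based half-open forward-ordered
#' coordinates are converted back to 1-based inclusive, with subject start/end
#' swapped for minus-strand hits. E-values are printed with 3 significant
#' digits, bit scores with 1 decimal — the precision the simulator stores, so
#' emit/write/parse round-trips are exact.
#'
#' @param hits Hit data frame in the internal convention.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  s1 <- hits$subject_start + 1
  s2 <- hits$subject_end
  minus <- hits$strand == "-"
  tab <- data.frame(
    hits$query_id, hits$subject_chromosome,
    sprintf("%.2f", hits$percent_identity),
    hits$align_length, hits$mismatches, hits$gap_opens,
    hits$q_start, hits$q_end,
    ifelse(minus, s2, s1), ifelse(minus, s1, s2),
    sprintf("%.3g", hits$e_value), sprintf("%.1f", hits$bit_score),
    stringsAsFactors = FALSE)
  write_tsv0(tab, path, col.names = FALSE)
  invisible(path)
}

#' Read / write a genetic map
#'
#' A genetic map is a four-column TSV with header: `marker` (marker id),
#' `linkage_group`, `cM` (position), `sequence_id` (the query sequence the
#' marker was developed from, as used in the hit table).
#'
#' @param map Data frame with those four columns.
#' @param path File path.
#' @return `read_genetic_map()` returns the map data frame;
#'   `write_genetic_map()` returns `path` invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(all(c("marker", "linkage_group", "cM", "sequence_id") %in%
                  names(map)))
  write_tsv0(map[, c("marker", "linkage_group", "cM", "sequence_id")], path)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "numeric", "character"))
}

#' Read / write 3-column BED intervals
#'
#' BED is 0-based half-open, which matches the package-internal coordinate
#' convention, so no shifting happens here. Used for pericentromere intervals
#' and block tracks.
#'
#' @param bed Data frame with columns `chrom`, `start`, `end` (plus optional
#'   extra columns, written after the first three).
#' @param path File path.
#' @return `read_bed()` returns a data frame with `chrom`, `start`, `end` (and
#'   a `name` column if a fourth column is present).
#' @export
write_bed <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  keep <- c("chrom", "start", "end",
            intersect("name", names(bed)))
  write_tsv0(bed[, keep, drop = FALSE], path, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  raw <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  names(raw)[1:3] <- c("chrom", "start", "end")
  if (ncol(raw) >= 4) names(raw)[4] <- "name"
  raw
}

#' Read / write subject chromosome lengths
#'
#' Two-column TSV with header: `chrom`, `length_bp`.
#'
#' @param chromosomes Data frame with `chrom` and `length_bp`.
#' @param path File path.
#' @return `read_chrom_lengths()` returns the data frame.
#' @export
write_chrom_lengths <- function(chromosomes, path) {
  stopifnot(all(c("chrom", "length_bp") %in% names(chromosomes)))
  write_tsv0(chromosomes[, c("chrom", "length_bp")], path)
  invisible(path)
}

#' @rdname write_chrom_lengths
#' @export
read_chrom_lengths <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = c("character", "numeric"))
}

#' Read / write best-two ortholog assignments
#'
#' TSV with header mirroring the columns of [assign_best_two()] output.
#' Missing secondaries are written as `NA`.
#'
#' @param assignments Output of [assign_best_two()].
#' @param path File path.
#' @return `read_assignments()` returns the assignments data frame.
#' @export
write_assignments <- function(assignments, path) {
  write_tsv0(assignments, path)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  out <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA")
  out$secondary_chrom <- as.character(out$secondary_chrom)
  out$secondary_strand <- as.character(out$secondary_strand)
  out
}

#' Write syntenic blocks as TSV and BED
#'
#' The TSV carries one row per block with the anchor markers collapsed into a
#' comma-separated column; the BED track places each block on its subject
#' chromosome (0-based half-open) for genome-browser display.
#'
#' @param blocks Output of [detect_blocks()].
#' @param path Output TSV path.
#' @param bed_path Optional BED path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path, bed_path = NULL) {
  flat <- blocks
  flat$anchor_markers <- vapply(blocks$anchors, function(a)
    paste(a$marker, collapse = ","), character(1))
  flat$anchors <- NULL
  write_tsv0(flat, path)
  if (!is.null(bed_path)) {
    write_bed(data.frame(chrom = blocks$subject_chromosome,
                         start = blocks$bp_start, end = blocks$bp_end,
                         name = blocks$block_id, stringsAsFactors = FALSE),
              bed_path)
  }
  invisible(path)
}

#' Write a flat key-value statistics table
#'
#' @param stats A named list or single-row data frame (e.g. [block_stats()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_stats_kv <- function(stats, path) {
  kv <- data.frame(key = names(stats),
                   value = vapply(stats, function(v) format(v, digits = 15),
                                  character(1)),
                   stringsAsFactors = FALSE)
  write_tsv0(kv, path)
  invisible(path)
}

#' Write the simulator truth event log
#'
#' @param truth The `truth` element of [simulate_synteny()] output.
#' @param path File path for the event-log TSV.
#' @return `path`, invisibly.
#' @export
write_truth_log <- function(truth, path) {
  write_tsv0(truth$event_log, path)
  invisible(path)
}
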