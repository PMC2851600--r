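blast_cols <- c("query_id", "subject_chromosome", "percent_identity",
                "align_length", "mismatches", "gap_opens", "q_start", "q_end",
                "subject_start", "subject_end", "e_value", "bit_score")

empty_hits <- function() {
  data.frame(query_id = character(0), subject_chromosome = character(0),
             percent_identity = numeric(0), align_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             q_start = integer(0), q_end = integer(0),
             subject_start = numeric(0), subject_end = numeric(0),
             strand = character(0), e_value = numeric(0),
             bit_score = numeric(0), stringsAsFactors = FALSE)
}

#' Parse a 12-column BLAST tabular hit file
#'
#' Reads the classic `outfmt 6` dialect (query, subject, % identity, alignment
#' length, mismatches, gap opens, q.start, q.end, s.start, s.end, E-value, bit
#' score; 1-based inclusive coordinates). Subject coordinates are normalised to
#' the package-internal convention: 0-based half-open, forward-ordered, with
#' `strand = "-"` when the raw file had `s.start > s.end`.
#'
#' @param path Path to a tab-separated hit file without header.
#' @return A hit data frame (see [emit_hits()] for columns). An empty file
#'   yields a zero-row frame; a row with the wrong column count is an error
#'   naming its line number.
#' @seealso [write_blast_hits()] for the inverse operation.
#' @export
parse_hits <- function(path) {
  if (!file.exists(path)) stop("no such hit file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(empty_hits())
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed hit row at line %d: expected 12 tab-separated fields, found %d",
                 bad[1], nf[bad[1]]), call. = FALSE)
  }
  raw <- read.table(path, sep = "\t", quote = "", comment.char = "",
                    stringsAsFactors = FALSE,
                    col.names = blast_cols,
                    colClasses = c("character", "character", "numeric",
                                   "integer", "integer", "integer", "integer",
                                   "integer", "numeric", "numeric", "numeric",
                                   "numeric"))
  minus <- raw$subject_start > raw$subject_end
  s_lo <- pmin(raw$subject_start, raw$subject_end)
  s_hi <- pmax(raw$subject_start, raw$subject_end)
  out <- raw
  out$subject_start <- s_lo - 1   # 1-based inclusive -> 0-based half-open
  out$subject_end <- s_hi
  out$strand <- ifelse(minus, "-", "+")
  out <- out[, c(blast_cols[1:10], "strand", "e_value", "bit_score")]
  out$e_value <- raw$e_value
  out$bit_score <- raw$bit_score
  out
}

#' Filter hits on E-value and alignment length
#'
#' Keeps hits with `e_value` strictly below `e_max` and `align_length` of at
#' least `min_len`, preserving input order. The defaults are the thresholds
#' used for the ortholog screen: E-value below 1e-10 and overlaps of 150 nt or
#' more.
#'
#' @param hits A hit data frame from [parse_hits()] or [emit_hits()].
#' @param e_max Exclusive E-value upper bound (> 0).
#' @param min_len Inclusive minimum alignment length (>= 0).
#' @return The qualifying subset, order preserved. Idempotent.
#' @export
filter_hits <- function(hits, e_max = 1e-10, min_len = 150) {
  stopifnot(e_max > 0, min_len >= 0)
  keep <- hits$e_value < e_max & hits$align_length >= min_len
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_assignments <- function() {
  data.frame(query_id = character(0),
             primary_chrom = character(0), primary_start = numeric(0),
             primary_end = numeric(0), primary_strand = character(0),
             primary_evalue = numeric(0), primary_bits = numeric(0),
             primary_len = integer(0),
             secondary_chrom = character(0), secondary_start = numeric(0),
             secondary_end = numeric(0), secondary_strand = character(0),
             secondary_evalue = numeric(0), secondary_bits = numeric(0),
             secondary_len = integer(0),
             n_qualifying_hits = integer(0), stringsAsFactors = FALSE)
}

#' Reduce filtered hits to the best two subject loci per query
#'
#' Implements the one-to-two ortholog assumption for a genome that went
#' through a whole-genome duplication: per query, hits on the same subject
#' chromosome whose intervals are separated by `min_separation_nt` or less are
#' merged into one segment (represented by its best-scoring hit), segments are
#' ranked by bit score (ties broken by lower E-value, then chromosome name,
#' then leftmost start), and the top two distinct segments become the primary
#' and secondary locus. Queries with a single segment get no secondary locus.
#'
#' The separation rule mirrors the distinctness criterion used for electronic
#' mapping: two loci count as different segments only when the gap between
#' them is greater than `min_separation_nt` (default 50 nt).
#'
#' @param hits A filtered hit data frame.
#' @param min_separation_nt Maximum gap (nt) at or below which two
#'   same-chromosome hits are merged into one segment.
#' @return One row per query: `query_id`, primary and secondary locus fields
#'   (chrom/start/end/strand/evalue/bits/len; secondary is `NA` when absent)
#'   and `n_qualifying_hits`. Output is independent of input row order.
#' @export
assign_best_two <- function(hits, min_separation_nt = 50) {
  if (nrow(hits) == 0L) return(empty_assignments())
  res <- lapply(split(seq_len(nrow(hits)), hits$query_id), function(rows) {
    h <- hits[rows, , drop = FALSE]
    segs <- merge_segments(h, min_separation_nt)
    o <- order(-segs$bit_score, segs$e_value, segs$subject_chromosome,
               segs$seg_start)
    segs <- segs[o, , drop = FALSE]
    top <- segs[1, ]
    second <- if (nrow(segs) >= 2L) segs[2, ] else NULL
    data.frame(
      query_id = h$query_id[1],
      primary_chrom = top$subject_chromosome,
      primary_start = top$seg_start, primary_end = top$seg_end,
      primary_strand = top$strand, primary_evalue = top$e_value,
      primary_bits = top$bit_score, primary_len = top$align_length,
      secondary_chrom = if (is.null(second)) NA_character_ else second$subject_chromosome,
      secondary_start = if (is.null(second)) NA_real_ else second$seg_start,
      secondary_end = if (is.null(second)) NA_real_ else second$seg_end,
      secondary_strand = if (is.null(second)) NA_character_ else second$strand,
      secondary_evalue = if (is.null(second)) NA_real_ else second$e_value,
      secondary_bits = if (is.null(second)) NA_real_ else second$bit_score,
      secondary_len = if (is.null(second)) NA_integer_ else second$align_length,
      n_qualifying_hits = nrow(h),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$query_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_separation_nt") <- min_separation_nt
  attr(out, "merged_segments") <- TRUE
  out
}

# Merge same-chromosome hits separated by <= gap_nt into segments; each
# segment is represented by its best hit (highest bits, then lowest E, then
# leftmost) but spans the union of its member intervals.
merge_segments <- function(h, gap_nt) {
  parts <- lapply(split(seq_len(nrow(h)), h$subject_chromosome), function(rows) {
    g <- h[rows, , drop = FALSE]
    g <- g[order(g$subject_start, g$subject_end), , drop = FALSE]
    seg_id <- integer(nrow(g))
    seg_id[1] <- 1L
    cur_end <- g$subject_end[1]
    for (i in seq_len(nrow(g))[-1]) {
      if (g$subject_start[i] - cur_end <= gap_nt) {
        seg_id[i] <- seg_id[i - 1]
      } else {
        seg_id[i] <- seg_id[i - 1] + 1L
      }
      cur_end <- max(cur_end, g$subject_end[i])
    }
    do.call(rbind, lapply(split(seq_len(nrow(g)), seg_id), function(srows) {
      s <- g[srows, , drop = FALSE]
      best <- s[order(-s$bit_score, s$e_value, s$subject_start), ][1, ]
      best$seg_start <- min(s$subject_start)
      best$seg_end <- max(s$subject_end)
      best
    }))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Long (one row per locus) view of best-two assignments
#'
#' Unpivots the primary/secondary locus columns of [assign_best_two()] output
#' into one row per locus, dropping absent secondaries. This is the input
#' shape used by the duplication-block reconstruction.
#'
#' @param assignments Output of [assign_best_two()].
#' @return Data frame: query_id, rank ("primary"/"secondary"), chrom, start,
#'   end, strand, e_value, bits, len.
#' @export
assignments_to_loci <- function(assignments) {
  a <- assignments
  prim <- data.frame(query_id = a$query_id, rank = "primary",
                     chrom = a$primary_chrom, start = a$primary_start,
                     end = a$primary_end, strand = a$primary_strand,
                     e_value = a$primary_evalue, bits = a$primary_bits,
                     len = a$primary_len, stringsAsFactors = FALSE)
  sec <- data.frame(query_id = a$query_id, rank = "secondary",
                    chrom = a$secondary_chrom, start = a$secondary_start,
                    end = a$secondary_end, strand = a$secondary_strand,
                    e_value = a$secondary_evalue, bits = a$secondary_bits,
                    len = a$secondary_len, stringsAsFactors = FALSE)
  sec <- sec[!is.na(sec$chrom), , drop = FALSE]
  out <- rbind(prim, sec)
  out <- out[order(out$query_id, out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
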