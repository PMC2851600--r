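#' Order reference sequences along each subject chromosome
#'
#' For the within-genome duplication analysis, every sequence with two subject
#' loci is a reference that links two regions of the subject genome. On each
#' chromosome, references are ordered by the physical position of their
#' on-chromosome locus and annotated with their partner: the duplicate locus
#' with the lowest E-value on a *second* chromosome (or, failing that, a
#' non-overlapping locus on the same chromosome — a tandem-like duplication;
#' overlapping same-chromosome duplicates are skipped). Sequences with a
#' single locus are excluded.
#'
#' @param loci Long-format loci (one row per locus) with columns `query_id`,
#'   `chrom`, `start`, `end`, `e_value` — e.g. [assignments_to_loci()] output.
#' @return Data frame sorted by (chrom, position): chrom, position (locus
#'   midpoint), start, end, query_id, e_value, partner_chrom,
#'   partner_position, partner_e.
#' @export
order_references <- function(loci) {
  loci$position <- (loci$start + loci$end) / 2
  counts <- table(loci$query_id)
  multi <- names(counts)[counts >= 2L]
  loci <- loci[loci$query_id %in% multi, , drop = FALSE]
  if (nrow(loci) == 0L) {
    return(data.frame(chrom = character(0), position = numeric(0),
                      start = numeric(0), end = numeric(0),
                      query_id = character(0), e_value = numeric(0),
                      partner_chrom = character(0),
                      partner_position = numeric(0), partner_e = numeric(0),
                      stringsAsFactors = FALSE))
  }
  by_query <- split(seq_len(nrow(loci)), loci$query_id)
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    home <- loci[i, ]
    others <- loci[setdiff(by_query[[home$query_id]], i), , drop = FALSE]
    diff_chrom <- others[others$chrom != home$chrom, , drop = FALSE]
    cand <- if (nrow(diff_chrom) > 0L) diff_chrom else {
      same <- others[others$chrom == home$chrom, , drop = FALSE]
      same[same$end <= home$start | same$start >= home$end, , drop = FALSE]
    }
    if (nrow(cand) == 0L) next
    best <- cand[order(cand$e_value, cand$chrom, cand$position), ][1, ]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = home$chrom, position = home$position,
      start = home$start, end = home$end,
      query_id = home$query_id, e_value = home$e_value,
      partner_chrom = best$chrom, partner_position = best$position,
      partner_e = best$e_value, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(0), position = numeric(0),
                      start = numeric(0), end = numeric(0),
                      query_id = character(0), e_value = numeric(0),
                      partner_chrom = character(0),
                      partner_position = numeric(0), partner_e = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect within-genome duplicate blocks from ordered references
#'
#' Scans each chromosome's ordered reference list for maximal runs of
#' consecutive references sharing one partner chromosome. Runs of at least
#' `min_loci` references become duplication blocks: the home interval spans
#' the run's loci, the partner interval spans their partner loci, and the
#' orientation is direct or inverted by the sign of the rank correlation
#' between home and partner positions. Consecutive order is enforced strictly
#' — a single reference with a different partner breaks the run — so blocks
#' on one home chromosome never overlap.
#'
#' @param ordered Output of [order_references()].
#' @param min_loci Minimum references per block (default 10).
#' @param annotation Optional data frame (query_id, linkage_group, cM) tracing
#'   references back to the genetic map; blocks are annotated with the
#'   majority linkage group and its cM range among annotated references.
#' @return Data frame: home_chromosome, home_start, home_end,
#'   partner_chromosome, partner_start, partner_end, orientation,
#'   n_reference_loci, linkage_group, cM_start, cM_end (annotation columns NA
#'   when unavailable).
#' @export
detect_duplicate_blocks <- function(ordered, min_loci = 10,
                                    annotation = NULL) {
  blocks <- list()
  for (ch in unique(ordered$chrom)) {
    g <- ordered[ordered$chrom == ch, , drop = FALSE]
    r <- rle(g$partner_chrom)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (r$lengths[k] < min_loci) next
      run <- g[starts[k]:stops[k], , drop = FALSE]
      rho <- suppressWarnings(cor(run$position, run$partner_position,
                                  method = "spearman"))
      lg <- NA_character_; cm_lo <- NA_real_; cm_hi <- NA_real_
      if (!is.null(annotation)) {
        ann <- annotation[match(run$query_id, annotation$query_id), ,
                          drop = FALSE]
        ann <- ann[!is.na(ann$query_id), , drop = FALSE]
        if (nrow(ann) > 0L) {
          lg <- names(sort(table(ann$linkage_group), decreasing = TRUE))[1]
          cms <- ann$cM[ann$linkage_group == lg]
          cm_lo <- min(cms); cm_hi <- max(cms)
        }
      }
      blocks[[length(blocks) + 1L]] <- data.frame(
        home_chromosome = ch,
        home_start = min(run$start), home_end = max(run$end),
        partner_chromosome = r$values[k],
        partner_start = min(run$partner_position),
        partner_end = max(run$partner_position),
        orientation = if (!is.na(rho) && rho < 0) "inverted" else "direct",
        n_reference_loci = nrow(run),
        linkage_group = lg, cM_start = cm_lo, cM_end = cm_hi,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(blocks) > 0L) do.call(rbind, blocks) else
    data.frame(home_chromosome = character(0), home_start = numeric(0),
               home_end = numeric(0), partner_chromosome = character(0),
               partner_start = numeric(0), partner_end = numeric(0),
               orientation = character(0), n_reference_loci = integer(0),
               linkage_group = character(0), cM_start = numeric(0),
               cM_end = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-chromosome partner summary of duplication blocks
#'
#' For each home chromosome: the distinct partner chromosomes it shares
#' duplication blocks with, the number of blocks, and the distinct linkage
#' groups its blocks trace back to (when annotated).
#'
#' @param blocks Output of [detect_duplicate_blocks()].
#' @param chromosomes Optional character vector of chromosomes to report even
#'   when they carry no blocks (empty partner sets).
#' @return Data frame: chrom, n_blocks, partners (comma-separated, sorted),
#'   linkage_groups (comma-separated, sorted; empty when unannotated).
#' @export
partner_summary <- function(blocks, chromosomes = NULL) {
  chroms <- unique(c(chromosomes, blocks$home_chromosome))
  rows <- lapply(chroms, function(ch) {
    b <- blocks[blocks$home_chromosome == ch, , drop = FALSE]
    lgs <- sort(unique(b$linkage_group[!is.na(b$linkage_group)]))
    data.frame(chrom = ch, n_blocks = nrow(b),
               partners = paste(sort(unique(b$partner_chromosome)),
                                collapse = ","),
               linkage_groups = paste(lgs, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
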