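#' Physical-to-genetic distance ratios between neighboring anchors
#'
#' One record per consecutive anchor pair within each syntenic block: the
#' genetic distance between the markers (on the query map) against the
#' physical distance between their subject loci (anchor midpoints). Pairs of
#' cosegregating markers (zero cM apart) carry no ratio; they are skipped and
#' counted in the `n_cosegregating` attribute. Cross-block pairs are never
#' formed — they would span rearrangement breakpoints.
#'
#' @param blocks Output of [detect_blocks()].
#' @return Data frame: block_id, linkage_group, subject_chromosome, marker_a,
#'   marker_b, delta_cM, delta_bp, ratio (bp/cM), with attribute
#'   `n_cosegregating`.
#' @export
neighbor_ratios <- function(blocks) {
  recs <- list()
  n_coseg <- 0L
  for (i in seq_len(nrow(blocks))) {
    a <- blocks$anchors[[i]]
    a <- a[order(a$cM, a$bp), , drop = FALSE]
    if (nrow(a) < 2L) next
    for (j in seq_len(nrow(a) - 1L)) {
      d_cM <- a$cM[j + 1L] - a$cM[j]
      if (d_cM == 0) {
        n_coseg <- n_coseg + 1L
        next
      }
      d_bp <- abs(a$bp[j + 1L] - a$bp[j])
      recs[[length(recs) + 1L]] <- data.frame(
        block_id = blocks$block_id[i],
        linkage_group = blocks$linkage_group[i],
        subject_chromosome = blocks$subject_chromosome[i],
        marker_a = a$marker[j], marker_b = a$marker[j + 1L],
        delta_cM = d_cM, delta_bp = d_bp, ratio = d_bp / d_cM,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs) > 0L) do.call(rbind, recs) else
    data.frame(block_id = character(0), linkage_group = character(0),
               subject_chromosome = character(0), marker_a = character(0),
               marker_b = character(0), delta_cM = numeric(0),
               delta_bp = numeric(0), ratio = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_cosegregating") <- n_coseg
  out
}

#' Summarise neighbor ratios
#'
#' @param records Output of [neighbor_ratios()] (at least one record).
#' @param threshold_bp_per_cM Threshold for the "fraction below" statistic;
#'   strict less-than, matching the convention "less than 100,000 bp/cM".
#' @return Named list: n, mean, median, frac_below.
#' @export
ratio_summary <- function(records, threshold_bp_per_cM = 1e5) {
  if (nrow(records) == 0L) {
    stop("ratio_summary needs at least one ratio record", call. = FALSE)
  }
  list(n = nrow(records),
       mean = mean(records$ratio),
       median = median(records$ratio),
       frac_below = mean(records$ratio < threshold_bp_per_cM))
}

#' Pair duplicate blocks anchored to the same genetic interval
#'
#' After a whole-genome duplication, one linkage-group interval is typically
#' syntenic to two subject regions. Two blocks form a duplicate pair when they
#' sit on the same linkage group and their cM intervals overlap by at least
#' `min_overlap` of the shorter interval.
#'
#' @param blocks Output of [detect_blocks()].
#' @param min_overlap Required cM overlap as a fraction of the shorter
#'   interval.
#' @return Data frame: block_a, block_b (block ids, a < b in table order),
#'   linkage_group, overlap_cM.
#' @export
pair_duplicate_blocks <- function(blocks, min_overlap = 0.5) {
  pairs <- list()
  for (lg in unique(blocks$linkage_group)) {
    b <- blocks[blocks$linkage_group == lg, , drop = FALSE]
    if (nrow(b) < 2L) next
    for (i in seq_len(nrow(b) - 1L)) {
      for (j in (i + 1L):nrow(b)) {
        ov <- min(b$cM_end[i], b$cM_end[j]) - max(b$cM_start[i], b$cM_start[j])
        shorter <- min(b$cM_end[i] - b$cM_start[i],
                       b$cM_end[j] - b$cM_start[j])
        if (shorter <= 0 || ov < min_overlap * shorter) next
        pairs[[length(pairs) + 1L]] <- data.frame(
          block_a = b$block_id[i], block_b = b$block_id[j],
          linkage_group = lg, overlap_cM = ov, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(block_a = character(0), block_b = character(0),
               linkage_group = character(0), overlap_cM = numeric(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ratio differences between duplicate block pairs
#'
#' For each duplicate pair (see [pair_duplicate_blocks()]), compares the two
#' block-level physical-to-genetic ratios (block bp span over block cM span)
#' and reports their absolute difference. The result is symmetric in pair
#' order.
#'
#' @param blocks Output of [detect_blocks()].
#' @param min_overlap Passed to [pair_duplicate_blocks()].
#' @return List with `pairs` (block_a, block_b, linkage_group, ratio_a,
#'   ratio_b, diff) and `summary` (mean, median, min, max of the differences;
#'   all `NA` when there are no pairs).
#' @export
duplicate_ratio_diffs <- function(blocks, min_overlap = 0.5) {
  dp <- pair_duplicate_blocks(blocks, min_overlap)
  block_ratio <- function(id) {
    i <- match(id, blocks$block_id)
    (blocks$bp_end[i] - blocks$bp_start[i]) /
      (blocks$cM_end[i] - blocks$cM_start[i])
  }
  if (nrow(dp) == 0L) {
    return(list(
      pairs = data.frame(block_a = character(0), block_b = character(0),
                         linkage_group = character(0), ratio_a = numeric(0),
                         ratio_b = numeric(0), diff = numeric(0),
                         stringsAsFactors = FALSE),
      summary = list(mean = NA_real_, median = NA_real_, min = NA_real_,
                     max = NA_real_)))
  }
  ra <- vapply(dp$block_a, block_ratio, numeric(1))
  rb <- vapply(dp$block_b, block_ratio, numeric(1))
  pairs <- data.frame(block_a = dp$block_a, block_b = dp$block_b,
                      linkage_group = dp$linkage_group,
                      ratio_a = ra, ratio_b = rb, diff = abs(ra - rb),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs,
       summary = list(mean = mean(pairs$diff), median = median(pairs$diff),
                      min = min(pairs$diff), max = max(pairs$diff)))
}
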