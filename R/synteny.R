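#' Chain ortholog anchors into syntenic blocks
#'
#' An anchor is one subject locus of one genetically mapped marker: each
#' best-two assignment contributes its primary and (when present) secondary
#' locus independently, so a marker may anchor two blocks — the one-to-two
#' pattern expected after a whole-genome duplication. Within each
#' (linkage group, subject chromosome) pair, anchors are sorted by cM and
#' consecutive anchors join a chain when both the cM gap and the bp gap
#' (between anchor midpoints) stay within the limits. Chains with fewer than
#' `min_loci` anchors or spanning less than `min_cM` are discarded: the block
#' definition is "at least three shared loci covering at least 4 cM".
#'
#' Orientation changes inside a chain do not break it; orientation is
#' descriptive (see [classify_orientation()]). Blocks are never merged across
#' subject chromosomes.
#'
#' @param assignments Output of [assign_best_two()].
#' @param map Genetic map data frame (marker, linkage_group, cM, sequence_id).
#' @param max_gap_cM Maximum genetic gap between consecutive anchors in a
#'   chain.
#' @param max_gap_bp Maximum physical gap between consecutive anchor midpoints.
#' @param min_loci Minimum anchors per block (inclusive).
#' @param min_cM Minimum genetic span per block (inclusive).
#' @return Data frame of class `synteny_blocks`: block_id, linkage_group,
#'   cM_start, cM_end, subject_chromosome, bp_start, bp_end, orientation,
#'   n_anchors, extended_bp_start, extended_bp_end (initially the bp bounds)
#'   and a list-column `anchors` (marker, cM, bp midpoint, start, end, strand
#'   per anchor, cM-sorted). Assignments whose query is not on the map are
#'   skipped with one warning.
#' @export
detect_blocks <- function(assignments, map, max_gap_cM = 15,
                          max_gap_bp = 5e6, min_loci = 3, min_cM = 4) {
  hit_map <- match(assignments$query_id, map$sequence_id)
  unmapped <- is.na(hit_map)
  if (any(unmapped)) {
    warning(sprintf("%d assignment(s) skipped: query not on the genetic map",
                    sum(unmapped)), call. = FALSE)
  }
  a <- assignments[!unmapped, , drop = FALSE]
  m <- map[hit_map[!unmapped], , drop = FALSE]
  loci <- rbind(
    data.frame(marker = m$marker, linkage_group = m$linkage_group, cM = m$cM,
               chrom = a$primary_chrom, start = a$primary_start,
               end = a$primary_end, strand = a$primary_strand,
               stringsAsFactors = FALSE),
    data.frame(marker = m$marker, linkage_group = m$linkage_group, cM = m$cM,
               chrom = a$secondary_chrom, start = a$secondary_start,
               end = a$secondary_end, strand = a$secondary_strand,
               stringsAsFactors = FALSE))
  loci <- loci[!is.na(loci$chrom), , drop = FALSE]
  loci$bp <- (loci$start + loci$end) / 2

  blocks <- list()
  for (key in split(seq_len(nrow(loci)),
                    paste(loci$linkage_group, loci$chrom, sep = "\r"))) {
    g <- loci[key, , drop = FALSE]
    g <- g[order(g$cM, g$bp), , drop = FALSE]
    n <- nrow(g)
    brk <- if (n > 1) {
      (diff(g$cM) > max_gap_cM) | (abs(diff(g$bp)) > max_gap_bp)
    } else logical(0)
    chain <- cumsum(c(1L, as.integer(brk)))
    for (cid in unique(chain)) {
      ch <- g[chain == cid, , drop = FALSE]
      if (nrow(ch) < min_loci) next
      if (max(ch$cM) - min(ch$cM) < min_cM) next
      blocks[[length(blocks) + 1L]] <- list(
        linkage_group = ch$linkage_group[1],
        cM_start = min(ch$cM), cM_end = max(ch$cM),
        subject_chromosome = ch$chrom[1],
        bp_start = min(ch$start), bp_end = max(ch$end),
        orientation = classify_orientation(ch),
        n_anchors = nrow(ch),
        anchors = ch[, c("marker", "cM", "bp", "start", "end", "strand")])
    }
  }
  if (length(blocks) == 0L) return(empty_blocks())
  out <- data.frame(
    block_id = sprintf("B%03d", seq_along(blocks)),
    linkage_group = vapply(blocks, `[[`, character(1), "linkage_group"),
    cM_start = vapply(blocks, `[[`, numeric(1), "cM_start"),
    cM_end = vapply(blocks, `[[`, numeric(1), "cM_end"),
    subject_chromosome = vapply(blocks, `[[`, character(1),
                                "subject_chromosome"),
    bp_start = vapply(blocks, `[[`, numeric(1), "bp_start"),
    bp_end = vapply(blocks, `[[`, numeric(1), "bp_end"),
    orientation = vapply(blocks, `[[`, character(1), "orientation"),
    n_anchors = vapply(blocks, `[[`, numeric(1), "n_anchors"),
    stringsAsFactors = FALSE)
  out$extended_bp_start <- out$bp_start
  out$extended_bp_end <- out$bp_end
  out$anchors <- lapply(blocks, function(b) {
    a <- b$anchors
    rownames(a) <- NULL
    a
  })
  o <- order(out$linkage_group, out$cM_start, out$subject_chromosome)
  out <- out[o, , drop = FALSE]
  out$block_id <- sprintf("B%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "params") <- list(max_gap_cM = max_gap_cM, max_gap_bp = max_gap_bp,
                              min_loci = min_loci, min_cM = min_cM)
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

empty_blocks <- function() {
  out <- data.frame(block_id = character(0), linkage_group = character(0),
                    cM_start = numeric(0), cM_end = numeric(0),
                    subject_chromosome = character(0), bp_start = numeric(0),
                    bp_end = numeric(0), orientation = character(0),
                    n_anchors = numeric(0), extended_bp_start = numeric(0),
                    extended_bp_end = numeric(0), stringsAsFactors = FALSE)
  out$anchors <- list()
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

#' Classify the orientation of a block's anchor order
#'
#' `direct` when the physical (bp) rank order of the anchors equals their
#' genetic (cM) rank order, `inverted` when it is exactly reversed, `mixed`
#' otherwise. Blocks are classified at detection time; this helper also
#' accepts a bare anchor table.
#'
#' @param block A single-row slice of [detect_blocks()] output, or an anchor
#'   data frame with `cM` and `bp` columns (>= 2 rows).
#' @return One of `"direct"`, `"inverted"`, `"mixed"`.
#' @export
classify_orientation <- function(block) {
  anchors <- if (is.data.frame(block) && "anchors" %in% names(block)) {
    block$anchors[[1]]
  } else block
  stopifnot(nrow(anchors) >= 2)
  o <- order(anchors$cM, anchors$bp)
  bp <- anchors$bp[o]
  rk <- rank(bp, ties.method = "first")
  n <- length(rk)
  if (all(rk == seq_len(n))) "direct"
  else if (all(rk == rev(seq_len(n)))) "inverted"
  else "mixed"
}

# Union length of possibly overlapping numeric intervals (used for cM, which
# is fractional; bp unions go through IRanges).
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s)
}

# Union of bp intervals per chromosome: a plain list of IRanges by chromosome.
bp_union <- function(chrom, start, end) {
  keep <- end > start
  chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  out <- lapply(unique(chrom), function(ch) {
    i <- chrom == ch
    IRanges::IRanges(start = as.integer(start[i]) + 1L,
                     end = as.integer(end[i]))
  })
  names(out) <- unique(chrom)
  out
}

#' Summarise syntenic block sizes and genome coverage
#'
#' Genetic coverage is the union of per-linkage-group cM intervals (duplicate
#' blocks over the same interval are counted once) as a percentage of the
#' total map length. Physical coverage is the union of subject bp intervals
#' over the genome size. Euchromatic coverage removes pericentromeric
#' intervals from both numerator and denominator, mirroring the exclusion of
#' pericentromeric DNA from coverage calculations.
#'
#' @param blocks Output of [detect_blocks()] (may be empty).
#' @param map_total_cM Total genetic length of the map, cM.
#' @param genome_bp Total subject genome size, bp.
#' @param pericentromeres Optional data frame (chrom, start, end; 0-based
#'   half-open) of pericentromeric intervals.
#' @return Named list: n_blocks, mean_cM, median_cM, frac_gt_20cM, mean_Mb,
#'   median_Mb, frac_gt_2Mb, genetic_coverage_pct, physical_coverage_pct,
#'   euchromatic_coverage_pct (NA when no pericentromeres given). All-zero
#'   when `blocks` is empty.
#' @export
block_stats <- function(blocks, map_total_cM, genome_bp,
                        pericentromeres = NULL) {
  if (nrow(blocks) == 0L) {
    return(list(n_blocks = 0, mean_cM = 0, median_cM = 0, frac_gt_20cM = 0,
                mean_Mb = 0, median_Mb = 0, frac_gt_2Mb = 0,
                genetic_coverage_pct = 0, physical_coverage_pct = 0,
                euchromatic_coverage_pct = 0))
  }
  gen_len <- blocks$cM_end - blocks$cM_start
  phy_len <- (blocks$bp_end - blocks$bp_start) / 1e6

  cm_cov <- sum(vapply(split(seq_len(nrow(blocks)), blocks$linkage_group),
                       function(rows) interval_union_length(
                         blocks$cM_start[rows], blocks$cM_end[rows]),
                       numeric(1)))

  un <- bp_union(blocks$subject_chromosome, blocks$bp_start, blocks$bp_end)
  un <- lapply(un, IRanges::reduce)
  bp_cov <- sum(vapply(un, function(ir) sum(IRanges::width(ir)), numeric(1)))

  euch_pct <- NA_real_
  if (!is.null(pericentromeres) && nrow(pericentromeres) > 0L) {
    peri <- lapply(bp_union(pericentromeres$chrom, pericentromeres$start,
                            pericentromeres$end), IRanges::reduce)
    peri_total <- sum(vapply(peri, function(ir) sum(IRanges::width(ir)),
                             numeric(1)))
    euch_bp <- 0
    for (ch in names(un)) {
      block_ir <- un[[ch]]
      if (ch %in% names(peri)) {
        block_ir <- IRanges::setdiff(block_ir, peri[[ch]])
      }
      euch_bp <- euch_bp + sum(IRanges::width(block_ir))
    }
    euch_pct <- 100 * euch_bp / (genome_bp - peri_total)
  }

  list(n_blocks = nrow(blocks),
       mean_cM = mean(gen_len), median_cM = median(gen_len),
       frac_gt_20cM = mean(gen_len > 20),
       mean_Mb = mean(phy_len), median_Mb = median(phy_len),
       frac_gt_2Mb = mean(phy_len > 2),
       genetic_coverage_pct = 100 * cm_cov / map_total_cM,
       physical_coverage_pct = 100 * bp_cov / genome_bp,
       euchromatic_coverage_pct = euch_pct)
}

#' Score detected block boundaries against simulator truth
#'
#' Matches block edges to the true rearrangement boundaries of a simulated
#' derived genome. A predicted edge and a true boundary match when the true
#' boundary lies within the inter-anchor gap straddling that edge (anchors
#' pooled per chromosome): marker subsampling means a boundary's position is
#' only knowable to within one anchor gap.
#'
#' *Precision* is computed over breakpoint claims: block edges whose nearest
#' outward anchor belongs to a block of a different linkage group, or beyond
#' which no anchor exists (a chromosome-end claim). An edge where the same
#' linkage group simply continues in the next block is a map-coverage gap —
#' the method asserts missing data there, not a rearrangement — and is not
#' counted as a claim.
#'
#' *Recall* is computed over the true internal boundaries that are resolvable
#' by this class of method: (i) both flanking true blocks must carry at least
#' `min_loci` mapped markers spanning at least `min_cM` — the detection
#' thresholds applied to the truth at the realised marker density — and
#' (ii) the flanking blocks must descend from different linkage groups.
#' A boundary flanked by a segment too small to ever pass the block
#' definition is invisible at this resolution, and a junction between two
#' segments of the *same* ancestral chromosome (e.g. a segment moved onto its
#' duplicate-partner chromosome) cannot be seen by chaining that sorts each
#' linkage group's anchors by cM — both copies' loci interleave into one
#' chain. Neither is a detection failure; both are resolution limits.
#'
#' @param blocks Output of [detect_blocks()].
#' @param truth The `truth` element of a simulation (uses `truth$blocks`).
#' @param map The genetic map used for detection.
#' @param derived The `derived` element of the simulation (for marker
#'   ortholog positions).
#' @param min_loci,min_cM Detectability thresholds; use the values given to
#'   [detect_blocks()].
#' @return List: precision, recall, n_true (resolvable internal boundaries),
#'   n_pred (breakpoint claims), n_matched_true, n_matched_pred.
#' @export
block_recovery <- function(blocks, truth, map, derived,
                           min_loci = 3, min_cM = 4) {
  tb <- truth$blocks
  marker_orth <- derived$genes[
    derived$genes$ancestor_gene %in% map$sequence_id, , drop = FALSE]

  prec_num <- 0L; prec_den <- 0L
  rec_num <- 0L; rec_den <- 0L
  for (ch in unique(c(blocks$subject_chromosome, tb$chrom))) {
    pb <- blocks[blocks$subject_chromosome == ch, , drop = FALSE]
    tc <- tb[tb$chrom == ch, , drop = FALSE]
    tc <- tc[order(tc$bp_start), , drop = FALSE]
    anchor_tab <- if (nrow(pb) > 0L) {
      do.call(rbind, lapply(seq_len(nrow(pb)), function(i) {
        data.frame(bp = pb$anchors[[i]]$bp, block = i,
                   lg = pb$linkage_group[i], stringsAsFactors = FALSE)
      }))
    } else data.frame(bp = numeric(0), block = integer(0),
                      lg = character(0), stringsAsFactors = FALSE)
    anchors <- sort(unique(anchor_tab$bp))

    # true boundary positions: junctions between consecutive true blocks,
    # plus the two chromosome ends
    junctions <- if (nrow(tc) > 1) {
      (tc$bp_end[-nrow(tc)] + tc$bp_start[-1]) / 2
    } else numeric(0)
    ends <- if (nrow(tc) > 0) c(tc$bp_start[1], tc$bp_end[nrow(tc)])
            else numeric(0)
    true_all <- sort(c(junctions, ends))

    gap_of <- function(x) {
      # inter-anchor interval containing x (extended beyond terminal anchors)
      if (length(anchors) == 0L) return(c(-Inf, Inf))
      lo <- c(-Inf, anchors)[findInterval(x, anchors) + 1L]
      hi <- c(anchors, Inf)[findInterval(x, anchors) + 1L]
      c(lo, hi)
    }
    matches <- function(edge, tset) {
      if (length(tset) == 0L) return(FALSE)
      g <- gap_of(edge)
      any(tset >= g[1] & tset <= g[2])
    }
    is_claim <- function(edge, block_i, side) {
      other <- anchor_tab[anchor_tab$block != block_i, , drop = FALSE]
      outward <- if (side == "right") other[other$bp > edge, , drop = FALSE]
                 else other[other$bp < edge, , drop = FALSE]
      if (nrow(outward) == 0L) return(TRUE)  # chromosome-end claim
      nearest <- if (side == "right") which.min(outward$bp)
                 else which.max(outward$bp)
      outward$lg[nearest] != pb$linkage_group[block_i]
    }

    for (i in seq_len(nrow(pb))) {
      for (side in c("left", "right")) {
        edge <- if (side == "left") pb$bp_start[i] else pb$bp_end[i]
        if (!is_claim(edge, i, side)) next
        prec_den <- prec_den + 1L
        if (matches(edge, true_all)) prec_num <- prec_num + 1L
      }
    }

    if (nrow(tc) > 1) {
      # resolvability of each true block at the realised marker density
      ok <- vapply(seq_len(nrow(tc)), function(i) {
        mo <- marker_orth[marker_orth$chrom == ch &
                            marker_orth$ord >= tc$ord_start[i] &
                            marker_orth$ord <= tc$ord_end[i], , drop = FALSE]
        nrow(mo) >= min_loci &&
          (max(mo$ancestor_cM) - min(mo$ancestor_cM)) >= min_cM
      }, logical(1))
      edges <- c(pb$bp_start, pb$bp_end)
      for (j in seq_len(nrow(tc) - 1L)) {
        if (!(ok[j] && ok[j + 1L])) next
        if (tc$linkage_group[j] == tc$linkage_group[j + 1L]) next
        rec_den <- rec_den + 1L
        g <- gap_of(junctions[j])
        if (any(edges >= g[1] & edges <= g[2])) rec_num <- rec_num + 1L
      }
    }
  }
  list(precision = if (prec_den > 0) prec_num / prec_den else NA_real_,
       recall = if (rec_den > 0) rec_num / rec_den else NA_real_,
       n_true = rec_den, n_pred = prec_den,
       n_matched_true = rec_num, n_matched_pred = prec_num)
}
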