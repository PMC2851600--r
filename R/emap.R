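#' Qualifying two-hit loci for electronic mapping
#'
#' Applies the electronic-mapping hit criteria to best-two assignments: the
#' sequence must have two distinct subject segments (secondary present; the
#' >50 nt separation rule is enforced during segment merging in
#' [assign_best_two()]), both E-values strictly below `e_max` and both
#' alignment lengths at least `min_len`.
#'
#' @param assignments Output of [assign_best_two()].
#' @param e_max Exclusive E-value bound for *both* hits (default 1e-30).
#' @param min_len Inclusive minimum alignment length for both hits.
#' @return Data frame of qualifying sequences: sequence_id, chrom_a, mid_a,
#'   e_a, chrom_b, mid_b, e_b (a = primary locus, b = secondary).
#' @export
qualifying_two_hit_loci <- function(assignments, e_max = 1e-30,
                                    min_len = 150) {
  a <- assignments
  ok <- !is.na(a$secondary_chrom) &
    a$primary_evalue < e_max & a$secondary_evalue < e_max &
    a$primary_len >= min_len & a$secondary_len >= min_len
  a <- a[ok, , drop = FALSE]
  out <- data.frame(
    sequence_id = a$query_id,
    chrom_a = a$primary_chrom, mid_a = (a$primary_start + a$primary_end) / 2,
    e_a = a$primary_evalue,
    chrom_b = a$secondary_chrom,
    mid_b = (a$secondary_start + a$secondary_end) / 2,
    e_b = a$secondary_evalue,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Interpolate a genetic position inside a syntenic block
#'
#' Linear interpolation of cM between the two anchors flanking the physical
#' position. Positions beyond the terminal anchor (but inside the extended
#' interval) clamp to the terminal anchor's cM. Works on inverted blocks
#' unchanged: interpolation is between the bp-flanking anchors, so the result
#' always lies between those anchors' cM values.
#'
#' @param bp Physical position (bp) on the block's subject chromosome.
#' @param block A single-row slice of [detect_blocks()] output.
#' @return Genetic position in cM. Blocks with fewer than two anchors return
#'   the bin midpoint with attribute `low_confidence = TRUE`.
#' @export
interpolate_position <- function(bp, block) {
  anchors <- block$anchors[[1]]
  if (nrow(anchors) < 2L) {
    mid <- (block$cM_start + block$cM_end) / 2
    attr(mid, "low_confidence") <- TRUE
    return(mid)
  }
  o <- order(anchors$bp)
  xs <- anchors$bp[o]
  ys <- anchors$cM[o]
  if (bp <= xs[1]) return(ys[1])
  if (bp >= xs[length(xs)]) return(ys[length(ys)])
  approx(xs, ys, xout = bp, ties = mean)$y
}

# genetic bin of a block: the anchor cM interval padded by the block's median
# adjacent-anchor cM gap on each side. Terminal anchors censor the true block
# extent by about one marker spacing, so the bin acknowledges that resolution.
block_bin <- function(block) {
  anchors <- block$anchors[[1]]
  pad <- if (nrow(anchors) >= 2L) {
    median(diff(sort(anchors$cM)))
  } else 0
  c(block$cM_start - pad, block$cM_end + pad)
}

#' Electronically map unpositioned sequences into genetic bins
#'
#' A sequence qualifying under the two-hit criteria (see
#' [qualifying_two_hit_loci()]) is mapped when at least one of its two hits
#' falls inside a syntenic block's (possibly extended) subject interval. The
#' linkage group and bin come from that block; a point estimate is obtained by
#' [interpolate_position()]. When both hits land in blocks anchored to
#' different map positions (different linkage group, or disjoint bins), the
#' hit with the lower E-value wins and the locus is flagged as a conflict.
#' Sequences qualifying on hit criteria but outside all blocks are returned in
#' the `unplaceable` element, not dropped silently.
#'
#' @param assignments Output of [assign_best_two()] for the sequences to map.
#' @param blocks Output of [detect_blocks()], optionally after
#'   [extend_all_blocks()].
#' @param map Optional genetic map used to set the `previously_mapped` flag.
#' @param categories Optional data frame (sequence_id, category) with the
#'   sequence class: gene-based, BES, EST singleton, EST contig, CDS.
#' @param e_max,min_len Hit criteria (defaults: E below 1e-30, 150 nt).
#' @return List with `loci` (sequence_id, category, chrom_a, mid_a, e_a,
#'   chrom_b, mid_b, e_b, linkage_group, inferred_cM, bin_lo, bin_hi,
#'   block_id, placed_by, conflict, previously_mapped) and `unplaceable`
#'   (character vector of qualifying sequence ids outside all blocks).
#' @export
electronic_map <- function(assignments, blocks, map = NULL,
                           categories = NULL, e_max = 1e-30, min_len = 150) {
  q <- qualifying_two_hit_loci(assignments, e_max = e_max, min_len = min_len)
  loci <- list()
  unplaceable <- character(0)

  place_hit <- function(chrom, mid) {
    cand <- which(blocks$subject_chromosome == chrom &
                    blocks$extended_bp_start <= mid &
                    blocks$extended_bp_end >= mid)
    if (length(cand) == 0L) return(NULL)
    if (length(cand) > 1L) {
      span <- blocks$extended_bp_end[cand] - blocks$extended_bp_start[cand]
      cand <- cand[which.min(span)]
    }
    b <- blocks[cand, , drop = FALSE]
    bin <- block_bin(b)
    list(block = b, linkage_group = b$linkage_group,
         cM = as.numeric(interpolate_position(mid, b)),
         bin_lo = bin[1], bin_hi = bin[2], block_id = b$block_id)
  }

  for (i in seq_len(nrow(q))) {
    pa <- place_hit(q$chrom_a[i], q$mid_a[i])
    pb <- place_hit(q$chrom_b[i], q$mid_b[i])
    if (is.null(pa) && is.null(pb)) {
      unplaceable <- c(unplaceable, q$sequence_id[i])
      next
    }
    conflict <- FALSE
    if (!is.null(pa) && !is.null(pb)) {
      agree <- pa$linkage_group == pb$linkage_group &&
        pa$bin_lo <= pb$bin_hi && pb$bin_lo <= pa$bin_hi
      if (!agree) conflict <- TRUE
      chosen <- if (q$e_a[i] <= q$e_b[i]) pa else pb
      placed_by <- if (q$e_a[i] <= q$e_b[i]) "primary" else "secondary"
    } else if (!is.null(pa)) {
      chosen <- pa; placed_by <- "primary"
    } else {
      chosen <- pb; placed_by <- "secondary"
    }
    loci[[length(loci) + 1L]] <- data.frame(
      sequence_id = q$sequence_id[i],
      chrom_a = q$chrom_a[i], mid_a = q$mid_a[i], e_a = q$e_a[i],
      chrom_b = q$chrom_b[i], mid_b = q$mid_b[i], e_b = q$e_b[i],
      linkage_group = chosen$linkage_group,
      inferred_cM = chosen$cM,
      bin_lo = chosen$bin_lo, bin_hi = chosen$bin_hi,
      block_id = chosen$block_id, placed_by = placed_by,
      conflict = conflict, stringsAsFactors = FALSE)
  }
  out <- if (length(loci) > 0L) do.call(rbind, loci) else
    data.frame(sequence_id = character(0), chrom_a = character(0),
               mid_a = numeric(0), e_a = numeric(0), chrom_b = character(0),
               mid_b = numeric(0), e_b = numeric(0),
               linkage_group = character(0), inferred_cM = numeric(0),
               bin_lo = numeric(0), bin_hi = numeric(0),
               block_id = character(0), placed_by = character(0),
               conflict = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$previously_mapped <- if (!is.null(map)) {
    out$sequence_id %in% map$sequence_id
  } else rep(FALSE, nrow(out))
  out$category <- if (!is.null(categories)) {
    categories$category[match(out$sequence_id, categories$sequence_id)]
  } else rep(NA_character_, nrow(out))
  list(loci = out, unplaceable = unplaceable)
}

#' Extend a duplicate block pair by colinearity
#'
#' Walks outward from each boundary of a syntenic block over electronically
#' mappable loci shared by the block's and its partner's subject regions, and
#' extends both extended intervals while consecutive shared loci keep the same
#' relative order in the two regions. The walk stops at the first run of
#' `break_tolerance` loci violating that order, or immediately when a locus on
#' the home chromosome pairs to a different partner chromosome. Original
#' anchors and bp bounds are untouched; only `extended_bp_start`/`_end` move,
#' and always outward (the extended interval contains the original).
#' Re-running with the same loci is a no-op.
#'
#' @param block,partner_block Single-row slices of [detect_blocks()] output,
#'   anchored to the same linkage-group interval (see
#'   [pair_duplicate_blocks()]).
#' @param loci Two-hit loci from [qualifying_two_hit_loci()].
#' @param break_tolerance Number of consecutive order-violating loci that
#'   breaks colinearity (default 1: a single out-of-order locus stops the
#'   walk).
#' @return List with updated `block` and `partner` rows.
#' @export
extend_block <- function(block, partner_block, loci, break_tolerance = 1) {
  home_ch <- block$subject_chromosome
  part_ch <- partner_block$subject_chromosome
  if (is.null(loci) || nrow(loci) == 0L) {
    return(list(block = block, partner = partner_block))
  }

  # loci with one hit on the home chromosome, oriented home-first
  on_home_a <- loci$chrom_a == home_ch
  on_home_b <- loci$chrom_b == home_ch
  sel <- on_home_a | on_home_b
  lh <- data.frame(
    pos_home = ifelse(on_home_a[sel], loci$mid_a[sel], loci$mid_b[sel]),
    partner_chrom = ifelse(on_home_a[sel], loci$chrom_b[sel],
                           loci$chrom_a[sel]),
    pos_part = ifelse(on_home_a[sel], loci$mid_b[sel], loci$mid_a[sel]),
    stringsAsFactors = FALSE)
  # drop self-pairs (both hits on the home chromosome yield two views)
  if (nrow(lh) == 0L) return(list(block = block, partner = partner_block))

  shared_in <- lh$partner_chrom == part_ch &
    lh$pos_home >= block$bp_start & lh$pos_home <= block$bp_end &
    lh$pos_part >= partner_block$bp_start &
    lh$pos_part <= partner_block$bp_end
  s <- NA_real_
  if (sum(shared_in) >= 2L) {
    s <- suppressWarnings(sign(cor(lh$pos_home[shared_in],
                                   lh$pos_part[shared_in],
                                   method = "spearman")))
  }
  if (is.na(s) || s == 0) {
    s <- if (block$orientation == partner_block$orientation) 1 else -1
  }

  # walks always start at the original anchor bounds; the walked-out interval
  # is then unioned into the current extended interval. Starting from the
  # anchors (not the current extension) makes the whole-set extension a fixed
  # point even when a block belongs to two duplicate pairs.
  h1 <- block$bp_start; h2 <- block$bp_end
  p1 <- partner_block$bp_start; p2 <- partner_block$bp_end

  walk <- function(side) {
    cand <- if (side == "right") {
      lh[lh$pos_home > h2, , drop = FALSE]
    } else {
      lh[lh$pos_home < h1, , drop = FALSE]
    }
    cand <- cand[order(cand$pos_home,
                       decreasing = (side == "left")), , drop = FALSE]
    last_part <- if (side == "right") {
      if (s > 0) p2 else p1
    } else {
      if (s > 0) p1 else p2
    }
    streak <- 0L
    for (i in seq_len(nrow(cand))) {
      if (cand$partner_chrom[i] != part_ch) break
      outward <- if (side == "right") {
        if (s > 0) cand$pos_part[i] > last_part else cand$pos_part[i] < last_part
      } else {
        if (s > 0) cand$pos_part[i] < last_part else cand$pos_part[i] > last_part
      }
      if (outward) {
        if (side == "right") {
          h2 <<- max(h2, cand$pos_home[i])
          if (s > 0) p2 <<- max(p2, cand$pos_part[i])
          else p1 <<- min(p1, cand$pos_part[i])
        } else {
          h1 <<- min(h1, cand$pos_home[i])
          if (s > 0) p1 <<- min(p1, cand$pos_part[i])
          else p2 <<- max(p2, cand$pos_part[i])
        }
        last_part <- cand$pos_part[i]
        streak <- 0L
      } else {
        streak <- streak + 1L
        if (streak >= break_tolerance) break
      }
    }
  }
  walk("right")
  walk("left")

  block$extended_bp_start <- min(block$extended_bp_start, h1)
  block$extended_bp_end <- max(block$extended_bp_end, h2)
  partner_block$extended_bp_start <- min(partner_block$extended_bp_start, p1)
  partner_block$extended_bp_end <- max(partner_block$extended_bp_end, p2)
  list(block = block, partner = partner_block)
}

#' Extend all duplicate block pairs
#'
#' Applies [extend_block()] to every duplicate pair found by
#' [pair_duplicate_blocks()], updating the extended intervals in place.
#' Blocks without a partner are unchanged.
#'
#' @param blocks Output of [detect_blocks()].
#' @param loci Two-hit loci from [qualifying_two_hit_loci()].
#' @param min_overlap Pairing threshold (fraction of the shorter cM interval).
#' @param break_tolerance Passed to [extend_block()].
#' @return `blocks` with updated `extended_bp_start`/`extended_bp_end`.
#' @export
extend_all_blocks <- function(blocks, loci, min_overlap = 0.5,
                              break_tolerance = 1) {
  pairs <- pair_duplicate_blocks(blocks, min_overlap)
  for (k in seq_len(nrow(pairs))) {
    ia <- match(pairs$block_a[k], blocks$block_id)
    ib <- match(pairs$block_b[k], blocks$block_id)
    res <- extend_block(blocks[ia, , drop = FALSE],
                        blocks[ib, , drop = FALSE],
                        loci, break_tolerance)
    blocks$extended_bp_start[ia] <- res$block$extended_bp_start
    blocks$extended_bp_end[ia] <- res$block$extended_bp_end
    blocks$extended_bp_start[ib] <- res$partner$extended_bp_start
    blocks$extended_bp_end[ib] <- res$partner$extended_bp_end
  }
  blocks
}

#' Validate electronic predictions against held-out map positions
#'
#' Compares each held-out marker's true genetic position (from the full map)
#' to its electronic bin and to its rank order among the tested markers.
#' A marker is *within interval* when its predicted linkage group is correct
#' and its true cM falls inside the predicted bin; *exactly ordered* when its
#' rank by inferred cM equals its rank by true cM within its linkage group;
#' *locally inverted* when it is part of an adjacent transposition (swapping
#' it with its true-order neighbour would make both exact).
#'
#' @param map The full genetic map including the held-out markers.
#' @param predictions The `loci` element of [electronic_map()] output for the
#'   held-out sequences.
#' @param region Optional list(linkage_group =, cM_range = c(lo, hi))
#'   restricting the comparison to one map region.
#' @return List: n_tested, n_within_interval, n_exact_order,
#'   n_locally_inverted, and a `details` data frame.
#' @export
validate_holdout <- function(map, predictions, region = NULL) {
  if (nrow(predictions) == 0L) {
    return(list(n_tested = 0L, n_within_interval = 0L, n_exact_order = 0L,
                n_locally_inverted = 0L,
                details = data.frame()))
  }
  idx <- match(predictions$sequence_id, map$sequence_id)
  d <- predictions[!is.na(idx), , drop = FALSE]
  m <- map[idx[!is.na(idx)], , drop = FALSE]
  d$true_lg <- m$linkage_group
  d$true_cM <- m$cM
  if (!is.null(region)) {
    keep <- d$true_lg == region$linkage_group &
      d$true_cM >= region$cM_range[1] & d$true_cM <= region$cM_range[2]
    d <- d[keep, , drop = FALSE]
  }
  d$within <- d$linkage_group == d$true_lg &
    d$true_cM >= d$bin_lo & d$true_cM <= d$bin_hi
  d$exact <- FALSE
  d$locally_inverted <- FALSE
  for (lg in unique(d$true_lg)) {
    rows <- which(d$true_lg == lg & d$linkage_group == lg)
    if (length(rows) == 0L) next
    r_true <- rank(d$true_cM[rows], ties.method = "first")
    r_pred <- rank(d$inferred_cM[rows], ties.method = "first")
    exact <- r_pred == r_true
    d$exact[rows] <- exact
    # adjacent transpositions: i and j swap ranks and are true-order neighbours
    for (i in seq_along(rows)) {
      if (exact[i]) next
      j <- which(r_true == r_pred[i])
      if (length(j) == 1L && !exact[j] &&
          r_pred[j] == r_true[i] && abs(r_true[i] - r_true[j]) == 1L) {
        d$locally_inverted[rows[i]] <- TRUE
      }
    }
  }
  rownames(d) <- NULL
  list(n_tested = nrow(d),
       n_within_interval = sum(d$within),
       n_exact_order = sum(d$exact),
       n_locally_inverted = sum(d$locally_inverted),
       details = d)
}

#' Hold-out validation experiment on a simulation
#'
#' Removes a set of markers from the simulated genetic map, recomputes blocks
#' from the reduced map, electronically maps the held-out sequences via the
#' duplicate reference blocks, and scores the predictions against the
#' markers' true positions — the in-silico analogue of remapping newly
#' designed markers inside a predicted interval.
#'
#' @param sim Output of [simulate_synteny()].
#' @param n_holdout Number of markers to hold out (sampled with the current
#'   RNG state) when `holdout_ids` is not given.
#' @param holdout_ids Optional explicit sequence ids to hold out.
#' @param e_max,min_len Hit filter for block detection (ortholog screen).
#' @param ... Passed to [detect_blocks()].
#' @return List: report (from [validate_holdout()]), holdout_ids, blocks,
#'   emap (the [electronic_map()] result).
#' @export
holdout_experiment <- function(sim, n_holdout = 20, holdout_ids = NULL,
                               e_max = 1e-10, min_len = 150, ...) {
  map <- sim$map
  if (is.null(holdout_ids)) {
    holdout_ids <- sample(map$sequence_id, min(n_holdout, nrow(map)))
  }
  map2 <- map[!(map$sequence_id %in% holdout_ids), , drop = FALSE]
  filtered <- filter_hits(sim$hits, e_max = e_max, min_len = min_len)
  assignments <- assign_best_two(filtered)
  amapped <- assignments[assignments$query_id %in% map2$sequence_id, ,
                         drop = FALSE]
  blocks <- detect_blocks(amapped, map2, ...)
  aheld <- assignments[assignments$query_id %in% holdout_ids, , drop = FALSE]
  em <- electronic_map(aheld, blocks, map = map2)
  report <- validate_holdout(map, em$loci)
  list(report = report, holdout_ids = holdout_ids, blocks = blocks,
       emap = em)
}
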