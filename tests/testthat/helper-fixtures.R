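# Shared fixture builders. Everything is generated in code; no data files.

# Small, fast simulator configuration for unit tests.
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_chromosomes = 2, genes_per_chromosome = 60,
                   mean_gene_spacing = 5000, map_length_per_chromosome = 100,
                   pericentromere_fraction = 0.4,
                   pericentromere_recombination_factor = 0.2,
                   fractionation_rate = 0.1, n_rearrangements = 2,
                   mean_segment_genes = 12, inversion_probability = 0.5,
                   divergence = 0.1, marker_fraction = 0.3, seed = 101L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# Simulate, filter, assign, detect — the standard pipeline prefix.
run_pipeline <- function(cfg, queries = "markers", ...) {
  sim <- simulate_synteny(cfg, queries = queries)
  filtered <- filter_hits(sim$hits)
  assignments <- assign_best_two(filtered)
  mapped <- assignments[assignments$query_id %in% sim$map$sequence_id, ,
                        drop = FALSE]
  blocks <- detect_blocks(mapped, sim$map, ...)
  list(sim = sim, filtered = filtered, assignments = assignments,
       mapped = mapped, blocks = blocks)
}

# One hand-built hit row in the internal (0-based half-open) convention.
make_hit <- function(query_id, chrom, start, end, e_value = 1e-50,
                     bit_score = 100, align_length = end - start,
                     strand = "+", percent_identity = 95) {
  data.frame(query_id = query_id, subject_chromosome = chrom,
             percent_identity = percent_identity,
             align_length = as.integer(align_length),
             mismatches = 0L, gap_opens = 0L, q_start = 1L,
             q_end = as.integer(align_length),
             subject_start = start, subject_end = end, strand = strand,
             e_value = e_value, bit_score = bit_score,
             stringsAsFactors = FALSE)
}

make_hits <- function(...) do.call(rbind, list(...))

# One hand-built synteny block row (same shape as detect_blocks output).
# anchors: data.frame with cM and bp (marker/start/end/strand optional).
make_block <- function(id, lg, chrom, anchors, width = 100,
                       extended = NULL) {
  if (is.null(anchors$marker)) {
    anchors$marker <- sprintf("%s_a%d", id, seq_len(nrow(anchors)))
  }
  if (is.null(anchors$start)) anchors$start <- anchors$bp - width / 2
  if (is.null(anchors$end)) anchors$end <- anchors$bp + width / 2
  if (is.null(anchors$strand)) anchors$strand <- "+"
  anchors <- anchors[, c("marker", "cM", "bp", "start", "end", "strand")]
  out <- data.frame(
    block_id = id, linkage_group = lg,
    cM_start = min(anchors$cM), cM_end = max(anchors$cM),
    subject_chromosome = chrom,
    bp_start = min(anchors$start), bp_end = max(anchors$end),
    orientation = if (nrow(anchors) >= 2) classify_orientation(anchors)
                  else "direct",
    n_anchors = nrow(anchors), stringsAsFactors = FALSE)
  out$extended_bp_start <- if (is.null(extended)) out$bp_start else extended[1]
  out$extended_bp_end <- if (is.null(extended)) out$bp_end else extended[2]
  out$anchors <- list(anchors)
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

bind_blocks <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

# Independent brute-force re-implementation of the filter rule: a literal
# row-by-row scan.
oracle_filter <- function(hits, e_max, min_len) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    keep[i] <- hits$e_value[i] < e_max && hits$align_length[i] >= min_len
  }
  hits[keep, , drop = FALSE]
}

# Independent brute-force chaining oracle: builds the anchor list and chains
# it with explicit loops, returning per-block summaries for comparison with
# detect_blocks. Written separately from the implementation on purpose.
oracle_blocks <- function(assignments, map, max_gap_cM = 15, max_gap_bp = 5e6,
                          min_loci = 3, min_cM = 4) {
  anchors <- NULL
  for (i in seq_len(nrow(assignments))) {
    mrow <- which(map$sequence_id == assignments$query_id[i])
    if (length(mrow) == 0) next
    for (side in c("primary", "secondary")) {
      ch <- assignments[[paste0(side, "_chrom")]][i]
      if (is.na(ch)) next
      s <- assignments[[paste0(side, "_start")]][i]
      e <- assignments[[paste0(side, "_end")]][i]
      anchors <- rbind(anchors, data.frame(
        lg = map$linkage_group[mrow], cM = map$cM[mrow], chrom = ch,
        start = s, end = e, bp = (s + e) / 2, stringsAsFactors = FALSE))
    }
  }
  res <- NULL
  for (lg in unique(anchors$lg)) {
    for (ch in unique(anchors$chrom[anchors$lg == lg])) {
      g <- anchors[anchors$lg == lg & anchors$chrom == ch, , drop = FALSE]
      g <- g[order(g$cM, g$bp), , drop = FALSE]
      chain <- list(g[1, , drop = FALSE])
      flush_chain <- function(chain_df) {
        if (nrow(chain_df) >= min_loci &&
            max(chain_df$cM) - min(chain_df$cM) >= min_cM) {
          data.frame(lg = lg, chrom = ch,
                     cM_start = min(chain_df$cM), cM_end = max(chain_df$cM),
                     bp_start = min(chain_df$start),
                     bp_end = max(chain_df$end),
                     n = nrow(chain_df), stringsAsFactors = FALSE)
        } else NULL
      }
      cur <- g[1, , drop = FALSE]
      for (i in seq_len(nrow(g))[-1]) {
        prev <- g[i - 1, ]
        joins <- (g$cM[i] - prev$cM) <= max_gap_cM &&
          abs(g$bp[i] - prev$bp) <= max_gap_bp
        if (joins) {
          cur <- rbind(cur, g[i, , drop = FALSE])
        } else {
          res <- rbind(res, flush_chain(cur))
          cur <- g[i, , drop = FALSE]
        }
      }
      res <- rbind(res, flush_chain(cur))
    }
  }
  if (is.null(res)) return(res)
  res[order(res$lg, res$cM_start, res$chrom, res$bp_start), , drop = FALSE]
}
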