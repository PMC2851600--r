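#' Map a physical position to a genetic position
#'
#' Integrates a piecewise-constant recombination density: a base density
#' outside the pericentromere and `factor` times that density inside, scaled
#' so the whole chromosome integrates to `map_cM`.
#'
#' @param x Physical positions, bp (0-based).
#' @param chrom_len Chromosome length, bp.
#' @param peri Numeric length-2 vector, pericentromere `[start, end)` in bp.
#' @param factor Recombination multiplier inside the pericentromere, `(0, 1]`.
#' @param map_cM Total genetic length of the chromosome.
#' @return Genetic positions in cM, same length as `x`.
#' @keywords internal
physical_to_cM <- function(x, chrom_len, peri, factor, map_cM) {
  peri_len <- max(0, peri[2] - peri[1])
  d_out <- map_cM / ((chrom_len - peri_len) + factor * peri_len)
  inside_before <- pmin(pmax(x - peri[1], 0), peri_len)
  outside_before <- x - inside_before
  d_out * (outside_before + factor * inside_before)
}

#' Simulate the ancestral (diploid) genome and its genetic map
#'
#' Lays genes along each chromosome with exponentially distributed intergenic
#' gaps, places a central pericentromeric interval, assigns genetic positions
#' by integrating a recombination density suppressed inside the pericentromere,
#' and samples a fraction of genes as genetically mapped markers.
#'
#' @param config A [sim_config()].
#' @return A list of class `ancestral_genome` with elements `genes`
#'   (gene_id, chrom, idx, start, end, length, gap_after, cM, is_marker;
#'   coordinates 0-based half-open), `chromosomes` (chrom, length_bp,
#'   map_length_cM), `pericentromeres` (chrom, start, end), `map` (marker,
#'   linkage_group, cM, sequence_id) and `config`.
#' @examples
#' anc <- simulate_ancestral_genome(sim_config(n_chromosomes = 1,
#'   genes_per_chromosome = 20, seed = 3))
#' head(anc$genes)
#' @export
simulate_ancestral_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  gene_list <- vector("list", config$n_chromosomes)
  chrom_rows <- vector("list", config$n_chromosomes)
  peri_rows <- vector("list", config$n_chromosomes)
  for (i in seq_len(config$n_chromosomes)) {
    n <- config$genes_per_chromosome
    chrom <- sprintf("Pv%d", i)
    lens <- pmax(200, round(rnorm(n, config$mean_gene_length,
                                  config$mean_gene_length / 5)))
    gaps <- round(rexp(n, 1 / config$mean_gene_spacing))
    gap0 <- round(rexp(1, 1 / config$mean_gene_spacing))
    starts <- gap0 + cumsum(c(0, (lens + gaps)[-n]))
    ends <- starts + lens
    last_end <- ends[n]
    if (!is.null(config$chromosome_length_bp)) {
      if (last_end > config$chromosome_length_bp) {
        stop(sprintf(
          "simulated genes on %s extend to %d bp, beyond chromosome_length_bp = %d",
          chrom, last_end, as.integer(config$chromosome_length_bp)),
          call. = FALSE)
      }
      L <- config$chromosome_length_bp
    } else {
      L <- last_end + round(config$mean_gene_spacing)
    }
    f <- config$pericentromere_fraction
    peri <- c(round(L * (0.5 - f / 2)), round(L * (0.5 + f / 2)))
    mids <- (starts + ends) / 2
    cM <- physical_to_cM(mids, L, peri,
                         config$pericentromere_recombination_factor,
                         config$map_length_per_chromosome)
    is_marker <- runif(n) < config$marker_fraction
    gene_list[[i]] <- data.frame(
      gene_id = sprintf("pv%02d_g%04d", i, seq_len(n)),
      chrom = chrom, idx = seq_len(n),
      start = starts, end = ends, length = lens, gap_after = gaps,
      cM = cM, is_marker = is_marker,
      stringsAsFactors = FALSE)
    chrom_rows[[i]] <- data.frame(
      chrom = chrom, length_bp = L,
      map_length_cM = config$map_length_per_chromosome,
      stringsAsFactors = FALSE)
    peri_rows[[i]] <- data.frame(
      chrom = chrom, start = peri[1], end = peri[2], stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_list)
  markers <- genes[genes$is_marker, , drop = FALSE]
  map <- data.frame(
    marker = paste0("m_", markers$gene_id),
    linkage_group = markers$chrom,
    cM = markers$cM,
    sequence_id = markers$gene_id,
    stringsAsFactors = FALSE)
  rownames(map) <- NULL
  structure(list(
    genes = genes,
    chromosomes = do.call(rbind, chrom_rows),
    pericentromeres = do.call(rbind, peri_rows),
    map = map,
    config = config
  ), class = "ancestral_genome")
}

#' Apply a whole-genome duplication, fractionation and rearrangement
#'
#' Doubles the ancestral genome into two full chromosome copies
#' (ancestor chromosome `Pv<i>` becomes `Gm<2i-1>` and `Gm<2i>`), deletes each
#' duplicated gene copy independently with probability `fractionation_rate`,
#' then applies `n_rearrangements` segmental moves (contiguous gene runs of
#' geometric length, optionally inverted, reinserted anywhere in the derived
#' genome). Physical coordinates are re-laid after editing, preserving each
#' gene's length and downstream gap.
#'
#' The returned truth contains the full event log, the surviving
#' ancestor-to-derived ortholog pairs, and true syntenic block boundaries:
#' maximal runs of derived genes sharing ancestor chromosome, WGD copy and
#' strand with strictly monotone ancestor order. These runs tile each derived
#' chromosome's gene space without overlap.
#'
#' @param ancestral Output of [simulate_ancestral_genome()].
#' @param config The same [sim_config()].
#' @return A list of class `derived_genome` with elements `genes` (derived_id,
#'   chrom, ord, start, end, strand, length, gap_after, ancestor_gene, copy,
#'   ancestor_idx, ancestor_chrom), `chromosomes`, `pericentromeres`, and
#'   `truth` (list: `event_log`, `ortholog_pairs`, `blocks`).
#' @export
apply_wgd_and_rearrange <- function(ancestral, config) {
  stopifnot(inherits(ancestral, "ancestral_genome"))
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  anc <- ancestral$genes
  n_anc_chrom <- config$n_chromosomes

  two <- rbind(
    cbind(anc, copy = 1L, stringsAsFactors = FALSE),
    cbind(anc, copy = 2L, stringsAsFactors = FALSE))
  anc_chrom_idx <- match(two$chrom, sprintf("Pv%d", seq_len(n_anc_chrom)))
  two$dchrom <- sprintf("Gm%d", 2L * (anc_chrom_idx - 1L) + two$copy)
  two$derived_id <- sprintf("%s_c%d", two$gene_id, two$copy)
  two$strand <- "+"

  events <- list()
  ev <- function(kind, chrom_from, chrom_to, genes, detail) {
    data.frame(step = length(events) + 1L, kind = kind,
               chrom_from = chrom_from, chrom_to = chrom_to,
               n_genes = length(genes),
               gene_ids = paste(genes, collapse = ","),
               detail = detail, stringsAsFactors = FALSE)
  }
  events[[1]] <- ev("wgd", "*", "*", character(0),
                    sprintf("duplicated %d genes into 2 copies", nrow(anc)))

  deleted <- runif(nrow(two)) < config$fractionation_rate
  if (any(deleted)) {
    events[[length(events) + 1L]] <- ev(
      "deletion", "*", "*", two$derived_id[deleted],
      sprintf("fractionation removed %d gene copies", sum(deleted)))
  }
  surv <- two[!deleted, , drop = FALSE]

  dchroms <- sprintf("Gm%d", seq_len(2L * n_anc_chrom))
  ord <- lapply(dchroms, function(ch) which(surv$dchrom == ch))
  names(ord) <- dchroms
  # ancestor order within each chromosome copy is already idx order
  ord <- lapply(ord, function(rows) rows[order(surv$idx[rows])])

  for (k in seq_len(config$n_rearrangements)) {
    sizes <- vapply(ord, length, integer(1))
    src_ok <- which(sizes >= 2L)
    if (length(src_ok) == 0L) break
    src <- src_ok[sample.int(length(src_ok), 1L)]
    seg_len <- min(1L + rgeom(1L, 1 / config$mean_segment_genes), sizes[src])
    at <- sample.int(sizes[src] - seg_len + 1L, 1L)
    seg <- ord[[src]][at:(at + seg_len - 1L)]
    ord[[src]] <- ord[[src]][-(at:(at + seg_len - 1L))]
    tgt <- sample.int(length(ord), 1L)
    inverted <- runif(1L) < config$inversion_probability
    if (inverted) {
      seg <- rev(seg)
      surv$strand[seg] <- ifelse(surv$strand[seg] == "+", "-", "+")
    }
    ins <- sample.int(length(ord[[tgt]]) + 1L, 1L) - 1L
    ord[[tgt]] <- append(ord[[tgt]], seg, after = ins)
    kind <- if (tgt == src) "move" else "fusion"
    events[[length(events) + 1L]] <- ev(
      kind, dchroms[src], dchroms[tgt], surv$derived_id[seg],
      sprintf("segment of %d genes excised at index %d, inserted after index %d",
              seg_len, at, ins))
    if (inverted) {
      events[[length(events) + 1L]] <- ev(
        "inversion", dchroms[tgt], dchroms[tgt], surv$derived_id[seg],
        "moved segment inverted")
    }
  }

  # re-layout physical coordinates per derived chromosome
  out_list <- vector("list", length(dchroms))
  chrom_rows <- vector("list", length(dchroms))
  peri_rows <- vector("list", length(dchroms))
  margin <- round(config$mean_gene_spacing)
  f <- config$pericentromere_fraction
  for (j in seq_along(dchroms)) {
    rows <- ord[[j]]
    if (length(rows) > 0L) {
      g <- surv[rows, , drop = FALSE]
      starts <- margin + cumsum(c(0, (g$length + g$gap_after)[-length(rows)]))
      g$start <- starts
      g$end <- starts + g$length
      g$ord <- seq_along(rows)
      g$chrom <- dchroms[j]
      L <- g$end[length(rows)] + margin
      out_list[[j]] <- g
    } else {
      L <- 2 * margin
    }
    chrom_rows[[j]] <- data.frame(chrom = dchroms[j], length_bp = L,
                                  stringsAsFactors = FALSE)
    peri_rows[[j]] <- data.frame(
      chrom = dchroms[j],
      start = round(L * (0.5 - f / 2)), end = round(L * (0.5 + f / 2)),
      stringsAsFactors = FALSE)
  }
  keep <- !vapply(out_list, is.null, logical(1))
  if (!any(keep)) {
    dg <- data.frame(derived_id = character(0), chrom = character(0),
                     ord = integer(0), start = numeric(0), end = numeric(0),
                     strand = character(0), length = numeric(0),
                     gap_after = numeric(0), ancestor_gene = character(0),
                     copy = integer(0), ancestor_idx = integer(0),
                     ancestor_chrom = character(0), ancestor_cM = numeric(0),
                     stringsAsFactors = FALSE)
    return(structure(list(
      genes = dg,
      chromosomes = do.call(rbind, chrom_rows),
      pericentromeres = do.call(rbind, peri_rows),
      truth = list(event_log = do.call(rbind, events),
                   ortholog_pairs = dg[, c("ancestor_gene", "chrom", "start",
                                           "end", "strand", "copy")],
                   blocks = NULL)
    ), class = "derived_genome"))
  }
  dg <- do.call(rbind, out_list[keep])
  dg <- data.frame(
    derived_id = dg$derived_id, chrom = dg$chrom, ord = dg$ord,
    start = dg$start, end = dg$end, strand = dg$strand,
    length = dg$length, gap_after = dg$gap_after,
    ancestor_gene = dg$gene_id, copy = dg$copy,
    ancestor_idx = dg$idx,
    stringsAsFactors = FALSE)
  dg$ancestor_chrom <- anc$chrom[match(dg$ancestor_gene, anc$gene_id)]
  dg$ancestor_cM <- anc$cM[match(dg$ancestor_gene, anc$gene_id)]
  dg <- dg[order(match(dg$chrom, dchroms), dg$ord), , drop = FALSE]
  rownames(dg) <- NULL

  truth_blocks <- derive_true_blocks(dg)
  ortho <- data.frame(
    ancestor_gene = dg$ancestor_gene, derived_gene = dg$derived_id,
    chrom = dg$chrom, start = dg$start, end = dg$end, strand = dg$strand,
    copy = dg$copy, stringsAsFactors = FALSE)

  structure(list(
    genes = dg,
    chromosomes = do.call(rbind, chrom_rows),
    pericentromeres = do.call(rbind, peri_rows),
    truth = list(
      event_log = do.call(rbind, events),
      ortholog_pairs = ortho,
      blocks = truth_blocks)
  ), class = "derived_genome")
}

# Maximal colinear runs in the final derived gene order: same ancestor
# chromosome, same WGD copy, constant strand, strictly monotone ancestor index
# (increasing on "+", decreasing on "-"). Fractionation gaps and excision
# scars do not break a run; inserted foreign segments and inversions do.
derive_true_blocks <- function(dg) {
  res <- list()
  for (ch in unique(dg$chrom)) {
    g <- dg[dg$chrom == ch, , drop = FALSE]
    g <- g[order(g$ord), , drop = FALSE]
    n <- nrow(g)
    if (n == 0L) next
    new_run <- c(TRUE, vapply(seq_len(n - 1L), function(i) {
      a <- i; b <- i + 1L
      if (g$ancestor_chrom[a] != g$ancestor_chrom[b]) return(TRUE)
      if (g$copy[a] != g$copy[b]) return(TRUE)
      if (g$strand[a] != g$strand[b]) return(TRUE)
      if (g$strand[a] == "+" && g$ancestor_idx[b] <= g$ancestor_idx[a])
        return(TRUE)
      if (g$strand[a] == "-" && g$ancestor_idx[b] >= g$ancestor_idx[a])
        return(TRUE)
      FALSE
    }, logical(1)))
    run_id <- cumsum(new_run)
    for (r in unique(run_id)) {
      b <- g[run_id == r, , drop = FALSE]
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch,
        bp_start = min(b$start), bp_end = max(b$end),
        ord_start = min(b$ord), ord_end = max(b$ord),
        linkage_group = b$ancestor_chrom[1],
        cM_start = min(b$ancestor_cM), cM_end = max(b$ancestor_cM),
        copy = b$copy[1],
        orientation = if (b$strand[1] == "+") "direct" else "inverted",
        n_genes = nrow(b),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Emit a simulated BLAST tabular hit set
#'
#' Each query sequence produces one hit per surviving derived ortholog copy.
#' Alignment lengths are a random fraction of the gene length; bit scores are
#' linear in alignment length times `(1 - divergence)`; E-values follow
#' `E = N * 2^-bits` (N = derived genome size) with lognormal noise, stored at
#' the 3-significant-digit precision the tabular writer emits so that writing
#' and re-parsing round-trips exactly. Decoy hits (mean `spurious_rate` per
#' query, Poisson) land at random positions with E-values above 1e-10.
#'
#' @param ancestral Output of [simulate_ancestral_genome()].
#' @param derived Output of [apply_wgd_and_rearrange()].
#' @param config The same [sim_config()].
#' @param queries Character vector of ancestor gene ids to emit hits for;
#'   default all genes. Use `ancestral$map$sequence_id` for markers only.
#' @return A hit table in the internal convention of [parse_hits()]:
#'   columns query_id, subject_chromosome, percent_identity, align_length,
#'   mismatches, gap_opens, q_start, q_end, subject_start, subject_end
#'   (0-based half-open, forward-ordered), strand, e_value, bit_score.
#' @export
emit_hits <- function(ancestral, derived, config, queries = NULL) {
  stopifnot(inherits(ancestral, "ancestral_genome"),
            inherits(derived, "derived_genome"))
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  if (is.null(queries)) queries <- ancestral$genes$gene_id
  total_bp <- sum(derived$chromosomes$length_bp)

  d <- derived$genes[derived$genes$ancestor_gene %in% queries, , drop = FALSE]
  n <- nrow(d)
  if (n > 0L) {
    # alignment extent and offset are properties of the query: the same
    # sequence aligns over the same stretch of both near-identical copies
    ug <- sort(unique(d$ancestor_gene))
    frac <- runif(length(ug), 0.5, 0.95)
    offfrac <- runif(length(ug))
    gi <- match(d$ancestor_gene, ug)
    aln <- pmax(50L, as.integer(round(d$length * frac[gi])))
    aln <- pmin(aln, d$length)
    pid <- pmin(100, pmax(60, 100 * (1 - config$divergence) + rnorm(n, 0, 1)))
    bits <- aln * (1 - config$divergence)
    log10e <- log10(total_bp) - bits * log10(2) +
      rnorm(n, 0, config$evalue_log_sd)
    off <- floor(offfrac[gi] * (d$length - aln + 1))
    s0 <- d$start + off
    true_hits <- data.frame(
      query_id = d$ancestor_gene,
      subject_chromosome = d$chrom,
      percent_identity = as.numeric(sprintf("%.2f", pid)),
      align_length = aln,
      mismatches = as.integer(round(aln * (1 - pid / 100))),
      gap_opens = rpois(n, 1),
      q_start = 1L, q_end = aln,
      subject_start = s0, subject_end = s0 + aln,
      strand = d$strand,
      e_value = as.numeric(sprintf("%.3g", 10^pmax(log10e, -300))),
      bit_score = as.numeric(sprintf("%.1f", bits)),
      stringsAsFactors = FALSE)
  } else {
    true_hits <- NULL
  }

  sp_counts <- rpois(length(queries), config$spurious_rate)
  m <- sum(sp_counts)
  if (m > 0L) {
    chroms <- derived$chromosomes
    pick <- sample.int(nrow(chroms), m, replace = TRUE)
    alns <- sample(50:300, m, replace = TRUE)
    maxs <- pmax(1, chroms$length_bp[pick] - alns)
    s0 <- floor(runif(m, 0, maxs))
    log10e <- runif(m, -9, -1)
    pid <- runif(m, 70, 85)
    sp <- data.frame(
      query_id = rep(queries, sp_counts),
      subject_chromosome = chroms$chrom[pick],
      percent_identity = as.numeric(sprintf("%.2f", pid)),
      align_length = alns,
      mismatches = as.integer(round(alns * (1 - pid / 100))),
      gap_opens = rpois(m, 1),
      q_start = 1L, q_end = alns,
      subject_start = s0, subject_end = s0 + alns,
      strand = sample(c("+", "-"), m, replace = TRUE),
      e_value = as.numeric(sprintf("%.3g", 10^log10e)),
      bit_score = as.numeric(sprintf("%.1f",
                                     (log10(total_bp) - log10e) / log10(2))),
      stringsAsFactors = FALSE)
  } else {
    sp <- NULL
  }
  hits <- rbind(true_hits, sp)
  if (is.null(hits)) return(empty_hits())
  hits <- hits[order(hits$query_id, hits$e_value, hits$subject_chromosome,
                     hits$subject_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Run the full simulator
#'
#' Convenience wrapper: ancestral genome, derived genome and hit table from a
#' single configuration.
#'
#' @param config A [sim_config()].
#' @param queries Which ancestor genes to emit hits for: `"all"` (default) or
#'   `"markers"` (only genetically mapped genes), or a character vector of
#'   gene ids.
#' @return List with `config`, `ancestral`, `derived`, `map`, `hits` and
#'   `truth` (shortcut to `derived$truth`).
#' @examples
#' sim <- simulate_synteny(sim_config(n_chromosomes = 2,
#'   genes_per_chromosome = 40, seed = 11), queries = "markers")
#' nrow(sim$hits)
#' @export
simulate_synteny <- function(config, queries = "all") {
  anc <- simulate_ancestral_genome(config)
  der <- apply_wgd_and_rearrange(anc, config)
  q <- if (identical(queries, "all")) NULL
       else if (identical(queries, "markers")) anc$map$sequence_id
       else queries
  hits <- emit_hits(anc, der, config, queries = q)
  list(config = config, ancestral = anc, derived = der,
       map = anc$map, hits = hits, truth = der$truth)
}
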