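# Hand-built assignments + map for threshold tests: three markers on Pv1
# whose orthologs sit on Gm1 at regular spacing.
three_anchor_fixture <- function(cM) {
  map <- data.frame(marker = paste0("m", 1:3), linkage_group = "Pv1",
                    cM = cM, sequence_id = paste0("s", 1:3),
                    stringsAsFactors = FALSE)
  h <- do.call(rbind, lapply(1:3, function(i)
    make_hit(paste0("s", i), "Gm1", i * 1e5, i * 1e5 + 500)))
  list(map = map, assignments = assign_best_two(h))
}

test_that("block thresholds are inclusive at three loci and 4 cM", {
  fx <- three_anchor_fixture(c(0, 2, 3.9))
  expect_equal(nrow(detect_blocks(fx$assignments, fx$map)), 0L)
  fx2 <- three_anchor_fixture(c(0, 2, 4.0))
  b <- detect_blocks(fx2$assignments, fx2$map)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_anchors, 3)
  # two anchors never make a block, whatever their span
  fx3 <- three_anchor_fixture(c(0, 10, 20))
  two <- fx3$assignments[1:2, ]
  expect_equal(nrow(detect_blocks(two, fx3$map)), 0L)
})

test_that("unmapped queries are skipped with a warning", {
  fx <- three_anchor_fixture(c(0, 5, 10))
  a <- rbind(fx$assignments,
             transform(fx$assignments[1, ], query_id = "not_on_map"))
  expect_warning(b <- detect_blocks(a, fx$map), "not on the genetic map")
  expect_equal(nrow(b), 1L)
})

test_that("anchor order classifies block orientation", {
  direct <- data.frame(cM = c(1, 5, 9), bp = c(10, 20, 30))
  inverted <- data.frame(cM = c(1, 5, 9), bp = c(30, 20, 10))
  mixed <- data.frame(cM = c(1, 5, 9), bp = c(10, 30, 20))
  expect_equal(classify_orientation(direct), "direct")
  expect_equal(classify_orientation(inverted), "inverted")
  expect_equal(classify_orientation(mixed), "mixed")
})

test_that("chaining splits at cM and bp gaps", {
  map <- data.frame(marker = paste0("m", 1:6), linkage_group = "Pv1",
                    cM = c(0, 2, 4, 30, 32, 34),
                    sequence_id = paste0("s", 1:6), stringsAsFactors = FALSE)
  h <- do.call(rbind, lapply(1:6, function(i)
    make_hit(paste0("s", i), "Gm1", i * 1e5, i * 1e5 + 500)))
  b <- detect_blocks(assign_best_two(h), map, max_gap_cM = 15)
  expect_equal(nrow(b), 2L)   # 26-cM gap splits the chain
  # same map, but a 6-Mb physical jump splits even at small cM gaps
  h2 <- do.call(rbind, lapply(1:6, function(i) {
    off <- if (i > 3) 6e6 else 0
    make_hit(paste0("s", i), "Gm1", i * 1e5 + off, i * 1e5 + 500 + off)
  }))
  map2 <- transform(map, cM = c(0, 2, 4, 6, 8, 10))
  b2 <- detect_blocks(assign_best_two(h2), map2, max_gap_bp = 5e6)
  expect_equal(nrow(b2), 2L)
})

test_that("block statistics aggregate sizes and union coverage", {
  b <- bind_blocks(
    make_block("B1", "Pv1", "Gm1",
               data.frame(cM = c(0, 5, 10), bp = c(0, 5e5, 1e6)), width = 0),
    make_block("B2", "Pv1", "Gm2",
               data.frame(cM = c(20, 30, 40), bp = c(0, 1e6, 2e6)), width = 0),
    make_block("B3", "Pv2", "Gm3",
               data.frame(cM = c(0, 15, 30), bp = c(0, 1.5e6, 3e6)), width = 0))
  s <- block_stats(b, map_total_cM = 200, genome_bp = 1e7)
  expect_equal(s$n_blocks, 3)
  expect_equal(s$mean_cM, 20)
  expect_equal(s$median_cM, 20)
  expect_equal(s$frac_gt_20cM, 1 / 3)
  expect_equal(s$frac_gt_2Mb, 1 / 3)

  # one block covering a full 100-cM linkage group of a 100-cM map
  full <- make_block("B1", "Pv1", "Gm1",
                     data.frame(cM = c(0, 50, 100), bp = c(0, 5e5, 1e6)))
  expect_equal(block_stats(full, 100, 1e7)$genetic_coverage_pct, 100)

  # duplicate blocks over the same cM interval are counted once
  dup <- bind_blocks(
    make_block("B1", "Pv1", "Gm1",
               data.frame(cM = c(0, 25, 50), bp = c(0, 5e5, 1e6))),
    make_block("B2", "Pv1", "Gm2",
               data.frame(cM = c(0, 25, 50), bp = c(0, 5e5, 1e6))))
  expect_equal(block_stats(dup, 100, 1e7)$genetic_coverage_pct, 50)

  # empty input: all-zero statistics
  s0 <- block_stats(full[0, ], 100, 1e7)
  expect_equal(s0$n_blocks, 0)
  expect_equal(s0$genetic_coverage_pct, 0)

  # pericentromere exclusion: block [0, 2e6) with pericentromere [1e6, 2e6)
  # on a 1e7 genome with 2e6 pericentromeric bp
  pb <- make_block("B1", "Pv1", "Gm1",
                   data.frame(cM = c(0, 5, 10), bp = c(1, 1e6, 2e6)),
                   width = 2)
  peri <- data.frame(chrom = c("Gm1", "Gm2"), start = c(1e6, 0),
                     end = c(2e6, 1e6), stringsAsFactors = FALSE)
  s2 <- block_stats(pb, 100, 1e7, peri)
  expect_equal(s2$euchromatic_coverage_pct, 100 * 1e6 / 8e6, tolerance = 1e-4)
})

test_that("union coverage equals a discretised brute-force scan", {
  p <- run_pipeline(tiny_cfg(seed = 91))
  genome_bp <- sum(p$sim$derived$chromosomes$length_bp)
  map_cM <- 2 * 100
  s <- block_stats(p$blocks, map_cM, genome_bp)
  # genetic: 0.05-cM grid over each linkage group
  covered <- 0; total <- 0
  for (lg in c("Pv1", "Pv2")) {
    grid <- seq(0.025, 100, by = 0.05)
    bl <- p$blocks[p$blocks$linkage_group == lg, ]
    hit <- vapply(grid, function(x)
      any(x >= bl$cM_start & x <= bl$cM_end), logical(1))
    covered <- covered + sum(hit) * 0.05
    total <- total + 100
  }
  expect_equal(s$genetic_coverage_pct, 100 * covered / total, tolerance = 0.02)
  # physical: 1-kb grid over each derived chromosome
  bp_cov <- 0
  for (ch in p$sim$derived$chromosomes$chrom) {
    L <- p$sim$derived$chromosomes$length_bp[
      p$sim$derived$chromosomes$chrom == ch]
    grid <- seq(500, L, by = 1000)
    bl <- p$blocks[p$blocks$subject_chromosome == ch, ]
    if (nrow(bl) == 0) next
    hit <- vapply(grid, function(x)
      any(x > bl$bp_start & x <= bl$bp_end), logical(1))
    bp_cov <- bp_cov + sum(hit) * 1000
  }
  expect_equal(s$physical_coverage_pct, 100 * bp_cov / genome_bp,
               tolerance = 0.02)
})

test_that("chaining agrees with an independently coded oracle", {
  for (sd in c(92, 93)) {
    p <- run_pipeline(tiny_cfg(seed = sd, n_rearrangements = 3))
    ob <- oracle_blocks(p$mapped, p$sim$map)
    b <- p$blocks
    b <- b[order(b$linkage_group, b$cM_start, b$subject_chromosome,
                 b$bp_start), ]
    expect_equal(nrow(b), nrow(ob))
    expect_equal(b$cM_start, ob$cM_start)
    expect_equal(b$cM_end, ob$cM_end)
    expect_equal(b$bp_start, ob$bp_start)
    expect_equal(b$bp_end, ob$bp_end)
    expect_equal(b$n_anchors, ob$n)
  }
})

test_that("a single rearrangement's breakpoints are bracketed by blocks", {
  # this seed moves a segment across linkage groups (Gm2 -> Gm4): both
  # junctions are resolvable and must be recovered within one anchor gap
  cfg <- tiny_cfg(n_chromosomes = 2, genes_per_chromosome = 120,
                  marker_fraction = 0.5, fractionation_rate = 0,
                  n_rearrangements = 1, mean_segment_genes = 40,
                  pericentromere_recombination_factor = 1, seed = 95)
  p <- run_pipeline(cfg)
  ev <- p$sim$truth$event_log
  mv <- ev[ev$kind %in% c("move", "fusion"), ]
  expect_false(substr(mv$chrom_from, 3, 3) == substr(mv$chrom_to, 3, 3) &&
                 mv$chrom_from == mv$chrom_to)
  rec <- block_recovery(p$blocks, p$sim$truth, p$sim$map, p$sim$derived)
  expect_gt(rec$n_true, 0)
  expect_equal(rec$recall, 1)
  expect_equal(rec$precision, 1)
})

test_that("same-linkage-group junctions are a documented blind spot", {
  # one ancestor chromosome: any move lands on the duplicate partner, both
  # flanks share the linkage group, and chaining interleaves the two copies;
  # no junction is counted resolvable, and no false breakpoint is claimed
  cfg <- tiny_cfg(n_chromosomes = 1, genes_per_chromosome = 120,
                  marker_fraction = 0.5, fractionation_rate = 0,
                  n_rearrangements = 1, mean_segment_genes = 40,
                  pericentromere_recombination_factor = 1, seed = 94)
  p <- run_pipeline(cfg)
  rec <- block_recovery(p$blocks, p$sim$truth, p$sim$map, p$sim$derived)
  expect_equal(rec$n_true, 0L)
  expect_equal(rec$precision, 1)
})

test_that("lossless dense simulation gives two full-length blocks per group", {
  cfg <- tiny_cfg(marker_fraction = 0.5, fractionation_rate = 0,
                  n_rearrangements = 0, genes_per_chromosome = 100,
                  seed = 95)
  p <- run_pipeline(cfg)
  for (lg in c("Pv1", "Pv2")) {
    bl <- p$blocks[p$blocks$linkage_group == lg, ]
    expect_equal(nrow(bl), 2L)
    expect_true(all(bl$cM_end - bl$cM_start >= 0.9 * 100))
    expect_equal(anyDuplicated(bl$subject_chromosome), 0L)
  }
})

test_that("detected blocks satisfy the block invariants on random runs", {
  for (sd in c(96, 97, 98)) {
    p <- run_pipeline(tiny_cfg(seed = sd, n_rearrangements = 4,
                               spurious_rate = 0.2))
    b <- p$blocks
    chrom_len <- p$sim$derived$chromosomes
    for (i in seq_len(nrow(b))) {
      expect_gte(b$n_anchors[i], 3)
      expect_gte(b$cM_end[i] - b$cM_start[i], 4)
      a <- b$anchors[[i]]
      expect_true(all(a$cM >= b$cM_start[i] & a$cM <= b$cM_end[i]))
      L <- chrom_len$length_bp[chrom_len$chrom == b$subject_chromosome[i]]
      expect_true(b$bp_start[i] >= 0 && b$bp_end[i] <= L)
      expect_lte(b$extended_bp_start[i], b$bp_start[i])
      expect_gte(b$extended_bp_end[i], b$bp_end[i])
    }
  }
})
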