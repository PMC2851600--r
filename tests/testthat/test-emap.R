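# Two duplicate reference blocks anchored to the same linkage-group interval,
# mirroring a 45-cM block shared by two subject regions (41.1-45.9 Mb and
# 11.9-16.2 Mb), plus shared two-hit loci that extend colinearity out to
# 36.0-49.0 Mb and 8.6-19.5 Mb before order breaks.
pv9_fixture <- function() {
  home <- make_block("H", "Pv9", "Gm4",
                     data.frame(cM = c(44, 66, 89),
                                bp = c(41.1e6, 43.5e6, 45.9e6)), width = 0)
  partner <- make_block("P", "Pv9", "Gm6",
                        data.frame(cM = c(44, 66, 89),
                                   bp = c(11.9e6, 14.0e6, 16.2e6)),
                        width = 0)
  loci <- data.frame(
    sequence_id = sprintf("e%d", 1:8),
    chrom_a = "Gm4",
    mid_a = c(42.0e6, 45.0e6, 47.0e6, 49.0e6, 50.0e6, 39.0e6, 36.0e6,
              34.0e6),
    e_a = 1e-60,
    chrom_b = "Gm6",
    mid_b = c(12.5e6, 15.5e6, 17.0e6, 19.5e6, 16.0e6, 10.5e6, 8.6e6,
              11.0e6),
    e_b = 1e-55,
    stringsAsFactors = FALSE)
  list(home = home, partner = partner, loci = loci)
}

test_that("hit criteria gate electronic mapping", {
  blocks <- make_block("B1", "Pv1", "Gm1",
                       data.frame(cM = c(0, 5, 10), bp = c(0, 5e5, 1e6)))
  # single qualifying hit: never mapped, never unplaceable (fails criteria)
  one <- assign_best_two(make_hit("q1", "Gm1", 1e5, 1e5 + 300,
                                  e_value = 1e-60))
  em1 <- electronic_map(one, blocks)
  expect_equal(nrow(em1$loci), 0L)
  expect_length(em1$unplaceable, 0L)

  # E-value bound is strict at 1e-30 for both hits
  two <- assign_best_two(make_hits(
    make_hit("q2", "Gm1", 1e5, 1e5 + 300, e_value = 1e-60, bit_score = 200),
    make_hit("q2", "Gm2", 1e5, 1e5 + 300, e_value = 1e-30, bit_score = 150)))
  expect_equal(nrow(electronic_map(two, blocks)$loci), 0L)
  two_ok <- assign_best_two(make_hits(
    make_hit("q2", "Gm1", 1e5, 1e5 + 300, e_value = 1e-60, bit_score = 200),
    make_hit("q2", "Gm2", 1e5, 1e5 + 300, e_value = 1e-31, bit_score = 150)))
  expect_equal(nrow(electronic_map(two_ok, blocks)$loci), 1L)

  # both alignment lengths must reach 150 nt
  short <- assign_best_two(make_hits(
    make_hit("q3", "Gm1", 1e5, 1e5 + 300, e_value = 1e-60, bit_score = 200),
    make_hit("q3", "Gm2", 1e5, 1e5 + 149, e_value = 1e-60, bit_score = 150,
             align_length = 149)))
  expect_equal(nrow(electronic_map(short, blocks)$loci), 0L)

  # two same-chromosome hits separated by exactly 50 nt merge into one
  # segment ("greater than 50" fails), so the sequence has no second locus
  sep50 <- assign_best_two(make_hits(
    make_hit("q4", "Gm1", 1e5, 1e5 + 300, e_value = 1e-60, bit_score = 200),
    make_hit("q4", "Gm1", 1e5 + 350, 1e5 + 650, e_value = 1e-60,
             bit_score = 150)))
  expect_true(is.na(sep50$secondary_chrom))
  expect_equal(nrow(electronic_map(sep50, blocks)$loci), 0L)

  # qualifying but outside every block: reported unplaceable
  outside <- assign_best_two(make_hits(
    make_hit("q5", "Gm7", 1e5, 1e5 + 300, e_value = 1e-60, bit_score = 200),
    make_hit("q5", "Gm8", 1e5, 1e5 + 300, e_value = 1e-60, bit_score = 150)))
  em5 <- electronic_map(outside, blocks)
  expect_equal(nrow(em5$loci), 0L)
  expect_equal(em5$unplaceable, "q5")
})

test_that("interpolation is linear between flanking anchors", {
  b <- make_block("B1", "Pv1", "Gm1",
                  data.frame(cM = c(10, 20, 40), bp = c(1e5, 2e5, 3e5)),
                  width = 0)
  expect_equal(interpolate_position(1.5e5, b), 15)   # midpoint -> midpoint
  expect_equal(interpolate_position(2e5, b), 20)     # coincident anchor
  expect_equal(interpolate_position(2.5e5, b), 30)
  # beyond the terminal anchor: clamps to the terminal anchor's cM
  expect_equal(interpolate_position(5e5, b), 40)
  expect_equal(interpolate_position(0, b), 10)
})

test_that("interpolation on inverted blocks stays within anchor bounds", {
  set.seed(121)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    cM <- sort(runif(n, 0, 100))
    bp <- sort(runif(n, 0, 1e6), decreasing = TRUE)   # inverted layout
    b <- make_block("B", "Pv1", "Gm1", data.frame(cM = cM, bp = bp),
                    width = 0)
    expect_equal(b$orientation, "inverted")
    probes <- runif(10, min(bp), max(bp))
    vals <- vapply(probes, interpolate_position, numeric(1), block = b)
    expect_true(all(vals >= min(cM) & vals <= max(cM)))
    # monotone along the block's orientation: larger bp, smaller cM
    o <- order(probes)
    expect_true(all(diff(vals[o]) <= 1e-9))
  }
  # fewer than two anchors: bin midpoint, flagged low confidence
  b1 <- make_block("B", "Pv1", "Gm1", data.frame(cM = 10, bp = 1e5))
  v <- interpolate_position(2e5, b1)
  expect_equal(as.numeric(v), 10)
  expect_true(attr(v, "low_confidence"))
})

test_that("simulated unmapped genes receive the true linkage group", {
  cfg <- tiny_cfg(n_chromosomes = 2, genes_per_chromosome = 150,
                  marker_fraction = 0.25, n_rearrangements = 2, seed = 122)
  sim <- simulate_synteny(cfg, queries = "all")
  a <- assign_best_two(filter_hits(sim$hits))
  am <- a[a$query_id %in% sim$map$sequence_id, ]
  blocks <- detect_blocks(am, sim$map)
  unmapped <- a[!(a$query_id %in% sim$map$sequence_id), ]
  em <- electronic_map(unmapped, blocks, map = sim$map)
  expect_gt(nrow(em$loci), 50)
  true_lg <- sim$ancestral$genes$chrom[
    match(em$loci$sequence_id, sim$ancestral$genes$gene_id)]
  expect_gte(mean(em$loci$linkage_group == true_lg), 0.95)
  expect_false(any(em$loci$previously_mapped))
  # bins contain the point estimates
  expect_true(all(em$loci$inferred_cM >= em$loci$bin_lo &
                    em$loci$inferred_cM <= em$loci$bin_hi))
})

test_that("leave-one-in control: mapped markers land in bins with their cM", {
  cfg <- tiny_cfg(n_chromosomes = 2, genes_per_chromosome = 150,
                  marker_fraction = 0.25, n_rearrangements = 2, seed = 123)
  p <- run_pipeline(cfg)
  em <- electronic_map(p$mapped, p$blocks, map = p$sim$map)
  expect_true(all(em$loci$previously_mapped))
  truth <- p$sim$map[match(em$loci$sequence_id, p$sim$map$sequence_id), ]
  in_bin <- em$loci$linkage_group == truth$linkage_group &
    truth$cM >= em$loci$bin_lo & truth$cM <= em$loci$bin_hi
  expect_gte(mean(in_bin), 0.95)
})

test_that("extension walks colinear loci out to the order break", {
  fx <- pv9_fixture()
  # no shared loci at all: a no-op
  res0 <- extend_block(fx$home, fx$partner, fx$loci[0, ])
  expect_equal(res0$block$extended_bp_start, fx$home$bp_start)
  expect_equal(res0$block$extended_bp_end, fx$home$bp_end)

  res <- extend_block(fx$home, fx$partner, fx$loci)
  expect_equal(res$block$extended_bp_start, 36.0e6)
  expect_equal(res$block$extended_bp_end, 49.0e6)
  expect_equal(res$partner$extended_bp_start, 8.6e6)
  expect_equal(res$partner$extended_bp_end, 19.5e6)
  # original anchors and bp bounds untouched
  expect_equal(res$block$bp_start, 41.1e6)
  expect_equal(res$block$bp_end, 45.9e6)
  # the extension grows the syntenic span from 9.1 Mb to 23.9 Mb
  orig <- (fx$home$bp_end - fx$home$bp_start) +
    (fx$partner$bp_end - fx$partner$bp_start)
  ext <- (res$block$extended_bp_end - res$block$extended_bp_start) +
    (res$partner$extended_bp_end - res$partner$extended_bp_start)
  expect_equal(orig / 1e6, 9.1)
  expect_equal(ext / 1e6, 23.9)

  # idempotence: extending again changes nothing
  res2 <- extend_block(res$block, res$partner, fx$loci)
  expect_equal(res2$block$extended_bp_start, 36.0e6)
  expect_equal(res2$block$extended_bp_end, 49.0e6)
  expect_equal(res2$partner$extended_bp_start, 8.6e6)
  expect_equal(res2$partner$extended_bp_end, 19.5e6)
})

test_that("extension stops at a locus pairing to a third chromosome", {
  fx <- pv9_fixture()
  loci <- fx$loci
  # replace the first outward locus on the right by one pairing to Gm9
  loci$chrom_b[loci$mid_a == 47.0e6] <- "Gm9"
  res <- extend_block(fx$home, fx$partner, loci)
  expect_equal(res$block$extended_bp_end, fx$home$bp_end)   # right walk dead
  expect_equal(res$block$extended_bp_start, 36.0e6)         # left unaffected
})

test_that("whole-set extension preserves supersets and idempotence", {
  p <- run_pipeline(tiny_cfg(seed = 124, n_rearrangements = 3,
                             marker_fraction = 0.2,
                             genes_per_chromosome = 120),
                    queries = "all")
  loci <- qualifying_two_hit_loci(p$assignments)
  ext <- extend_all_blocks(p$blocks, loci)
  expect_true(all(ext$extended_bp_start <= ext$bp_start))
  expect_true(all(ext$extended_bp_end >= ext$bp_end))
  ext2 <- extend_all_blocks(ext, loci)
  expect_equal(ext2$extended_bp_start, ext$extended_bp_start)
  expect_equal(ext2$extended_bp_end, ext$extended_bp_end)
})

test_that("hold-out classification separates exact and inverted order", {
  map <- data.frame(marker = paste0("m", 1:4), linkage_group = "Pv1",
                    cM = c(10, 20, 30, 40),
                    sequence_id = paste0("s", 1:4), stringsAsFactors = FALSE)
  pred <- data.frame(
    sequence_id = paste0("s", 1:4), linkage_group = "Pv1",
    inferred_cM = c(11, 31, 21, 39),    # middle pair transposed
    bin_lo = 0, bin_hi = 50, stringsAsFactors = FALSE)
  rep <- validate_holdout(map, pred)
  expect_equal(rep$n_tested, 4L)
  expect_equal(rep$n_within_interval, 4L)
  expect_equal(rep$n_exact_order, 2L)
  expect_equal(rep$n_locally_inverted, 2L)
  # empty hold-out set: empty report
  rep0 <- validate_holdout(map, pred[0, ])
  expect_equal(rep0$n_tested, 0L)
})

test_that("held-out markers are recovered inside their predicted bins", {
  sim <- simulate_synteny(tiny_cfg(n_chromosomes = 2,
                                   genes_per_chromosome = 150,
                                   marker_fraction = 0.3,
                                   n_rearrangements = 2, seed = 125),
                          queries = "markers")
  set.seed(126)
  he <- holdout_experiment(sim, n_holdout = 12)
  expect_gt(he$report$n_tested, 5)
  expect_gte(he$report$n_within_interval / he$report$n_tested, 0.9)
})
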