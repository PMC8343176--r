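test_that("Kosambi function and inverse are exact", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi_inverse(0), 0)
  r <- seq(0, 0.49, by = 0.01)
  expect_lt(max(abs(kosambi_inverse(kosambi(r)) - r)), 1e-12)
  expect_equal(kosambi(0.5), Inf)
  expect_error(kosambi(0.6), "0.5")
  # quadrature oracle for the defining ODE dd/dr = 1/(1-4r^2) (in Morgans)
  quad <- stats::integrate(function(x) 1 / (1 - 4 * x^2), 0, 0.25)$value
  expect_equal(kosambi(0.25), 100 * quad, tolerance = 1e-8)
})

test_that("selfed-RIL discordance recursion matches the closed form", {
  for (r in c(0.01, 0.05, 0.1, 0.25, 0.4)) {
    R_oracle <- ril_discordance_recursion(r, generations = 3000)
    expect_equal(R_oracle, 2 * r / (1 + 2 * r), tolerance = 1e-10)
    expect_equal(ril_rf_to_meiotic(R_oracle), r, tolerance = 1e-9)
  }
  expect_equal(ril_rf_to_meiotic(0.5), 0.5)  # unlinked fixed point
})

test_that("pairwise recombination fractions behave at the extremes", {
  withr::local_seed(5)
  col <- sample(c("A", "B"), 60, TRUE)
  g <- cbind(m1 = col, m2 = col,                       # identical
             m3 = ifelse(col == "A", "B", "A"),        # complement
             m4 = sample(c("A", "B"), 60, TRUE))       # unlinked
  bins <- make_bins(g)
  rf <- pairwise_rf(bins)
  expect_equal(rf$R["chr1:0000000", "chr1:0100000"], 0)
  expect_equal(rf$r["chr1:0000000", "chr1:0100000"], 0)
  expect_equal(rf$lod["chr1:0000000", "chr1:0100000"], 60 * log10(2))
  expect_equal(rf$R["chr1:0000000", "chr1:0200000"], 1)
  # few co-scored lines -> unreliable
  g2 <- cbind(a = c("A", "B", rep(NA, 20)), b = c("A", "B", rep(NA, 20)))
  rf2 <- pairwise_rf(make_bins(g2))
  expect_true(is.na(rf2$R[1, 2]))
})

test_that("pairwise R matches a per-pair tally with HET as missing", {
  withr::local_seed(6)
  g <- matrix(sample(c("A", "B", "H", NA), 30 * 6, TRUE), 30, 6)
  bins <- make_bins(g)
  rf <- pairwise_rf(bins, min_scored = 1)
  for (i in 1:5) for (j in (i + 1):6) {
    x <- g[, i]; y <- g[, j]
    ok <- x %in% c("A", "B") & y %in% c("A", "B")
    expect_equal(rf$R[i, j], sum(x[ok] != y[ok]) / sum(ok))
    expect_equal(rf$n[i, j], sum(ok))
  }
})

sim_marker_panel <- function(seed, n_lines = 80, m = 8, map_cM = 60,
                             err = 0) {
  cfg <- sim_config(n_lines = n_lines, n_chromosomes = 1,
                    chrom_length_bp = 1e6, map_length_cM = map_cM,
                    n_snps_per_chrom = m, seed = seed)
  truth <- simulate_ril_genomes(cfg)
  g <- truth$genotypes$geno
  g[g == "H"] <- NA
  if (err > 0) {
    flip <- which(stats::runif(length(g)) < err & !is.na(g))
    g[flip] <- ifelse(g[flip] == "A", "B", "A")
  }
  starts <- (rank(truth$loci$pos, ties.method = "first") - 1L) * 100000L
  bm <- binned_markers(g, data.frame(chrom = "chr1", start = starts,
                                     end = starts + 100000L,
                                     label = sprintf("chr1:%07d", starts)))
  rilqtl:::recompute_marker_qc(bm)
}

test_that("MST ordering recovers the physical order on clean data", {
  bins <- sim_marker_panel(seed = 61, n_lines = 100, m = 12)
  rf <- pairwise_rf(bins)
  ord <- order_markers_mst(rf, bins$markers$label,
                           stats::setNames(bins$markers$start,
                                           bins$markers$label))
  expect_equal(ord, bins$markers$label)
})

test_that("MST order beats almost all permutations on small instances", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  all_perm <- perms(1:7)
  for (seed in c(71, 72, 73)) {
    bins <- sim_marker_panel(seed = seed, n_lines = 50, m = 7, err = 0.03)
    rf <- pairwise_rf(bins, min_scored = 5)
    labs <- bins$markers$label
    ord <- order_markers_mst(rf, labs,
                             stats::setNames(bins$markers$start, labs))
    ours <- order_cost(rf$R, ord)
    costs <- vapply(all_perm, function(p) order_cost(rf$R, labs[p]),
                    numeric(1))
    expect_lte(ours, stats::quantile(costs, 0.01) + 1e-12)
  }
})

test_that("duplicate markers are placed adjacent and order is shuffle-stable", {
  withr::local_seed(65)
  # a long map keeps adjacent-marker discordances well away from zero, so
  # the only zero-R pair is the deliberate duplicate
  bins <- sim_marker_panel(seed = 66, n_lines = 100, m = 6, map_cM = 200)
  g <- cbind(bins$geno, dup = bins$geno[, 3])
  starts <- c(bins$markers$start, 250000L)
  bm <- binned_markers(g, data.frame(chrom = "chr1", start = starts,
                                     end = starts + 100000L,
                                     label = c(bins$markers$label, "dup")))
  rf <- pairwise_rf(rilqtl:::recompute_marker_qc(bm), min_scored = 5)
  phys <- stats::setNames(bm$markers$start, bm$markers$label)
  ord <- order_markers_mst(rf, bm$markers$label, phys)
  i <- which(ord == bins$markers$label[3]); j <- which(ord == "dup")
  expect_equal(abs(i - j), 1L)
  ord2 <- order_markers_mst(rf, sample(bm$markers$label), phys)
  expect_true(identical(ord, ord2) || identical(ord, rev(ord2)))
})

test_that("disconnected marker graphs are reported as an error", {
  g <- cbind(a = c("A", "B", NA, NA), b = c("A", "B", NA, NA),
             c = c(NA, NA, "A", "B"), d = c(NA, NA, "A", "B"))
  bins <- make_bins(g)
  rf <- pairwise_rf(bins, min_scored = 2)
  expect_error(order_markers_mst(rf, bins$markers$label,
                                 stats::setNames(bins$markers$start,
                                                 bins$markers$label)),
               "disconnected")
})

test_that("map construction is invariant to marker input order", {
  bins <- sim_marker_panel(seed = 68, n_lines = 90, m = 10)
  map1 <- build_linkage_map(bins, min_scored = 5)
  perm <- sample(ncol(bins$geno))
  bins2 <- binned_markers(bins$geno[, perm],
                          bins$markers[perm, , drop = FALSE])
  map2 <- build_linkage_map(rilqtl:::recompute_marker_qc(bins2),
                            min_scored = 5)
  expect_equal(map1$marker, map2$marker)
  expect_equal(map1$cM, map2$cM, tolerance = 1e-12)
})

test_that("crossover-count correction tracks the simulated map length", {
  cfg <- sim_config(n_lines = 150, n_chromosomes = 1, chrom_length_bp = 4e6,
                    map_length_cM = 80, n_snps_per_chrom = 40, seed = 90)
  truth <- simulate_ril_genomes(cfg)
  g <- truth$genotypes$geno
  g[g == "H"] <- NA
  starts <- (rank(truth$loci$pos, ties.method = "first") - 1L) * 100000L
  bins <- rilqtl:::recompute_marker_qc(binned_markers(
    g, data.frame(chrom = "chr1", start = starts, end = starts + 100000L,
                  label = sprintf("chr1:%07d", starts))))
  map <- correct_map_lengths(build_linkage_map(bins), bins)
  lens <- attr(map, "lengths")
  # corrected length estimates the meiotic map length (80 cM)
  expect_lt(abs(lens$corrected_cM - 80) / 80, 0.25)

  # injecting 1% genotyping errors inflates the raw map but the corrected
  # length moves by less than 15%
  set.seed(91)
  g2 <- bins$geno
  flip <- which(stats::runif(length(g2)) < 0.01 & !is.na(g2))
  g2[flip] <- ifelse(g2[flip] == "A", "B", "A")
  bins2 <- rilqtl:::recompute_marker_qc(binned_markers(g2, bins$markers))
  map2 <- correct_map_lengths(build_linkage_map(bins2), bins2)
  lens2 <- attr(map2, "lengths")
  expect_gt(lens2$raw_cM, lens$raw_cM)
  expect_lt(abs(lens2$corrected_cM - lens$corrected_cM) /
              lens$corrected_cM, 0.15)
})

test_that("a non-recombining chromosome has corrected length zero", {
  withr::local_seed(95)
  col <- sample(c("A", "B"), 40, TRUE)
  g <- matrix(col, 40, 6)
  bins <- make_bins(g)
  map <- correct_map_lengths(build_linkage_map(bins), bins)
  expect_equal(attr(map, "lengths")$corrected_cM, 0)
  expect_equal(attr(map, "lengths")$raw_cM, 0)
})
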