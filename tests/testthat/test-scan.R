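# small marker panel + map straight from an error-free simulation
scan_fixture <- function(seed = 1, n_lines = 120, m = 30, map_cM = 80,
                         n_chrom = 1) {
  cfg <- sim_config(n_lines = n_lines, n_chromosomes = n_chrom,
                    chrom_length_bp = 3e6, map_length_cM = map_cM,
                    n_snps_per_chrom = m, seed = seed)
  truth <- simulate_ril_genomes(cfg)
  g <- truth$genotypes$geno
  g[g == "H"] <- NA
  rows <- lapply(unique(truth$loci$chrom), function(ch) {
    sel <- truth$loci$chrom == ch
    starts <- (rank(truth$loci$pos[sel], ties.method = "first") - 1L) * 100000L
    data.frame(chrom = ch, start = starts, end = starts + 100000L,
               label = sprintf("%s:%07d", ch, starts))
  })
  mk <- do.call(rbind, rows)
  bins <- rilqtl:::recompute_marker_qc(binned_markers(g, mk))
  map <- correct_map_lengths(build_linkage_map(bins), bins)
  list(truth = truth, bins = bins, map = map)
}

test_that("null markers are dropped and informative markers kept", {
  g <- cbind(a = c("A", "B", "A"), b = rep(NA_character_, 3),
             c = c("A", NA, "B"))
  bins <- make_bins(g)
  out <- drop_null_markers(bins)
  expect_equal(colnames(out$geno), bins$markers$label[c(1, 3)])
  expect_equal(attr(out, "n_dropped"), 1)
})

test_that("genotype probabilities are degenerate at scored markers", {
  fx <- scan_fixture(seed = 2, n_lines = 30, m = 8)
  gp <- calc_genoprob(fx$bins, fx$map, step_cM = 1, error_prob = 0)
  mpos <- which(!is.na(gp$grid$marker))
  for (j in mpos) {
    obs <- fx$bins$geno[, gp$grid$marker[j]]
    pb <- gp$pBB[, j]
    expect_true(all(abs(pb[obs %in% "B"] - 1) < 1e-9))
    expect_true(all(abs(pb[obs %in% "A"]) < 1e-9))
  }
})

test_that("the midpoint between discordant flanking markers is uninformative", {
  g <- cbind(m1 = c("A", "B"), m2 = c("B", "A"))
  bins <- make_bins(g)
  map <- structure(data.frame(chrom = "chr1", marker = bins$markers$label,
                              order_index = 1:2, start = bins$markers$start,
                              r_adj = c(NA, 0.2), cM = c(0, 20)),
                   class = c("linkage_map", "data.frame"))
  gp <- calc_genoprob(bins, map, step_cM = 10, error_prob = 0)
  mid <- which(gp$grid$cM == 10)
  expect_equal(unname(gp$pBB[, mid]), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("genotype probabilities equal exhaustive enumeration on toys", {
  withr::local_seed(33)
  for (inst in 1:10) {
    m <- sample(3:6, 1)
    obs <- sample(c("A", "B", NA), m, TRUE)
    cm <- sort(sample(0:12, m))
    e <- 0.02
    g <- matrix(obs, 1)
    starts <- (seq_len(m) - 1L) * 100000L
    bins <- rilqtl:::recompute_marker_qc(binned_markers(
      g, data.frame(chrom = "c1", start = starts, end = starts + 100000L,
                    label = sprintf("c1:%07d", starts))))
    map <- structure(data.frame(chrom = "c1", marker = bins$markers$label,
                                order_index = seq_len(m), start = starts,
                                r_adj = NA, cM = cm),
                     class = c("linkage_map", "data.frame"))
    gp <- calc_genoprob(bins, map, step_cM = 1, error_prob = e)
    # oracle: enumerate all 2^G hidden assignments over the full grid
    grid <- gp$grid$cM
    G <- length(grid)
    if (G > 14) next
    trans <- function(d) { r <- kosambi_inverse(d); 2 * r / (1 + 2 * r) }
    Rg <- trans(diff(grid))
    emit <- function(state, o) {
      if (is.na(o)) return(1)
      if ((o == "B") == (state == 2)) 1 - e else e
    }
    obs_at <- rep(NA_character_, G)
    obs_at[match(round(cm, 9), round(grid, 9))] <- obs
    states <- as.matrix(expand.grid(rep(list(1:2), G)))
    w <- apply(states, 1, function(s) {
      p <- 0.5 * emit(s[1], obs_at[1])
      for (t in 2:G) {
        sw <- if (s[t] == s[t - 1]) 1 - Rg[t - 1] else Rg[t - 1]
        p <- p * sw * emit(s[t], obs_at[t])
      }
      p
    })
    oracle <- vapply(seq_len(G), function(t) {
      sum(w[states[, t] == 2]) / sum(w)
    }, numeric(1))
    expect_equal(unname(gp$pBB[1, ]), oracle, tolerance = 1e-10)
  }
})

test_that("single-marker LOD matches the regression closed form", {
  withr::local_seed(44)
  fx <- scan_fixture(seed = 4, n_lines = 100, m = 10)
  gp <- calc_genoprob(fx$bins, fx$map, step_cM = 1, error_prob = 1e-4)
  j <- which(!is.na(gp$grid$marker))[4]
  x <- gp$pBB[, j]
  y <- 3 + 2 * x + rnorm(100, 0, 1)
  prof <- scan_hk(gp, stats::setNames(y, rownames(gp$pBB)))
  fit <- stats::lm(y ~ x)
  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  expect_equal(prof$lod[j], (100 / 2) * log10(rss0 / rss1), tolerance = 1e-8)
  expect_equal(prof$effect[j], unname(stats::coef(fit)[2]) / 2,
               tolerance = 1e-8)
  # LOD-R2 identity
  r2 <- summary(fit)$r.squared
  expect_equal(prof$lod[j], -(100 / 2) * log10(1 - r2), tolerance = 1e-8)
})

test_that("a genotype-independent phenotype yields only modest LOD peaks", {
  withr::local_seed(45)
  fx <- scan_fixture(seed = 5, n_lines = 120, m = 25)
  gp <- calc_genoprob(fx$bins, fx$map)
  y <- rnorm(120)
  prof <- scan_hk(gp, stats::setNames(y, rownames(gp$pBB)))
  thr <- permutation_threshold(gp, stats::setNames(y, rownames(gp$pBB)),
                               n_perm = 200, seed = 9)
  expect_lt(max(prof$lod, na.rm = TRUE), thr + 2)
})

test_that("CIM with zero cofactors reduces to the plain scan", {
  fx <- scan_fixture(seed = 6, n_lines = 60, m = 12)
  gp <- calc_genoprob(fx$bins, fx$map)
  withr::local_seed(46)
  y <- stats::setNames(rnorm(60), rownames(gp$pBB))
  p1 <- scan_hk(gp, y)
  p2 <- scan_cim(gp, y, n_covar = 0)
  expect_equal(p2$lod, p1$lod, tolerance = 1e-10)
  expect_error(scan_cim(gp, y, n_covar = 20), "cofactors")
})

test_that("CIM cofactors are excluded within the scan window", {
  fx <- scan_fixture(seed = 7, n_lines = 100, m = 20)
  gp <- calc_genoprob(fx$bins, fx$map)
  withr::local_seed(47)
  j <- which(!is.na(gp$grid$marker))[10]
  y <- 5 + 3 * gp$pBB[, j] + rnorm(100, 0, 1)
  prof <- scan_cim(gp, stats::setNames(y, rownames(gp$pBB)), n_covar = 2,
                   window_cM = 10)
  cof <- attr(prof, "cofactors")
  expect_lte(nrow(cof), 2)
  # at the position of each cofactor the LOD is still computed (not
  # self-conditioned away): the strongest cofactor sits near the true QTL
  # and the CIM profile keeps a peak there
  expect_gt(max(prof$lod, na.rm = TRUE), 3)
})

test_that("permutation thresholds are deterministic and edge cases hold", {
  fx <- scan_fixture(seed = 8, n_lines = 50, m = 10)
  gp <- calc_genoprob(fx$bins, fx$map)
  withr::local_seed(48)
  y <- stats::setNames(rnorm(50), rownames(gp$pBB))
  t1 <- permutation_threshold(gp, y, n_perm = 150, seed = 5)
  t2 <- permutation_threshold(gp, y, n_perm = 150, seed = 5)
  expect_identical(as.numeric(t1), as.numeric(t2))
  t_all <- permutation_threshold(gp, y, n_perm = 150, alpha = 1, seed = 5)
  expect_equal(as.numeric(t_all), min(attr(t_all, "null_max")))
  expect_warning(permutation_threshold(gp, y, n_perm = 50, seed = 5),
                 "permutations")
})

test_that("multiple-QTL variance decomposition has its exact reductions", {
  fx <- scan_fixture(seed = 9, n_lines = 100, m = 15)
  gp <- calc_genoprob(fx$bins, fx$map)
  j <- which(!is.na(gp$grid$marker))[8]
  # phenotype an exact function of one locus -> Var = 100
  y <- stats::setNames(2 * gp$pBB[, j], rownames(gp$pBB))
  pk <- data.frame(chrom = gp$grid$chrom[j], peak_cM = gp$grid$cM[j])
  fq <- fit_multiple_qtl(gp, y, pk)
  expect_equal(fq$overall_var, 100, tolerance = 1e-6)
  expect_equal(fq$per_qtl$var_drop1, 100, tolerance = 1e-6)
  # single QTL: drop-one equals marginal equals overall
  withr::local_seed(49)
  y2 <- stats::setNames(2 * gp$pBB[, j] + rnorm(100), rownames(gp$pBB))
  fq2 <- fit_multiple_qtl(gp, y2, pk)
  expect_equal(fq2$per_qtl$var_drop1, fq2$per_qtl$var_marginal,
               tolerance = 1e-9)
  expect_equal(fq2$overall_var, fq2$per_qtl$var_marginal, tolerance = 1e-9)
})

test_that("support intervals match a brute-force grid scan", {
  prof <- structure(data.frame(
    chrom = "c1", cM = 0:20, marker = NA,
    lod = c(1, 2, 3, 4, 5, 6, 7, 8, 7.2, 6.4, 5, 4, 6.9, 3, 2, 1, 1, 1, 1,
            1, 1), effect = 0), class = c("scan_result", "data.frame"))
  si <- support_interval(prof, "c1", 7, drop = 1.5)
  ok <- prof$lod >= 8 - 1.5
  # contiguous run containing the peak
  lo <- 8; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- 8; while (hi < 21 && ok[hi + 1]) hi <- hi + 1
  expect_equal(unname(si), c(prof$cM[lo], prof$cM[hi]))
  # flat profile spans the whole chromosome
  prof$lod <- rep(5, 21)
  si2 <- support_interval(prof, "c1", 10, drop = 1.5)
  expect_equal(unname(si2), c(0, 20))
})

test_that("an injected QTL is detected at the right place with sane Var", {
  fx <- scan_fixture(seed = 10, n_lines = 163, m = 25, n_chrom = 2)
  gp <- calc_genoprob(fx$bins, fx$map)
  withr::local_seed(50)
  # choose a marker near the middle of chr2 as the QTL
  j <- which(gp$grid$chrom == "chr2" & !is.na(gp$grid$marker))[12]
  x <- 2 * gp$pBB[, j] - 1
  y <- stats::setNames(9 + 0.59 * x + rnorm(163, 0, 1.11),
                       rownames(gp$pBB))
  prof <- scan_hk(gp, y)
  thr <- permutation_threshold(gp, y, n_perm = 300, seed = 11)
  qtl <- detect_qtl(prof, thr, trait = "Rc")
  expect_gte(nrow(qtl), 1)
  expect_equal(qtl$chrom[1], "chr2")
  expect_lt(abs(qtl$peak_cM[1] - gp$grid$cM[j]), 5)
  expect_true(qtl$lo_cM[1] <= qtl$peak_cM[1] &
                qtl$peak_cM[1] <= qtl$hi_cM[1])
  fq <- fit_multiple_qtl(gp, y, qtl)
  expect_gt(fq$per_qtl$var_drop1[1], 8)
  expect_lt(fq$per_qtl$var_drop1[1], 40)
})
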