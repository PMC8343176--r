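#' Remove markers with no genotype information
#'
#' @param bins a [binned_markers()] object.
#' @return the object without markers whose calls are all missing.
#' @export
drop_null_markers <- function(bins) {
  stopifnot(inherits(bins, "binned_markers"))
  keep <- colSums(!is.na(bins$geno)) > 0L
  out <- binned_markers(bins$geno[, keep, drop = FALSE],
                        bins$markers[keep, , drop = FALSE])
  rownames(out$markers) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Conditional genotype probabilities on a cM grid
#'
#' For a selfed RIL the residual genotype is modelled as a two-state
#' {AA, BB} Markov chain along the genetic map, with inter-position
#' transition probability `R(d) = 2r/(1+2r)`, `r = kosambi_inverse(d)`
#' (heterozygous marker calls are treated as missing). Emissions allow a
#' genotyping error probability `error_prob` at scored markers. The
#' forward-backward recursion gives `P(AA)`/`P(BB)` at every grid position
#' (a regular `step_cM` lattice merged with the marker positions).
#'
#' @param bins a [binned_markers()] object.
#' @param map a `linkage_map`; markers absent from the map are ignored.
#' @param step_cM grid step, default 1 cM.
#' @param error_prob genotyping-error allowance, default 1e-4.
#' @param use_corrected use corrected cM positions when present, default
#'   TRUE.
#' @return object of class `genoprob`: list with `pBB` (lines x positions
#'   matrix of P(BB)), `grid` (data frame chrom, cM, marker label or NA).
#' @export
calc_genoprob <- function(bins, map, step_cM = 1, error_prob = 1e-4,
                          use_corrected = TRUE) {
  stopifnot(inherits(bins, "binned_markers"), inherits(map, "linkage_map"))
  cm_col <- if (use_corrected && "cM_corr" %in% names(map)) "cM_corr" else "cM"
  n <- nrow(bins$geno)
  pcols <- list(); gridrows <- list()
  for (ch in unique(map$chrom)) {
    mm <- map[map$chrom == ch, , drop = FALSE]
    mm <- mm[order(mm$order_index), , drop = FALSE]
    if (!all(mm$marker %in% colnames(bins$geno))) {
      stop("map marker absent from genotype matrix on ", ch)
    }
    cm_m <- mm[[cm_col]]
    grid <- sort(unique(c(seq(0, max(cm_m), by = step_cM), cm_m)))
    is_marker <- match(round(grid, 9), round(cm_m, 9))
    g <- bins$geno[, mm$marker, drop = FALSE]
    obs <- matrix(0L, n, length(grid))  # 0 none, 1 A, 2 B
    for (k in seq_along(cm_m)) {
      j <- which(is_marker == k)
      obs[g[, k] %in% "A", j] <- 1L
      obs[g[, k] %in% "B", j] <- 2L
    }
    e <- error_prob
    m <- length(grid)
    # emission likelihoods per position: n x 2
    lik <- function(o) cbind(ifelse(o == 0L, 1, ifelse(o == 1L, 1 - e, e)),
                             ifelse(o == 0L, 1, ifelse(o == 2L, 1 - e, e)))
    Rstep <- {
      r <- kosambi_inverse(diff(grid))
      2 * r / (1 + 2 * r)
    }
    alpha <- array(0, dim = c(n, 2, m))
    a <- matrix(0.5, n, 2) * lik(obs[, 1L])
    alpha[, , 1L] <- a / rowSums(a)
    if (m > 1L) for (t in 2:m) {
      Rt <- Rstep[t - 1L]
      prev <- matrix(alpha[, , t - 1L], n, 2)
      a <- cbind(prev[, 1L] * (1 - Rt) + prev[, 2L] * Rt,
                 prev[, 1L] * Rt + prev[, 2L] * (1 - Rt)) * lik(obs[, t])
      alpha[, , t] <- a / rowSums(a)
    }
    beta <- array(1, dim = c(n, 2, m))
    if (m > 1L) for (t in (m - 1L):1L) {
      Rt <- Rstep[t]
      nxt <- matrix(beta[, , t + 1L], n, 2) * lik(obs[, t + 1L])
      b <- cbind(nxt[, 1L] * (1 - Rt) + nxt[, 2L] * Rt,
                 nxt[, 1L] * Rt + nxt[, 2L] * (1 - Rt))
      beta[, , t] <- b / rowSums(b)
    }
    post <- alpha * beta
    pBB <- matrix(0, n, m)
    for (t in seq_len(m)) {
      pt <- matrix(post[, , t], n, 2)
      pBB[, t] <- pt[, 2L] / (pt[, 1L] + pt[, 2L])
    }
    pcols[[ch]] <- pBB
    gridrows[[ch]] <- data.frame(chrom = ch, cM = grid,
                                 marker = mm$marker[is_marker],
                                 stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, gridrows)
  rownames(grid) <- NULL
  pBB <- do.call(cbind, pcols)
  rownames(pBB) <- rownames(bins$geno)
  structure(list(pBB = pBB, grid = grid), class = "genoprob")
}

#' @export
print.genoprob <- function(x, ...) {
  cat("genoprob:", nrow(x$pBB), "lines x", ncol(x$pBB),
      "grid positions on", length(unique(x$grid$chrom)), "chromosome(s)\n")
  invisible(x)
}

## shared regression engine: LOD of [1, covar, p] against [1, covar] at
## every grid position, for a matrix of response vectors (columns).
hk_engine <- function(gprob, Y, covar = NULL, skip_cols = NULL) {
  n <- nrow(Y)
  G <- ncol(gprob$pBB)
  X0 <- cbind(rep(1, n), covar)
  q0 <- qr.Q(qr(X0))
  rss0 <- colSums(Y^2) - colSums(crossprod(q0, Y)^2)
  lod <- matrix(NA_real_, G, ncol(Y))
  eff <- rep(NA_real_, G)
  for (gpos in seq_len(G)) {
    p <- gprob$pBB[, gpos]
    X <- cbind(X0, p)
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) next
    q1 <- qr.Q(qrx)
    rss1 <- colSums(Y^2) - colSums(crossprod(q1, Y)^2)
    lod[gpos, ] <- (n / 2) * log10(rss0 / rss1)
    if (ncol(Y) == 1L) {
      beta <- qr.coef(qrx, Y[, 1L])
      eff[gpos] <- beta[length(beta)] / 2
    }
  }
  list(lod = lod, effect = eff)
}

#' Haley-Knott genome scan
#'
#' At each grid position the phenotype is regressed on the conditional
#' probability `P(BB)` (plus any covariate columns);
#' `LOD = (n/2) log10(RSS0/RSS1)` against the covariates-only null. The
#' additive effect is half the fitted difference between `p = 1` and
#' `p = 0`, so a positive effect means the B-parent allele increases the
#' trait.
#'
#' @param gprob a `genoprob` object.
#' @param values named numeric vector of line values (names matching the
#'   rownames of the probability matrix) or a vector aligned to them.
#' @param covar optional numeric matrix of covariates (no intercept).
#' @return `scan_result` data frame (chrom, cM, marker, lod, effect).
#' @export
scan_hk <- function(gprob, values, covar = NULL) {
  stopifnot(inherits(gprob, "genoprob"))
  v <- align_values(gprob, values)
  keep <- !is.na(v)
  Y <- matrix(v[keep] - mean(v[keep]))
  g2 <- gprob
  g2$pBB <- gprob$pBB[keep, , drop = FALSE]
  cv <- if (!is.null(covar)) as.matrix(covar)[keep, , drop = FALSE]
  res <- hk_engine(g2, Y, cv)
  if (anyNA(res$lod[, 1L])) {
    warning("rank-deficient design at ", sum(is.na(res$lod[, 1L])),
            " position(s); skipped")
  }
  out <- data.frame(chrom = gprob$grid$chrom, cM = gprob$grid$cM,
                    marker = gprob$grid$marker,
                    lod = res$lod[, 1L], effect = res$effect,
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  out
}

align_values <- function(gprob, values) {
  if (!is.null(names(values))) {
    v <- values[rownames(gprob$pBB)]
    if (all(is.na(v))) stop("phenotype names do not match line names")
    return(as.numeric(v))
  }
  if (length(values) != nrow(gprob$pBB)) {
    stop("phenotype length does not match line count")
  }
  as.numeric(values)
}

#' Composite interval mapping
#'
#' Cofactor markers are chosen by forward selection on single-marker
#' Haley-Knott regressions (up to `n_covar`). At each scan position,
#' cofactors within `window_cM` of the position on the same chromosome are
#' excluded, and the LOD is computed against the null carrying the same
#' retained cofactors, so a cofactor never absorbs the signal it sits on.
#'
#' @param gprob a `genoprob` object.
#' @param values line phenotype values as in [scan_hk()].
#' @param n_covar number of cofactors, default 3; refused when
#'   `n_covar >= n/5`.
#' @param window_cM exclusion window, default 10 cM.
#' @return `scan_result` data frame; chosen cofactor positions in attribute
#'   `cofactors`.
#' @export
scan_cim <- function(gprob, values, n_covar = 3L, window_cM = 10) {
  stopifnot(inherits(gprob, "genoprob"))
  v <- align_values(gprob, values)
  keep <- !is.na(v)
  n <- sum(keep)
  if (n_covar >= n / 5) stop("too many cofactors for the population size")
  y <- v[keep] - mean(v[keep])
  P <- gprob$pBB[keep, , drop = FALSE]
  marker_pos <- which(!is.na(gprob$grid$marker))
  # forward selection among marker positions
  chosen <- integer(0)
  if (n_covar > 0L) for (step in seq_len(n_covar)) {
    Xbase <- cbind(rep(1, n), P[, chosen, drop = FALSE])
    q0 <- qr.Q(qr(Xbase))
    res0 <- y - q0 %*% crossprod(q0, y)
    rss <- vapply(marker_pos, function(j) {
      if (j %in% chosen) return(Inf)
      p <- P[, j] - q0 %*% crossprod(q0, P[, j])
      ssp <- sum(p^2)
      if (ssp < 1e-12) return(Inf)
      sum(res0^2) - sum(res0 * p)^2 / ssp
    }, numeric(1))
    best <- marker_pos[which.min(rss)]
    if (!is.finite(min(rss))) break
    chosen <- c(chosen, best)
  }
  grid <- gprob$grid
  lod <- numeric(nrow(grid)); eff <- numeric(nrow(grid))
  for (gpos in seq_len(nrow(grid))) {
    excl <- grid$chrom[chosen] == grid$chrom[gpos] &
      abs(grid$cM[chosen] - grid$cM[gpos]) < window_cM
    use <- chosen[!excl]
    X0 <- cbind(rep(1, n), P[, use, drop = FALSE])
    q0 <- qr.Q(qr(X0))
    rss0 <- sum(y^2) - sum(crossprod(q0, y)^2)
    X1 <- cbind(X0, P[, gpos])
    qrx <- qr(X1)
    if (qrx$rank < ncol(X1)) { lod[gpos] <- NA_real_; next }
    q1 <- qr.Q(qrx)
    rss1 <- sum(y^2) - sum(crossprod(q1, y)^2)
    lod[gpos] <- (n / 2) * log10(rss0 / rss1)
    b <- qr.coef(qrx, y)
    eff[gpos] <- b[length(b)] / 2
  }
  out <- data.frame(chrom = grid$chrom, cM = grid$cM, marker = grid$marker,
                    lod = lod, effect = eff, stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  attr(out, "cofactors") <- grid[chosen, c("chrom", "cM", "marker")]
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype across lines `n_perm` times, records the
#' genome-wide maximum Haley-Knott LOD of each permutation, and returns the
#' `(1 - alpha)` type-7 quantile of that null distribution.
#'
#' @param gprob a `genoprob` object.
#' @param values line phenotype values.
#' @param n_perm number of permutations; default 1000 for desk use (the
#'   full-scale convention is 10000); a warning is emitted below 100.
#' @param alpha genome-wide significance level, default 0.1.
#' @param seed integer seed, recorded on the result.
#' @param covar optional covariate matrix, permuted rows kept fixed.
#' @return numeric threshold with attributes `alpha`, `n_perm`, `seed`, and
#'   `null_max` (the permutation maxima).
#' @export
permutation_threshold <- function(gprob, values, n_perm = 1000L,
                                  alpha = 0.1, seed = 1L, covar = NULL) {
  stopifnot(inherits(gprob, "genoprob"))
  if (n_perm < 100L) warning("fewer than 100 permutations: threshold noisy")
  v <- align_values(gprob, values)
  keep <- !is.na(v)
  y <- v[keep]
  set.seed(seed)
  n <- length(y)
  Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(n))
  Y <- sweep(Y, 2, colMeans(Y))
  g2 <- gprob
  g2$pBB <- gprob$pBB[keep, , drop = FALSE]
  cv <- if (!is.null(covar)) as.matrix(covar)[keep, , drop = FALSE]
  res <- hk_engine(g2, Y, cv)
  null_max <- apply(res$lod, 2, max, na.rm = TRUE)
  thr <- stats::quantile(null_max, 1 - alpha, type = 7, names = FALSE)
  attr(thr, "alpha") <- alpha
  attr(thr, "n_perm") <- n_perm
  attr(thr, "seed") <- seed
  attr(thr, "null_max") <- null_max
  thr
}

#' LOD support interval around a peak
#'
#' The widest contiguous grid interval containing the peak on which the LOD
#' stays within `drop` of the peak value.
#'
#' @param profile a `scan_result`.
#' @param peak_chrom,peak_cM peak location.
#' @param drop LOD drop, default 1.5.
#' @return numeric `c(lo_cM, hi_cM)`.
#' @export
support_interval <- function(profile, peak_chrom, peak_cM, drop = 1.5) {
  p <- profile[profile$chrom == peak_chrom, , drop = FALSE]
  p <- p[order(p$cM), , drop = FALSE]
  i <- which.min(abs(p$cM - peak_cM))
  thr <- p$lod[i] - drop
  ok <- !is.na(p$lod) & p$lod >= thr
  lo <- i; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- i; while (hi < nrow(p) && ok[hi + 1L]) hi <- hi + 1L
  c(lo_cM = p$cM[lo], hi_cM = p$cM[hi])
}

#' Detect QTL peaks above a threshold
#'
#' Iteratively takes the highest grid position above the threshold, records
#' it, and masks the contiguous above-threshold run containing it (extended
#' by `min_sep` cM) before looking for the next peak, so the shoulders of a
#' single broad peak are not reported as extra QTLs. QTLs are named by
#' trait label plus an ordinal (e.g. Rc1).
#'
#' @param profile a `scan_result`.
#' @param threshold LOD threshold.
#' @param trait trait label used for naming.
#' @param drop support-interval LOD drop, default 1.5.
#' @param min_sep minimum separation beyond the support interval, default
#'   10 cM.
#' @return data frame (name, chrom, peak_cM, lod, effect, lo_cM, hi_cM).
#' @export
detect_qtl <- function(profile, threshold, trait = "trait", drop = 1.5,
                       min_sep = 10) {
  p <- profile
  out <- list()
  repeat {
    cand <- which(!is.na(p$lod) & p$lod >= threshold)
    if (!length(cand)) break
    i <- cand[which.max(p$lod[cand])]
    si <- support_interval(profile, p$chrom[i], p$cM[i], drop = drop)
    out[[length(out) + 1L]] <- data.frame(
      chrom = p$chrom[i], peak_cM = p$cM[i], lod = p$lod[i],
      effect = p$effect[i], lo_cM = si[1L], hi_cM = si[2L],
      stringsAsFactors = FALSE)
    # mask the contiguous above-threshold run containing the peak
    run <- support_interval(p, p$chrom[i], p$cM[i],
                            drop = p$lod[i] - threshold)
    mask <- p$chrom == p$chrom[i] &
      p$cM >= min(run[1L], si[1L]) - min_sep &
      p$cM <= max(run[2L], si[2L]) + min_sep
    p$lod[mask] <- NA_real_
  }
  if (!length(out)) {
    return(data.frame(name = character(), chrom = character(),
                      peak_cM = numeric(), lod = numeric(),
                      effect = numeric(), lo_cM = numeric(),
                      hi_cM = numeric()))
  }
  res <- do.call(rbind, out)
  # ordinals by decreasing significance: <trait>1 is the strongest peak
  res$name <- paste0(trait, rank(-res$lod, ties.method = "first"))
  res <- res[order(res$chrom, res$peak_cM), , drop = FALSE]
  rownames(res) <- NULL
  res[c("name", "chrom", "peak_cM", "lod", "effect", "lo_cM", "hi_cM")]
}

#' Percent variance explained from a multiple-QTL model
#'
#' Fits the joint linear model with one additive term (the conditional
#' `P(BB)`) per QTL at its peak. Reports the overall model R-squared x 100
#' and, per QTL, both the drop-one decrease in R-squared x 100 (type-III
#' style) and the marginal single-term R-squared x 100. Peaks closer than
#' 1 cM on the same chromosome are merged first.
#'
#' @param gprob a `genoprob` object.
#' @param values line phenotype values.
#' @param peaks data frame with columns `chrom`, `peak_cM` (e.g. from
#'   [detect_qtl()]).
#' @return list (overall_var, per_qtl = data frame chrom, peak_cM,
#'   var_drop1, var_marginal).
#' @export
fit_multiple_qtl <- function(gprob, values, peaks) {
  stopifnot(inherits(gprob, "genoprob"), nrow(peaks) >= 1L)
  # merge collinear peaks
  peaks <- peaks[order(peaks$chrom, peaks$peak_cM), , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))[-1L]) {
    if (peaks$chrom[i] == peaks$chrom[i - 1L] &&
        abs(peaks$peak_cM[i] - peaks$peak_cM[i - 1L]) < 1) keep[i] <- FALSE
  }
  peaks <- peaks[keep, , drop = FALSE]
  v <- align_values(gprob, values)
  ok <- !is.na(v)
  y <- v[ok]
  cols <- vapply(seq_len(nrow(peaks)), function(k) {
    sel <- gprob$grid$chrom == peaks$chrom[k]
    j <- which(sel)[which.min(abs(gprob$grid$cM[sel] - peaks$peak_cM[k]))]
    j
  }, integer(1))
  X <- gprob$pBB[ok, cols, drop = FALSE]
  r2 <- function(Xm) {
    f <- stats::lm.fit(cbind(1, Xm), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  full <- r2(X)
  per <- data.frame(chrom = peaks$chrom, peak_cM = peaks$peak_cM,
                    var_drop1 = NA_real_, var_marginal = NA_real_)
  for (k in seq_len(nrow(peaks))) {
    per$var_drop1[k] <- 100 * (full - if (nrow(peaks) > 1L)
      r2(X[, -k, drop = FALSE]) else 0)
    per$var_marginal[k] <- 100 * r2(X[, k, drop = FALSE])
  }
  list(overall_var = 100 * full, per_qtl = per)
}
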