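#' Per-line light response relative to dark
#'
#' Hypocotyl inhibition is standardised across genotypes as the ratio of a
#' line's mean length under a light treatment to its mean length in the
#' dark. Ratios are computed from per-line means, not paired replicates:
#' dark-grown and light-grown seedlings are different individuals.
#'
#' @param pheno a `pheno_table` (line, trait, replicate, value).
#' @param trait the light trait (e.g. "Rc").
#' @param dark_trait name of the dark control trait, default "dark".
#' @return data frame (line, mean_light, mean_dark, ratio); lines without a
#'   dark mean get NA with a warning.
#' @export
relative_to_dark <- function(pheno, trait, dark_trait = "dark") {
  stopifnot(inherits(pheno, "data.frame"))
  if (!dark_trait %in% pheno$trait) stop("dark trait absent from table")
  ml <- tapply(pheno$value[pheno$trait == trait],
               pheno$line[pheno$trait == trait], mean)
  md <- tapply(pheno$value[pheno$trait == dark_trait],
               pheno$line[pheno$trait == dark_trait], mean)
  lines <- names(ml)
  dark <- md[lines]
  if (anyNA(dark)) warning("lines without a dark mean: ratio set to NA")
  data.frame(line = lines, mean_light = as.numeric(ml),
             mean_dark = as.numeric(dark),
             ratio = as.numeric(ml / dark),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variance components and broad-sense heritability from one-way ANOVA
#'
#' Fits the one-way by-line ANOVA and reports the among-line mean square
#' (MSG), the residual mean square (MSE), the genotypic variance
#' `GV = (MSG - MSE)/r`, the phenotypic variance `PV = MSG/r`, and the
#' broad-sense heritability `H2 = GV/PV` clamped to `[0, 1]`. For
#' unbalanced designs `r` is the effective replicate number
#' `r0 = (N - sum(n_i^2)/N)/(g - 1)`.
#'
#' @param pheno a `pheno_table`.
#' @param trait trait to analyse.
#' @return list (MSG, MSE, r, GV, PV, H2, n_lines, n_obs).
#' @export
anova_components <- function(pheno, trait) {
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("trait not present: ", trait)
  d$line <- factor(d$line)
  g <- nlevels(d$line)
  if (g < 2L) stop("need at least two lines for MSG")
  fit <- stats::aov(value ~ line, data = d)
  tab <- summary(fit)[[1L]]
  MSG <- tab["line", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  ni <- as.numeric(table(d$line))
  N <- sum(ni)
  r0 <- (N - sum(ni^2) / N) / (g - 1)
  GV <- max((MSG - MSE) / r0, 0)
  PV <- MSG / r0
  H2 <- min(max(GV / PV, 0), 1)
  list(MSG = MSG, MSE = MSE, r = r0, GV = GV, PV = PV, H2 = H2,
       n_lines = g, n_obs = N)
}

#' Box-Cox power transform with profile-likelihood lambda
#'
#' Maximises the Box-Cox profile log-likelihood on a grid over `[-2, 2]`
#' (step 0.05) and refines the optimum with golden-section search
#' ([stats::optimize()]) inside the best grid cell. The transform is
#' `(y^lambda - 1)/lambda` for nonzero lambda and `log(y)` at zero.
#'
#' @param values strictly positive numeric vector.
#' @param grid lambda grid, default `seq(-2, 2, by = 0.05)`.
#' @return list (lambda, transformed, profile = data.frame(lambda, loglik)).
#' @export
boxcox_transform <- function(values, grid = seq(-2, 2, by = 0.05)) {
  values <- values[!is.na(values)]
  if (any(values <= 0)) stop("Box-Cox requires strictly positive values")
  n <- length(values)
  logy <- log(values)
  prof <- function(lam) {
    z <- if (abs(lam) < 1e-12) logy else (values^lam - 1) / lam
    -n / 2 * log(sum((z - mean(z))^2) / n) + (lam - 1) * sum(logy)
  }
  ll <- vapply(grid, prof, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE)
  lam <- opt$maximum
  transformed <- if (abs(lam) < 1e-12) logy else (values^lam - 1) / lam
  list(lambda = lam, transformed = transformed,
       profile = data.frame(lambda = grid, loglik = ll))
}

#' Per-line BLUEs and BLUPs
#'
#' BLUEs are the fixed-effect line means. BLUPs come from the one-way random
#' intercept model `value ~ 1 + (1 | line)` fitted by REML via \pkg{lme4};
#' for balanced data this equals the shrinkage estimate
#' `mu + (sg2 / (sg2 + se2/n_i)) (line mean - mu)`. If the mixed fit fails
#' to converge, a method-of-moments fallback applies that shrinkage formula
#' with ANOVA-derived components.
#'
#' @param pheno a `pheno_table`.
#' @param trait trait to analyse.
#' @param transform optional function applied to values first (e.g. the
#'   Box-Cox transform); default identity.
#' @return data frame (line, n, mean, blue, blup).
#' @export
blue_blup <- function(pheno, trait, transform = identity) {
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!nrow(d)) stop("trait not present: ", trait)
  d$value <- transform(d$value)
  d$line <- factor(d$line)
  means <- tapply(d$value, d$line, mean)
  ni <- as.numeric(table(d$line))
  if (any(ni == 0L)) stop("line with zero replicates")
  blup <- tryCatch({
    fit <- lme4::lmer(value ~ 1 + (1 | line), data = d,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    stats::coef(fit)$line[levels(d$line), "(Intercept)"]
  }, error = function(e) NULL)
  if (is.null(blup)) {
    vc <- anova_components(structure(d, class = c("pheno_table", "data.frame")),
                           trait)
    sg2 <- max((vc$MSG - vc$MSE) / vc$r, 0)
    se2 <- vc$MSE
    mu <- mean(d$value)
    shrink <- sg2 / (sg2 + se2 / ni)
    blup <- mu + shrink * (means - mu)
  }
  data.frame(line = levels(d$line), n = ni, mean = as.numeric(means),
             blue = as.numeric(means), blup = as.numeric(blup),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher's LSD letter groups
#'
#' All pairwise two-sample t tests on the pooled residual mean square from
#' the one-way ANOVA (Fisher's least significant difference, no multiplicity
#' adjustment), with letters assigned by insert-and-absorb so that any two
#' groups sharing no letter differ at the chosen level.
#'
#' @param pheno a `pheno_table` restricted to the groups of interest, with
#'   the grouping labels in `line` (or supply `group_col`).
#' @param trait trait to analyse.
#' @param alpha significance level, default 0.05.
#' @param group_col column holding group labels, default "line".
#' @return data frame (group, mean, se, letters), ordered by decreasing
#'   mean; the logical significance matrix is attached as attribute
#'   `sig_matrix`.
#' @export
lsd_groups <- function(pheno, trait, alpha = 0.05, group_col = "line") {
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  d$group <- factor(d[[group_col]])
  g <- nlevels(d$group)
  if (g < 2L) stop("need at least two groups")
  fit <- stats::aov(value ~ group, data = d)
  MSE <- summary(fit)[[1L]]["Residuals", "Mean Sq"]
  dfe <- stats::df.residual(fit)
  means <- tapply(d$value, d$group, mean)
  ni <- as.numeric(table(d$group))
  se <- sqrt(MSE / ni)
  o <- order(means, decreasing = TRUE)
  means <- means[o]; ni <- ni[o]; se <- se[o]
  labs <- names(means)
  sig <- matrix(FALSE, g, g, dimnames = list(labs, labs))
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    tstat <- (means[i] - means[j]) / sqrt(MSE * (1 / ni[i] + 1 / ni[j]))
    p <- 2 * stats::pt(-abs(tstat), dfe)
    sig[i, j] <- sig[j, i] <- p < alpha
  }
  letters <- assign_letters(sig)
  data.frame(group = labs, mean = as.numeric(means), se = as.numeric(se),
             letters = letters, row.names = NULL,
             stringsAsFactors = FALSE) -> res
  attr(res, "sig_matrix") <- sig
  res
}

## insert-and-absorb letter assignment: groups are in decreasing-mean order;
## sig[i, j] TRUE means i and j differ significantly.
assign_letters <- function(sig) {
  g <- nrow(sig)
  # columns of `member` are letter classes (sets of mutually non-different
  # groups covering all non-significant pairs)
  classes <- list(seq_len(g))
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    if (!sig[i, j]) next
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (k in seq_along(classes)) {
        if (i %in% classes[[k]] && j %in% classes[[k]]) {
          a <- setdiff(classes[[k]], i)
          b <- setdiff(classes[[k]], j)
          classes[[k]] <- a
          classes[[length(classes) + 1L]] <- b
          changed <- TRUE
          break
        }
      }
    }
  }
  # absorb classes contained in others
  keep <- rep(TRUE, length(classes))
  for (k in seq_along(classes)) for (l in seq_along(classes)) {
    if (k != l && keep[k] && keep[l] &&
        all(classes[[k]] %in% classes[[l]])) {
      if (length(classes[[k]]) < length(classes[[l]]) || k > l) keep[k] <- FALSE
    }
  }
  classes <- classes[keep]
  # order classes by their first (highest-mean) member for stable letters
  classes <- classes[order(vapply(classes, min, numeric(1)))]
  out <- character(g)
  for (k in seq_along(classes)) {
    for (i in classes[[k]]) out[i] <- paste0(out[i], letters[k])
  }
  out
}
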