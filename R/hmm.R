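#' Hidden Markov model parameters for RIL genotype inference
#'
#' The chain runs along each chromosome over hidden states {AA, HET, BB} with
#' observations {A, H, B, missing} at diagnostic SNPs. Emissions mirror the
#' low-depth observation model: a homozygous state is called correctly with
#' probability `1 - call_error` and flipped otherwise (a tiny floor keeps the
#' heterozygous observation possible, avoiding -Inf path scores); a
#' heterozygous state is sampled as a single allele with probability
#' `het_miscall`, split evenly between the two homozygous calls. The
#' transition kernel over a physical gap of d bp leaves the current state
#' with probability `1 - exp(-switch_rate * d)`; transitions into HET are
#' down-weighted by `kappa` because heterozygous tracts are rare at F6. The
#' initial distribution puts mass `het_init` on HET (the expected residual
#' heterozygosity, (1/2)^generations for selfing) and the rest evenly on the
#' homozygous states.
#'
#' @param call_error probability a called homozygous allele is wrong.
#' @param het_miscall probability a heterozygous site is called homozygous.
#' @param switch_rate expected state switches per bp; either a scalar or a
#'   named vector per chromosome. For an F6 RIL the expected number of
#'   apparent breakpoints per chromosome is about twice the per-meiosis map
#'   length in Morgans (map expansion under selfing), so the default for a
#'   chromosome of physical length L and meiotic length m Morgans is
#'   `2 * m / L`; see [switch_rate_for()].
#' @param kappa down-weight for transitions entering the HET state.
#' @param het_init initial probability of HET, default `(1/2)^5` for F6.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(call_error = 0.01, het_miscall = 0.5,
                       switch_rate = 8e-8, kappa = 0.1,
                       het_init = 0.5^5) {
  stopifnot(call_error >= 0, call_error <= 1,
            het_miscall >= 0, het_miscall <= 1,
            all(switch_rate >= 0), kappa >= 0,
            het_init >= 0, het_init < 1)
  structure(list(call_error = call_error, het_miscall = het_miscall,
                 switch_rate = switch_rate, kappa = kappa,
                 het_init = het_init),
            class = "hmm_params")
}

#' Per-chromosome switch rate from map and physical lengths
#'
#' @param map_length_cM per-meiosis map length(s), cM.
#' @param chrom_length_bp physical length(s), bp.
#' @param expansion apparent-breakpoint expansion factor for inbred lines
#'   (default 2, the selfed-RIL limit).
#' @return expected switches per bp (named like the inputs).
#' @export
switch_rate_for <- function(map_length_cM, chrom_length_bp, expansion = 2) {
  expansion * (map_length_cM / 100) / chrom_length_bp
}

## Emission matrix: rows = observation code (1 A, 2 H, 3 B, 4 missing),
## cols = hidden state (AA, HET, BB). Probabilities, not logs.
emission_matrix <- function(p) {
  eps <- p$call_error
  eta <- p$het_miscall
  floor_h <- 1e-6
  e_AA <- c(1 - eps - floor_h, floor_h, eps)
  e_HET <- c(eta / 2, 1 - eta, eta / 2)
  e_BB <- c(eps, floor_h, 1 - eps - floor_h)
  rbind(A = c(e_AA[1], e_HET[1], e_BB[1]),
        H = c(e_AA[2], e_HET[2], e_BB[2]),
        B = c(e_AA[3], e_HET[3], e_BB[3]),
        miss = c(1, 1, 1))
}

## 3x3 transition matrix over a gap of d bp.
transition_matrix <- function(p, d, rate) {
  leave <- 1 - exp(-rate * d)
  k <- p$kappa
  t_AA <- c(1 - leave, leave * k / (1 + k), leave / (1 + k))
  t_HET <- c(leave / 2, 1 - leave, leave / 2)
  t_BB <- c(leave / (1 + k), leave * k / (1 + k), 1 - leave)
  rbind(t_AA, t_HET, t_BB)
}

init_probs <- function(p) {
  h <- p$het_init
  c((1 - h) / 2, h, (1 - h) / 2)
}

obs_codes <- function(x) {
  o <- match(x, c("A", "H", "B"))
  o[is.na(o)] <- 4L
  o
}

## Vectorised Viterbi over all lines of one chromosome.
## obs: n x m matrix of codes 1..4; gaps: length m-1 bp gaps.
viterbi_chrom <- function(obs, gaps, params, rate) {
  n <- nrow(obs); m <- ncol(obs)
  logE <- log(emission_matrix(params))
  logPi <- log(init_probs(params))
  delta <- matrix(logPi, n, 3, byrow = TRUE) + logE[obs[, 1L], , drop = FALSE]
  psi <- array(0L, dim = c(n, 3, m))
  for (t in seq_len(m)[-1L]) {
    logT <- log(transition_matrix(params, gaps[t - 1L], rate))
    newd <- matrix(0, n, 3)
    for (s in 1:3) {
      cand <- delta + matrix(logT[, s], n, 3, byrow = TRUE)
      best <- max.col(cand, ties.method = "first")
      psi[, s, t] <- best
      newd[, s] <- cand[cbind(seq_len(n), best)]
    }
    delta <- newd + logE[obs[, t], , drop = FALSE]
  }
  path <- matrix(0L, n, m)
  path[, m] <- max.col(delta, ties.method = "first")
  if (m > 1L) for (t in m:2L) {
    path[, t - 1L] <- psi[cbind(seq_len(n), path[, t], t)]
  }
  list(path = path, logprob = delta[cbind(seq_len(n), path[, m])])
}

## Forward-backward posteriors for one chromosome; returns n x 3 x m array.
forward_backward_chrom <- function(obs, gaps, params, rate) {
  n <- nrow(obs); m <- ncol(obs)
  E <- emission_matrix(params)
  pi0 <- init_probs(params)
  alpha <- array(0, dim = c(n, 3, m))
  beta <- array(0, dim = c(n, 3, m))
  sc <- matrix(0, n, m)
  a <- matrix(pi0, n, 3, byrow = TRUE) * E[obs[, 1L], , drop = FALSE]
  sc[, 1L] <- rowSums(a)
  alpha[, , 1L] <- a / sc[, 1L]
  for (t in seq_len(m)[-1L]) {
    Tm <- transition_matrix(params, gaps[t - 1L], rate)
    a <- (alpha[, , t - 1L] %*% Tm) * E[obs[, t], , drop = FALSE]
    sc[, t] <- rowSums(a)
    alpha[, , t] <- a / sc[, t]
  }
  beta[, , m] <- 1
  if (m > 1L) for (t in (m - 1L):1L) {
    Tm <- transition_matrix(params, gaps[t], rate)
    b <- (beta[, , t + 1L] * E[obs[, t + 1L], , drop = FALSE]) %*% t(Tm)
    beta[, , t] <- b / rowSums(b)
  }
  post <- alpha * beta
  for (t in seq_len(m)) post[, , t] <- post[, , t] / rowSums(post[, , t])
  list(posterior = post, loglik = rowSums(log(sc)))
}

#' Score a single hidden-state path under the genotype HMM
#'
#' Utility for validation: returns the joint log-probability of a given
#' state path and observation sequence for one line on one chromosome.
#'
#' @param obs character vector of observed calls ("A","H","B",NA).
#' @param path integer vector of hidden states (1 AA, 2 HET, 3 BB).
#' @param gaps bp gaps between adjacent sites (length `length(obs) - 1`).
#' @param params an [hmm_params()].
#' @param rate switch rate per bp for this chromosome.
#' @return log joint probability.
#' @export
hmm_path_loglik <- function(obs, path, gaps, params, rate) {
  o <- obs_codes(obs)
  logE <- log(emission_matrix(params))
  lp <- log(init_probs(params))[path[1L]] + logE[o[1L], path[1L]]
  if (length(o) > 1L) for (t in 2:length(o)) {
    Tm <- transition_matrix(params, gaps[t - 1L], rate)
    lp <- lp + log(Tm[path[t - 1L], path[t]]) + logE[o[t], path[t]]
  }
  unname(lp)
}

#' Infer RIL genotypes along chromosomes with a hidden Markov model
#'
#' Decodes each line's state sequence over the diagnostic SNPs of each
#' chromosome, imputing a state at every SNP including unobserved ones.
#' Viterbi decoding (the default) returns the jointly most probable path;
#' posterior decoding returns the per-site marginal argmax and attaches the
#' marginal probability of the chosen state. Lines with no non-missing call
#' on a chromosome are returned all-NA there.
#'
#' @param calls a [genotype_matrix()] of observed calls in parental space
#'   (from [project_to_parental()]), codes "A"/"H"/"B"/NA.
#' @param params an [hmm_params()].
#' @param method "viterbi" or "posterior".
#' @return a [genotype_matrix()] of inferred genotypes; Viterbi path log
#'   probabilities (per line per chromosome) are attached as attribute
#'   `path_loglik`; posterior decoding attaches a `posterior` matrix of the
#'   chosen-state marginals.
#' @export
infer_genotypes <- function(calls, params = hmm_params(),
                            method = c("viterbi", "posterior")) {
  stopifnot(inherits(calls, "genotype_matrix"))
  method <- match.arg(method)
  if (ncol(calls$geno) == 0L) stop("empty diagnostic SNP set")
  loci <- calls$loci
  chroms <- unique(loci$chrom)
  n <- nrow(calls$geno)
  out <- matrix(NA_character_, n, ncol(calls$geno),
                dimnames = dimnames(calls$geno))
  postm <- if (method == "posterior") matrix(NA_real_, n, ncol(calls$geno))
  ll <- matrix(NA_real_, n, length(chroms), dimnames = list(NULL, chroms))
  codes <- c("A", "H", "B")
  for (ch in chroms) {
    j <- which(loci$chrom == ch)
    rate <- if (length(params$switch_rate) > 1L) {
      if (!ch %in% names(params$switch_rate)) {
        stop("no switch rate for chromosome ", ch)
      }
      params$switch_rate[[ch]]
    } else params$switch_rate
    obs <- matrix(obs_codes(calls$geno[, j, drop = FALSE]), n, length(j))
    gaps <- diff(loci$pos[j])
    has_data <- rowSums(obs != 4L) > 0L
    if (!any(has_data)) next
    ob <- obs[has_data, , drop = FALSE]
    if (method == "viterbi") {
      v <- viterbi_chrom(ob, gaps, params, rate)
      out[has_data, j] <- codes[v$path]
      ll[has_data, ch] <- v$logprob
    } else {
      fb <- forward_backward_chrom(ob, gaps, params, rate)
      dec <- apply(fb$posterior, c(1, 3), which.max)
      out[has_data, j] <- codes[dec]
      pm <- apply(fb$posterior, c(1, 3), max)
      postm[has_data, j] <- pm
      ll[has_data, ch] <- fb$loglik
    }
  }
  gm <- genotype_matrix(out, loci)
  attr(gm, "path_loglik") <- ll
  if (method == "posterior") attr(gm, "posterior") <- postm
  gm
}

#' Posterior state marginals from the genotype HMM
#'
#' Forward-backward marginals for QC: at every site the three state
#' probabilities sum to one.
#'
#' @param calls observed calls as in [infer_genotypes()].
#' @param params an [hmm_params()].
#' @return list per chromosome of arrays lines x 3 x sites.
#' @export
genotype_posteriors <- function(calls, params = hmm_params()) {
  stopifnot(inherits(calls, "genotype_matrix"))
  loci <- calls$loci
  res <- list()
  for (ch in unique(loci$chrom)) {
    j <- which(loci$chrom == ch)
    rate <- if (length(params$switch_rate) > 1L) params$switch_rate[[ch]]
      else params$switch_rate
    obs <- matrix(obs_codes(calls$geno[, j, drop = FALSE]),
                  nrow(calls$geno), length(j))
    fb <- forward_backward_chrom(obs, diff(loci$pos[j]), params, rate)
    res[[ch]] <- fb$posterior
  }
  res
}

#' Filter loci by population allele frequency
#'
#' Keeps loci whose A-parent allele frequency among non-missing homozygous
#' calls lies in `[lo, hi]` (boundary inclusive). Heterozygous calls do not
#' enter the tally. Per-chromosome overrides allow relaxed thresholds, as
#' used for a chromosome with known segregation distortion.
#'
#' @param geno a [genotype_matrix()].
#' @param lo,hi frequency bounds, default 0.40 and 0.60.
#' @param overrides optional named list `list(chr4 = c(0.2, 0.8))` of
#'   per-chromosome bounds.
#' @return the filtered [genotype_matrix()]; number of removed loci in
#'   attribute `n_removed`.
#' @export
filter_population_frequency <- function(geno, lo = 0.40, hi = 0.60,
                                        overrides = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (nrow(geno$geno) < 2L) stop("need at least two lines")
  nA <- colSums(geno$geno == "A", na.rm = TRUE)
  nB <- colSums(geno$geno == "B", na.rm = TRUE)
  freq <- ifelse(nA + nB > 0, nA / (nA + nB), NA_real_)
  lo_v <- rep(lo, ncol(geno$geno))
  hi_v <- rep(hi, ncol(geno$geno))
  if (!is.null(overrides)) {
    for (ch in names(overrides)) {
      sel <- geno$loci$chrom == ch
      lo_v[sel] <- overrides[[ch]][1L]
      hi_v[sel] <- overrides[[ch]][2L]
    }
  }
  keep <- !is.na(freq) & freq >= lo_v & freq <= hi_v
  out <- genotype_matrix(geno$geno[, keep, drop = FALSE],
                         geno$loci[keep, , drop = FALSE])
  attr(out, "freq") <- freq[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}
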