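#' Configuration for a simulated RIL population
#'
#' Bundles the design of a simulated biparental recombinant inbred line (RIL)
#' population derived by single-seed descent: population and genome size, the
#' meiotic map length driving crossover counts, the number of selfing rounds
#' (5 rounds of selfing after the F1 gives an F6 population), and the
#' observation model for low-depth sequencing-derived variant calls.
#'
#' @param n_lines number of RILs.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp physical length per chromosome (recycled to
#'   `n_chromosomes`).
#' @param map_length_cM meiotic (per-meiosis) genetic length per chromosome in
#'   centiMorgans; crossover counts per meiosis are Poisson with this mean in
#'   Morgans (no interference, no obligate chiasma).
#' @param selfing_generations rounds of selfing after the F1 (default 5, F6).
#' @param n_snps_per_chrom number of segregating SNPs per chromosome.
#' @param mean_depth expected sequencing calls per SNP per line; a site is
#'   observed unless its Poisson read count is zero, so the missing fraction
#'   is `exp(-mean_depth)`.
#' @param call_error probability a called homozygous allele is wrong.
#' @param het_miscall probability a truly heterozygous site is called
#'   homozygous (one allele sampled), as happens at depth 1.
#' @param distortion optional list `(chrom, start_bp, end_bp, s, favored)`
#'   applying viability selection with coefficient `s` in `[0,1)` favouring
#'   parental allele `favored` ("A" or "B") at the focal locus (the region
#'   midpoint) during every selfing generation; linked sites hitchhike.
#' @param seed integer seed recorded in the config and used by the simulation
#'   entry points.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 163L,
                       n_chromosomes = 5L,
                       chrom_length_bp = 2e7,
                       map_length_cM = 80,
                       selfing_generations = 5L,
                       n_snps_per_chrom = 8000L,
                       mean_depth = 0.5,
                       call_error = 0.01,
                       het_miscall = 0.5,
                       distortion = NULL,
                       seed = 1L) {
  stopifnot(n_lines >= 1, n_chromosomes >= 1, selfing_generations >= 0)
  chrom_length_bp <- rep_len(as.numeric(chrom_length_bp), n_chromosomes)
  map_length_cM <- rep_len(as.numeric(map_length_cM), n_chromosomes)
  if (any(chrom_length_bp <= 0)) stop("chromosome lengths must be positive")
  if (any(map_length_cM < 0)) stop("map lengths must be non-negative")
  if (n_snps_per_chrom < 1) stop("need at least one SNP per chromosome")
  for (p in c(mean_depth, call_error, het_miscall)) {
    if (p < 0) stop("rates must be non-negative")
  }
  if (call_error > 1 || het_miscall > 1) stop("probabilities must be in [0,1]")
  if (!is.null(distortion)) {
    stopifnot(is.list(distortion),
              all(c("chrom", "start_bp", "end_bp", "s") %in% names(distortion)))
    if (distortion$s < 0 || distortion$s >= 1) {
      stop("selection coefficient must be in [0,1)")
    }
    if (is.null(distortion$favored)) distortion$favored <- "A"
    stopifnot(distortion$favored %in% c("A", "B"))
  }
  structure(list(n_lines = as.integer(n_lines),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = chrom_length_bp,
                 map_length_cM = map_length_cM,
                 selfing_generations = as.integer(selfing_generations),
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 mean_depth = mean_depth,
                 call_error = call_error,
                 het_miscall = het_miscall,
                 distortion = distortion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

chrom_names <- function(n) paste0("chr", seq_len(n))

## A haplotype is a mosaic of the two parental genomes, stored as internal
## breakpoints (ascending, exclusive of 0 and L) plus one parental label per
## segment (0 = parent A, 1 = parent B).
hap_eval <- function(hap, pos) {
  hap$lab[findInterval(pos, hap$brk) + 1L]
}

hap_simplify <- function(hap) {
  if (length(hap$brk) == 0L) return(hap)
  keep <- hap$lab[-1L] != hap$lab[-length(hap$lab)]
  list(brk = hap$brk[keep], lab = c(hap$lab[1L], hap$lab[-1L][keep]))
}

## One meiotic product of a diplotype (h1, h2): crossover count is Poisson
## with mean equal to the map length in Morgans, positions uniform on (0, L).
gamete <- function(h1, h2, len_bp, map_morgans) {
  k <- stats::rpois(1L, map_morgans)
  xo <- if (k > 0L) sort(stats::runif(k, 0, len_bp)) else numeric(0)
  start <- sample.int(2L, 1L)
  brk <- sort(unique(c(h1$brk, h2$brk, xo)))
  mid <- (c(0, brk) + c(brk, len_bp)) / 2
  src <- (start - 1L + findInterval(mid, xo)) %% 2L  # 0 -> h1, 1 -> h2
  lab <- ifelse(src == 0L, hap_eval(h1, mid), hap_eval(h2, mid))
  hap_simplify(list(brk = brk, lab = lab))
}

diplo_genotype_at <- function(h1, h2, pos) {
  hap_eval(h1, pos) + hap_eval(h2, pos)  # 0 = AA, 1 = het, 2 = BB
}

#' Simulate RIL genomes by iterated meiosis and single-seed descent
#'
#' Starting from an F1 (one chromosome from each fully inbred parent), each
#' line is selfed for `selfing_generations` rounds with single-seed descent.
#' Per meiosis, crossover counts per chromosome are Poisson with mean equal to
#' the meiotic map length in Morgans and positions are uniform (Haldane
#' process, no interference). If the config carries a `distortion` block,
#' offspring survive each generation with genotype-dependent viability at the
#' focal locus, producing a chromosome-arm scale allele-frequency cline by
#' hitchhiking.
#'
#' @param config a [sim_config()].
#' @return a `truth_set` list with elements `genotypes` (a
#'   [genotype_matrix()] of the true genotypes, codes "A"/"B"/"H", at every
#'   simulated SNP), `breakpoints` (per line, per chromosome, positions where
#'   the diplotype genotype changes), `loci` (data frame chrom/pos/a_is_ref),
#'   and the `config`.
#' @export
simulate_ril_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_chromosomes
  cn <- chrom_names(nc)
  loci <- do.call(rbind, lapply(seq_len(nc), function(ci) {
    pos <- sort(sample.int(config$chrom_length_bp[ci], config$n_snps_per_chrom))
    data.frame(chrom = cn[ci], pos = pos)
  }))
  loci$a_is_ref <- stats::runif(nrow(loci)) < 0.5

  dist <- config$distortion
  focal <- NULL
  if (!is.null(dist)) {
    focal <- list(ci = match(dist$chrom, cn),
                  pos = (dist$start_bp + dist$end_bp) / 2,
                  s = dist$s,
                  fav = if (dist$favored == "A") 0L else 2L)
    if (is.na(focal$ci)) stop("distortion chromosome not simulated")
  }

  map_M <- config$map_length_cM / 100
  len <- config$chrom_length_bp
  geno <- matrix(NA_integer_, config$n_lines, nrow(loci))
  breakpoints <- vector("list", config$n_lines)
  pos_by_chrom <- split(loci$pos, factor(loci$chrom, levels = cn))
  idx_by_chrom <- split(seq_len(nrow(loci)), factor(loci$chrom, levels = cn))

  hap_a <- list(brk = numeric(0), lab = 0L)
  hap_b <- list(brk = numeric(0), lab = 1L)

  for (l in seq_len(config$n_lines)) {
    plant <- lapply(seq_len(nc), function(ci) list(h1 = hap_a, h2 = hap_b))
    for (g in seq_len(config$selfing_generations)) {
      repeat {
        offspring <- lapply(seq_len(nc), function(ci) {
          list(h1 = gamete(plant[[ci]]$h1, plant[[ci]]$h2, len[ci], map_M[ci]),
               h2 = gamete(plant[[ci]]$h1, plant[[ci]]$h2, len[ci], map_M[ci]))
        })
        if (is.null(focal)) break
        gt <- diplo_genotype_at(offspring[[focal$ci]]$h1,
                                offspring[[focal$ci]]$h2, focal$pos)
        w <- if (gt == focal$fav) 1 else if (gt == 1L) 1 - focal$s / 2 else
          1 - focal$s
        if (stats::runif(1) < w) break
      }
      plant <- offspring
    }
    bps <- vector("list", nc)
    names(bps) <- cn
    for (ci in seq_len(nc)) {
      h1 <- plant[[ci]]$h1; h2 <- plant[[ci]]$h2
      geno[l, idx_by_chrom[[ci]]] <- diplo_genotype_at(h1, h2,
                                                       pos_by_chrom[[ci]])
      brk <- sort(unique(c(h1$brk, h2$brk)))
      if (length(brk)) {
        mid <- (c(0, brk) + c(brk, len[ci])) / 2
        gt <- diplo_genotype_at(h1, h2, mid)
        brk <- brk[gt[-1L] != gt[-length(gt)]]
      }
      bps[[ci]] <- brk
    }
    breakpoints[[l]] <- bps
  }

  codes <- c("A", "H", "B")
  gmat <- matrix(codes[geno + 1L], nrow(geno), ncol(geno))
  rownames(gmat) <- sprintf("RIL%03d", seq_len(config$n_lines))
  gm <- genotype_matrix(gmat, loci[c("chrom", "pos")])
  structure(list(genotypes = gm, breakpoints = breakpoints, loci = loci,
                 config = config),
            class = "truth_set")
}

#' Simulate low-depth variant calls from a truth set
#'
#' Observes each SNP x line with probability `1 - exp(-mean_depth)` (the
#' Poisson zero class is missing), flips homozygous calls with probability
#' `call_error`, and calls truly heterozygous sites homozygous (a single
#' sampled allele) with probability `het_miscall`. Parental libraries are
#' simulated as `n_parent_libs` replicate homozygous libraries per parent
#' under the same observation model. Calls are reported in REF/ALT space
#' ("0" = hom-ref, "1" = hom-alt, "H", NA) using the per-SNP `a_is_ref`
#' orientation of the truth set, as a variant caller would.
#'
#' @param truth a `truth_set` from [simulate_ril_genomes()].
#' @param config the [sim_config()]; defaults to the one inside `truth`.
#' @param n_parent_libs replicate libraries per parent (default 3).
#' @param parent_depth expected calls per SNP for parental libraries
#'   (default `10 * mean_depth`, parents are usually sequenced deeper).
#' @return list with `ril` (a [variant_table()] of RIL calls) and `parents`
#'   (a [variant_table()] of parental library calls, libraries named
#'   `PA_1.. / PB_1..`).
#' @export
simulate_variant_calls <- function(truth, config = truth$config,
                                   n_parent_libs = 3L,
                                   parent_depth = 10 * config$mean_depth) {
  stopifnot(inherits(truth, "truth_set"))
  set.seed(config$seed + 1L)
  loci <- truth$loci
  gmat <- truth$genotypes$geno
  n <- nrow(gmat); m <- ncol(gmat)

  corrupt <- function(truth_codes, depth) {
    # truth_codes: character matrix in A/H/B space
    obs <- matrix(stats::runif(length(truth_codes)) <
                    (1 - exp(-depth)), nrow(truth_codes))
    out <- truth_codes
    is_h <- out == "H"
    mis <- is_h & (stats::runif(length(out)) < config$het_miscall)
    out[mis] <- ifelse(stats::runif(sum(mis)) < 0.5, "A", "B")
    hom <- out %in% c("A", "B")
    flip <- hom & (stats::runif(length(out)) < config$call_error)
    out[flip] <- ifelse(out[flip] == "A", "B", "A")
    out[!obs] <- NA_character_
    out
  }
  to_refalt <- function(mat) {
    out <- mat
    a_ref <- matrix(rep(loci$a_is_ref, each = nrow(mat)), nrow(mat))
    iA <- which(mat == "A"); iB <- which(mat == "B")
    out[iA] <- ifelse(a_ref[iA], "0", "1")
    out[iB] <- ifelse(a_ref[iB], "1", "0")
    out
  }

  ril_calls <- to_refalt(corrupt(gmat, config$mean_depth))
  rownames(ril_calls) <- rownames(gmat)

  par_truth <- rbind(
    matrix("A", n_parent_libs, m), matrix("B", n_parent_libs, m))
  par_calls <- to_refalt(corrupt(par_truth, parent_depth))
  rownames(par_calls) <- c(sprintf("PA_%d", seq_len(n_parent_libs)),
                           sprintf("PB_%d", seq_len(n_parent_libs)))

  loci_out <- data.frame(chrom = loci$chrom, pos = loci$pos,
                         ref = "A", alt = "T",
                         stringsAsFactors = FALSE)
  list(ril = variant_table(ril_calls, loci_out),
       parents = variant_table(par_calls, loci_out))
}

#' Specification of a simulated phenotype experiment
#'
#' @param traits character vector of trait names.
#' @param grand_mean named numeric, mm, one per trait.
#' @param qtl data frame with columns `chrom`, `pos`, `effect`, `trait`:
#'   additive effects in mm per allele substitution half-difference (line
#'   value changes by `2 * effect` between the two homozygous classes).
#' @param line_sd standard deviation of the polygenic line effect (mm).
#' @param rep_sd replicate-level residual standard deviation (mm).
#' @param n_reps replicates per line per trait (default 10, at least 2).
#' @param top_k_selection optional integer k: replicates are the k largest of
#'   a pool of `3 * k` simulated seedlings, emulating measuring only the
#'   tallest seedlings; off (NULL) by default because it biases means upward.
#' @return object of class `pheno_sim_spec`.
#' @export
pheno_sim_spec <- function(traits = c("dark", "Rc", "FRc", "Bc"),
                           grand_mean = c(dark = 15, Rc = 9, FRc = 11, Bc = 10),
                           qtl = data.frame(chrom = "chr5", pos = 1e7,
                                            effect = 0.59, trait = "Rc"),
                           line_sd = 1.0,
                           rep_sd = 1.5,
                           n_reps = 10L,
                           top_k_selection = NULL) {
  stopifnot(n_reps >= 2, line_sd >= 0, rep_sd >= 0,
            all(names(grand_mean) == traits) || all(traits %in% names(grand_mean)))
  if (!is.null(qtl) && nrow(qtl)) {
    stopifnot(all(c("chrom", "pos", "effect", "trait") %in% names(qtl)))
    if (!all(qtl$trait %in% traits)) stop("QTL trait not in trait list")
  }
  structure(list(traits = traits, grand_mean = grand_mean, qtl = qtl,
                 line_sd = line_sd, rep_sd = rep_sd,
                 n_reps = as.integer(n_reps),
                 top_k_selection = top_k_selection),
            class = "pheno_sim_spec")
}

#' Simulate replicated phenotypes driven by additive QTLs
#'
#' Each replicate value is `grand_mean + sum_k a_k x_k + u_line + e`, with
#' `x_k` coded -1/+1 by the line's parental allele at QTL k (heterozygous
#' residual genotypes code 0), `u_line ~ N(0, line_sd^2)` shared across
#' traits' genetic background only through the QTLs (an independent line
#' effect is drawn per trait), and `e ~ N(0, rep_sd^2)`. With
#' `top_k_selection = k`, the replicates kept are the k largest of a pool of
#' `3k`, an upward-biased truncation emulating measuring only the tallest
#' seedlings.
#'
#' @param truth a `truth_set`.
#' @param spec a [pheno_sim_spec()].
#' @param seed integer seed.
#' @return a tidy data frame (line, trait, replicate, value) of class
#'   `pheno_table`.
#' @export
simulate_phenotypes <- function(truth, spec = pheno_sim_spec(), seed = 1L) {
  stopifnot(inherits(truth, "truth_set"), inherits(spec, "pheno_sim_spec"))
  set.seed(seed)
  gm <- truth$genotypes
  lines <- rownames(gm$geno)
  n <- length(lines)

  qtl_x <- NULL
  if (!is.null(spec$qtl) && nrow(spec$qtl)) {
    qtl_x <- sapply(seq_len(nrow(spec$qtl)), function(k) {
      ci <- spec$qtl$chrom[k]
      sel <- gm$loci$chrom == ci
      if (!any(sel)) stop("QTL position not on a simulated chromosome")
      j <- which(sel)[which.min(abs(gm$loci$pos[sel] - spec$qtl$pos[k]))]
      x <- gm$geno[, j]
      ifelse(x == "A", -1, ifelse(x == "B", 1, 0))
    })
  }

  out <- list()
  for (tr in spec$traits) {
    mu <- spec$grand_mean[[tr]]
    gvals <- rep(mu, n)
    if (!is.null(qtl_x)) {
      for (k in seq_len(nrow(spec$qtl))) {
        if (spec$qtl$trait[k] == tr) gvals <- gvals + spec$qtl$effect[k] * qtl_x[, k]
      }
    }
    gvals <- gvals + stats::rnorm(n, 0, spec$line_sd)
    r <- spec$n_reps
    if (is.null(spec$top_k_selection)) {
      vals <- rep(gvals, each = r) + stats::rnorm(n * r, 0, spec$rep_sd)
      reps <- rep(seq_len(r), times = n)
    } else {
      k <- spec$top_k_selection
      pool <- 3L * k
      vals <- unlist(lapply(gvals, function(g) {
        sort(g + stats::rnorm(pool, 0, spec$rep_sd), decreasing = TRUE)[seq_len(k)]
      }))
      r <- k
      reps <- rep(seq_len(k), times = n)
    }
    out[[tr]] <- data.frame(line = rep(lines, each = r), trait = tr,
                            replicate = reps, value = vals,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pheno_table", "data.frame")
  res
}
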