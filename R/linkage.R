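#' Kosambi map function and its inverse
#'
#' `kosambi()` converts a recombination fraction to map distance,
#' `d = 25 ln((1+2r)/(1-2r))` cM, allowing moderate crossover interference;
#' `kosambi_inverse()` is the exact inverse `r = tanh(d/50)/2`.
#'
#' @param r recombination fraction(s) in `[0, 0.5]`.
#' @param d map distance(s) in cM.
#' @return distances in cM, or recombination fractions.
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE)) stop("r must be in [0, 0.5]")
  ifelse(r >= 0.5, Inf, 25 * log((1 + 2 * r) / (1 - 2 * r)))
}

#' @rdname kosambi
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("d must be non-negative")
  tanh(d / 50) / 2
}

#' Convert selfed-RIL discordance to meiotic recombination fraction
#'
#' For fully selfed RILs the observed discordance fraction between two loci
#' is `R = 2r/(1+2r)` where r is the per-meiosis recombination fraction;
#' the inverse is `r = R/(2(1-R))`, capped at 0.5.
#'
#' @param R observed discordance fraction(s).
#' @return meiotic-scale recombination fraction(s).
#' @export
ril_rf_to_meiotic <- function(R) {
  pmin(R / (2 * (1 - R)), 0.5)
}

#' Pairwise recombination fractions between binned markers
#'
#' For every marker pair, counts discordant homozygous calls across lines
#' (heterozygous calls are treated as missing), giving the RIL-scale
#' discordance `R`, the meiotic-scale `r = R/(2(1-R))` capped at 0.5, and a
#' LOD score of linkage against r = 0.5 from the binomial likelihood. Pairs
#' co-scored in fewer than `min_scored` lines are marked unreliable (NA).
#'
#' @param bins a [binned_markers()] object.
#' @param min_scored minimum co-scored lines per pair, default 10.
#' @return list of matrices `R`, `r`, `lod`, `n` (co-scored counts).
#' @export
pairwise_rf <- function(bins, min_scored = 10L) {
  stopifnot(inherits(bins, "binned_markers"))
  g <- bins$geno
  if (ncol(g) < 2L) stop("need at least two markers")
  MA <- (g == "A"); MA[is.na(MA)] <- FALSE
  MB <- (g == "B"); MB[is.na(MB)] <- FALSE
  storage.mode(MA) <- "numeric"; storage.mode(MB) <- "numeric"
  D <- crossprod(MA, MB) + crossprod(MB, MA)
  scored <- MA + MB
  N <- crossprod(scored)
  R <- D / N
  unrel <- N < min_scored
  R[unrel] <- NA_real_
  r <- ril_rf_to_meiotic(R)
  # binomial LOD: k discordant of n, MLE R vs null 0.5
  k <- D
  lod <- matrix(NA_real_, nrow(R), ncol(R))
  ok <- !unrel & N > 0
  Rk <- pmin(pmax(R, 1e-12), 1 - 1e-12)
  lod[ok] <- (k[ok] * log10(Rk[ok]) + (N[ok] - k[ok]) * log10(1 - Rk[ok]) -
                N[ok] * log10(0.5))
  lod[ok & k == 0] <- (N[ok & k == 0]) * log10(2)  # exact at R = 0
  diag(lod) <- NA_real_
  dimnames(R) <- dimnames(r) <- dimnames(lod) <- dimnames(N) <-
    list(colnames(g), colnames(g))
  list(R = R, r = r, lod = lod, n = N)
}

#' Order markers on one chromosome via a minimum spanning tree
#'
#' Builds the complete weighted graph over the chromosome's markers with
#' pairwise discordance `R` as edge weight (unreliable pairs contribute no
#' edge), extracts the minimum spanning tree, takes the tree's
#' maximum-weight path as the backbone order, and inserts each off-path
#' marker next to its nearest backbone neighbour on whichever side adds the
#' smaller adjacent-`R` sum. Orientation is fixed so the first marker has
#' the smaller physical window start. Co-segregating (duplicate) markers tie
#' at weight 0 and end up adjacent.
#'
#' @param rf result of [pairwise_rf()] restricted to one chromosome (or the
#'   full matrices plus `labels` selecting the chromosome's markers).
#' @param labels marker labels to order.
#' @param physical_start named vector of window starts for orientation.
#' @return character vector: the ordered labels.
#' @export
order_markers_mst <- function(rf, labels, physical_start) {
  labels <- sort(labels)  # canonical vertex order: result independent of input order
  R <- rf$R[labels, labels, drop = FALSE]
  m <- length(labels)
  if (m == 1L) return(labels)
  idx <- which(upper.tri(R) & !is.na(R), arr.ind = TRUE)
  if (!nrow(idx)) stop("no reliable marker pairs on this chromosome")
  gph <- igraph::graph_from_data_frame(
    data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
               weight = R[idx]),
    directed = FALSE,
    vertices = data.frame(name = labels))
  comp <- igraph::components(gph)
  if (comp$no > 1L) {
    stop("marker graph is disconnected: components of sizes ",
         paste(comp$csize, collapse = ", "))
  }
  tree <- igraph::mst(gph, weights = igraph::E(gph)$weight)
  # in a tree the unique path is the shortest path, so the weighted diameter
  # is the maximum-weight path
  backbone <- names(igraph::get_diameter(tree, weights = igraph::E(tree)$weight))
  ord <- backbone
  off <- sort(setdiff(labels, backbone))  # deterministic insertion order
  Rfill <- R
  Rfill[is.na(Rfill)] <- 0.5
  for (mk in off) {
    nn_pos <- which.min(Rfill[mk, ord])
    cost_insert <- function(p) {
      # cost of order with mk inserted after position p (p = 0 -> front)
      left <- if (p >= 1L) Rfill[mk, ord[p]] else 0
      right <- if (p < length(ord)) Rfill[mk, ord[p + 1L]] else 0
      removed <- if (p >= 1L && p < length(ord)) Rfill[ord[p], ord[p + 1L]] else 0
      left + right - removed
    }
    before <- cost_insert(nn_pos - 1L)
    after <- cost_insert(nn_pos)
    if (before <= after) {
      ord <- append(ord, mk, after = nn_pos - 1L)
    } else {
      ord <- append(ord, mk, after = nn_pos)
    }
  }
  if (physical_start[[ord[1L]]] > physical_start[[ord[length(ord)]]]) {
    ord <- rev(ord)
  }
  ord
}

#' Sum of adjacent discordances for a marker order
#'
#' The objective the ordering minimises; exposed for validation.
#'
#' @param R discordance matrix.
#' @param ord marker order (labels or indices).
#' @param na_value value substituted for unreliable pairs, default 0.5.
#' @return numeric path cost.
#' @export
order_cost <- function(R, ord, na_value = 0.5) {
  w <- R[cbind(ord[-length(ord)], ord[-1L])]
  w[is.na(w)] <- na_value
  sum(w)
}

#' Build a per-chromosome linkage map from binned markers
#'
#' Applies pre-ordering screens in the spirit of the MSTmap interface
#' (markers above `max_missing` missingness are dropped; markers farther
#' than `detach_cM` from every other marker are detached; linked groups
#' smaller than `min_group` markers are dropped), orders each chromosome's
#' markers with [order_markers_mst()], and assigns cumulative Kosambi
#' positions from adjacent-pair recombination fractions.
#'
#' @param bins a [binned_markers()] object after QC.
#' @param max_missing pre-ordering missingness screen, default 0.25.
#' @param detach_cM detachment threshold, default 5 cM: a marker whose
#'   minimum Kosambi distance to every other marker on the chromosome
#'   exceeds this is excluded from the map.
#' @param min_group minimum linked-group size, default 2.
#' @param min_scored passed to [pairwise_rf()].
#' @return a `linkage_map` data frame (chrom, marker, order_index, start,
#'   r_adj, cM) with per-chromosome raw lengths in attribute `lengths`; the
#'   pairwise matrices are attached as attribute `rf`.
#' @export
build_linkage_map <- function(bins, max_missing = 0.25, detach_cM = 5,
                              min_group = 2L, min_scored = 10L) {
  stopifnot(inherits(bins, "binned_markers"))
  bins <- recompute_marker_qc(bins)
  keep <- bins$markers$missing_frac <= max_missing
  bins2 <- binned_markers(bins$geno[, keep, drop = FALSE],
                          bins$markers[keep, , drop = FALSE])
  rf <- pairwise_rf(bins2, min_scored = min_scored)
  mk <- bins2$markers
  phys <- stats::setNames(mk$start, mk$label)
  rows <- list()
  lens <- list()
  for (ch in unique(mk$chrom)) {
    labs <- mk$label[mk$chrom == ch]
    if (length(labs) >= 2L) {
      d <- kosambi(rf$r[labs, labs, drop = FALSE])
      diag(d) <- Inf
      min_d <- apply(d, 1, min, na.rm = TRUE)
      labs <- labs[min_d <= detach_cM]
    }
    if (length(labs) < min_group) next
    ord <- order_markers_mst(rf, labs, phys)
    r_adj <- c(NA_real_,
               rf$r[cbind(ord[-length(ord)], ord[-1L])])
    r_adj[-1L][is.na(r_adj[-1L])] <- 0.5 - 1e-9
    step <- kosambi(ifelse(is.na(r_adj), 0, pmin(r_adj, 0.5 - 1e-9)))
    cm <- cumsum(ifelse(is.na(step), 0, step))
    rows[[ch]] <- data.frame(chrom = ch, marker = ord,
                             order_index = seq_along(ord),
                             start = unname(phys[ord]),
                             r_adj = r_adj, cM = cm,
                             stringsAsFactors = FALSE)
    lens[[ch]] <- cm[length(cm)]
  }
  if (!length(rows)) stop("no chromosome retained enough markers to map")
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  class(map) <- c("linkage_map", "data.frame")
  attr(map, "lengths") <- data.frame(chrom = names(lens),
                                     raw_cM = unlist(lens),
                                     row.names = NULL)
  attr(map, "rf") <- rf
  map
}

#' Correct map lengths by counting apparent crossovers
#'
#' Distance estimates from pairwise recombination fractions inflate the map
#' when genotyping errors masquerade as double crossovers. This correction
#' re-estimates each adjacent interval by direct crossover counting on
#' per-line genotype runs: missing spans flanked by the same genotype are
#' imputed to it, single markers disagreeing with identical flanking
#' genotypes are treated as errors and smoothed away, and each remaining
#' genotype change is attributed to the middle interval of its span. The
#' interval discordance `R = crossovers / informative lines` is then mapped
#' through `r = R/(2(1-R))` and Kosambi as before.
#'
#' @param map a `linkage_map` from [build_linkage_map()].
#' @param bins the [binned_markers()] the map was built from.
#' @return the map with columns `r_adj_corr` and `cM_corr` added and
#'   corrected lengths in attribute `lengths` (column `corrected_cM`).
#' @export
correct_map_lengths <- function(map, bins) {
  stopifnot(inherits(map, "linkage_map"), inherits(bins, "binned_markers"))
  lens <- attr(map, "lengths")
  lens$corrected_cM <- NA_real_
  map$r_adj_corr <- NA_real_
  map$cM_corr <- NA_real_
  for (ch in unique(map$chrom)) {
    sel <- map$chrom == ch
    ord <- map$marker[sel]
    g <- bins$geno[, ord, drop = FALSE]
    g[g == "H"] <- NA_character_
    m <- ncol(g)
    xo <- numeric(max(m - 1L, 0L))
    informative <- numeric(max(m - 1L, 0L))
    for (l in seq_len(nrow(g))) {
      v <- g[l, ]
      idx <- which(!is.na(v))
      if (length(idx) < 2L) next
      vals <- v[idx]
      # smooth singletons: x y x -> x x x
      if (length(vals) >= 3L) {
        for (i in 2:(length(vals) - 1L)) {
          if (vals[i] != vals[i - 1L] && vals[i - 1L] == vals[i + 1L]) {
            vals[i] <- vals[i - 1L]
          }
        }
      }
      informative[idx[1L]:(idx[length(idx)] - 1L)] <-
        informative[idx[1L]:(idx[length(idx)] - 1L)] + 1
      ch_pos <- which(vals[-1L] != vals[-length(vals)])
      for (cc in ch_pos) {
        left <- idx[cc]; right <- idx[cc + 1L]
        j <- (left + right - 1L) %/% 2L
        xo[j] <- xo[j] + 1
      }
    }
    R <- ifelse(informative > 0, xo / informative, 0)
    r <- ril_rf_to_meiotic(R)
    step <- kosambi(pmin(r, 0.5 - 1e-9))
    cm <- cumsum(c(0, step))
    map$r_adj_corr[sel] <- c(NA_real_, r)
    map$cM_corr[sel] <- cm
    lens$corrected_cM[lens$chrom == ch] <- cm[length(cm)]
  }
  attr(map, "lengths") <- lens
  map
}

#' Selfed-RIL two-locus discordance by pedigree recursion
#'
#' Independent generation-by-generation recursion over the ten two-locus
#' diplotype classes under selfing with recombination fraction `r` per
#' meiosis. Used to validate the closed form `R = 2r/(1+2r)` reached at
#' complete inbreeding.
#'
#' @param r per-meiosis recombination fraction.
#' @param generations number of selfing generations (large for the fixed
#'   point).
#' @return the discordance fraction among lines fixed at both loci.
#' @export
ril_discordance_recursion <- function(r, generations = 2000L) {
  # haplotypes: 1 AB, 2 Ab, 3 aB, 4 ab; diplotype = unordered pair
  haps <- expand.grid(h1 = 1:4, h2 = 1:4)
  gamete_dist <- function(h1, h2) {
    # alleles at locus 1/2 for haplotype h: a1 = h in (1,2); a2 = h in (1,3)
    a1 <- c(1, 1, 0, 0); a2 <- c(1, 0, 1, 0)
    p <- numeric(4)
    for (g in 1:4) {
      # parental combinations
      p[g] <- 0.5 * (1 - r) * ((g == h1) + (g == h2))
      # recombinant: locus1 from one, locus2 from the other
      rec1 <- which(a1 == a1[h1] & a2 == a2[h2])
      rec2 <- which(a1 == a1[h2] & a2 == a2[h1])
      p[g] <- p[g] + 0.5 * r * ((g == rec1) + (g == rec2))
    }
    p
  }
  # state: 4x4 symmetric frequency matrix over ordered diplotypes
  f <- matrix(0, 4, 4)
  f[1, 4] <- f[4, 1] <- 0.5  # F1 = AB/ab
  for (g in seq_len(generations)) {
    fn <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      if (f[i, j] == 0) next
      gd <- gamete_dist(i, j)
      fn <- fn + f[i, j] * outer(gd, gd)
    }
    f <- fn
  }
  fixed <- c(f[1, 1], f[2, 2], f[3, 3], f[4, 4])
  recomb <- fixed[2] + fixed[3]
  recomb / sum(fixed)
}
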