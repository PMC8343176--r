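#' Collapse SNP genotypes into 100-Kb window markers
#'
#' Chromosomes are tiled with consecutive fixed-width windows anchored at
#' position 0 (0-based half-open). Per line per window, the marker genotype
#' is the strict majority among the called (non-NA) SNP genotypes
#' {A, B, H}; windows with fewer than `min_snps` called SNPs for the line, or
#' with a tie for the plurality, are NA. The final partial window of a
#' chromosome is kept (it can still collect `min_snps` calls). Per-marker QC
#' statistics (missing fraction and A-allele occurrence among homozygous
#' calls) are computed on the result.
#'
#' @param geno a [genotype_matrix()] with physical positions.
#' @param window_bp window width, default 100000.
#' @param min_snps minimum called SNPs per line per window, default 10.
#' @return a [binned_markers()] object.
#' @export
bin_genotypes <- function(geno, window_bp = 100000, min_snps = 10L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (window_bp <= 0) stop("window size must be positive")
  loci <- geno$loci
  n <- nrow(geno$geno)
  marker_rows <- list()
  gcols <- list()
  for (ch in unique(loci$chrom)) {
    j <- which(loci$chrom == ch)
    win <- (loci$pos[j] - 1L) %/% window_bp  # 1-based pos -> 0-based window
    for (w in sort(unique(win))) {
      jj <- j[win == w]
      sub <- geno$geno[, jj, drop = FALSE]
      nA <- rowSums(sub == "A", na.rm = TRUE)
      nB <- rowSums(sub == "B", na.rm = TRUE)
      nH <- rowSums(sub == "H", na.rm = TRUE)
      tot <- nA + nB + nH
      top <- pmax(nA, nB, nH)
      ties <- (nA == top) + (nB == top) + (nH == top) > 1L
      g <- rep(NA_character_, n)
      pick <- tot >= min_snps & !ties
      g[pick & nA == top] <- "A"
      g[pick & nB == top] <- "B"
      g[pick & nH == top] <- "H"
      marker_rows[[length(marker_rows) + 1L]] <-
        data.frame(chrom = ch, start = w * window_bp,
                   end = (w + 1) * window_bp,
                   label = sprintf("%s:%07d", ch, w * window_bp),
                   stringsAsFactors = FALSE)
      gcols[[length(gcols) + 1L]] <- g
    }
  }
  markers <- do.call(rbind, marker_rows)
  gmat <- do.call(cbind, gcols)
  rownames(gmat) <- rownames(geno$geno)
  bm <- binned_markers(gmat, markers)
  recompute_marker_qc(bm)
}

recompute_marker_qc <- function(bins) {
  g <- bins$geno
  bins$markers$missing_frac <- colMeans(is.na(g))
  nA <- colSums(g == "A", na.rm = TRUE)
  nB <- colSums(g == "B", na.rm = TRUE)
  bins$markers$occ_A <- ifelse(nA + nB > 0, nA / (nA + nB), NA_real_)
  bins
}

#' Marker-level quality control
#'
#' Removes binned markers with more than `max_missing` missing observations
#' across lines and markers whose A-allele occurrence (among non-missing
#' homozygous calls, heterozygous calls excluded from the denominator) falls
#' outside `[occ_lo, occ_hi]`; both retention rules are boundary-inclusive.
#'
#' @param bins a [binned_markers()] object.
#' @param max_missing maximum tolerated missing fraction, default 0.25.
#' @param occ_lo,occ_hi occurrence bounds, default 0.35 and 0.65.
#' @return the filtered [binned_markers()]; removal counts in attribute
#'   `n_removed` (named: missing, occurrence).
#' @export
qc_markers <- function(bins, max_missing = 0.25, occ_lo = 0.35,
                       occ_hi = 0.65) {
  stopifnot(inherits(bins, "binned_markers"))
  if (nrow(bins$geno) < 2L) stop("need at least two lines")
  bins <- recompute_marker_qc(bins)
  mfrac <- bins$markers$missing_frac
  occ <- bins$markers$occ_A
  bad_miss <- mfrac > max_missing
  bad_occ <- is.na(occ) | occ < occ_lo | occ > occ_hi
  keep <- !bad_miss & !bad_occ
  out <- binned_markers(bins$geno[, keep, drop = FALSE],
                        bins$markers[keep, , drop = FALSE])
  rownames(out$markers) <- NULL
  attr(out, "n_removed") <- c(missing = sum(bad_miss),
                              occurrence = sum(bad_occ & !bad_miss))
  out
}

#' Flag candidate segregation-distortion regions
#'
#' Reports maximal runs of at least `k` consecutive markers (per chromosome,
#' in physical order) whose allele occurrence falls outside
#' `[occ_lo, occ_hi]` as candidate distortion intervals. The flagged
#' intervals are advisory: excluding them is an explicit action via
#' [exclude_markers()], never automatic, mirroring how a distorted
#' chromosome arm is removed only after manual confirmation of population
#' integrity.
#'
#' @param bins a [binned_markers()] object (QC stats recomputed internally).
#' @param k minimum run length, default 10.
#' @param occ_lo,occ_hi occurrence band, default 0.35 and 0.65.
#' @return an [interval_set()] of flagged physical intervals (possibly
#'   zero rows).
#' @export
flag_distortion_region <- function(bins, k = 10L, occ_lo = 0.35,
                                   occ_hi = 0.65) {
  stopifnot(inherits(bins, "binned_markers"))
  bins <- recompute_marker_qc(bins)
  res <- list()
  for (ch in unique(bins$markers$chrom)) {
    sel <- which(bins$markers$chrom == ch)
    sel <- sel[order(bins$markers$start[sel])]
    occ <- bins$markers$occ_A[sel]
    out_of_band <- is.na(occ) | occ < occ_lo | occ > occ_hi
    r <- rle(out_of_band)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (r$values[i] && r$lengths[i] >= k) {
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch,
          start = bins$markers$start[sel[starts[i]]],
          end = bins$markers$end[sel[ends[i]]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric()),
                     class = c("interval_set", "data.frame")))
  }
  df <- do.call(rbind, res)
  interval_set(df$chrom, df$start, df$end)
}

#' Drop markers overlapping given intervals
#'
#' Explicit exclusion step for confirmed distortion regions: markers whose
#' window overlaps any interval are removed.
#'
#' @param bins a [binned_markers()] object.
#' @param iv an [interval_set()].
#' @return the reduced [binned_markers()].
#' @export
exclude_markers <- function(bins, iv) {
  stopifnot(inherits(bins, "binned_markers"))
  if (!nrow(iv)) return(bins)
  drop <- rep(FALSE, ncol(bins$geno))
  for (i in seq_len(nrow(iv))) {
    drop <- drop | (bins$markers$chrom == iv$chrom[i] &
                      bins$markers$start < iv$end[i] &
                      bins$markers$end > iv$start[i])
  }
  out <- binned_markers(bins$geno[, !drop, drop = FALSE],
                        bins$markers[!drop, , drop = FALSE])
  rownames(out$markers) <- NULL
  attr(out, "n_excluded") <- sum(drop)
  out
}
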