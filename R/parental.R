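#' Call diagnostic parental SNPs from replicated parental libraries
#'
#' A locus enters the diagnostic set when each parent's combined call is
#' homozygous and the two parents carry different alleles. A parent's
#' combined call is homozygous only if all its non-missing library calls
#' agree and are homozygous: a single heterozygous library call anywhere is
#' treated as a potentially spurious heterozygous site and discards the
#' locus. A parent with no non-missing call at a locus cannot be certified
#' homozygous, so the locus is dropped.
#'
#' @param parent_a a [variant_table()] of replicate libraries for parent A.
#' @param parent_b a [variant_table()] for parent B, same loci.
#' @return a `diagnostic_snps` data frame (chrom, pos, allele_A, allele_B in
#'   REF/ALT space) with provenance counters in attribute `counters`
#'   (n_input, n_removed_het, n_removed_nondiag, n_removed_missing,
#'   n_removed_te, n_retained).
#' @export
call_parental_snps <- function(parent_a, parent_b) {
  stopifnot(inherits(parent_a, "variant_table"),
            inherits(parent_b, "variant_table"))
  if (!identical(parent_a$loci[c("chrom", "pos")],
                 parent_b$loci[c("chrom", "pos")])) {
    stop("parental tables must share loci")
  }
  m <- ncol(parent_a$calls)
  if (m == 0L) stop("zero overlapping loci between parents")

  combine <- function(calls) {
    # per locus: "0"/"1" if all non-missing calls agree and are homozygous;
    # "het" if any library call is heterozygous; NA if all missing;
    # "discord" if homozygous calls disagree
    apply(calls, 2, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_character_)
      if (any(x == "H")) return("het")
      u <- unique(x)
      if (length(u) == 1L) u else "discord"
    })
  }
  ca <- combine(parent_a$calls)
  cb <- combine(parent_b$calls)

  has_het <- (!is.na(ca) & ca == "het") | (!is.na(cb) & cb == "het")
  missing <- is.na(ca) | is.na(cb)
  hom_ok <- !missing & !has_het &
    ca %in% c("0", "1") & cb %in% c("0", "1")
  diag <- hom_ok & ca != cb
  nondiag <- hom_ok & ca == cb
  discord <- !missing & !has_het & !hom_ok

  loci <- parent_a$loci
  out <- data.frame(chrom = loci$chrom[diag], pos = loci$pos[diag],
                    allele_A = ca[diag], allele_B = cb[diag],
                    stringsAsFactors = FALSE)
  class(out) <- c("diagnostic_snps", "data.frame")
  attr(out, "counters") <- c(
    n_input = m,
    n_removed_het = sum(has_het),
    n_removed_missing = sum(missing & !has_het),
    n_removed_nondiag = sum(nondiag) + sum(discord),
    n_removed_te = 0L,
    n_retained = sum(diag))
  out
}

#' Remove diagnostic SNPs overlapping transposable elements
#'
#' A SNP is removed when its (1-based) position falls inside any interval of
#' the annotation; with the internal 0-based half-open convention, SNP
#' position p (1-based) overlaps interval `[start, end)` iff
#' `start <= p - 1 < end`.
#'
#' @param snps a `diagnostic_snps` set.
#' @param te an [interval_set()] of transposable-element annotations.
#' @return the filtered `diagnostic_snps` with updated counters.
#' @export
filter_te_overlap <- function(snps, te) {
  stopifnot(inherits(snps, "diagnostic_snps"), inherits(te, "interval_set"))
  counters <- attr(snps, "counters")
  hit <- rep(FALSE, nrow(snps))
  for (ch in unique(snps$chrom)) {
    sel <- snps$chrom == ch
    tch <- te[te$chrom == ch, , drop = FALSE]
    if (!nrow(tch)) next
    q <- IRanges::IRanges(start = snps$pos[sel], width = 1L)
    s <- IRanges::IRanges(start = tch$start + 1L, end = tch$end)
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  out <- snps[!hit, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diagnostic_snps", "data.frame")
  counters["n_removed_te"] <- counters[["n_removed_te"]] + sum(hit)
  counters["n_retained"] <- nrow(out)
  attr(out, "counters") <- counters
  out
}

#' Project RIL variant calls onto parental (A/B) space
#'
#' Restricts a RIL call table to the diagnostic loci and recodes REF/ALT
#' calls into parental alleles using the diagnostic assignment.
#'
#' @param calls a [variant_table()] of RIL calls.
#' @param snps a `diagnostic_snps` set.
#' @return a [genotype_matrix()] of observed (not yet inferred) calls.
#' @export
project_to_parental <- function(calls, snps) {
  stopifnot(inherits(calls, "variant_table"),
            inherits(snps, "diagnostic_snps"))
  key_c <- paste(calls$loci$chrom, calls$loci$pos)
  key_s <- paste(snps$chrom, snps$pos)
  idx <- match(key_s, key_c)
  if (anyNA(idx)) stop("diagnostic SNPs missing from the call table")
  sub <- calls$calls[, idx, drop = FALSE]
  out <- matrix(NA_character_, nrow(sub), ncol(sub),
                dimnames = dimnames(sub))
  a_allele <- matrix(rep(snps$allele_A, each = nrow(sub)), nrow(sub))
  out[sub == "H"] <- "H"
  hom <- sub %in% c("0", "1") & !is.na(sub)
  out[hom] <- ifelse(sub[hom] == a_allele[hom], "A", "B")
  genotype_matrix(out, data.frame(chrom = snps$chrom, pos = snps$pos,
                                  stringsAsFactors = FALSE))
}
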