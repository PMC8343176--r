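#' Per-library biallelic variant calls
#'
#' Matrix-backed container for biallelic SNP calls across libraries (parental
#' replicates or RILs). Calls live in REF/ALT space: `"0"` hom-ref, `"1"`
#' hom-alt, `"H"` heterozygous, `NA` missing.
#'
#' @param calls character matrix, libraries x loci.
#' @param loci data frame with columns `chrom`, `pos` (1-based) and optionally
#'   `ref`, `alt`; positions must be sorted within chromosome.
#' @return object of class `variant_table`.
#' @export
variant_table <- function(calls, loci) {
  stopifnot(is.matrix(calls), nrow(loci) == ncol(calls),
            all(c("chrom", "pos") %in% names(loci)))
  ok <- calls %in% c("0", "1", "H") | is.na(calls)
  if (!all(ok)) stop("calls must be in {0, 1, H, NA}")
  for (ch in unique(loci$chrom)) {
    p <- loci$pos[loci$chrom == ch]
    if (is.unsorted(p)) stop("positions must be sorted within chromosome")
  }
  structure(list(calls = calls, loci = as.data.frame(loci)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$calls), "libraries x", ncol(x$calls),
      "loci on", length(unique(x$loci$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Subset a variant table by library
#'
#' @param vt a [variant_table()].
#' @param libs library names or indices to keep.
#' @return a [variant_table()] with the selected libraries.
#' @export
subset_libraries <- function(vt, libs) {
  stopifnot(inherits(vt, "variant_table"))
  variant_table(vt$calls[libs, , drop = FALSE], vt$loci)
}

#' Lines x loci categorical genotype matrix
#'
#' Genotypes in parental space: `"A"`, `"B"`, `"H"`, `NA`.
#'
#' @param geno character matrix lines x loci.
#' @param loci data frame with `chrom`, `pos`, sorted within chromosome.
#' @param posterior optional numeric array of per-call posteriors.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, loci, posterior = NULL) {
  stopifnot(is.matrix(geno), nrow(loci) == ncol(geno))
  ok <- geno %in% c("A", "B", "H") | is.na(geno)
  if (!all(ok)) stop("genotypes must be in {A, B, H, NA}")
  structure(list(geno = geno, loci = as.data.frame(loci),
                 posterior = posterior),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(factor(x$geno, levels = c("A", "B", "H")), useNA = "always")
  cat("genotype_matrix:", nrow(x$geno), "lines x", ncol(x$geno), "loci\n")
  cat("  calls: A =", tab[["A"]], " B =", tab[["B"]], " H =", tab[["H"]],
      " NA =", tab[[length(tab)]], "\n")
  invisible(x)
}

#' Binned 100-Kb window markers
#'
#' @param geno character matrix lines x markers, codes `"A"`, `"B"`, `"H"`, `NA`.
#' @param markers data frame with `chrom`, `start`, `end` (0-based half-open
#'   physical window), `label`, and QC columns `missing_frac`, `occ_A`
#'   (A-allele occurrence among non-missing homozygous calls).
#' @return object of class `binned_markers`.
#' @export
binned_markers <- function(geno, markers) {
  stopifnot(is.matrix(geno), nrow(markers) == ncol(geno),
            all(c("chrom", "start", "end", "label") %in% names(markers)))
  colnames(geno) <- markers$label
  structure(list(geno = geno, markers = as.data.frame(markers)),
            class = "binned_markers")
}

#' @export
print.binned_markers <- function(x, ...) {
  cat("binned_markers:", nrow(x$geno), "lines x", ncol(x$geno),
      "window markers on", length(unique(x$markers$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Interval set (0-based, half-open)
#'
#' Internal convention for all interval work: 0-based half-open
#' `[start, end)`. 1-based coordinates exist only at VCF/GFF boundaries.
#'
#' @param chrom,start,end vectors defining the intervals.
#' @param name optional per-interval labels (e.g. gene ids).
#' @return data frame of class `interval_set`.
#' @export
interval_set <- function(chrom, start, end, name = NULL) {
  if (any(end <= start)) stop("interval end must exceed start")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  class(df) <- c("interval_set", "data.frame")
  df
}

as_iranges_list <- function(iv) {
  # 0-based half-open -> IRanges (1-based closed), split by chromosome
  split(IRanges::IRanges(start = iv$start + 1L, end = iv$end), iv$chrom)
}

#' Merge overlapping intervals
#'
#' @param iv an [interval_set()].
#' @return an `interval_set` with overlapping/adjacent-overlap intervals
#'   merged per chromosome.
#' @export
merge_intervals <- function(iv) {
  rl <- as_iranges_list(iv)
  out <- do.call(rbind, lapply(names(rl), function(ch) {
    red <- IRanges::reduce(rl[[ch]])
    data.frame(chrom = ch, start = IRanges::start(red) - 1L,
               end = IRanges::end(red), stringsAsFactors = FALSE)
  }))
  interval_set(out$chrom, out$start, out$end)
}

#' Total bases covered by an interval set
#'
#' @param iv an [interval_set()].
#' @return numeric count of distinct covered base pairs.
#' @export
covered_bp <- function(iv) {
  m <- merge_intervals(iv)
  sum(m$end - m$start)
}
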