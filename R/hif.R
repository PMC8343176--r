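#' Design of a heterogeneous inbred family (HIF)
#'
#' A HIF is the selfed progeny of a RIL still heterozygous across a QTL
#' interval: sibs homozygous for alternative alleles there, but isogenic
#' elsewhere, isolate the QTL's effect.
#'
#' @param interval_markers marker labels inside the QTL interval.
#' @param background_markers marker labels outside the interval used to
#'   check background identity.
#' @param background_genotype expected background genotype, a named
#'   character vector over `background_markers` ("A"/"B"); sibs deviating at
#'   a scored background marker are discarded. NULL skips the check.
#' @return object of class `hif_design`.
#' @export
hif_design <- function(interval_markers, background_markers = character(),
                       background_genotype = NULL) {
  stopifnot(length(interval_markers) >= 1L)
  if (!is.null(background_genotype)) {
    stopifnot(all(background_markers %in% names(background_genotype)))
  }
  structure(list(interval_markers = interval_markers,
                 background_markers = background_markers,
                 background_genotype = background_genotype),
            class = "hif_design")
}

#' Classify HIF sibs by allele at the QTL interval
#'
#' A sib is A-class when homozygous A at every interval marker, B-class when
#' homozygous B at every interval marker; anything else (a heterozygous
#' call, a recombinant within the interval, a missing interval call, or a
#' background mismatch) is discarded.
#'
#' @param progeny a [genotype_matrix()] or [binned_markers()] of sib
#'   genotypes (lines = sibs).
#' @param design an [hif_design()].
#' @return character vector of classes ("A", "B", "discarded") named by sib;
#'   class counts in attribute `counts`. If a class is empty the result
#'   carries attribute `underpowered = TRUE`.
#' @export
classify_hif_sibs <- function(progeny, design) {
  stopifnot(inherits(design, "hif_design"))
  g <- progeny$geno
  if (!all(design$interval_markers %in% colnames(g))) {
    stop("interval markers missing from progeny genotypes")
  }
  iv <- g[, design$interval_markers, drop = FALSE]
  all_a <- rowSums(iv == "A", na.rm = TRUE) == ncol(iv) & !apply(is.na(iv), 1, any)
  all_b <- rowSums(iv == "B", na.rm = TRUE) == ncol(iv) & !apply(is.na(iv), 1, any)
  cls <- ifelse(all_a, "A", ifelse(all_b, "B", "discarded"))
  if (!is.null(design$background_genotype) &&
      length(design$background_markers)) {
    bg <- g[, design$background_markers, drop = FALSE]
    want <- design$background_genotype[design$background_markers]
    mismatch <- vapply(seq_len(nrow(bg)), function(i) {
      x <- bg[i, ]
      any(!is.na(x) & x != want)
    }, logical(1))
    cls[mismatch] <- "discarded"
  }
  names(cls) <- rownames(g)
  counts <- c(A = sum(cls == "A"), B = sum(cls == "B"),
              discarded = sum(cls == "discarded"))
  attr(cls, "counts") <- counts
  if (counts[["A"]] == 0L || counts[["B"]] == 0L) {
    attr(cls, "underpowered") <- TRUE
    warning("a HIF allele class is empty: contrast underpowered")
  }
  cls
}

#' Test the HIF allele contrast
#'
#' Compares the two homozygous sib classes with the pooled-ANOVA LSD
#' machinery: class means with standard errors, the mean difference
#' (B minus A), its p value, and letter groups. When the QTL scan's
#' additive-effect sign is supplied, a direction-agreement flag records
#' whether the HIF contrast confirms it (scan effects are coded so positive
#' means the B allele increases the trait).
#'
#' @param pheno a `pheno_table` of sib phenotypes (line = sib id).
#' @param trait trait to test.
#' @param classes classification from [classify_hif_sibs()].
#' @param scan_effect optional additive effect from the scan at this QTL.
#' @param alpha significance level, default 0.05.
#' @return list (means, delta, p, letters, direction_agrees).
#' @export
hif_effect_test <- function(pheno, trait, classes, scan_effect = NULL,
                            alpha = 0.05) {
  keep <- classes[pheno$line] %in% c("A", "B")
  d <- pheno[keep & pheno$trait == trait, , drop = FALSE]
  d$class <- unname(classes[d$line])
  if (length(unique(d$class)) < 2L) stop("need sibs in both allele classes")
  if (min(table(d$class)) < 2L) stop("need at least two sibs per class")
  groups <- lsd_groups(
    structure(data.frame(line = d$class, trait = trait, value = d$value,
                         stringsAsFactors = FALSE),
              class = c("pheno_table", "data.frame")),
    trait, alpha = alpha)
  mA <- groups$mean[groups$group == "A"]
  mB <- groups$mean[groups$group == "B"]
  delta <- mB - mA
  tt <- stats::t.test(d$value[d$class == "B"], d$value[d$class == "A"],
                      var.equal = TRUE)
  agree <- if (!is.null(scan_effect)) sign(delta) == sign(scan_effect)
  list(means = groups, delta = delta, p = tt$p.value,
       letters = stats::setNames(groups$letters, groups$group),
       direction_agrees = agree)
}
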