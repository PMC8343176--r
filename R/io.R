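#' Read a VCF into a variant table
#'
#' Parses a VCF 4.x with a GT field via \pkg{vcfR}. Biallelic SNP rows are
#' mapped to the four-state alphabet (`0/0` -> "0", `1/1` -> "1", `0/1` or
#' `1/0` -> "H", `./.` or `.` -> NA). Phased (`|`) and unphased (`/`)
#' separators are treated identically; phase carries no information for
#' inbred-line calls. Multi-allelic and non-SNP rows are skipped and counted.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return a [variant_table()]; the number of skipped rows is attached as
#'   attribute `n_skipped`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[is_snp, , drop = FALSE]
  chrom <- fix[is_snp, "CHROM"]
  pos <- as.integer(fix[is_snp, "POS"])
  gt_norm <- gsub("\\|", "/", gt)
  calls <- matrix(NA_character_, nrow(gt_norm), ncol(gt_norm))
  calls[gt_norm %in% "0/0"] <- "0"
  calls[gt_norm %in% "1/1"] <- "1"
  calls[gt_norm %in% c("0/1", "1/0")] <- "H"
  calls <- t(calls)
  rownames(calls) <- colnames(gt)
  o <- order(chrom, pos)
  loci <- data.frame(chrom = chrom[o], pos = pos[o],
                     ref = ref[is_snp][o], alt = alt[is_snp][o],
                     stringsAsFactors = FALSE)
  vt <- variant_table(calls[, o, drop = FALSE], loci)
  attr(vt, "n_skipped") <- n_skipped
  vt
}

#' Write a variant table as a minimal VCF 4.2
#'
#' Emits a GT-only VCF; missing calls are written as `./.`. The seed (if
#' supplied) is recorded in the header so outputs are self-describing.
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @param seed optional integer recorded as a `##rilqtl_seed` header line.
#' @export
write_vcf <- function(vt, path, seed = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  loci <- vt$loci
  ref <- if ("ref" %in% names(loci)) loci$ref else rep("A", nrow(loci))
  alt <- if ("alt" %in% names(loci)) loci$alt else rep("T", nrow(loci))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rilqtl",
           if (!is.null(seed)) paste0("##rilqtl_seed=", seed),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(vt$calls)), collapse = "\t"))
  gt <- vt$calls
  enc <- matrix("./.", nrow(gt), ncol(gt))
  enc[gt == "0"] <- "0/0"
  enc[gt == "1"] <- "1/1"
  enc[gt == "H"] <- "0/1"
  body <- paste(loci$chrom, loci$pos, ".", ref, alt, ".", "PASS", ".", "GT",
                apply(enc, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genomic intervals from BED or GFF3
#'
#' Dialect is auto-detected from the file extension (`.bed` is 0-based
#' half-open; `.gff`/`.gff3` is 1-based closed). Parsing goes through
#' \pkg{rtracklayer}; the result is normalised to the package-internal
#' 0-based half-open convention.
#'
#' @param path path to a BED or GFF3 file.
#' @param feature optional GFF3 `type` filter (e.g. "gene").
#' @return an [interval_set()]; GFF3 `ID`/`Name` attributes populate `name`.
#' @export
read_intervals <- function(path, feature = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  gr <- rtracklayer::import(path)
  if (ext %in% c("gff", "gff3") && !is.null(feature)) {
    gr <- gr[gr$type == feature]
  }
  if (length(gr) == 0L) stop("no intervals read from ", path)
  nm <- NULL
  md <- S4Vectors::mcols(gr)
  for (col in c("ID", "Name", "name")) {
    if (col %in% names(md) && !all(is.na(md[[col]]))) {
      nm <- as.character(md[[col]]); break
    }
  }
  # GRanges is 1-based closed regardless of source dialect
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L,
               GenomicRanges::end(gr),
               name = nm)
}

#' Write a tidy phenotype table
#'
#' @param pheno a `pheno_table` data frame (line, trait, replicate, value).
#' @param path output CSV path.
#' @export
write_pheno_csv <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy phenotype table
#'
#' @param path CSV with columns line, trait, replicate, value.
#' @return a `pheno_table` data frame.
#' @export
read_pheno_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line", "trait", "replicate", "value")
  if (!all(need %in% names(df))) {
    stop("phenotype CSV must have columns ", paste(need, collapse = ", "))
  }
  class(df) <- c("pheno_table", "data.frame")
  df
}

#' Read a genotype or binned-marker matrix written by [write_geno_csv()]
#'
#' Column headers of the form `chrom:pos` reconstruct a
#' [genotype_matrix()]; any other headers reconstruct a [binned_markers()]
#' object with windows recovered from the label (`chrom:start`).
#'
#' @param path CSV path.
#' @param window_bp window width used to rebuild binned windows, default
#'   100000.
#' @return a [genotype_matrix()] or [binned_markers()].
#' @export
read_geno_csv <- function(path, window_bp = 100000) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  lines <- df[[1L]]
  g <- as.matrix(df[, -1L, drop = FALSE])
  g[g == "N"] <- NA_character_
  rownames(g) <- lines
  lab <- colnames(g)
  parts <- strsplit(lab, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  if (grepl("^0*[0-9]+$", parts[[1L]][2L]) &&
      all(pos %% window_bp == 0)) {
    markers <- data.frame(chrom = chrom, start = pos,
                          end = pos + window_bp, label = lab,
                          stringsAsFactors = FALSE)
    recompute_marker_qc(binned_markers(g, markers))
  } else {
    genotype_matrix(g, data.frame(chrom = chrom, pos = pos,
                                  stringsAsFactors = FALSE))
  }
}

#' Write and read diagnostic parental SNP sets
#'
#' @param snps a `diagnostic_snps` data frame.
#' @param path CSV path.
#' @export
write_diagnostic_csv <- function(snps, path) {
  utils::write.csv(as.data.frame(snps), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagnostic_csv
#' @export
read_diagnostic_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(allele_A = "character",
                                       allele_B = "character"))
  class(df) <- c("diagnostic_snps", "data.frame")
  attr(df, "counters") <- c(n_input = NA, n_removed_het = NA,
                            n_removed_missing = NA, n_removed_nondiag = NA,
                            n_removed_te = NA, n_retained = nrow(df))
  df
}

#' Write a genotype or binned-marker matrix as CSV
#'
#' Symbols A/B/H/N, lines in rows; locus metadata is prepended as columns of
#' a separate header block (chrom, pos or window).
#'
#' @param x a [genotype_matrix()] or [binned_markers()].
#' @param path output CSV path.
#' @export
write_geno_csv <- function(x, path) {
  if (inherits(x, "genotype_matrix")) {
    meta <- x$loci[c("chrom", "pos")]
    lab <- paste(meta$chrom, meta$pos, sep = ":")
  } else if (inherits(x, "binned_markers")) {
    meta <- x$markers
    lab <- meta$label
  } else stop("unsupported object")
  g <- x$geno
  g[is.na(g)] <- "N"
  df <- data.frame(line = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("line", lab)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
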