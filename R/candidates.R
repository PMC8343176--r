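#' High-impact variant-effect categories
#'
#' The six annotation categories treated as potentially function-altering
#' when shortlisting candidate genes.
#'
#' @export
IMPACT_CATEGORIES <- c("missense", "splice_donor", "splice_acceptor",
                       "start_lost", "stop_gained", "stop_lost")

#' Read a variant-effect annotation table
#'
#' @param path CSV with columns gene, chrom, pos, impact (one of
#'   [IMPACT_CATEGORIES]) and optionally detail.
#' @return validated data frame of class `effect_table`.
#' @export
read_effect_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "pos", "impact")
  if (!all(need %in% names(df))) {
    stop("effect table needs columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$impact), IMPACT_CATEGORIES)
  if (length(bad)) stop("unknown impact categories: ",
                        paste(bad, collapse = ", "))
  class(df) <- c("effect_table", "data.frame")
  df
}

#' Genes overlapping a physical QTL interval
#'
#' Any-overlap rule on the internal 0-based half-open convention: a gene
#' `[gs, ge)` is included iff it intersects the query `[start, end)`.
#'
#' @param annotation an [interval_set()] with a `name` column of gene ids.
#' @param chrom,start,end the physical query interval (0-based half-open).
#' @return character vector of gene ids (in annotation order).
#' @export
genes_in_interval <- function(annotation, chrom, start, end) {
  stopifnot(inherits(annotation, "interval_set"),
            "name" %in% names(annotation))
  sel <- annotation$chrom == chrom
  a <- annotation[sel, , drop = FALSE]
  if (!nrow(a)) return(character())
  q <- IRanges::IRanges(start = start + 1L, end = end)
  s <- IRanges::IRanges(start = a$start + 1L, end = a$end)
  hit <- IRanges::overlapsAny(s, q)
  a$name[hit]
}

#' Shortlist candidate genes in a QTL interval
#'
#' Candidates are the intersection of (i) genes in the interval, (ii) a
#' curated list of genes with documented roles in the trait (e.g. light
#' signalling), and (iii) genes carrying at least one high-impact variant.
#' Each candidate is annotated with its per-category variant counts; the
#' result is ranked by total impactful-variant count.
#'
#' @param genes character vector from [genes_in_interval()].
#' @param effects an `effect_table` (or compatible data frame).
#' @param curated character vector of curated gene ids.
#' @return data frame (gene, n_impactful, one count column per category,
#'   stop_gained flag), ranked; zero rows when the curated set is empty.
#' @export
shortlist <- function(genes, effects, curated) {
  cand <- intersect(intersect(genes, curated), unique(effects$gene))
  if (!length(cand)) {
    cols <- c(list(gene = character(), n_impactful = integer()),
              stats::setNames(rep(list(integer()), length(IMPACT_CATEGORIES)),
                              paste0("n_", IMPACT_CATEGORIES)),
              list(stop_gained = logical()))
    return(as.data.frame(cols, stringsAsFactors = FALSE))
  }
  rows <- lapply(cand, function(g) {
    e <- effects[effects$gene == g, , drop = FALSE]
    cnt <- vapply(IMPACT_CATEGORIES, function(cat) sum(e$impact == cat),
                  integer(1))
    c(list(gene = g, n_impactful = sum(cnt)),
      stats::setNames(as.list(cnt), paste0("n_", IMPACT_CATEGORIES)),
      list(stop_gained = cnt[["stop_gained"]] > 0L))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  out <- out[order(-out$n_impactful, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a genetic support interval to physical coordinates
#'
#' Linear interpolation between the window midpoints of the markers
#' flanking each cM endpoint; endpoints beyond the mapped range clamp to
#' the terminal markers.
#'
#' @param map a `linkage_map`.
#' @param chrom chromosome label.
#' @param lo_cM,hi_cM genetic interval.
#' @param window_bp marker window width for midpoints, default 100000.
#' @return numeric `c(start, end)` physical interval (0-based half-open).
#' @export
cm_to_bp <- function(map, chrom, lo_cM, hi_cM, window_bp = 100000) {
  mm <- map[map$chrom == chrom, , drop = FALSE]
  cm_col <- if ("cM_corr" %in% names(mm) && !anyNA(mm$cM_corr)) "cM_corr"
    else "cM"
  cm <- mm[[cm_col]]
  mid <- mm$start + window_bp / 2
  o <- order(cm)
  cm <- cm[o]; mid <- mid[o]
  interp <- function(x) {
    if (x <= cm[1L]) return(mid[1L])
    if (x >= cm[length(cm)]) return(mid[length(mid)])
    stats::approx(cm, mid, xout = x, ties = mean)$y
  }
  lo <- interp(lo_cM); hi <- interp(hi_cM)
  c(start = min(lo, hi), end = max(lo, hi))
}
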