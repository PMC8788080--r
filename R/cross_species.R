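#' Filter an ortholog table for gene-to-gene comparison
#'
#' Keeps one2one orthologs and, among one2many orthologs, the groups
#' (keyed by \code{gene_id_a}) contributing exactly one high-confidence
#' pair, of which that single high-confidence pair is retained.  one2many
#' groups with only low-confidence pairs or several high-confidence pairs,
#' and all many2many orthologs, are excluded.
#'
#' @param map ortholog data.frame (see \code{\link{readOrthologMap}}).
#' @return the filtered data.frame.
#' @export
filterOrthologs <- function(map) {
  map <- validateOrthologMap(map)
  one2one <- map[map$homology_type == "one2one", ]
  o2m <- map[map$homology_type == "one2many", ]
  keep <- if (nrow(o2m)) {
    do.call(rbind, lapply(split(o2m, o2m$gene_id_a), function(grp) {
      high <- grp[grp$confidence == "high", ]
      if (nrow(high) == 1L) high else NULL
    }))
  } else NULL
  out <- rbind(one2one, keep)
  rownames(out) <- NULL
  out
}

.mapCategories <- function(calls) {
  stats::setNames(calls$category, calls$gene_id)
}

.mapElevated <- function(calls) {
  stats::setNames(strsplit(calls$elevated_tissues, ";", fixed = TRUE),
                  calls$gene_id)
}

#' Cross-species classification overlap
#'
#' Joins the two species' specificity calls over the retained ortholog
#' pairs, builds the 5 x 5 category contingency matrix, and flags
#' agreement per pair: same category, and for elevated categories
#' additionally an overlap of the (tissue-vocabulary-mapped) elevated
#' tissue sets.
#'
#' @param callsA,callsB specificity tables from \code{\link{classifyAll}}.
#' @param orthologs filtered ortholog data.frame.
#' @param tissueMap optional named character vector translating species-A
#'   tissues to species-B tissues (default identity).
#' @return list with \code{table} (one row per retained pair:
#'   \code{gene_id_a}, \code{gene_id_b}, \code{category_a},
#'   \code{category_b}, \code{elevated_a}, \code{elevated_b},
#'   \code{agreement}), \code{contingency} (5 x 5 matrix, species A rows),
#'   and \code{categoryAgreement} (per-category percent agreement among
#'   pairs of that species-A category).
#' @export
classificationOverlap <- function(callsA, callsB, orthologs,
                                  tissueMap = NULL) {
  known <- orthologs$gene_id_a %in% callsA$gene_id &
    orthologs$gene_id_b %in% callsB$gene_id
  if (any(!known)) {
    warning(sprintf("%d ortholog pair(s) referencing unknown genes skipped",
                    sum(!known)))
    orthologs <- orthologs[known, ]
  }
  catA <- .mapCategories(callsA); catB <- .mapCategories(callsB)
  elvA <- .mapElevated(callsA); elvB <- .mapElevated(callsB)
  elevated <- c("tissue_enriched", "group_enriched", "tissue_enhanced")
  mapT <- function(t) {
    if (is.null(tissueMap)) t
    else unname(tissueMap[t])
  }
  tab <- data.frame(
    gene_id_a = orthologs$gene_id_a,
    gene_id_b = orthologs$gene_id_b,
    category_a = unname(catA[orthologs$gene_id_a]),
    category_b = unname(catB[orthologs$gene_id_b]),
    stringsAsFactors = FALSE)
  tab$elevated_a <- vapply(elvA[orthologs$gene_id_a],
                           paste, character(1), collapse = ";")
  tab$elevated_b <- vapply(elvB[orthologs$gene_id_b],
                           paste, character(1), collapse = ";")
  tab$agreement <- vapply(seq_len(nrow(tab)), function(i) {
    if (tab$category_a[i] != tab$category_b[i]) return(FALSE)
    if (!tab$category_a[i] %in% elevated) return(TRUE)
    ta <- mapT(elvA[[tab$gene_id_a[i]]])
    tb <- elvB[[tab$gene_id_b[i]]]
    length(intersect(ta, tb)) > 0
  }, logical(1))
  contingency <- table(factor(tab$category_a, .SPECIFICITY_CATEGORIES),
                       factor(tab$category_b, .SPECIFICITY_CATEGORIES),
                       dnn = c("species_a", "species_b"))
  categoryAgreement <- vapply(.SPECIFICITY_CATEGORIES, function(cat) {
    i <- tab$category_a == cat
    if (!any(i)) NA_real_ else 100 * mean(tab$agreement[i])
  }, numeric(1))
  list(table = tab, contingency = unclass(contingency),
       categoryAgreement = categoryAgreement)
}

#' Per-tissue cross-species Spearman correlation
#'
#' For each shared tissue, the Spearman correlation of the two species'
#' expression over the retained ortholog pairs.  Tissues with fewer than
#' three informative genes are skipped with a warning.
#'
#' @param nxA,nxB \linkS4class{ExpressionMatrix} objects (any stage) with
#'   tissue columns for species A and B.
#' @param orthologs filtered ortholog data.frame.
#' @param tissues character vector of shared tissues; a named vector maps
#'   species-A column names to species-B column names.
#' @return data.frame with columns \code{tissue}, \code{rho}, \code{n}.
#' @export
tissueSpearman <- function(nxA, nxB, orthologs, tissues = NULL) {
  vA <- exprValues(nxA); vB <- exprValues(nxB)
  if (is.null(tissues))
    tissues <- intersect(colnames(vA), colnames(vB))
  tB <- if (!is.null(names(tissues))) unname(tissues) else tissues
  tA <- if (!is.null(names(tissues))) names(tissues) else tissues
  pairs <- orthologs[orthologs$gene_id_a %in% rownames(vA) &
                       orthologs$gene_id_b %in% rownames(vB), ]
  rows <- list()
  for (i in seq_along(tA)) {
    a <- vA[pairs$gene_id_a, tA[i]]
    b <- vB[pairs$gene_id_b, tB[i]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L) {
      warning(sprintf("tissue '%s' skipped: fewer than 3 shared genes", tA[i]))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      tissue = tA[i],
      rho = suppressWarnings(stats::cor(a[ok], b[ok], method = "spearman")),
      n = sum(ok), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(tissue = character(), rho = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
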