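#' Tissue specificity classification of one gene
#'
#' Applies the atlas specificity rules, in strict order of precedence, to a
#' gene's per-tissue NX profile:
#' \enumerate{
#'   \item \emph{tissue enriched}: a single tissue has at least
#'     \code{foldChange}-fold higher NX than any other tissue (and is
#'     detected);
#'   \item \emph{group enriched}: the candidate group G of tissues with NX
#'     above max/\code{foldChange} has between \code{groupMin} and
#'     \code{groupMax} members, and mean(G) is at least
#'     \code{foldChange}-fold above every tissue outside G (and detected);
#'   \item \emph{tissue enhanced}: one or more tissues have NX at least
#'     \code{foldChange}-fold above the mean over all tissues (and
#'     detected);
#'   \item \emph{low specificity}: detected in at least one tissue;
#'   \item \emph{not detected} otherwise.
#' }
#' Detection means NX >= \code{detectionThreshold}.  Fold comparisons are
#' inclusive; a tie for the single top tissue therefore falls through to
#' the group rule.
#'
#' @param nxRow numeric vector of NX values, named by tissue.
#' @param config \linkS4class{PipelineConfig}.
#' @return list with \code{category}, \code{elevated_tissues} (character,
#'   ordered by decreasing NX) and \code{fold_change}.
#' @export
classifySpecificity <- function(nxRow, config = PipelineConfig()) {
  x <- nxRow
  if (length(x) < 2L) stop("at least two tissues are required")
  if (any(!is.finite(x)) || any(x < 0)) stop("NX values must be finite and >= 0")
  if (is.null(names(x))) names(x) <- paste0("tissue", seq_along(x))
  fc <- config@foldChange
  det <- config@detectionThreshold
  ord <- order(x, decreasing = TRUE)
  mx <- x[ord[1L]]
  second <- x[ord[2L]]
  if (mx >= fc * second && mx >= det)
    return(list(category = "tissue_enriched",
                elevated_tissues = names(x)[ord[1L]],
                fold_change = unname(if (second > 0) mx / second else Inf)))
  grp <- which(x > mx / fc)
  if (length(grp) >= config@groupMin && length(grp) <= config@groupMax) {
    gmean <- mean(x[grp])
    outside <- if (length(grp) < length(x)) max(x[-grp]) else 0
    if (gmean >= fc * outside && gmean >= det)
      return(list(category = "group_enriched",
                  elevated_tissues = names(x)[intersect(ord, grp)],
                  fold_change = unname(if (outside > 0) gmean / outside else Inf)))
  }
  mn <- mean(x)
  enh <- which(x >= fc * mn & x >= det)
  if (length(enh))
    return(list(category = "tissue_enhanced",
                elevated_tissues = names(x)[intersect(ord, enh)],
                fold_change = unname(mx / mn)))
  if (any(x >= det))
    return(list(category = "low_specificity",
                elevated_tissues = character(),
                fold_change = NA_real_))
  list(category = "not_detected", elevated_tissues = character(),
       fold_change = NA_real_)
}

#' Tissue distribution classification of one gene
#'
#' Counts the tissues with NX at or above the detection threshold and
#' assigns: \emph{detected in all} (all tissues), \emph{detected in many}
#' (at least \code{ceiling(manyFraction * T)} but not all; 14 of 44 tissues
#' at the default 31 percent), \emph{detected in single} (exactly one),
#' \emph{not detected} (none), \emph{detected in some} otherwise.
#'
#' @inheritParams classifySpecificity
#' @return list with \code{category} and \code{n_detected}.
#' @export
classifyDistribution <- function(nxRow, config = PipelineConfig()) {
  x <- nxRow
  if (length(x) < 2L) stop("at least two tissues are required")
  if (any(!is.finite(x)) || any(x < 0)) stop("NX values must be finite and >= 0")
  T <- length(x)
  d <- sum(x >= config@detectionThreshold)
  manyMin <- ceiling(config@manyFraction * T)
  category <-
    if (d == T) "detected_in_all"
    else if (d >= manyMin) "detected_in_many"
    else if (d == 1L) "detected_in_single"
    else if (d == 0L) "not_detected"
    else "detected_in_some"
  list(category = category, n_detected = as.integer(d))
}

#' Classify every gene of a grouped NX matrix
#'
#' Runs \code{\link{classifySpecificity}} and
#' \code{\link{classifyDistribution}} on each gene row and asserts that
#' both category systems partition the gene set.
#'
#' @param nx \linkS4class{ExpressionMatrix} at stage \code{nx} with grouped
#'   tissue columns.
#' @param config \linkS4class{PipelineConfig}.
#' @return list with \code{specificity} (data.frame: \code{gene_id},
#'   \code{category}, \code{elevated_tissues} semicolon-joined,
#'   \code{fold_change}), \code{distribution} (data.frame: \code{gene_id},
#'   \code{category}, \code{n_detected}) and \code{tissueSummary}
#'   (data.frame of per-tissue elevated gene counts).
#' @export
classifyAll <- function(nx, config = PipelineConfig()) {
  stopifnot(is(nx, "ExpressionMatrix"))
  v <- exprValues(nx)
  genes <- rownames(v)
  if (!length(genes)) {
    empty <- data.frame(gene_id = character(), category = character(),
                        stringsAsFactors = FALSE)
    return(list(specificity = cbind(empty,
                                    elevated_tissues = character(),
                                    fold_change = numeric()),
                distribution = cbind(empty, n_detected = integer()),
                tissueSummary = data.frame(tissue = character(),
                                           n_elevated = integer())))
  }
  spec <- vector("list", length(genes))
  dist <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    spec[[i]] <- classifySpecificity(v[i, ], config)
    dist[[i]] <- classifyDistribution(v[i, ], config)
  }
  specificity <- data.frame(
    gene_id = genes,
    category = vapply(spec, `[[`, character(1), "category"),
    elevated_tissues = vapply(spec, function(s)
      paste(s$elevated_tissues, collapse = ";"), character(1)),
    fold_change = vapply(spec, `[[`, numeric(1), "fold_change"),
    stringsAsFactors = FALSE)
  distribution <- data.frame(
    gene_id = genes,
    category = vapply(dist, `[[`, character(1), "category"),
    n_detected = vapply(dist, `[[`, integer(1), "n_detected"),
    stringsAsFactors = FALSE)
  stopifnot(sum(table(factor(specificity$category,
                             .SPECIFICITY_CATEGORIES))) == length(genes),
            sum(table(factor(distribution$category,
                             .DISTRIBUTION_CATEGORIES))) == length(genes))
  elev <- elevatedGenesByTissue(specificity)
  tissueSummary <- data.frame(
    tissue = colnames(v),
    n_elevated = vapply(colnames(v), function(t)
      length(elev[[t]]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(specificity = specificity, distribution = distribution,
       tissueSummary = tissueSummary)
}

#' Elevated genes per tissue from a specificity table
#'
#' Elevated means tissue enriched, group enriched or tissue enhanced; a
#' gene contributes to every tissue in its elevated set.
#'
#' @param specificity specificity data.frame from \code{\link{classifyAll}}.
#' @return named list: tissue -> character vector of gene ids (tissues
#'   with no elevated genes are absent).
#' @export
elevatedGenesByTissue <- function(specificity) {
  el <- specificity[specificity$category %in%
                      c("tissue_enriched", "group_enriched", "tissue_enhanced"), ]
  if (!nrow(el)) return(stats::setNames(list(), character()))
  tl <- strsplit(el$elevated_tissues, ";", fixed = TRUE)
  long <- data.frame(gene_id = rep(el$gene_id, lengths(tl)),
                     tissue = unlist(tl), stringsAsFactors = FALSE)
  split(long$gene_id, long$tissue)
}
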