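#' Pairwise Spearman correlation between columns
#'
#' Rank-based correlation per column pair (average ranks for ties).  A
#' constant column has no defined correlation; its entries are recorded as
#' \code{NA} with a warning.  The diagonal is exactly 1.
#'
#' @param x \linkS4class{ExpressionMatrix} or numeric matrix with at least
#'   two columns and two genes.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(x) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  if (ncol(v) < 2L || nrow(v) < 2L)
    stop("at least two columns and two genes are required")
  constant <- apply(v, 2L, function(col) stats::sd(col) == 0)
  rho <- suppressWarnings(stats::cor(v, method = "spearman"))
  if (any(constant))
    warning(sprintf("constant column(s) with undefined correlation: %s",
                    paste(colnames(v)[constant], collapse = ", ")))
  diag(rho) <- 1
  rho
}

#' Hierarchical tissue tree on 1 - Spearman distance
#'
#' Transforms a correlation matrix into the dissimilarity 1 - rho and
#' clusters it agglomeratively, either with the classical Ward criterion
#' applied to the given dissimilarities (\code{"ward"}) or with average
#' linkage / UPGMA (\code{"average"}).
#'
#' @param corr symmetric correlation matrix (from
#'   \code{\link{spearmanMatrix}}).
#' @param linkage \code{"ward"} or \code{"average"}.
#' @return an \code{hclust} object; export with \code{\link{writeNewick}}.
#' @export
tissueTree <- function(corr, linkage = c("ward", "average")) {
  linkage <- match.arg(linkage)
  if (anyNA(corr)) {
    bad <- which(is.na(corr) & upper.tri(corr), arr.ind = TRUE)
    stop(sprintf("missing correlation(s) for pair(s): %s",
                 paste(apply(bad, 1L, function(i)
                   paste(rownames(corr)[i[1L]], colnames(corr)[i[2L]],
                         sep = "~")), collapse = ", ")))
  }
  d <- stats::as.dist(1 - corr)
  stats::hclust(d, method = if (linkage == "ward") "ward.D" else "average")
}
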