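#' Upper-tail hypergeometric probability
#'
#' P(X >= q), inclusive of q, for X hypergeometric with \code{m} success
#' states, \code{n} failure states and \code{k} draws (the
#' \code{phyper(q - 1, m, n, k, lower.tail = FALSE)} convention).
#' Computation is exact for small counts and numerically stable in the
#' extreme tail (log-space available via \code{logP}).
#'
#' @param q observed overlap count(s).
#' @param m success-state count(s).
#' @param n failure-state count(s).
#' @param k draw count(s).
#' @param logP return log probabilities.
#' @return numeric vector of tail probabilities.
#' @examples
#' hypergeomUpper(3, m = 5, n = 15, k = 4)  # 155/4845
#' @export
hypergeomUpper <- function(q, m, n, k, logP = FALSE) {
  if (any(q < 0 | m < 0 | n < 0 | k < 0))
    stop("all hypergeometric arguments must be >= 0")
  if (any(q > pmin(m, k)))
    stop("q must not exceed min(m, k)")
  if (any(k > m + n))
    stop("k must not exceed m + n")
  stats::phyper(q - 1, m, n, k, lower.tail = FALSE, log.p = logP)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement, capped
#' at 1; output order matches input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted values, same order as the input.
#' @export
bhAdjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

.enrichmentTable <- function(tests, alpha, cap) {
  tests$fdr <- bhAdjust(tests$p_value)
  tests$fdr_displayed <- pmax(tests$fdr, cap)
  tests$significant <- tests$fdr < alpha
  tests
}

#' Cluster x tissue hypergeometric enrichment
#'
#' For every cluster and every tissue with elevated genes, tests the
#' overlap between the tissue's elevated genes and the cluster members.
#' In \code{standard} mode the urn is: m = elevated genes for the tissue,
#' n = remaining genes, k = cluster size, q = overlap.  In
#' \code{literal} mode the arguments are passed exactly as printed
#' in the originating method description (m = cluster size, n = all genes,
#' k = cluster size), which is statistically inconsistent but retained for
#' auditability.  BH adjustment runs across all tests in the batch.
#'
#' @param labels named integer vector gene -> cluster (or a
#'   \linkS4class{ClusterAssignment}).
#' @param specificity specificity table from \code{\link{classifyAll}}.
#' @param config \linkS4class{PipelineConfig}; \code{associationAlpha} is
#'   the significance threshold, \code{fdrDisplayCap} the display floor.
#' @param mode \code{"standard"} or \code{"literal"}.
#' @param alpha significance threshold (default
#'   \code{config@associationAlpha}).
#' @return data.frame with columns \code{cluster_id}, \code{tissue},
#'   \code{q}, \code{m}, \code{n}, \code{k}, \code{mode}, \code{p_value},
#'   \code{fdr}, \code{fdr_displayed}, \code{significant}.
#' @export
clusterTissueEnrichment <- function(labels, specificity,
                                    config = PipelineConfig(),
                                    mode = c("standard", "literal"),
                                    alpha = config@associationAlpha) {
  mode <- match.arg(mode)
  if (is(labels, "ClusterAssignment")) labels <- clusterLabels(labels)
  genes <- names(labels)
  if (!setequal(genes, specificity$gene_id))
    stop("labels and specificity table must cover the same genes")
  elev <- elevatedGenesByTissue(specificity)
  total <- length(genes)
  clusters <- sort(unique(labels))
  rows <- list()
  for (cl in clusters) {
    members <- genes[labels == cl]
    k <- length(members)
    for (t in names(elev)) {
      mset <- elev[[t]]
      q <- sum(members %in% mset)
      if (mode == "standard") {
        m <- length(mset); n <- total - m; kk <- k
      } else {
        m <- k; n <- total; kk <- k
      }
      rows[[length(rows) + 1L]] <-
        data.frame(cluster_id = cl, tissue = t, q = q, m = m, n = n, k = kk,
                   mode = mode, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cluster_id = integer(), tissue = character(),
                      q = integer(), m = integer(), n = integer(),
                      k = integer(), mode = character(), p_value = numeric(),
                      fdr = numeric(), fdr_displayed = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  tests <- do.call(rbind, rows)
  tests$p_value <- hypergeomUpper(tests$q, tests$m, tests$n, tests$k)
  .enrichmentTable(tests, alpha, config@fdrDisplayCap)
}

#' Cross-species tissue-pair overlap tests
#'
#' For every pair of tissues (one per species) with elevated orthologs,
#' tests the overlap between orthologs elevated in the species-A tissue
#' and orthologs elevated in the species-B tissue, over the retained
#' ortholog universe.  \code{literal} mode uses q = elevated in
#' both, m = min of the two elevated counts, n = total orthologs,
#' k = elevated in either or both; \code{standard} mode uses the usual urn
#' (m = elevated in A, n = rest, k = elevated in B).  BH runs across all
#' pairs; displayed FDR is floored at \code{fdrDisplayCap}.
#'
#' @param callsA,callsB specificity tables for the two species.
#' @param orthologs ortholog data.frame (columns \code{gene_id_a},
#'   \code{gene_id_b}) restricted to the comparison universe.
#' @param config \linkS4class{PipelineConfig}.
#' @param mode \code{"literal"} (default) or \code{"standard"}.
#' @param tissueMap optional named character vector translating species-A
#'   tissue names to species-B names (default: shared vocabulary).
#' @param alpha significance threshold.
#' @return data.frame with one row per tested tissue pair (columns
#'   \code{tissue_a}, \code{tissue_b}, \code{q}, \code{m}, \code{n},
#'   \code{k}, \code{mode}, \code{p_value}, \code{fdr},
#'   \code{fdr_displayed}, \code{significant}).
#' @export
speciesTissueOverlap <- function(callsA, callsB, orthologs,
                                 config = PipelineConfig(),
                                 mode = c("literal", "standard"),
                                 tissueMap = NULL,
                                 alpha = config@associationAlpha) {
  mode <- match.arg(mode)
  if (!nrow(orthologs)) stop("empty ortholog set")
  pairs <- orthologs[orthologs$gene_id_a %in% callsA$gene_id &
                       orthologs$gene_id_b %in% callsB$gene_id, ]
  if (!nrow(pairs)) stop("no ortholog pair covered by both call tables")
  total <- nrow(pairs)
  elevA <- elevatedGenesByTissue(callsA)
  elevB <- elevatedGenesByTissue(callsB)
  pairElevA <- lapply(elevA, function(g) which(pairs$gene_id_a %in% g))
  pairElevB <- lapply(elevB, function(g) which(pairs$gene_id_b %in% g))
  pairElevA <- pairElevA[lengths(pairElevA) > 0]
  pairElevB <- pairElevB[lengths(pairElevB) > 0]
  rows <- list()
  for (ta in names(pairElevA)) for (tb in names(pairElevB)) {
    ia <- pairElevA[[ta]]; ib <- pairElevB[[tb]]
    q <- length(intersect(ia, ib))
    u <- length(union(ia, ib))
    if (mode == "literal") {
      m <- min(length(ia), length(ib)); n <- total; k <- u
    } else {
      m <- length(ia); n <- total - m; k <- length(ib)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(tissue_a = ta, tissue_b = tb, q = q, m = m, n = n, k = k,
                 mode = mode, stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, rows)
  tests$p_value <- hypergeomUpper(tests$q, tests$m, tests$n, tests$k)
  .enrichmentTable(tests, alpha, config@fdrDisplayCap)
}

#' Gene-set enrichment of clusters against a GMT collection
#'
#' Standard hypergeometric overlap of every cluster with every gene set,
#' over the clustered gene universe, BH-adjusted across the batch.  Sets
#' with no gene in the universe are skipped with a warning.
#'
#' @param labels named integer vector gene -> cluster (or a
#'   \linkS4class{ClusterAssignment}).
#' @param sets named list of gene id vectors (see \code{\link{readGMT}}).
#' @param config \linkS4class{PipelineConfig}.
#' @param alpha significance threshold (default
#'   \code{config@mergeAlpha}).
#' @return data.frame with one row per cluster x set test.
#' @export
geneSetEnrichment <- function(labels, sets, config = PipelineConfig(),
                              alpha = config@mergeAlpha) {
  if (is(labels, "ClusterAssignment")) labels <- clusterLabels(labels)
  genes <- names(labels)
  sets <- lapply(sets, intersect, y = genes)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sprintf("gene set(s) with no gene in the universe skipped: %s",
                    paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  if (!length(sets))
    return(data.frame(cluster_id = integer(), set = character(),
                      q = integer(), m = integer(), n = integer(),
                      k = integer(), p_value = numeric(), fdr = numeric(),
                      fdr_displayed = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  total <- length(genes)
  rows <- list()
  for (cl in sort(unique(labels))) {
    members <- genes[labels == cl]
    for (s in names(sets)) {
      m <- length(sets[[s]])
      rows[[length(rows) + 1L]] <-
        data.frame(cluster_id = cl, set = s,
                   q = sum(members %in% sets[[s]]), m = m, n = total - m,
                   k = length(members), stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_value <- hypergeomUpper(tests$q, tests$m, tests$n, tests$k)
  .enrichmentTable(tests, alpha, config@fdrDisplayCap)
}
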