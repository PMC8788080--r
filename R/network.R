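#' Build the tissue / gene-combination network of enriched genes
#'
#' Considers only tissue enriched and group enriched genes.  Each distinct
#' combination of elevated tissues observed among them becomes one gene
#' node (carrying the gene count and whether it contains tissue-enriched
#' genes), connected by an edge to each member tissue node.  Every gene
#' appears in exactly one gene node; tissue-enriched combinations have
#' exactly one edge.
#'
#' @param specificity specificity table from \code{\link{classifyAll}}.
#' @param organSystems optional named character vector tissue -> organ
#'   system (used as a node attribute for display).
#' @return a \linkS4class{GeneNetwork} (display flags unset; see
#'   \code{\link{applyDisplayRules}}).
#' @export
buildGeneNetwork <- function(specificity, organSystems = NULL) {
  el <- specificity[specificity$category %in%
                      c("tissue_enriched", "group_enriched"), ]
  if (nrow(el) && any(!nzchar(el$elevated_tissues)))
    stop("enriched/group-enriched call with empty elevated tissue set")
  if (!nrow(el)) {
    return(new("GeneNetwork",
               tissueNodes = data.frame(tissue = character(),
                                        organ_system = character(),
                                        n_genes = integer(),
                                        stringsAsFactors = FALSE),
               geneNodes = data.frame(node_id = character(),
                                      tissues = character(),
                                      n_genes = integer(),
                                      has_enriched = logical(),
                                      displayed = logical(),
                                      gene_ids = character(),
                                      stringsAsFactors = FALSE),
               edges = data.frame(gene_node = character(),
                                  tissue = character(),
                                  stringsAsFactors = FALSE)))
  }
  combos <- vapply(strsplit(el$elevated_tissues, ";", fixed = TRUE),
                   function(t) paste(sort(t), collapse = ";"), character(1))
  byCombo <- split(seq_len(nrow(el)), combos)
  geneNodes <- do.call(rbind, lapply(names(byCombo), function(cmb) {
    idx <- byCombo[[cmb]]
    data.frame(node_id = cmb, tissues = cmb, n_genes = length(idx),
               has_enriched = any(el$category[idx] == "tissue_enriched"),
               displayed = NA,
               gene_ids = paste(el$gene_id[idx], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  edges <- do.call(rbind, lapply(geneNodes$node_id, function(cmb)
    data.frame(gene_node = cmb,
               tissue = strsplit(cmb, ";", fixed = TRUE)[[1L]],
               stringsAsFactors = FALSE)))
  tissues <- sort(unique(edges$tissue))
  tissueNodes <- data.frame(
    tissue = tissues,
    organ_system = if (is.null(organSystems)) NA_character_
                   else unname(organSystems[tissues]),
    n_genes = vapply(tissues, function(t)
      sum(geneNodes$n_genes[geneNodes$node_id %in%
                              edges$gene_node[edges$tissue == t]]),
      integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  new("GeneNetwork", tissueNodes = tissueNodes, geneNodes = geneNodes,
      edges = edges)
}

#' Display-filtering rules for gene nodes
#'
#' A gene node is flagged displayed if it (1) contains tissue-enriched
#' genes, or (2) contains at least 5 genes, or (3) ranks among the top 2
#' largest nodes of any connected tissue and contains at least 2 genes.
#' Rule-3 ranking uses competition ranking on gene counts (ties share
#' ranks), so two equal-count nodes can both be top 2.
#'
#' @param net a \linkS4class{GeneNetwork}.
#' @return the network with the \code{displayed} flag filled in.
#' @export
applyDisplayRules <- function(net) {
  gn <- net@geneNodes
  if (!nrow(gn)) return(net)
  counts <- stats::setNames(gn$n_genes, gn$node_id)
  topRank <- rep(Inf, nrow(gn))
  for (t in net@tissueNodes$tissue) {
    nodes <- net@edges$gene_node[net@edges$tissue == t]
    cnt <- counts[nodes]
    rank <- vapply(cnt, function(x) 1L + sum(cnt > x), integer(1))
    idx <- match(nodes, gn$node_id)
    topRank[idx] <- pmin(topRank[idx], rank)
  }
  gn$displayed <- gn$has_enriched |
    gn$n_genes >= 5L |
    (topRank <= 2 & gn$n_genes >= 2L)
  net@geneNodes <- gn
  net
}

#' Export a gene network
#'
#' GraphML (via igraph, with node attributes \code{type},
#' \code{n_genes}, \code{has_enriched}, \code{displayed},
#' \code{organ_system}), SIF (\code{geneNode elevated_in tissue} lines) or
#' a plain TSV edge list.
#'
#' @param net a \linkS4class{GeneNetwork} (display flags computed).
#' @param path output file path.
#' @param format \code{"graphml"}, \code{"sif"} or \code{"tsv"}.
#' @return invisibly, \code{path}.
#' @export
exportNetwork <- function(net, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  gn <- net@geneNodes
  tn <- net@tissueNodes
  if (format == "sif") {
    lines <- if (nrow(net@edges))
      paste(net@edges$gene_node, "elevated_in", net@edges$tissue) else character()
    writeLines(lines, path)
    return(invisible(path))
  }
  if (format == "tsv") {
    writeTable(net@edges, path)
    return(invisible(path))
  }
  # gene-combination vertex names are prefixed so that a single-tissue
  # combination cannot collide with the tissue vertex of the same name
  gid <- paste0("genes|", gn$node_id)
  vertices <- data.frame(
    name = c(tn$tissue, gid),
    type = c(rep("tissue", nrow(tn)), rep("gene_combination", nrow(gn))),
    combination = c(tn$tissue, gn$node_id),
    n_genes = c(tn$n_genes, gn$n_genes),
    has_enriched = c(rep(NA, nrow(tn)), gn$has_enriched),
    displayed = c(rep(NA, nrow(tn)), gn$displayed),
    organ_system = c(tn$organ_system, rep(NA_character_, nrow(gn))),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = paste0("genes|", net@edges$gene_node),
                      to = net@edges$tissue, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
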