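#' @import methods
NULL

.EXPR_STAGES <- c("counts", "tpm", "ptpm", "tissue_mean", "tmm", "nx")

.SPECIFICITY_CATEGORIES <- c("tissue_enriched", "group_enriched",
                             "tissue_enhanced", "low_specificity",
                             "not_detected")

.DISTRIBUTION_CATEGORIES <- c("detected_in_all", "detected_in_many",
                              "detected_in_some", "detected_in_single",
                              "not_detected")

#' ExpressionMatrix: a gene-by-column expression matrix with a unit stage
#'
#' Dense non-negative gene x column matrix tagged with the normalization
#' stage it represents (\code{counts}, \code{tpm}, \code{ptpm},
#' \code{tissue_mean}, \code{tmm} or \code{nx}).  Columns are samples,
#' tissues or grouped tissues depending on the stage.  Gene lengths (in kb)
#' travel with the object; they are required only for the counts-to-TPM
#' step.
#'
#' @slot values numeric matrix with gene ids as rownames and column ids as
#'   colnames.
#' @slot stage character scalar, one of the stage vocabulary.
#' @slot geneLengths numeric vector of per-gene lengths in kb (length zero
#'   when unknown).
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
         representation(values = "matrix",
                        stage = "character",
                        geneLengths = "numeric"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (length(object@stage) != 1L || !object@stage %in% .EXPR_STAGES)
    msg <- c(msg, sprintf("stage must be one of: %s",
                          paste(.EXPR_STAGES, collapse = ", ")))
  if ((nrow(v) && is.null(rownames(v))) || (ncol(v) && is.null(colnames(v))))
    msg <- c(msg, "values must have gene ids as rownames and column ids as colnames")
  else {
    dup <- rownames(v)[duplicated(rownames(v))]
    if (length(dup))
      msg <- c(msg, sprintf("duplicate gene id: %s", dup[1L]))
    dup <- colnames(v)[duplicated(colnames(v))]
    if (length(dup))
      msg <- c(msg, sprintf("duplicate column id: %s", dup[1L]))
  }
  if (!is.numeric(v))
    msg <- c(msg, "values must be numeric")
  else if (any(!is.finite(v)))
    msg <- c(msg, "values must be finite")
  else if (any(v < 0))
    msg <- c(msg, "values must be non-negative")
  if (length(object@geneLengths)) {
    if (length(object@geneLengths) != nrow(v))
      msg <- c(msg, "geneLengths must have one entry per gene")
    else if (any(!is.finite(object@geneLengths)) || any(object@geneLengths <= 0))
      msg <- c(msg, "geneLengths must be positive and finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample/tissue ids).
#' @param stage normalization stage of the values.
#' @param geneLengths optional per-gene lengths in kb.
#' @return an \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, "counts")
#' @export
ExpressionMatrix <- function(values, stage, geneLengths = NULL) {
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, stage = stage,
      geneLengths = if (is.null(geneLengths)) numeric() else
        unname(as.numeric(geneLengths)))
}

#' SampleSheet: sample annotation with tissue hierarchy
#'
#' Maps each sequenced sample to a tissue, each tissue to a grouped tissue,
#' and each grouped tissue to an organ system.  Both maps must be
#' functional (a tissue belongs to exactly one grouped tissue, a grouped
#' tissue to exactly one organ system).
#'
#' @slot data data.frame with columns \code{sample_id}, \code{tissue},
#'   \code{grouped_tissue}, \code{organ_system} plus optional subject
#'   columns.
#' @exportClass SampleSheet
setClass("SampleSheet", representation(data = "data.frame"))

setValidity("SampleSheet", function(object) {
  d <- object@data
  msg <- character()
  need <- c("sample_id", "tissue", "grouped_tissue", "organ_system")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  dup <- d$sample_id[duplicated(d$sample_id)]
  if (length(dup))
    msg <- c(msg, sprintf("duplicate sample_id: %s", dup[1L]))
  tg <- unique(d[, c("tissue", "grouped_tissue")])
  bad <- tg$tissue[duplicated(tg$tissue)]
  if (length(bad))
    msg <- c(msg, sprintf("tissue '%s' maps to more than one grouped_tissue", bad[1L]))
  go <- unique(d[, c("grouped_tissue", "organ_system")])
  bad <- go$grouped_tissue[duplicated(go$grouped_tissue)]
  if (length(bad))
    msg <- c(msg, sprintf("grouped_tissue '%s' maps to more than one organ_system", bad[1L]))
  if (length(msg)) msg else TRUE
})

#' Construct a SampleSheet
#'
#' @param data data.frame with columns \code{sample_id}, \code{tissue},
#'   \code{grouped_tissue}, \code{organ_system}.
#' @return a \linkS4class{SampleSheet}.
#' @export
SampleSheet <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  new("SampleSheet", data = data)
}

#' PipelineConfig: tunable parameters of the annotation pipeline
#'
#' Holds every threshold and algorithm parameter used downstream, with the
#' atlas defaults: 4-fold specificity cutoff, NX >= 1 detection, group size
#' 2--5, 31 percent "detected in many" fraction, UMAP n_neighbors = 15 and
#' n_epochs = 1000, DBSCAN eps = 0.1 with minPts = 5, 50 k-means
#' iterations, cluster merging at BH-adjusted p < 0.05, final cluster-tissue
#' association at BH-adjusted p < 0.001, and an FDR display floor of 1e-100.
#'
#' @slot detectionThreshold NX detection cut-off (default 1).
#' @slot foldChange fold-change cut-off for specificity rules (default 4).
#' @slot groupMin,groupMax allowed group-enriched group sizes (2, 5).
#' @slot manyFraction fraction of tissues defining "detected in many" (0.31).
#' @slot umapNeighbors,umapEpochs UMAP parameters (15, 1000).
#' @slot dbscanEps,dbscanMinPts DBSCAN parameters (0.1, 5).
#' @slot kmeansIterations maximum Lloyd iterations (50).
#' @slot mergeAlpha BH threshold for cluster merging (0.05).
#' @slot associationAlpha BH threshold for final cluster-tissue association
#'   (0.001).
#' @slot fdrDisplayCap display floor for exported FDR values (1e-100).
#' @slot adjacencyEps inter-cluster adjacency radius; \code{NA} means "use
#'   \code{dbscanEps}".
#' @slot areaUnit embedding area per extra k-means center; \code{NA} means
#'   "total hull area / 50".
#' @slot randomSeed integer seed handed to every stochastic step.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
         representation(detectionThreshold = "numeric",
                        foldChange = "numeric",
                        groupMin = "numeric",
                        groupMax = "numeric",
                        manyFraction = "numeric",
                        umapNeighbors = "numeric",
                        umapEpochs = "numeric",
                        dbscanEps = "numeric",
                        dbscanMinPts = "numeric",
                        kmeansIterations = "numeric",
                        mergeAlpha = "numeric",
                        associationAlpha = "numeric",
                        fdrDisplayCap = "numeric",
                        adjacencyEps = "numeric",
                        areaUnit = "numeric",
                        randomSeed = "numeric"),
         prototype(detectionThreshold = 1,
                   foldChange = 4,
                   groupMin = 2,
                   groupMax = 5,
                   manyFraction = 0.31,
                   umapNeighbors = 15,
                   umapEpochs = 1000,
                   dbscanEps = 0.1,
                   dbscanMinPts = 5,
                   kmeansIterations = 50,
                   mergeAlpha = 0.05,
                   associationAlpha = 0.001,
                   fdrDisplayCap = 1e-100,
                   adjacencyEps = NA_real_,
                   areaUnit = NA_real_,
                   randomSeed = 42))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  pos <- c("detectionThreshold", "foldChange", "umapNeighbors", "umapEpochs",
           "dbscanEps", "dbscanMinPts", "kmeansIterations", "mergeAlpha",
           "associationAlpha", "fdrDisplayCap")
  for (s in pos) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (object@groupMin < 2)
    msg <- c(msg, "groupMin must be >= 2")
  if (object@groupMax < object@groupMin)
    msg <- c(msg, "groupMax must be >= groupMin")
  if (!(object@manyFraction > 0 && object@manyFraction < 1))
    msg <- c(msg, "manyFraction must be strictly between 0 and 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param ... named parameters overriding the defaults (see slot docs).
#' @return a \linkS4class{PipelineConfig}.
#' @examples
#' cfg <- PipelineConfig(foldChange = 4, randomSeed = 1)
#' @export
PipelineConfig <- function(...) new("PipelineConfig", ...)

#' Embedding: 2-D gene coordinates from UMAP
#'
#' @slot coords numeric matrix (genes x 2) with gene ids as rownames.
#' @slot parameters list of UMAP parameters used.
#' @slot seed integer seed used.
#' @exportClass Embedding
setClass("Embedding",
         representation(coords = "matrix", parameters = "list",
                        seed = "numeric"))

setValidity("Embedding", function(object) {
  if (ncol(object@coords) != 2L) return("coords must have two columns")
  if (is.null(rownames(object@coords))) return("coords must have gene ids as rownames")
  if (any(!is.finite(object@coords))) return("coords must be finite")
  TRUE
})

#' SeedCenters: initial k-means centers derived from density clustering
#'
#' @slot centers numeric matrix (centers x 2).
#' @slot provenance character, \code{"density_centroid"} or
#'   \code{"area_sample"} per center.
#' @exportClass SeedCenters
setClass("SeedCenters",
         representation(centers = "matrix", provenance = "character"))

setValidity("SeedCenters", function(object) {
  if (nrow(object@centers) < 1L) return("at least one center required")
  if (nrow(object@centers) != length(object@provenance))
    return("one provenance entry per center required")
  if (!all(object@provenance %in% c("density_centroid", "area_sample")))
    return("provenance must be density_centroid or area_sample")
  TRUE
})

#' ClusterAssignment: final Tissue Expression Cluster membership
#'
#' @slot labels named integer vector, gene id -> cluster id (contiguous
#'   from 1).
#' @slot clusters data.frame with one row per cluster: \code{cluster_id},
#'   \code{n_genes}, \code{significant_tissues} (semicolon-joined, at the
#'   association threshold), \code{min_fdr}, \code{min_fdr_displayed}.
#' @slot enrichment data.frame of all final cluster x tissue tests.
#' @slot trace list of per-round merge diagnostics.
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
         representation(labels = "integer", clusters = "data.frame",
                        enrichment = "data.frame", trace = "list"))

setValidity("ClusterAssignment", function(object) {
  l <- object@labels
  if (is.null(names(l))) return("labels must be named by gene id")
  k <- length(unique(l))
  if (k && !identical(sort(unique(l)), seq_len(k)))
    return("cluster ids must be contiguous integers from 1")
  if (nrow(object@clusters) != k)
    return("one summary row per cluster required")
  if (k && sum(object@clusters$n_genes) != length(l))
    return("cluster sizes must sum to the number of genes")
  TRUE
})

#' GeneNetwork: tissue / gene-combination bipartite network
#'
#' One gene node per distinct combination of elevated tissues among tissue
#' and group enriched genes, connected to each member tissue.
#'
#' @slot tissueNodes data.frame: \code{tissue}, \code{organ_system},
#'   \code{n_genes} (total elevated genes connected).
#' @slot geneNodes data.frame: \code{node_id}, \code{tissues}
#'   (semicolon-joined), \code{n_genes}, \code{has_enriched},
#'   \code{displayed}, \code{gene_ids} (semicolon-joined).
#' @slot edges data.frame: \code{gene_node}, \code{tissue}.
#' @exportClass GeneNetwork
setClass("GeneNetwork",
         representation(tissueNodes = "data.frame", geneNodes = "data.frame",
                        edges = "data.frame"))

setValidity("GeneNetwork", function(object) {
  gn <- object@geneNodes
  if (nrow(gn) == 0L) return(TRUE)
  if (any(gn$n_genes < 1)) return("gene nodes must contain at least one gene")
  deg <- table(object@edges$gene_node)
  if (!all(gn$node_id %in% names(deg)))
    return("every gene node must connect to at least one tissue")
  TRUE
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix [stage: %s] %d genes x %d columns\n",
              object@stage, nrow(object@values), ncol(object@values)))
  if (length(object@geneLengths))
    cat("  with per-gene lengths (kb)\n")
})

setMethod("show", "SampleSheet", function(object) {
  d <- object@data
  cat(sprintf("SampleSheet: %d samples, %d tissues, %d grouped tissues, %d organ systems\n",
              nrow(d), length(unique(d$tissue)),
              length(unique(d$grouped_tissue)),
              length(unique(d$organ_system))))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  for (s in slotNames(object))
    cat(sprintf("  %s: %s\n", s, format(slot(object, s))))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment: %d genes in %d clusters\n",
              length(object@labels), nrow(object@clusters)))
})

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork: %d tissue nodes, %d gene nodes (%d displayed), %d edges\n",
              nrow(object@tissueNodes), nrow(object@geneNodes),
              sum(object@geneNodes$displayed %in% TRUE), nrow(object@edges)))
})
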