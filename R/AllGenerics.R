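#' Accessors for the tecmap S4 classes
#'
#' \code{geneIds} and \code{columnIds} return the row/column identifiers of
#' an \linkS4class{ExpressionMatrix}; \code{exprValues} the numeric matrix;
#' \code{exprStage} the normalization stage tag; \code{geneLengths} the
#' per-gene lengths (kb, possibly empty); \code{sampleInfo} the underlying
#' data.frame of a \linkS4class{SampleSheet}; \code{clusterLabels} the
#' gene -> cluster map of a \linkS4class{ClusterAssignment};
#' \code{clusterSummary} its per-cluster table; \code{embeddingCoords} the
#' gene coordinates of an \linkS4class{Embedding}.
#'
#' @param x the object.
#' @return the slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("columnIds", function(x) standardGeneric("columnIds"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("exprStage", function(x) standardGeneric("exprStage"))

#' @rdname accessors
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("clusterSummary", function(x) standardGeneric("clusterSummary"))

#' @rdname accessors
#' @export
setGeneric("embeddingCoords", function(x) standardGeneric("embeddingCoords"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("columnIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("exprStage", "ExpressionMatrix", function(x) x@stage)

#' @rdname accessors
#' @export
setMethod("geneLengths", "ExpressionMatrix", function(x) {
  if (length(x@geneLengths)) stats::setNames(x@geneLengths, geneIds(x))
  else x@geneLengths
})

#' @rdname accessors
#' @export
setMethod("sampleInfo", "SampleSheet", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("clusterSummary", "ClusterAssignment", function(x) x@clusters)

#' @rdname accessors
#' @export
setMethod("embeddingCoords", "Embedding", function(x) x@coords)
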