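#' Counts to transcripts per million
#'
#' Per column, counts are divided by gene length (kb) to give rates, and
#' rates are rescaled so each column sums to one million.
#'
#' @param counts \linkS4class{ExpressionMatrix} at stage \code{counts}.
#' @param lengths per-gene lengths in kb; defaults to the lengths stored in
#'   \code{counts}.
#' @return \linkS4class{ExpressionMatrix} at stage \code{tpm}.
#' @export
computeTPM <- function(counts, lengths = geneLengths(counts)) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (exprStage(counts) != "counts")
    stop("computeTPM expects a counts-stage matrix")
  v <- exprValues(counts)
  if (!length(lengths))
    stop("gene lengths are required to compute TPM")
  lengths <- if (!is.null(names(lengths))) {
    miss <- setdiff(rownames(v), names(lengths))
    if (length(miss)) stop(sprintf("missing length for gene '%s'", miss[1L]))
    lengths[rownames(v)]
  } else {
    if (length(lengths) != nrow(v)) stop("one length per gene is required")
    lengths
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive")
  zero <- colSums(v) == 0
  if (any(zero))
    stop(sprintf("all-zero column: %s", colnames(v)[which(zero)[1L]]))
  rate <- v / lengths
  tpm <- sweep(rate, 2L, colSums(rate), "/") * 1e6
  ExpressionMatrix(tpm, "tpm", unname(lengths))
}

#' TPM restricted and renormalized to protein-coding genes (pTPM)
#'
#' Drops non-coding genes and rescales every column so the protein-coding
#' genes alone sum to one million.
#'
#' @param tpm \linkS4class{ExpressionMatrix} at stage \code{tpm}.
#' @param annotation data.frame with columns \code{gene_id} and
#'   \code{is_protein_coding}.
#' @return \linkS4class{ExpressionMatrix} at stage \code{ptpm} containing
#'   only the protein-coding genes.
#' @export
computePTPM <- function(tpm, annotation) {
  stopifnot(is(tpm, "ExpressionMatrix"))
  if (exprStage(tpm) != "tpm")
    stop("computePTPM expects a tpm-stage matrix")
  if (anyDuplicated(annotation$gene_id))
    stop("duplicate gene_id in annotation")
  coding <- annotation$gene_id[as.logical(annotation$is_protein_coding)]
  v <- exprValues(tpm)
  keep <- rownames(v) %in% coding
  if (!any(keep))
    stop("no protein-coding genes present")
  v <- v[keep, , drop = FALSE]
  cs <- colSums(v)
  if (any(cs == 0))
    stop(sprintf("no protein-coding expression in column: %s",
                 colnames(v)[which(cs == 0)[1L]]))
  ptpm <- sweep(v, 2L, cs, "/") * 1e6
  len <- geneLengths(tpm)
  ExpressionMatrix(ptpm, "ptpm",
                   if (length(len)) unname(len[rownames(v)]) else NULL)
}

#' Average samples of the same tissue
#'
#' One output column per tissue; the value is the arithmetic mean of that
#' tissue's sample columns.  Tissue order follows first appearance in the
#' sample sheet.
#'
#' @param x \linkS4class{ExpressionMatrix} with sample columns.
#' @param sheet \linkS4class{SampleSheet} covering every column.
#' @return \linkS4class{ExpressionMatrix} at stage \code{tissue_mean}.
#' @export
aggregateTissueMean <- function(x, sheet) {
  stopifnot(is(x, "ExpressionMatrix"), is(sheet, "SampleSheet"))
  v <- exprValues(x)
  d <- sampleInfo(sheet)
  miss <- setdiff(colnames(v), d$sample_id)
  if (length(miss))
    stop(sprintf("sample missing from sheet: %s", miss[1L]))
  tissueOf <- stats::setNames(d$tissue, d$sample_id)[colnames(v)]
  tissues <- unique(tissueOf)
  out <- vapply(tissues, function(t)
    rowMeans(v[, tissueOf == t, drop = FALSE]), numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v),
                dimnames = list(rownames(v), tissues))
  ExpressionMatrix(out, "tissue_mean",
                   if (length(x@geneLengths)) x@geneLengths else NULL)
}

#' TMM between-column correction
#'
#' Computes trimmed-mean-of-M-values scaling factors (trim 30 percent on
#' M, 5 percent on A, precision-weighted, reference column chosen by the
#' 75th-percentile rule, factors renormalized to geometric mean 1) and
#' divides every column by its factor.  The operation is stage-agnostic:
#' it is applied both to the tissue-mean matrix (for classification) and
#' to the sample-level matrix (for clustering).
#'
#' @param x \linkS4class{ExpressionMatrix} with at least two columns.
#' @return list with \code{matrix} (\linkS4class{ExpressionMatrix}, stage
#'   \code{tmm}), \code{factors} (named numeric) and
#'   \code{reference_column}.
#' @export
tmmCorrect <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  if (ncol(v) < 2L)
    stop("TMM correction requires at least two columns")
  lib <- colSums(v)
  if (any(lib == 0))
    stop(sprintf("all-zero column: %s", colnames(v)[which(lib == 0)[1L]]))
  f75 <- apply(sweep(v, 2L, lib, "/"), 2L, stats::quantile, probs = 0.75,
               names = FALSE)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- suppressWarnings(
    edgeR::calcNormFactors(v, lib.size = lib, method = "TMM",
                           refColumn = ref))
  if (any(!is.finite(f))) {
    warning("no genes survived TMM filters for some column(s); factor set to 1")
    f[!is.finite(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  names(f) <- colnames(v)
  corrected <- sweep(v, 2L, f, "/")
  list(matrix = ExpressionMatrix(corrected, "tmm",
                                 if (length(x@geneLengths)) x@geneLengths else NULL),
       factors = f,
       reference_column = colnames(v)[ref])
}

#' Gene-wise pareto scaling (NX)
#'
#' Divides each gene row by the square root of its standard deviation
#' (n - 1 denominator).  Rows with zero standard deviation pass through
#' unchanged.  Applied to the TMM-corrected tissue-mean matrix this yields
#' the NX expression score.
#'
#' @param x \linkS4class{ExpressionMatrix} (typically stage \code{tmm}).
#' @return \linkS4class{ExpressionMatrix} at stage \code{nx}.
#' @export
paretoScale <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  s <- apply(v, 1L, stats::sd)
  scale <- ifelse(s > 0, sqrt(s), 1)
  ExpressionMatrix(v / scale, "nx",
                   if (length(x@geneLengths)) x@geneLengths else NULL)
}

#' Grouped-tissue expression as the maximum over member tissues
#'
#' @param nx \linkS4class{ExpressionMatrix} with tissue columns (stage
#'   \code{nx}).
#' @param sheet \linkS4class{SampleSheet} mapping every tissue column to a
#'   grouped tissue.
#' @return \linkS4class{ExpressionMatrix} at stage \code{nx} with one
#'   column per grouped tissue (order of first appearance).
#' @export
groupedTissueMax <- function(nx, sheet) {
  stopifnot(is(nx, "ExpressionMatrix"), is(sheet, "SampleSheet"))
  v <- exprValues(nx)
  d <- unique(sampleInfo(sheet)[, c("tissue", "grouped_tissue")])
  groupOf <- stats::setNames(d$grouped_tissue, d$tissue)
  miss <- setdiff(colnames(v), names(groupOf))
  if (length(miss))
    stop(sprintf("tissue not mapped to a grouped tissue: %s", miss[1L]))
  g <- groupOf[colnames(v)]
  groups <- unique(unname(g))
  out <- vapply(groups, function(gr)
    apply(v[, g == gr, drop = FALSE], 1L, max), numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v), dimnames = list(rownames(v), groups))
  ExpressionMatrix(out, "nx",
                   if (length(nx@geneLengths)) nx@geneLengths else NULL)
}

#' Run the full NX normalization ladder
#'
#' counts -> TPM -> pTPM -> per-tissue mean -> TMM -> pareto (NX) ->
#' grouped-tissue max.  Also returns the sample-level TMM-corrected pTPM
#' matrix used by Tissue Expression Clustering.
#'
#' @param counts \linkS4class{ExpressionMatrix} at stage \code{counts}
#'   (with gene lengths), or at stage \code{tpm} to skip the first step.
#' @param sheet \linkS4class{SampleSheet}.
#' @param annotation gene annotation data.frame (\code{gene_id},
#'   \code{is_protein_coding}); defaults to all genes protein-coding.
#' @return list with elements \code{tpm}, \code{ptpm}, \code{tissueMean},
#'   \code{tissueTmm}, \code{tmmFactors}, \code{nx}, \code{nxGrouped},
#'   \code{sampleTmm} (sample-level TMM-corrected pTPM) and
#'   \code{sampleTmmFactors}.
#' @export
normalizeAtlas <- function(counts, sheet, annotation = NULL) {
  stopifnot(is(counts, "ExpressionMatrix"))
  tpm <- if (exprStage(counts) == "counts") computeTPM(counts) else counts
  if (exprStage(tpm) != "tpm")
    stop("input must be at stage counts or tpm")
  if (is.null(annotation))
    annotation <- data.frame(gene_id = geneIds(tpm),
                             is_protein_coding = TRUE,
                             stringsAsFactors = FALSE)
  ptpm <- computePTPM(tpm, annotation)
  tm <- aggregateTissueMean(ptpm, sheet)
  tmm <- tmmCorrect(tm)
  nx <- paretoScale(tmm$matrix)
  nxg <- groupedTissueMax(nx, sheet)
  stmm <- tmmCorrect(ptpm)
  list(tpm = tpm, ptpm = ptpm, tissueMean = tm, tissueTmm = tmm$matrix,
       tmmFactors = tmm$factors, nx = nx, nxGrouped = nxg,
       sampleTmm = stmm$matrix, sampleTmmFactors = stmm$factors)
}
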