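#' Read a gene x column expression matrix from TSV
#'
#' The canonical table dialect is tab-separated, UTF-8, decimal point, with
#' a header row of column ids and the gene id in the first column.  Input
#' ordering of genes and columns is preserved, never sorted.
#'
#' @param path file path.
#' @param stage normalization stage of the stored values.
#' @param geneLengths optional named numeric vector of gene lengths (kb).
#' @return an \linkS4class{ExpressionMatrix}.
#' @export
readExpressionMatrix <- function(path, stage, geneLengths = NULL) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         colClasses = "character", quote = "")
  if (ncol(d) < 2L)
    stop("expression TSV must have a gene id column plus at least one data column")
  ids <- d[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate gene id: %s", dup[1L]))
  body <- as.matrix(d[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at gene '%s', column '%s'",
                 ids[bad[1L]], colnames(body)[bad[2L]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at gene '%s', column '%s'",
                 ids[bad[1L]], colnames(body)[bad[2L]]))
  }
  dimnames(num) <- list(ids, colnames(body))
  if (!is.null(geneLengths)) geneLengths <- unname(geneLengths[ids])
  ExpressionMatrix(num, stage, geneLengths)
}

#' Write an ExpressionMatrix to TSV
#'
#' Values are written with full double precision (15 significant digits) so
#' that write/read round-trips preserve values to at least 12 significant
#' digits.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output file path.
#' @param idColumn name for the gene id column (default \code{"gene_id"}).
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path, idColumn = "gene_id") {
  v <- exprValues(x)
  d <- data.frame(rownames(v), apply(v, 2L, format, digits = 15,
                                     trim = TRUE, scientific = NA),
                  check.names = FALSE, stringsAsFactors = FALSE)
  names(d) <- c(idColumn, colnames(v))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Requires columns \code{sample_id}, \code{tissue}, \code{grouped_tissue},
#' \code{organ_system}; validity of the tissue hierarchy is enforced.
#'
#' @param path file path.
#' @return a \linkS4class{SampleSheet}.
#' @export
readSampleSheet <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE, quote = "")
  SampleSheet(d)
}

#' Write a data.frame (or SampleSheet) as TSV
#'
#' @param x data.frame or \linkS4class{SampleSheet}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTable <- function(x, path) {
  if (is(x, "SampleSheet")) x <- sampleInfo(x)
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then member gene ids.
#'
#' @param path file path.
#' @return named list of character vectors of gene ids.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT lines must contain name, description and at least one gene")
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param description per-set description (recycled).
#' @return invisibly, \code{path}.
#' @export
writeGMT <- function(sets, path, description = "") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a dendrogram as Newick
#'
#' Branch lengths are the merge heights of the agglomeration.
#'
#' @param tree an \code{hclust} object (as returned by
#'   \code{\link{tissueTree}}) or an \code{ape::phylo}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the \linkS4class{PipelineConfig} slots
#' field-for-field; absent keys keep their defaults.  Unknown keys are an
#' error so that typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return a \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- slotNames("PipelineConfig")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  do.call(PipelineConfig, lapply(y, as.numeric))
}

#' Write a pipeline configuration to YAML
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePipelineConfig <- function(config, path) {
  vals <- lapply(slotNames(config), function(s) slot(config, s))
  names(vals) <- slotNames(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Read an ortholog table from TSV
#'
#' Columns: \code{gene_id_a}, \code{gene_id_b}, \code{homology_type}
#' (one2one / one2many / many2many), \code{confidence} (high / low).
#'
#' @param path file path.
#' @return a validated ortholog data.frame.
#' @export
readOrthologMap <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  validateOrthologMap(d)
}

#' Validate an ortholog table
#'
#' @param map data.frame with the ortholog columns (see
#'   \code{\link{readOrthologMap}}).
#' @return the validated data.frame.
#' @export
validateOrthologMap <- function(map) {
  need <- c("gene_id_a", "gene_id_b", "homology_type", "confidence")
  miss <- setdiff(need, names(map))
  if (length(miss))
    stop(sprintf("ortholog map missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(map[, c("gene_id_a", "gene_id_b")]))
    stop("duplicate (gene_id_a, gene_id_b) pair in ortholog map")
  if (!all(map$homology_type %in% c("one2one", "one2many", "many2many")))
    stop("homology_type must be one2one, one2many or many2many")
  if (!all(map$confidence %in% c("high", "low")))
    stop("confidence must be high or low")
  map
}
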