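#' Run the full atlas annotation pipeline
#'
#' Orchestrates: (optional) simulation -> normalization ladder ->
#' specificity/distribution classification -> tissue similarity tree ->
#' Tissue Expression Clustering -> cluster-tissue enrichment -> enriched
#' gene network, writing every output as TSV / Newick / GraphML into
#' \code{outDir} together with a JSON run manifest (config snapshot, input
#' digests, per-stage dimensions, seed, package version, timestamps).  On
#' error, outputs already written are renamed with a \code{.partial}
#' suffix and the failing stage is named.
#'
#' @param config a \linkS4class{PipelineConfig}, or the path to a YAML
#'   file readable by \code{\link{readPipelineConfig}}.
#' @param outDir output directory (created if missing).
#' @param counts \linkS4class{ExpressionMatrix} at stage \code{counts} or
#'   \code{tpm}; if \code{NULL}, a synthetic atlas is simulated with
#'   \code{simulate} arguments.
#' @param sheet \linkS4class{SampleSheet} (required with \code{counts}).
#' @param annotation optional gene annotation data.frame.
#' @param simulate named list of \code{\link{simulateAtlas}} arguments
#'   used when \code{counts} is \code{NULL} (the config's
#'   \code{randomSeed} is used unless overridden).
#' @return invisibly, a list with all in-memory results plus
#'   \code{manifest}.
#' @export
runPipeline <- function(config = PipelineConfig(), outDir = "tecmap_out",
                        counts = NULL, sheet = NULL, annotation = NULL,
                        simulate = list()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- "setup"
  manifest <- list(
    tool = "tecmap",
    version = as.character(utils::packageVersion("tecmap")),
    seed = config@randomSeed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = stats::setNames(lapply(slotNames(config), function(s)
      slot(config, s)), slotNames(config)),
    stages = list())
  out <- function(name) file.path(outDir, name)
  note <- function(stageName, ...) {
    manifest$stages[[stageName]] <<- list(...)
  }
  emit <- function(writer, x, name) {
    writer(x, out(name))
    written <<- c(written, out(name))
  }
  result <- list()
  ok <- FALSE
  on.exit({
    if (!ok) {
      for (f in written) if (file.exists(f))
        file.rename(f, paste0(f, ".partial"))
      message(sprintf("pipeline aborted during stage '%s'; partial outputs kept with .partial suffix",
                      stage))
    }
  })

  stage <- "simulate"
  if (is.null(counts)) {
    args <- utils::modifyList(list(seed = config@randomSeed), simulate)
    sim <- do.call(simulateAtlas, args)
    counts <- sim$counts; sheet <- sim$sheet; annotation <- sim$annotation
    result$truth <- sim$truth
    emit(writeTable, sim$truth, "truth.tsv")
    emit(writeExpressionMatrix, counts, "counts.tsv")
    emit(writeTable, sheet, "samples.tsv")
    note("simulate", n_genes = nrow(exprValues(counts)),
         n_samples = ncol(exprValues(counts)))
  } else if (is.null(sheet)) {
    stop("a sample sheet is required when counts are supplied")
  }
  manifest$inputs <- list()

  stage <- "normalize"
  norm <- normalizeAtlas(counts, sheet, annotation)
  result$normalized <- norm
  emit(writeExpressionMatrix, norm$nxGrouped, "nx_grouped.tsv")
  emit(writeExpressionMatrix, norm$nx, "nx.tsv")
  emit(writeExpressionMatrix, norm$sampleTmm, "tmm_samples.tsv")
  note("normalize", n_genes = nrow(exprValues(norm$nx)),
       n_tissues = ncol(exprValues(norm$nx)),
       n_grouped = ncol(exprValues(norm$nxGrouped)),
       tmm_factors = as.list(norm$tmmFactors))

  stage <- "classify"
  calls <- classifyAll(norm$nxGrouped, config)
  result$calls <- calls
  emit(writeTable, merge(calls$specificity, calls$distribution,
                         by = "gene_id", suffixes = c("_specificity",
                                                      "_distribution")),
       "classification.tsv")
  emit(writeTable, calls$tissueSummary, "tissue_elevated_counts.tsv")
  note("classify",
       specificity = as.list(table(calls$specificity$category)),
       distribution = as.list(table(calls$distribution$category)))

  stage <- "tree"
  corr <- spearmanMatrix(norm$nx)
  tree <- tissueTree(corr, "ward")
  result$tree <- tree
  emit(writeNewick, tree, "tissue_tree.nwk")
  emit(function(x, p) writeTable(data.frame(tissue = rownames(x), x,
                                            check.names = FALSE), p),
       corr, "tissue_spearman.tsv")
  note("tree", n_tissues = nrow(corr))

  stage <- "cluster"
  tec <- runTissueExpressionClustering(norm$sampleTmm, calls$specificity,
                                       config)
  result$clustering <- tec
  coords <- embeddingCoords(tec$embedding)
  emit(writeTable, data.frame(gene_id = rownames(coords), coords,
                              cluster_id = clusterLabels(tec$assignment)[
                                rownames(coords)],
                              stringsAsFactors = FALSE),
       "gene_clusters.tsv")
  emit(writeTable, clusterSummary(tec$assignment), "cluster_summary.tsv")
  note("cluster", n_clusters = nrow(clusterSummary(tec$assignment)),
       merge_rounds = length(tec$assignment@trace))

  stage <- "enrich"
  enr <- clusterTissueEnrichment(tec$assignment, calls$specificity, config)
  result$enrichment <- enr
  emit(writeTable, enr, "cluster_tissue_enrichment.tsv")
  note("enrich", n_tests = nrow(enr), n_significant = sum(enr$significant))

  stage <- "network"
  d <- unique(sampleInfo(sheet)[, c("grouped_tissue", "organ_system")])
  net <- applyDisplayRules(buildGeneNetwork(
    calls$specificity,
    organSystems = stats::setNames(d$organ_system, d$grouped_tissue)))
  result$network <- net
  if (nrow(net@geneNodes)) {
    emit(exportNetwork, net, "network.graphml")
  }
  note("network", n_gene_nodes = nrow(net@geneNodes),
       n_displayed = sum(net@geneNodes$displayed %in% TRUE))

  stage <- "manifest"
  files <- list.files(outDir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$outputs <- stats::setNames(
    as.list(unname(tools::md5sum(files))), basename(files))
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  result$manifest <- manifest
  ok <- TRUE
  invisible(result)
}
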