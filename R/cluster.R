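#' Log/Z-score transform of a sample-level expression matrix
#'
#' Values are log-transformed as log10(v + 1) and Z-scored per gene row
#' (n - 1 standard deviation).  Rows with zero standard deviation are set
#' to all-zero rather than dropped, so every gene keeps a (degenerate)
#' profile and can still be embedded.
#'
#' @param x \linkS4class{ExpressionMatrix} (sample-level TMM-corrected) or
#'   numeric matrix.
#' @return numeric matrix of Z-scores, same dimnames as the input.
#' @export
zscoreTransform <- function(x) {
  v <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  lg <- log10(v + 1)
  mu <- rowMeans(lg)
  s <- apply(lg, 1L, stats::sd)
  z <- (lg - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

#' 2-D UMAP embedding of gene profiles
#'
#' Runs uwot's UMAP on the Z-scored profiles with no internal rescaling of
#' the inputs (scale = "none") and the configured n_neighbors and
#' n_epochs.  Single-threaded optimization makes the embedding
#' deterministic for a fixed seed.
#'
#' @param z numeric matrix (genes x samples) with gene ids as rownames.
#' @param config \linkS4class{PipelineConfig}.
#' @param seed integer seed (default \code{config@randomSeed}).
#' @return an \linkS4class{Embedding}.
#' @export
embedUMAP <- function(z, config = PipelineConfig(),
                      seed = config@randomSeed) {
  if (nrow(z) < config@umapNeighbors + 1)
    stop(sprintf("at least n_neighbors + 1 = %d genes are required",
                 config@umapNeighbors + 1))
  set.seed(seed)
  coords <- uwot::umap(z,
                       n_neighbors = config@umapNeighbors,
                       n_epochs = config@umapEpochs,
                       scale = FALSE,
                       n_threads = 1,
                       n_sgd_threads = 0)
  rownames(coords) <- rownames(z)
  colnames(coords) <- c("x", "y")
  new("Embedding", coords = coords,
      parameters = list(n_neighbors = config@umapNeighbors,
                        n_epochs = config@umapEpochs, scale = "none"),
      seed = seed)
}

#' Density-based clustering (DBSCAN) of 2-D points
#'
#' Classical density-reachability clustering: points with at least
#' \code{minPts} neighbours (self included) within \code{eps} are core
#' points; clusters are the connected components of density-reachable
#' points; non-core points within \code{eps} of a core join its cluster;
#' the rest are noise (label 0).
#'
#' @param coords numeric matrix (points x 2).
#' @param eps reachability radius.
#' @param minPts minimum neighbourhood size (self included).
#' @return integer vector of cluster labels (0 = noise).
#' @export
dbscanClusters <- function(coords, eps, minPts) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nbr <- d <= eps
  core <- rowSums(nbr) >= minPts
  labels <- integer(n)
  cl <- 0L
  for (i in which(core)) {
    if (labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      reach <- which(nbr[p, ] & labels == 0L)
      if (length(reach)) {
        labels[reach] <- cl
        queue <- c(queue, reach[core[reach]])
      }
    }
  }
  labels
}

.hullArea <- function(pts) {
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  x <- hp[, 1L]; y <- hp[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Initial k-means centers from density clusters
#'
#' Runs DBSCAN on the embedding (noise points are ignored for seeding),
#' places one center at each density cluster's centroid, and gives the two
#' largest clusters (by member count) additional centers in proportion to
#' their approximate area: \code{round(hullArea / areaUnit)} extra centers
#' drawn by seeded sampling of member coordinates, where the area is the
#' convex hull of the members and \code{areaUnit} defaults to the total
#' hull area of all clusters divided by 50.  If DBSCAN finds no cluster,
#' a single center at the global centroid is returned with a warning.
#'
#' @param embedding an \linkS4class{Embedding}.
#' @param config \linkS4class{PipelineConfig}.
#' @param seed integer seed for the area-proportional sampling.
#' @return a \linkS4class{SeedCenters}.
#' @export
seedCenters <- function(embedding, config = PipelineConfig(),
                        seed = config@randomSeed) {
  coords <- embeddingCoords(embedding)
  labels <- dbscanClusters(coords, config@dbscanEps, config@dbscanMinPts)
  if (all(labels == 0L)) {
    warning("DBSCAN found no density cluster; seeding a single global centroid")
    return(new("SeedCenters",
               centers = matrix(colMeans(coords), 1L, 2L,
                                dimnames = list(NULL, c("x", "y"))),
               provenance = "density_centroid"))
  }
  ids <- sort(unique(labels[labels > 0L]))
  centroids <- t(vapply(ids, function(cl)
    colMeans(coords[labels == cl, , drop = FALSE]), numeric(2)))
  sizes <- vapply(ids, function(cl) sum(labels == cl), integer(1))
  areas <- vapply(ids, function(cl)
    .hullArea(coords[labels == cl, , drop = FALSE]), numeric(1))
  areaUnit <- if (is.finite(config@areaUnit)) config@areaUnit
              else sum(areas) / 50
  centers <- centroids
  provenance <- rep("density_centroid", nrow(centroids))
  set.seed(seed)
  for (cl in ids[order(sizes, decreasing = TRUE)][seq_len(min(2L, length(ids)))]) {
    idx <- which(ids == cl)
    nExtra <- if (areaUnit > 0) round(areas[idx] / areaUnit) else 0
    if (nExtra > 0) {
      members <- which(labels == cl)
      pick <- sample(members, min(nExtra, length(members)))
      centers <- rbind(centers, coords[pick, , drop = FALSE])
      provenance <- c(provenance, rep("area_sample", length(pick)))
    }
  }
  rownames(centers) <- NULL
  colnames(centers) <- c("x", "y")
  new("SeedCenters", centers = centers, provenance = provenance)
}

#' k-means partition from fixed initial centers
#'
#' Plain Lloyd iterations (at most \code{kmeansIterations}, no
#' re-initialization) from the given seed centers.  A center whose cluster
#' empties is dropped with a warning and the remaining clusters are
#' relabelled contiguously.  The within-cluster sum of squares after each
#' iteration is returned for auditing; it is non-increasing.
#'
#' @param embedding an \linkS4class{Embedding}.
#' @param centers a \linkS4class{SeedCenters} (or numeric matrix).
#' @param config \linkS4class{PipelineConfig}.
#' @return list with \code{labels} (named integer vector), \code{centers}
#'   (final centroids) and \code{sse} (per-iteration objective).
#' @export
kmeansPartition <- function(embedding, centers, config = PipelineConfig()) {
  coords <- embeddingCoords(embedding)
  cen <- if (is(centers, "SeedCenters")) centers@centers else as.matrix(centers)
  if (nrow(cen) < 1L) stop("at least one center is required")
  sse <- numeric()
  labels <- integer(nrow(coords))
  for (iter in seq_len(config@kmeansIterations)) {
    d2 <- outer(rowSums(coords^2), rowSums(cen^2), "+") -
      2 * coords %*% t(cen)
    newLabels <- max.col(-d2, ties.method = "first")
    occupied <- sort(unique(newLabels))
    if (length(occupied) < nrow(cen)) {
      warning(sprintf("%d empty cluster(s) dropped during k-means",
                      nrow(cen) - length(occupied)))
      newLabels <- match(newLabels, occupied)
      cen <- cen[occupied, , drop = FALSE]
      d2 <- d2[, occupied, drop = FALSE]
    }
    sse <- c(sse, sum(d2[cbind(seq_len(nrow(coords)), newLabels)]))
    converged <- identical(newLabels, labels)
    labels <- newLabels
    cen <- rowsum(coords, labels) /
      as.vector(table(factor(labels, seq_len(nrow(cen)))))
    if (converged) break
  }
  names(labels) <- rownames(coords)
  list(labels = labels, centers = cen, sse = sse)
}

.clusterPairMinDist <- function(coords, labels) {
  ids <- sort(unique(labels))
  k <- length(ids)
  d <- as.matrix(stats::dist(coords))
  out <- matrix(Inf, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    m <- min(d[labels == ids[i], labels == ids[j]])
    out[i, j] <- out[j, i] <- m
  }
  out
}

.significantTissueSets <- function(labels, specificity, config, alpha) {
  enr <- clusterTissueEnrichment(labels, specificity, config,
                                 mode = "standard", alpha = alpha)
  ids <- sort(unique(labels))
  sets <- lapply(ids, function(cl) {
    d <- enr[enr$cluster_id == cl, ]
    sort(d$tissue[d$significant])
  })
  names(sets) <- ids
  list(sets = sets, enrichment = enr)
}

#' Merge adjacent clusters enriched for the same tissues
#'
#' Iteratively: (a) every cluster x tissue overlap is tested
#' hypergeometrically and BH-adjusted across the batch; (b) each cluster's
#' significant-tissue set is read off at \code{mergeAlpha}; (c) every
#' adjacent pair with identical, non-empty significant sets is merged
#' (adjacency = minimum inter-member distance at most
#' \code{adjacencyEps}, which defaults to \code{dbscanEps}).  The loop
#' repeats until no merge applies, so chains of pairwise-adjacent clusters
#' with the same tissue signature collapse into one.  Final cluster ids
#' are contiguous (by order of first gene appearance) and the final
#' significant tissues are recomputed at \code{associationAlpha}.
#'
#' @param labels named integer vector gene -> cluster (k-means output).
#' @param embedding the \linkS4class{Embedding} the labels live in.
#' @param specificity specificity table from \code{\link{classifyAll}}.
#' @param config \linkS4class{PipelineConfig}.
#' @return a \linkS4class{ClusterAssignment}.
#' @export
mergeAdjacentClusters <- function(labels, embedding, specificity,
                                  config = PipelineConfig()) {
  coords <- embeddingCoords(embedding)
  if (!setequal(names(labels), rownames(coords)))
    stop("labels and embedding must cover the same genes")
  if (!setequal(names(labels), specificity$gene_id))
    stop("labels and specificity table must cover the same genes")
  labels <- labels[rownames(coords)]
  adjEps <- if (is.finite(config@adjacencyEps)) config@adjacencyEps
            else config@dbscanEps
  trace <- list()
  repeat {
    st <- .significantTissueSets(labels, specificity, config,
                                 config@mergeAlpha)
    sets <- st$sets
    ids <- as.integer(names(sets))
    minDist <- .clusterPairMinDist(coords, labels)
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    merged <- 0L
    for (i in seq_len(length(ids) - 1L)) for (j in seq(i + 1L, length(ids))) {
      if (minDist[i, j] <= adjEps &&
          length(sets[[i]]) > 0 &&
          identical(sets[[i]], sets[[j]])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) { parent[max(ri, rj)] <- min(ri, rj); merged <- merged + 1L }
      }
    }
    trace[[length(trace) + 1L]] <-
      list(n_clusters = length(ids), n_merges = merged)
    if (merged == 0L) break
    root <- vapply(seq_along(ids), find, integer(1))
    labels <- stats::setNames(match(root[match(labels, ids)],
                                    sort(unique(root))),
                              names(labels))
  }
  # contiguous ids in order of first gene appearance
  labels <- stats::setNames(match(labels, unique(labels)), names(labels))
  final <- .significantTissueSets(labels, specificity, config,
                                  config@associationAlpha)
  enr <- final$enrichment
  summ <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    e <- enr[enr$cluster_id == cl, ]
    data.frame(cluster_id = cl,
               n_genes = sum(labels == cl),
               significant_tissues = paste(sort(e$tissue[e$significant]),
                                           collapse = ";"),
               min_fdr = if (nrow(e)) min(e$fdr) else NA_real_,
               min_fdr_displayed = if (nrow(e))
                 max(min(e$fdr), config@fdrDisplayCap) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(summ))
    summ <- data.frame(cluster_id = integer(), n_genes = integer(),
                       significant_tissues = character(), min_fdr = numeric(),
                       min_fdr_displayed = numeric(), stringsAsFactors = FALSE)
  new("ClusterAssignment", labels = labels, clusters = summ,
      enrichment = enr, trace = trace)
}

#' Tissue Expression Clustering
#'
#' The full gene-clustering pipeline: Z-score the sample-level
#' TMM-corrected matrix, embed it in 2-D with UMAP, seed k-means centers
#' from DBSCAN density clusters (with area-proportional extras for the two
#' largest), run Lloyd k-means, and merge adjacent clusters that are
#' significantly enriched for the same tissues.  Every gene receives
#' exactly one final Tissue Expression Cluster.
#'
#' @param sampleTmm \linkS4class{ExpressionMatrix} at stage \code{tmm}
#'   with sample columns.
#' @param specificity specificity table from \code{\link{classifyAll}}
#'   covering the same genes.
#' @param config \linkS4class{PipelineConfig}; \code{randomSeed} drives
#'   the embedding and the center sampling.
#' @return list with \code{embedding} (\linkS4class{Embedding}),
#'   \code{assignment} (\linkS4class{ClusterAssignment}) and
#'   \code{kmeans} (raw pre-merge k-means result).
#' @export
runTissueExpressionClustering <- function(sampleTmm, specificity,
                                          config = PipelineConfig()) {
  z <- zscoreTransform(sampleTmm)
  embedding <- embedUMAP(z, config)
  centers <- seedCenters(embedding, config)
  km <- kmeansPartition(embedding, centers, config)
  assignment <- mergeAdjacentClusters(km$labels, embedding, specificity,
                                      config)
  list(embedding = embedding, assignment = assignment, kmeans = km)
}
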