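mkEmbedding <- function(coords, ids = paste0("g", seq_len(nrow(coords)))) {
  rownames(coords) <- ids
  colnames(coords) <- c("x", "y")
  new("Embedding", coords = coords, parameters = list(), seed = 0)
}

blob <- function(n, cx, cy, radius) {
  cbind(cx + runif(n, -radius, radius), cy + runif(n, -radius, radius))
}

test_that("Z-scores follow the log10(x+1), n-1 SD convention", {
  m <- matrix(c(5, 5, 5, 1, 3, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("const", "var"), paste0("s", 1:3)))
  z <- zscoreTransform(ExpressionMatrix(m, "tmm"))
  expect_identical(unname(z["const", ]), c(0, 0, 0))

  two <- matrix(c(1, 3), 1, 2, dimnames = list("g", c("a", "b")))
  z2 <- zscoreTransform(two)
  expect_equal(unname(z2[1, ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(501)
  r <- matrix(rexp(20 * 8, 1 / 50), 20, 8,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
  zr <- zscoreTransform(r)
  expect_equal(unname(rowMeans(zr)), rep(0, 20), tolerance = 1e-9)
  sds <- apply(zr, 1, sd)
  expect_true(all(abs(sds - 1) < 1e-9 | sds == 0))
})

test_that("UMAP embedding is shaped and seeded deterministically", {
  set.seed(502)
  z <- matrix(rnorm(200 * 10), 200, 10,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  cfg <- PipelineConfig(umapEpochs = 100, randomSeed = 3)
  e1 <- embedUMAP(z, cfg)
  expect_identical(dim(embeddingCoords(e1)), c(200L, 2L))
  e2 <- embedUMAP(z, cfg)
  expect_identical(embeddingCoords(e1), embeddingCoords(e2))
  expect_error(embedUMAP(z[1:10, ], cfg), "n_neighbors")
})

test_that("orthogonal planted modules separate in the embedding", {
  cfg <- PipelineConfig(umapEpochs = 300)
  for (seed in 1:3) {
    set.seed(seed)
    prof <- rbind(matrix(rep(c(5, 0), each = 5), 100, 10, byrow = TRUE),
                  matrix(rep(c(0, 5), each = 5), 100, 10, byrow = TRUE)) +
      matrix(rnorm(200 * 10, 0, 0.3), 200, 10)
    rownames(prof) <- paste0("g", 1:200)
    cfg@randomSeed <- seed
    emb <- embeddingCoords(embedUMAP(zscoreTransform(prof), cfg))
    c1 <- colMeans(emb[1:100, ]); c2 <- colMeans(emb[101:200, ])
    spread <- mean(c(sqrt(rowSums((emb[1:100, ] - rep(c1, each = 100))^2)),
                     sqrt(rowSums((emb[101:200, ] - rep(c2, each = 100))^2))))
    expect_gt(sqrt(sum((c1 - c2)^2)), 3 * spread)
  }
})

test_that("DBSCAN recovers tight separated blobs and flags noise", {
  set.seed(503)
  pts <- rbind(blob(40, 0, 0, 0.02), blob(40, 1, 0, 0.02), c(5, 5))
  labels <- dbscanClusters(pts, eps = 0.1, minPts = 5)
  expect_identical(length(unique(labels[1:40])), 1L)
  expect_identical(length(unique(labels[41:80])), 1L)
  expect_false(labels[1] == labels[41])
  expect_identical(labels[81], 0L)  # isolated point is noise
})

test_that("center seeding places one centroid per density cluster", {
  set.seed(504)
  pts <- rbind(blob(60, 0, 0, 0.025), blob(60, 1, 0, 0.025))
  emb <- mkEmbedding(pts)
  cfg <- PipelineConfig()
  sc <- seedCenters(emb, cfg)
  expect_gte(nrow(sc@centers), 2L)
  cents <- sc@centers[sc@provenance == "density_centroid", , drop = FALSE]
  d1 <- min(sqrt((cents[, 1] - 0)^2 + cents[, 2]^2))
  d2 <- min(sqrt((cents[, 1] - 1)^2 + cents[, 2]^2))
  expect_lt(d1, 0.05)
  expect_lt(d2, 0.05)

  same <- mkEmbedding(matrix(rep(c(2, 3), each = 30), 30, 2))
  sc2 <- seedCenters(same, cfg)
  expect_identical(nrow(sc2@centers), 1L)   # hull area 0, no extras
  expect_equal(unname(sc2@centers[1, ]), c(2, 3))

  sc3 <- seedCenters(emb, cfg, seed = 11)
  sc4 <- seedCenters(emb, cfg, seed = 11)
  expect_identical(sc3@centers, sc4@centers)

  sparse <- mkEmbedding(matrix(seq(0, 100, length.out = 8), 8, 2))
  expect_warning(sc5 <- seedCenters(sparse, cfg), "no density cluster")
  expect_identical(nrow(sc5@centers), 1L)
})

test_that("area-proportional extras go to the two largest clusters", {
  set.seed(505)
  pts <- rbind(blob(300, 0, 0, 0.5), blob(200, 5, 0, 0.4),
               blob(30, 10, 0, 0.03))
  emb <- mkEmbedding(pts)
  cfg <- PipelineConfig(dbscanEps = 0.3)
  sc <- seedCenters(emb, cfg)
  expect_gt(sum(sc@provenance == "area_sample"), 0)
  # extras are sampled member coordinates of the two big blobs
  extras <- sc@centers[sc@provenance == "area_sample", , drop = FALSE]
  expect_true(all(extras[, 1] < 7))
})

test_that("Lloyd k-means from given centers labels blobs correctly", {
  set.seed(506)
  pts <- rbind(blob(50, 0, 0, 0.1), blob(50, 3, 0, 0.1))
  emb <- mkEmbedding(pts)
  cfg <- PipelineConfig()
  km <- kmeansPartition(emb, rbind(c(-0.5, 0), c(3.5, 0)), cfg)
  expect_identical(unname(km$labels[1:50]), rep(1L, 50))
  expect_identical(unname(km$labels[51:100]), rep(2L, 50))
  expect_true(all(diff(km$sse) <= 1e-9))

  one <- kmeansPartition(emb, matrix(c(0, 0), 1, 2), cfg)
  expect_identical(unname(unique(one$labels)), 1L)

  # a center far from all points empties and is dropped
  expect_warning(
    km3 <- kmeansPartition(emb, rbind(c(0, 0), c(3, 0), c(100, 100)), cfg),
    "empty cluster")
  expect_identical(sort(unique(unname(km3$labels))), c(1L, 2L))
})

test_that("k-means objective is non-increasing across iterations", {
  set.seed(507)
  for (i in 1:5) {
    pts <- matrix(rnorm(400), 200, 2)
    emb <- mkEmbedding(pts)
    start <- pts[sample(200, 6), ]
    km <- kmeansPartition(emb, start, PipelineConfig())
    expect_true(all(diff(km$sse) <= 1e-9))
  }
})

mergeFixture <- function(coordsList, tissueOf, nPerCluster = 30,
                         extraLow = 200) {
  # builds labels/embedding/specificity where cluster i sits at
  # coordsList[[i]] and its genes are elevated for tissueOf[[i]]
  set.seed(42)
  k <- length(coordsList)
  coords <- NULL; labels <- integer(); calls <- NULL
  gid <- 0
  for (i in seq_len(k)) {
    n <- nPerCluster
    pts <- cbind(coordsList[[i]][1] + runif(n, 0, 0.04),
                 coordsList[[i]][2] + runif(n, 0, 0.04))
    ids <- paste0("g", gid + seq_len(n)); gid <- gid + n
    coords <- rbind(coords, pts)
    labels <- c(labels, rep(i, n))
    calls <- rbind(calls, toyCalls(
      ids,
      if (nzchar(tissueOf[[i]])) "tissue_enriched" else "low_specificity",
      tissueOf[[i]]))
  }
  # background genes keep the urn honest
  ids <- paste0("bg", seq_len(extraLow))
  pts <- cbind(runif(extraLow, 20, 21), runif(extraLow, 20, 21))
  coords <- rbind(coords, pts)
  labels <- c(labels, rep(k + 1L, extraLow))
  calls <- rbind(calls, toyCalls(ids, "low_specificity", ""))
  rownames(coords) <- calls$gene_id
  colnames(coords) <- c("x", "y")
  list(embedding = new("Embedding", coords = coords, parameters = list(),
                       seed = 0),
       labels = setNames(as.integer(labels), calls$gene_id),
       calls = calls)
}

test_that("adjacent clusters with identical tissue signatures merge", {
  fx <- mergeFixture(list(c(0, 0), c(0.05, 0)), c("testis", "testis"))
  res <- mergeAdjacentClusters(fx$labels, fx$embedding, fx$calls,
                               PipelineConfig())
  labs <- clusterLabels(res)
  expect_identical(length(unique(labs[1:60])), 1L)

  # same signature but far apart: no merge
  fx2 <- mergeFixture(list(c(0, 0), c(5, 0)), c("testis", "testis"))
  res2 <- mergeAdjacentClusters(fx2$labels, fx2$embedding, fx2$calls,
                                PipelineConfig())
  expect_identical(length(unique(clusterLabels(res2)[1:60])), 2L)

  # adjacent but different signatures: no merge
  fx3 <- mergeFixture(list(c(0, 0), c(0.05, 0)), c("testis", "brain"))
  res3 <- mergeAdjacentClusters(fx3$labels, fx3$embedding, fx3$calls,
                                PipelineConfig())
  expect_identical(length(unique(clusterLabels(res3)[1:60])), 2L)
})

test_that("superset signatures block merging", {
  fx <- mergeFixture(list(c(0, 0), c(0.05, 0)), c("testis", "testis"))
  # give cluster 2 an extra brain-elevated contingent -> {testis, brain}
  extra <- toyCalls(paste0("x", 1:30), "tissue_enriched", "brain")
  coords <- rbind(embeddingCoords(fx$embedding),
                  matrix(c(0.07 + runif(30, 0, 0.02),
                           runif(30, 0, 0.02)), 30, 2,
                         dimnames = list(extra$gene_id, c("x", "y"))))
  labels <- c(fx$labels, setNames(rep(2L, 30), extra$gene_id))
  emb <- new("Embedding", coords = coords, parameters = list(), seed = 0)
  res <- mergeAdjacentClusters(labels, emb, rbind(fx$calls, extra),
                               PipelineConfig())
  expect_identical(length(unique(clusterLabels(res)[1:60])), 2L)
})

test_that("a pairwise-adjacent chain with one signature collapses fully", {
  fx <- mergeFixture(list(c(0, 0), c(0.07, 0), c(0.14, 0)),
                     c("testis", "testis", "testis"))
  res <- mergeAdjacentClusters(fx$labels, fx$embedding, fx$calls,
                               PipelineConfig())
  expect_identical(length(unique(clusterLabels(res)[1:90])), 1L)
  # merge loop reached a fixed point and cluster count never increased
  rounds <- res@trace
  expect_identical(rounds[[length(rounds)]]$n_merges, 0L)
  counts <- vapply(rounds, `[[`, numeric(1), "n_clusters")
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster ids are contiguous and sizes sum to the gene count", {
  fx <- mergeFixture(list(c(0, 0), c(0.05, 0), c(3, 3)),
                     c("testis", "testis", "brain"))
  res <- mergeAdjacentClusters(fx$labels, fx$embedding, fx$calls,
                               PipelineConfig())
  labs <- clusterLabels(res)
  expect_identical(sort(unique(unname(labs))),
                   seq_len(nrow(clusterSummary(res))))
  expect_identical(sum(clusterSummary(res)$n_genes), length(labs))
  # significant tissues at the association threshold are recorded
  summ <- clusterSummary(res)
  expect_true("testis" %in% unlist(strsplit(summ$significant_tissues, ";")))
})
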