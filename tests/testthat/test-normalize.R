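mkMatrix <- function(v, stage = "counts", lengths = NULL,
                     genes = paste0("g", seq_len(nrow(v))),
                     cols = paste0("s", seq_len(ncol(v)))) {
  dimnames(v) <- list(genes, cols)
  ExpressionMatrix(v, stage, lengths)
}

test_that("TPM follows the rate-renormalization formula", {
  counts <- mkMatrix(matrix(c(10, 20), 2, 1), lengths = c(1, 2))
  tpm <- computeTPM(counts)
  expect_equal(unname(exprValues(tpm)[, 1]), c(5e5, 5e5))

  one <- mkMatrix(matrix(37, 1, 1), lengths = 2.5)
  expect_equal(unname(exprValues(computeTPM(one))[, 1]), 1e6)

  set.seed(11)
  big <- mkMatrix(matrix(rpois(250, 50), 50, 5),
                  lengths = runif(50, 0.3, 5))
  sums <- colSums(exprValues(computeTPM(big)))
  expect_equal(unname(sums), rep(1e6, 5), tolerance = 1e-6 / 1e6)

  expect_error(computeTPM(mkMatrix(matrix(c(0, 0, 1, 2), 2, 2),
                                   lengths = c(1, 1))), "all-zero column")
  expect_error(computeTPM(mkMatrix(matrix(1:4, 2, 2))), "lengths")
})

test_that("pTPM renormalizes over protein-coding genes only", {
  tpm <- mkMatrix(matrix(c(2e5, 3e5, 5e5), 3, 1), stage = "tpm")
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    is_protein_coding = c(TRUE, TRUE, FALSE))
  ptpm <- computePTPM(tpm, ann)
  expect_identical(geneIds(ptpm), c("g1", "g2"))
  expect_equal(unname(exprValues(ptpm)[, 1]), c(4e5, 6e5))

  allCoding <- data.frame(gene_id = c("g1", "g2", "g3"),
                          is_protein_coding = TRUE)
  expect_equal(exprValues(computePTPM(tpm, allCoding)), exprValues(tpm))

  set.seed(12)
  r <- mkMatrix(matrix(runif(80, 0, 100), 20, 4), stage = "tpm")
  r <- ExpressionMatrix(sweep(exprValues(r), 2, colSums(exprValues(r)), "/") * 1e6,
                        "tpm")
  ann <- data.frame(gene_id = geneIds(r),
                    is_protein_coding = rep(c(TRUE, FALSE), 10))
  expect_equal(unname(colSums(exprValues(computePTPM(r, ann)))),
               rep(1e6, 4), tolerance = 1e-6 / 1e6)
  noneCoding <- data.frame(gene_id = geneIds(r), is_protein_coding = FALSE)
  expect_error(computePTPM(r, noneCoding), "no protein-coding")
})

test_that("tissue aggregation is the per-tissue arithmetic mean", {
  sheet <- toySheet(c("brain", "liver"), reps = 2)
  m <- mkMatrix(matrix(c(2, 1, 4, 3, 10, 20, 30, 40), 2, 4,
                       dimnames = NULL), stage = "ptpm",
                cols = sampleInfo(sheet)$sample_id)
  tm <- aggregateTissueMean(m, sheet)
  expect_identical(columnIds(tm), c("brain", "liver"))
  expect_equal(unname(exprValues(tm)[1, ]), c(mean(c(2, 4)), mean(c(10, 30))))

  single <- toySheet("brain", reps = 1)
  m1 <- mkMatrix(matrix(c(5, 7), 2, 1), stage = "ptpm",
                 cols = sampleInfo(single)$sample_id)
  expect_equal(unname(exprValues(aggregateTissueMean(m1, single))),
               unname(exprValues(m1)))

  sheet4 <- toySheet(paste0("t", 1:4), reps = 3)
  set.seed(4)
  v <- matrix(runif(10 * 12, 0, 50), 10, 12)
  m4 <- mkMatrix(v, stage = "ptpm", cols = sampleInfo(sheet4)$sample_id)
  tm4 <- exprValues(aggregateTissueMean(m4, sheet4))
  for (t in 1:4)
    expect_equal(unname(tm4[, t]),
                 unname(rowMeans(v[, (t - 1) * 3 + 1:3])))

  mbad <- mkMatrix(v[, 1:2, drop = FALSE], stage = "ptpm",
                   cols = c("t1_r1", "unknown"))
  expect_error(aggregateTissueMean(mbad, sheet4), "unknown")
})

test_that("TMM factors are neutral under identity and pure scaling", {
  set.seed(21)
  base <- matrix(rpois(400, 200) + 1, 100, 4)
  m <- mkMatrix(base, stage = "tissue_mean")
  same <- mkMatrix(cbind(base[, 1], base[, 1], base[, 1]), stage = "tissue_mean")
  f <- tmmCorrect(same)$factors
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-9)

  scaled <- mkMatrix(cbind(base[, 1], 3 * base[, 1], 0.5 * base[, 1]),
                     stage = "tissue_mean")
  f2 <- tmmCorrect(scaled)$factors
  expect_equal(unname(f2), rep(1, 3), tolerance = 1e-9)

  expect_error(tmmCorrect(mkMatrix(base[, 1, drop = FALSE],
                                   stage = "tissue_mean")),
               "at least two columns")
})

test_that("TMM compensates a one-gene spike-in", {
  set.seed(22)
  a <- rpois(500, 150) + 1
  b <- a
  b[1] <- b[1] * 100
  # ladder contract: TMM correction acts on column-normalized (pTPM-style)
  # values, so both columns are scaled to the same total first
  v <- cbind(A = a / sum(a), B = b / sum(b)) * 1e6
  m <- mkMatrix(v, stage = "tissue_mean", cols = c("A", "B"))
  res <- tmmCorrect(m)
  corrected <- exprValues(res$matrix)
  ratio <- stats::median(corrected[-1, "B"] / corrected[-1, "A"])
  expect_gt(ratio, 0.95)
  expect_lt(ratio, 1.05)
})

test_that("TMM factors agree with an explicit Robinson-Oshlack oracle", {
  set.seed(23)
  for (i in 1:5) {
    v <- matrix(rpois(50 * 4, exp(runif(200, 2, 7))) + 1, 50, 4)
    m <- mkMatrix(v, stage = "tissue_mean")
    expect_equal(unname(tmmCorrect(m)$factors), bruteTmmFactors(v),
                 tolerance = 1e-10)
  }
})

test_that("pareto scaling divides by the square root of the SD", {
  const <- mkMatrix(matrix(c(5, 5, 5), 1, 3), stage = "tmm")
  expect_equal(unname(exprValues(paretoScale(const))[1, ]), c(5, 5, 5))

  row <- mkMatrix(matrix(c(1, 9, 2), 1, 3), stage = "tmm")
  expect_equal(unname(exprValues(paretoScale(row))[1, ]),
               c(1, 9, 2) / 19^0.25, tolerance = 1e-12)

  set.seed(31)
  v <- matrix(runif(60, 0, 100), 10, 6)
  scaled <- exprValues(paretoScale(mkMatrix(v, stage = "tmm")))
  for (i in 1:10)
    expect_equal(sd(scaled[i, ]), sqrt(sd(v[i, ])), tolerance = 1e-9)
})

test_that("grouped-tissue values are the maximum over member tissues", {
  sheet <- SampleSheet(data.frame(
    sample_id = paste0("s", 1:3),
    tissue = c("t1", "t2", "t3"),
    grouped_tissue = c("g12", "g12", "g3"),
    organ_system = "sys1", stringsAsFactors = FALSE))
  nx <- mkMatrix(matrix(c(2, 1, 7, 3, 4, 9), 2, 3, byrow = TRUE),
                 stage = "nx", cols = c("t1", "t2", "t3"))
  g <- groupedTissueMax(nx, sheet)
  expect_identical(columnIds(g), c("g12", "g3"))
  # row1 = (2,1,7), row2 = (3,4,9): g12 takes max(t1,t2), g3 passes through
  expect_equal(unname(exprValues(g)), matrix(c(2, 4, 7, 9), 2, 2))

  singleton <- groupedTissueMax(
    mkMatrix(matrix(1:2, 2, 1), stage = "nx", cols = "t3"), sheet)
  expect_equal(unname(exprValues(singleton)), matrix(c(1, 2), 2, 1))

  expect_error(groupedTissueMax(
    mkMatrix(matrix(1, 1, 1), stage = "nx", cols = "t9"), sheet), "t9")
})

test_that("a synthetic 98-to-44 mapping matches the per-cell max oracle", {
  tissues <- paste0("tis", 1:98)
  groups <- paste0("grp", rep(1:44, length.out = 98))
  sheet <- SampleSheet(data.frame(
    sample_id = tissues, tissue = tissues, grouped_tissue = groups,
    organ_system = paste0("sys", rep(1:14, length.out = 44))[
      rep(1:44, length.out = 98)],
    stringsAsFactors = FALSE))
  set.seed(41)
  v <- matrix(runif(20 * 98, 0, 30), 20, 98)
  nx <- mkMatrix(v, stage = "nx", cols = tissues)
  g <- exprValues(groupedTissueMax(nx, sheet))
  expect_identical(ncol(g), 44L)
  for (k in sample(44, 6))
    expect_equal(unname(g[, paste0("grp", k)]),
                 apply(v[, groups == paste0("grp", k), drop = FALSE], 1, max))
})

test_that("the noiseless ladder reproduces planted fold changes", {
  sim <- simulateAtlas(nGenes = 400, nTissues = 12, nReplicates = 2,
                       noiseCV = 0, nbDispersion = 0, seed = 5)
  norm <- normalizeAtlas(sim$counts, sim$sheet, sim$annotation)
  nx <- exprValues(norm$nxGrouped)
  enriched <- sim$truth[sim$truth$category == "tissue_enriched", ]
  pick <- enriched[sample(nrow(enriched), 25), ]
  for (i in seq_len(nrow(pick))) {
    row <- nx[pick$gene_id[i], ]
    target <- pick$elevated_tissues[i]
    ratio <- row[target] / max(row[setdiff(names(row), target)])
    expect_equal(unname(ratio), 8, tolerance = 0.01)
  }
})
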