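# Independent brute-force oracles used to verify the package's kernels.
# These deliberately re-derive each quantity from first principles and
# share no code with the implementation under test.

# Upper-tail hypergeometric probability by direct enumeration of the
# support with binomial coefficients (exact for m + n <= 25).
bruteHypergeomUpper <- function(q, m, n, k) {
  lo <- max(0L, k - n)
  hi <- min(m, k)
  if (q > hi) return(0)
  i <- seq(max(q, lo), hi)
  sum(choose(m, i) * choose(n, k - i)) / choose(m + n, k)
}

# Benjamini-Hochberg step-up from the textbook definition.
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Spearman correlation as rank-then-Pearson with average ranks.
bruteSpearman <- function(a, b) {
  stats::cor(rank(a, ties.method = "average"), rank(b, ties.method = "average"),
             method = "pearson")
}

# Robinson-Oshlack TMM scaling factors, written out explicitly:
# relative abundances, M/A values against the reference column, double
# trimming (30% on M, 5% on A), precision weights, geometric-mean-1
# renormalization.
bruteTmmFactors <- function(mat) {
  lib <- colSums(mat)
  rel <- sweep(mat, 2, lib, "/")
  f75 <- apply(rel, 2, quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    if (j == ref) { f[j] <- 1; next }
    keep <- mat[, j] > 0 & mat[, ref] > 0
    obs <- mat[keep, j]; refv <- mat[keep, ref]
    M <- log2((obs / lib[j]) / (refv / lib[ref]))
    A <- 0.5 * log2((obs / lib[j]) * (refv / lib[ref]))
    w <- (lib[j] - obs) / (lib[j] * obs) + (lib[ref] - refv) / (lib[ref] * refv)
    nn <- length(M)
    loM <- floor(nn * 0.3) + 1; hiM <- nn + 1 - loM
    loA <- floor(nn * 0.05) + 1; hiA <- nn + 1 - loA
    rM <- rank(M); rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (max(abs(M)) < 1e-6) f[j] <- 1
    else f[j] <- 2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  f / exp(mean(log(f)))
}

# UPGMA (average linkage) agglomeration by explicit recomputation of the
# average inter-cluster distance at every step; returns merge heights in
# order.
bruteUpgmaHeights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in seq(i + 1L, length(clusters))) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestD) { bestD <- dd; best <- c(i, j) }
      }
    heights <- c(heights, bestD)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# Literal transliteration of the specificity category definitions,
# checked tissue by tissue with explicit loops (shares no code with
# classifySpecificity).
naiveSpecificity <- function(x, fc = 4, det = 1, gmin = 2, gmax = 5) {
  T <- length(x)
  for (t in seq_len(T)) {
    others <- x[-t]
    if (all(x[t] >= fc * others) && x[t] >= det)
      return("tissue_enriched")
  }
  mx <- max(x)
  G <- which(x > mx / fc)
  if (length(G) >= gmin && length(G) <= gmax) {
    gm <- mean(x[G])
    ok <- gm >= det
    for (t in setdiff(seq_len(T), G))
      if (!(gm >= fc * x[t])) ok <- FALSE
    if (ok) return("group_enriched")
  }
  for (t in seq_len(T))
    if (x[t] >= fc * mean(x) && x[t] >= det)
      return("tissue_enhanced")
  if (any(x >= det)) return("low_specificity")
  "not_detected"
}

# Small expression fixture: deterministic 4-tissue, 2-replicate sheet.
toySheet <- function(tissues = c("brain", "liver", "testis", "lung"),
                     reps = 2) {
  SampleSheet(data.frame(
    sample_id = paste0(rep(tissues, each = reps), "_r", seq_len(reps)),
    tissue = rep(tissues, each = reps),
    grouped_tissue = rep(tissues, each = reps),
    organ_system = rep(c("nervous", "internal", "reproductive", "internal")[
      seq_along(tissues)], each = reps),
    stringsAsFactors = FALSE))
}

# Specificity-call table builder for network / enrichment toys.
toyCalls <- function(gene_id, category, elevated) {
  data.frame(gene_id = gene_id, category = category,
             elevated_tissues = elevated,
             fold_change = NA_real_, stringsAsFactors = FALSE)
}
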