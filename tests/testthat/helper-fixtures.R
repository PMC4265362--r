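# Shared fixtures and independent oracles used across the test files.

toy_count_matrix <- function() {
  count_matrix(
    matrix(c(3L, 1L, 0L, 2L), 2, 2,
           dimnames = list(c("g1", "g2"), c("s1", "s2"))),
    c(g1 = 100, g2 = 200)
  )
}

random_count_matrix <- function(n_genes, n_samples, seed = 1L, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_matrix(m, setNames(sample(200:5000, n_genes, replace = TRUE),
                           rownames(m)))
}

# expression matrix straight from a numeric matrix (bypassing normalization)
raw_expression <- function(values, log_transformed = FALSE) {
  em <- rpkm(count_matrix(
    matrix(1L, nrow(values), ncol(values), dimnames = dimnames(values)),
    setNames(rep(1000, nrow(values)), rownames(values))
  ))
  em$values <- values
  em$provenance <- "raw"
  em$log_transformed <- log_transformed
  em
}

# --- independent oracles -----------------------------------------------------

# Published TMM formula: pairwise trimmed (30% on M, 5% on A), precision
# weighted mean of gene-wise log ratios against a reference sample.
oracle_tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                            logratioTrim = 0.3, sumTrim = 0.05) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]; ref <- ref[keep0]
  M <- log2((obs / lib_obs) / (ref / lib_ref))
  A <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

oracle_tmm_factors <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    oracle_tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref])
  }, numeric(1))
  f / exp(mean(log(f)))
}

# mean-of-order-statistics quantile normalization (tie-free inputs)
oracle_quantile <- function(X) {
  m <- rowMeans(apply(X, 2, sort))
  apply(X, 2, function(x) m[rank(x)])
}

# brute-force MST weight via Pruefer-sequence enumeration (all n^(n-2)
# labeled trees)
prufer_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (i in seq) degree[i] <- degree[i] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  ptr <- 0L
  for (i in seq) {
    leaf <- which(degree == 1L)[1L]
    ptr <- ptr + 1L
    edges[ptr, ] <- c(leaf, i)
    degree[leaf] <- degree[leaf] - 1L
    degree[i] <- degree[i] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

all_tree_edges <- function(n) {
  if (n == 2L) return(list(matrix(c(1L, 2L), 1, 2)))
  seqs <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), n - 2L)))
  lapply(seq_len(nrow(seqs)), function(r) prufer_edges(seqs[r, ], n))
}

brute_force_mst_weight <- function(dm) {
  n <- nrow(dm)
  trees <- all_tree_edges(n)
  min(vapply(trees, function(e) sum(dm[e]), numeric(1)))
}

# classical runs count of labels ordered by a univariate value
oracle_runs <- function(values, labels) {
  l <- labels[order(values)]
  1L + sum(l[-1] != l[-length(l)])
}

# classical two-sample KS statistic
oracle_ks <- function(x, y) {
  unname(suppressWarnings(ks.test(x, y))$statistic)
}

# one-dimensional data wrapped as a 1 x N expression matrix
univariate_matrix <- function(values) {
  matrix(values, 1, length(values),
         dimnames = list("g1", sprintf("s%02d", seq_along(values))))
}
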