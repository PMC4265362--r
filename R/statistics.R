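#' MST-based Kolmogorov-Smirnov statistic
#'
#' Walks the samples in HDP rank order and computes
#' `d_i = r_i / n1 - s_i / n2`, where `r_i` (`s_i`) counts group-X (group-Y)
#' samples among the first `i` visited; the statistic is `max_i |d_i|`. On
#' univariate data this reduces to the classical two-sample KS statistic.
#' Large values are extreme.
#'
#' @param ranks An `mst` returned by [hdp_rank()], or an integer rank
#'   permutation (rank of each sample, `1..N`).
#' @param labels Two-group phenotype labels (factor/character, optionally
#'   named by sample) or a logical group indicator.
#' @return The KS statistic `D`, a number in `[0, 1]`.
#' @export
ks_mst_stat <- function(ranks, labels) {
  if (inherits(ranks, "mst")) {
    if (is.null(ranks$ranks)) abort("call hdp_rank() on the tree first")
    ranks <- ranks$ranks
  }
  n <- length(ranks)
  if (!setequal(ranks, seq_len(n))) abort("`ranks` must be a permutation of 1..N")
  g <- binary_groups(labels, n)
  gv <- g[order(ranks)]  # group indicator in visit order
  n1 <- sum(gv); n2 <- n - n1
  cum1 <- cumsum(gv)
  d <- cum1 / n1 - (seq_len(n) - cum1) / n2
  max(abs(d))
}

#' MST-based Wald-Wolfowitz (runs) statistic
#'
#' Removes every MST edge whose endpoints carry different phenotype labels
#' and returns the number of remaining disjoint subtrees,
#' `R = #removed edges + 1`. On univariate data this is the classical runs
#' count of the label sequence sorted by value. Small values are extreme
#' (few subtrees = the groups separate in expression space).
#'
#' @param tree An `mst` from [build_mst()].
#' @inheritParams ks_mst_stat
#' @return The subtree count `R`, an integer in `[2, N]` for two non-empty
#'   groups.
#' @export
ww_mst_stat <- function(tree, labels) {
  stopifnot(inherits(tree, "mst"))
  g <- binary_groups(labels, tree$n)
  mixed <- sum(g[tree$edges[, 1L]] != g[tree$edges[, 2L]])
  mixed + 1L
}

#' Energy-type N-statistic
#'
#' Two-sample energy statistic built from Euclidean distances:
#' `N = sqrt( n1*n2/N * [ mean cross-group distance
#'   - mean within-X distance / 2 - mean within-Y distance / 2 ] )`,
#' where the within-group means run over all ordered pairs including the
#' zero diagonal (denominators `n1^2`, `n2^2`). The bracket is clipped at 0
#' before the square root. Large values are extreme. Tests the general
#' hypothesis F = G.
#'
#' @param dm Square symmetric distance matrix over the samples.
#' @inheritParams ks_mst_stat
#' @return The N-statistic, a non-negative number.
#' @export
n_statistic <- function(dm, labels) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) abort("`dm` must be a square matrix")
  n <- nrow(dm)
  g <- binary_groups(labels, n)
  n1 <- sum(g); n2 <- n - n1
  cross <- sum(dm[g, !g, drop = FALSE])
  within_x <- sum(dm[g, g, drop = FALSE])
  within_y <- sum(dm[!g, !g, drop = FALSE])
  bracket <- cross / (n1 * n2) - within_x / (2 * n1^2) - within_y / (2 * n2^2)
  sqrt(n1 * n2 / n * max(bracket, 0))
}

# Coerce labels to a logical indicator of the first group; allow a logical
# vector to pass through. Errors when either group is empty.
binary_groups <- function(labels, n) {
  if (is.logical(labels)) {
    g <- labels
  } else {
    f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
    if (nlevels(f) != 2L) abort("labels must have exactly two groups")
    g <- f == levels(f)[1L]
  }
  if (length(g) != n) abort("labels must have one entry per sample")
  if (!any(g) || all(g)) abort("each group must have at least one member")
  g
}
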