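# Draw B random relabelings preserving (n1, n2), as an N x B logical matrix
# (TRUE = group X). `order_ids` canonicalizes the draw to sample-ID order so
# permuting the columns of the input (together with its labels) leaves the
# drawn relabelings -- and hence every permutation P-value -- unchanged.
draw_permutations <- function(n, n1, B, seed, order_ids = seq_len(n)) {
  set.seed(seed)
  G <- matrix(FALSE, n, B)
  for (b in seq_len(B)) G[order_ids[sample.int(n, n1)], b] <- TRUE
  G
}

perm_pvalues <- function(observed, permuted, tail) {
  B <- length(permuted)
  # tie detection tolerates floating-point noise: a permutation whose
  # statistic is mathematically equal to the observed one (e.g. the group
  # swap for a symmetric statistic) must count as a tie on every platform
  tol <- 1e-9 * max(1, abs(observed))
  if (tail == "upper") {
    b_ties <- sum(permuted >= observed - tol)
    b_strict <- sum(permuted > observed + tol)
  } else {
    b_ties <- sum(permuted <= observed + tol)
    b_strict <- sum(permuted < observed - tol)
  }
  c(p.value = (b_ties + 1) / (B + 1), p.prop = b_strict / B)
}

new_test_outcome <- function(statistic, pv, B, tail, seed, perm_stats = NULL) {
  out <- tibble::tibble(
    statistic = statistic,
    p.value = unname(pv["p.value"]),
    p.prop = unname(pv["p.prop"]),
    n_permutations = as.integer(B),
    tail = tail,
    seed = as.integer(seed)
  )
  class(out) <- c("test_outcome", class(out))
  attr(out, "perm_stats") <- perm_stats
  out
}

#' Permutation P-value for an arbitrary label statistic
#'
#' Draws `B` uniformly random relabelings that preserve the group sizes,
#' recomputes the statistic for each, and reports the permutation P-value
#' `(b + 1) / (B + 1)`, where `b` counts permuted statistics at least as
#' extreme as the observed one (`>=` for `tail = "upper"`, `<=` for
#' `tail = "lower"`). The classical plug-in estimate -- the proportion of
#' permutations *strictly* more extreme -- is reported alongside as
#' `p.prop`; it is the estimator used by the simulation study and is
#' anti-conservative for discrete statistics such as the subtree count.
#'
#' @param statistic_fn Function taking a logical group indicator (TRUE =
#'   group X) and returning a numeric statistic; must be deterministic.
#' @param labels Two-group phenotype labels or logical indicator.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param tail `"upper"` (large statistic extreme; KS, N) or `"lower"`
#'   (small statistic extreme; WW subtree count).
#' @return A one-row tibble of class `test_outcome` with columns
#'   `statistic`, `p.value`, `p.prop`, `n_permutations`, `tail`, `seed`;
#'   the permuted statistics are kept in the `"perm_stats"` attribute.
#' @export
permutation_pvalue <- function(statistic_fn, labels, B = 1000L, seed = 1L,
                               tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  check_scalar_number(B, "B", lower = 1)
  g <- binary_groups_any(labels)
  n <- length(g); n1 <- sum(g)
  observed <- statistic_fn(g)
  G <- draw_permutations(n, n1, B, seed)
  permuted <- vapply(seq_len(B), function(b) statistic_fn(G[, b]), numeric(1))
  new_test_outcome(observed, perm_pvalues(observed, permuted, tail), B, tail,
                   seed, perm_stats = permuted)
}

binary_groups_any <- function(labels) {
  if (is.logical(labels)) {
    if (!any(labels) || all(labels)) abort("each group must have at least one member")
    labels
  } else {
    binary_groups(labels, length(labels))
  }
}

# Vectorized statistics over an N x K logical relabeling matrix ---------------

nstat_columns <- function(dm, G) {
  n <- nrow(dm)
  n1 <- sum(G[, 1L]); n2 <- n - n1
  H <- dm %*% G
  within_x <- colSums(G * H)
  cross <- colSums(H) - within_x
  within_y <- sum(dm) - within_x - 2 * cross
  bracket <- pmax(cross / (n1 * n2) - within_x / (2 * n1^2) - within_y / (2 * n2^2), 0)
  sqrt(n1 * n2 / n * bracket)
}

ks_columns <- function(hdp_order, G) {
  n <- nrow(G)
  n1 <- sum(G[, 1L]); n2 <- n - n1
  cum1 <- apply(G[hdp_order, , drop = FALSE], 2L, cumsum)
  d <- abs(cum1 / n1 - (seq_len(n) - cum1) / n2)
  apply(d, 2L, max)
}

ww_columns <- function(edges, G) {
  mixed <- colSums(G[edges[, 1L], , drop = FALSE] != G[edges[, 2L], , drop = FALSE])
  mixed + 1
}

#' Gene set analysis with MST-based multivariate tests
#'
#' For each gene set: subsets the expression matrix, computes the Euclidean
#' distance matrix between samples once (distances do not depend on labels),
#' builds the MST and its HDP ranking once where needed, then draws `B`
#' label permutations and computes permutation P-values for the requested
#' statistics. Each set's permutation stream is seeded by
#' `derive_seed(seed, set_name)`, so results are independent of set order,
#' and permutations are drawn over samples in sample-ID order, so reordering
#' the columns of `em` (with labels carried by name) leaves all P-values
#' unchanged.
#'
#' @param em An `expression_matrix` (typically normalized and
#'   log-transformed).
#' @param sets A [gene_set_collection()]; every gene must be present in
#'   `em` (use [filter_gene_sets()] first).
#' @param labels Two-group phenotype labels; if named, matched to the sample
#'   IDs of `em`. Each group needs at least 2 samples.
#' @param method Character vector among `"N"`, `"WW"`, `"KS"`; all requested
#'   statistics share one permutation stream per set.
#' @param B Number of permutations per set (default 1000).
#' @param seed Global integer seed.
#' @param normalization Optional label recorded in the output (defaults to
#'   the matrix provenance).
#' @return A tibble of class `gsa_result`, one row per set x method, with
#'   columns `set`, `size`, `method`, `statistic`, `p.value`, `p.prop`,
#'   `tail`, `n_permutations`, `seed`, `normalization`.
#' @export
gsa_test <- function(em, sets, labels, method = c("N", "WW", "KS"),
                     B = 1000L, seed = 1L, normalization = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  method <- match.arg(method, c("N", "WW", "KS"), several.ok = TRUE)
  check_scalar_number(B, "B", lower = 1)
  sample_ids <- colnames(em$values)
  g0 <- group_indicator(labels, sample_ids)
  # canonicalize to sample-ID order: statistics, tie-breaks and permutation
  # draws then depend on the labeled point cloud only, not on column order
  ord <- order(sample_ids)
  values <- em$values[, ord, drop = FALSE]
  g0 <- g0[ord]
  n <- length(g0); n1 <- sum(g0)
  if (is.null(normalization)) normalization <- em$provenance
  gene_ids <- rownames(values)
  set_names <- names(sets)

  rows <- purrr::map(set_names, function(nm) {
    genes <- sets[[nm]]
    if (!all(genes %in% gene_ids)) {
      abort(sprintf("set %s contains genes absent from the expression matrix", nm))
    }
    x <- values[genes, , drop = FALSE]
    dm <- euclidean_distances(x)
    need_tree <- any(method %in% c("WW", "KS"))
    tree <- if (need_tree) build_mst(dm) else NULL
    if ("KS" %in% method) tree <- hdp_rank(tree)
    set_seed <- derive_seed(seed, nm)
    G <- draw_permutations(n, n1, B, set_seed)
    Gall <- unname(cbind(g0, G))
    purrr::map(method, function(m) {
      stats_all <- switch(m,
        N = nstat_columns(dm, Gall),
        WW = ww_columns(tree$edges, Gall),
        KS = ks_columns(tree$hdp_order, Gall)
      )
      tail <- if (m == "WW") "lower" else "upper"
      pv <- perm_pvalues(stats_all[1L], stats_all[-1L], tail)
      tibble::tibble(
        set = nm, size = length(genes), method = m,
        statistic = stats_all[1L],
        p.value = unname(pv["p.value"]), p.prop = unname(pv["p.prop"]),
        tail = tail, n_permutations = as.integer(B),
        seed = as.integer(set_seed), normalization = normalization
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  class(rows) <- c("gsa_result", class(rows))
  rows
}
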