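#' Pairwise Euclidean distances between samples
#'
#' Treats each sample (column) as a point in R^p, p being the number of
#' genes, and returns the full symmetric matrix of Euclidean distances.
#'
#' @param values Numeric matrix, genes as rows and samples as columns.
#' @return A symmetric `N x N` numeric matrix with zero diagonal and a
#'   `"metric"` attribute.
#' @export
euclidean_distances <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) abort("`values` must be a numeric matrix")
  if (ncol(values) < 2L) abort("need at least 2 samples to compute distances")
  if (anyNA(values)) abort("missing values are not allowed")
  d <- as.matrix(dist(t(values), method = "euclidean"))
  attr(d, "metric") <- "euclidean"
  d
}

#' Minimum spanning tree of a distance matrix
#'
#' Exact MST by Kruskal's algorithm. Ties in edge weight are broken
#' deterministically by ordering edges on (weight, smaller node index,
#' larger node index), so the tree is a pure function of the distance
#' matrix.
#'
#' @param dm Square symmetric numeric distance matrix.
#' @return An object of class `mst`: list with `edges` (an `(N-1) x 2`
#'   integer matrix, each row `i < j`), `weights`, and `n`.
#' @export
build_mst <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) abort("`dm` must be a square matrix")
  n <- nrow(dm)
  if (n < 2L) abort("need at least 2 nodes")
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  w <- dm[idx]
  ord <- order(w, idx[, 1L], idx[, 2L])
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  edges <- matrix(0L, n - 1L, 2L)
  weights <- numeric(n - 1L)
  k <- 0L
  for (e in ord) {
    ra <- find(idx[e, 1L]); rb <- find(idx[e, 2L])
    if (ra != rb) {
      parent[ra] <- rb
      k <- k + 1L
      edges[k, ] <- idx[e, ]
      weights[k] <- w[e]
      if (k == n - 1L) break
    }
  }
  structure(list(edges = edges, weights = weights, n = n), class = "mst")
}

#' @export
print.mst <- function(x, ...) {
  cat(sprintf("<mst> %d nodes, total weight %.6g%s\n", x$n, sum(x$weights),
              if (!is.null(x$ranks)) sprintf(", rooted at %d (HDP ranked)", x$root) else ""))
  invisible(x)
}

tree_adjacency <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

tree_bfs_depths <- function(adj, start, n) {
  d <- rep(NA_integer_, n)
  d[start] <- 0L
  queue <- start
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) if (is.na(d[u])) {
      d[u] <- d[v] + 1L
      queue <- c(queue, u)
    }
  }
  d
}

#' Rank MST nodes by the high directed preorder traversal
#'
#' Roots the tree at a node of maximal eccentricity (geodesic distance
#' measured as the number of edges along the tree; ties broken by the
#' smallest node index) and performs a depth-first traversal that visits the
#' children of each node in decreasing order of subtree height (ties again by
#' smallest index). Ranks are assigned in visit order, placing samples at the
#' two extremes of the tree at opposite ends of the ranking.
#'
#' @param tree An `mst` from [build_mst()].
#' @return The `mst` with elements `root`, `hdp_order` (nodes in visit
#'   order) and `ranks` (rank of each node, a bijection of `1..N`).
#' @export
hdp_rank <- function(tree) {
  stopifnot(inherits(tree, "mst"))
  n <- tree$n
  adj <- tree_adjacency(tree$edges, n)
  ecc <- vapply(seq_len(n), function(s) max(tree_bfs_depths(adj, s, n)), integer(1))
  root <- which.max(ecc)  # first maximum = smallest index
  depth <- tree_bfs_depths(adj, root, n)
  bfs_order <- order(depth, seq_len(n))
  children <- vector("list", n)
  for (v in bfs_order) {
    for (u in adj[[v]]) if (depth[u] == depth[v] + 1L) children[[v]] <- c(children[[v]], u)
  }
  height <- rep(0L, n)
  for (v in rev(bfs_order)) {
    if (length(children[[v]])) height[v] <- 1L + max(height[children[[v]]])
  }
  visit <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    ch <- children[[v]]
    if (length(ch)) {
      ch <- ch[order(-height[ch], ch)]
      stack <- c(stack, rev(ch))
    }
  }
  tree$root <- root
  tree$hdp_order <- visit
  tree$ranks <- order(visit)  # ranks[node] = position in visit order
  tree
}
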