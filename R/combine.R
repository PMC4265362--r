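#' Combiner specification for gene-level gene set analysis
#'
#' Describes how per-gene P-values are transformed and summed into a set
#' score `T = sum_i H(p_i)`: `"FM"` (Fisher, `H = -2 log p`), `"SM"`
#' (Stouffer, `H = qnorm(1 - p)`), or `"GM"` (Gamma method,
#' `H = qgamma(1 - p, shape = w, scale = 1)`). For GM the shape `w` and the
#' soft truncation threshold (STT) determine each other through the fixed
#' point `w = qgamma(1 - STT, shape = w)`: the STT is the P-value whose
#' transform equals `w` itself, tuning the combiner between Fisher-like
#' behaviour (STT = 1/e at `w = 1`) and Stouffer-like behaviour (STT -> 0.5
#' as `w` grows).
#'
#' @param method `"FM"`, `"SM"` or `"GM"`.
#' @param stt Soft truncation threshold in (0, 0.5); GM only. Default 0.05.
#' @param shape Optional GM shape `w`; when supplied, `stt` is derived from
#'   it and both must agree to relative tolerance 1e-6 if both are given.
#' @return A list of class `combiner_spec` with elements `method`, and for
#'   GM also `stt` and `shape`.
#' @export
#' @examples
#' combiner_spec("GM", stt = 0.05)$shape  # ~0.0137
combiner_spec <- function(method = c("FM", "SM", "GM"), stt = 0.05, shape = NULL) {
  method <- match.arg(method)
  out <- list(method = method)
  if (method == "GM") {
    if (!is.null(shape)) {
      check_scalar_number(shape, "shape", lower = 1e-12)
      derived_stt <- shape_to_stt(shape)
      if (!missing(stt) &&
          abs(stt - derived_stt) > 1e-6 * max(stt, derived_stt)) {
        abort("`stt` and `shape` disagree: they must satisfy w = qgamma(1 - stt, shape = w)")
      }
      out$stt <- derived_stt
      out$shape <- shape
    } else {
      out$stt <- stt
      out$shape <- stt_to_shape(stt)
    }
  }
  structure(out, class = "combiner_spec")
}

#' @export
print.combiner_spec <- function(x, ...) {
  if (x$method == "GM") {
    cat(sprintf("<combiner_spec> GM (shape w = %.5g, STT = %.5g)\n", x$shape, x$stt))
  } else {
    cat(sprintf("<combiner_spec> %s\n", x$method))
  }
  invisible(x)
}

#' Fisher combination statistic
#'
#' `T = sum_i -2 log(p_i)`. The transform is unbounded as `p -> 0` and
#' finite (zero) at `p = 1`, so both very small and moderately small
#' P-values move the score.
#'
#' @param p Numeric vector of per-gene P-values in (0, 1].
#' @return The combined statistic.
#' @export
fisher_T <- function(p) {
  if (any(p <= 0) || any(p > 1)) abort("Fisher's method needs p in (0, 1]; floor zeros at 1/(B+1)")
  sum(-2 * log(p))
}

#' Stouffer combination statistic
#'
#' `T = sum_i qnorm(1 - p_i)`, antisymmetric about `p = 0.5`: P-values above
#' one half push the score down as strongly as those below push it up.
#'
#' @param p Numeric vector of per-gene P-values in (0, 1).
#' @return The combined statistic.
#' @export
stouffer_T <- function(p) {
  if (any(p <= 0) || any(p >= 1)) abort("Stouffer's method needs p strictly inside (0, 1)")
  sum(qnorm(p, lower.tail = FALSE))
}

#' Gamma-method combination statistic
#'
#' `T = sum_i qgamma(1 - p_i, shape = w, scale = 1)`. With `w = 1` this is
#' exactly `fisher_T / 2`; small `w` concentrates all weight on extremely
#' small P-values (soft truncation).
#'
#' @param p Numeric vector of per-gene P-values in (0, 1).
#' @param spec A [combiner_spec()] with method `"GM"`, or a positive shape
#'   `w` directly.
#' @return The combined statistic.
#' @export
gamma_T <- function(p, spec) {
  w <- if (inherits(spec, "combiner_spec")) {
    if (spec$method != "GM") abort("`spec` must be a GM combiner")
    spec$shape
  } else {
    check_scalar_number(spec, "shape", lower = 1e-12)
    spec
  }
  if (any(p <= 0) || any(p >= 1)) abort("the Gamma method needs p strictly inside (0, 1)")
  sum(qgamma(p, shape = w, scale = 1, lower.tail = FALSE))
}

#' Solve the soft-truncation fixed point for the Gamma method shape
#'
#' Finds the shape `w` satisfying `w = qgamma(1 - stt, shape = w, scale = 1)`
#' by bracketing and root refinement to relative tolerance 1e-6. The
#' solution is strictly increasing in `stt`; `stt = 1/e` gives `w = 1`
#' (Fisher), and `stt -> 0.5` is the Stouffer limit (`w -> Inf`), so the
#' admissible domain is `(0, 0.5)`.
#'
#' @param stt Soft truncation threshold in (0, 0.5).
#' @return The shape parameter `w > 0`.
#' @export
#' @examples
#' stt_to_shape(0.05)      # ~0.0137
#' stt_to_shape(exp(-1))   # 1
stt_to_shape <- function(stt) {
  if (!is.numeric(stt) || length(stt) != 1L || !is.finite(stt) ||
      stt <= 0 || stt >= 0.5) {
    abort("`stt` must lie strictly inside (0, 0.5); stt = 0.5 is the Stouffer limit")
  }
  f <- function(w) qgamma(stt, shape = w, scale = 1, lower.tail = FALSE) - w
  lo <- 1e-12
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2  # fixed point grows as stt -> 0.5
  uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Soft truncation threshold implied by a Gamma shape
#'
#' Inverse of [stt_to_shape()]: `stt = 1 - pgamma(w, shape = w)`.
#'
#' @param shape Positive Gamma shape `w`.
#' @return The STT in (0, 0.5).
#' @export
shape_to_stt <- function(shape) {
  check_scalar_number(shape, "shape", lower = 1e-12)
  pgamma(shape, shape = shape, scale = 1, lower.tail = FALSE)
}

# Vectorized Welch t-test P-values --------------------------------------------
# X: genes x samples matrix; G: samples x K logical relabeling matrix with a
# constant number of TRUEs per column. Returns a genes x K matrix of
# two-sided P-values, floored at the smallest positive double.
welch_p_matrix <- function(X, G) {
  n <- ncol(X)
  n1 <- sum(G[, 1L]); n2 <- n - n1
  if (n1 < 2L || n2 < 2L) abort("each group needs at least 2 samples for the t test")
  S1 <- X %*% G
  Q1 <- (X^2) %*% G
  S <- rowSums(X); Q <- rowSums(X^2)
  m1 <- S1 / n1
  m2 <- (S - S1) / n2
  v1 <- pmax((Q1 - n1 * m1^2) / (n1 - 1), 0)
  v2 <- pmax(((Q - Q1) - n2 * m2^2) / (n2 - 1), 0)
  a1 <- v1 / n1; a2 <- v2 / n2
  se2 <- a1 + a2
  df <- se2^2 / (a1^2 / (n1 - 1) + a2^2 / (n2 - 1))
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(abs(tt), df = df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # constant gene in both groups: no evidence either way
  pmax(p, .Machine$double.xmin)
}

#' Per-gene Welch t-test P-values
#'
#' The built-in univariate gene test: a two-sample unequal-variance t test on
#' log-transformed normalized values, two-sided, with P-values floored at
#' the smallest positive double. This is the default plug-in for
#' [combine_and_permute()]; any callable with the same contract can replace
#' it.
#'
#' @param em A log-transformed `expression_matrix`.
#' @param labels Two-group phenotype labels (each group >= 2 samples).
#' @return A tibble with columns `gene_id` and `p.value`, one row per gene.
#' @export
default_gene_test <- function(em, labels) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!em$log_transformed) abort("gene-level testing expects log-transformed values")
  g <- group_indicator(labels, colnames(em$values))
  p <- welch_p_matrix(em$values, matrix(g, ncol = 1L))[, 1L]
  tibble::tibble(gene_id = rownames(em$values), p.value = unname(p))
}

combiner_transform_columns <- function(pmat, spec) {
  # clip to the open unit interval before transforming; zeros from plug-in
  # tests are expected to be pre-floored by the caller
  pmat <- pmin(pmax(pmat, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
  H <- switch(spec$method,
    FM = -2 * log(pmat),
    SM = qnorm(pmat, lower.tail = FALSE),
    GM = qgamma(pmat, shape = spec$shape, scale = 1, lower.tail = FALSE)
  )
  colSums(H)
}

#' Combined gene-level P-value for one gene set by sample permutation
#'
#' Computes the observed combined statistic `T = sum_i H(p_i)` from the
#' plug-in gene test on the true labels, then re-runs the gene test inside
#' each of `B` label permutations and recombines, yielding the permutation
#' P-value `P_c = (b + 1)/(B + 1)` (upper tail). The parametric null of the
#' combiner is never used: genes within a set are correlated, which is
#' exactly what the permutation null absorbs. Gene-level P-values equal to 0
#' are floored at `1/(B + 1)` before transformation.
#'
#' @param em A log-transformed `expression_matrix` containing at least the
#'   set's genes.
#' @param set_genes Character vector of gene IDs forming the set.
#' @param labels Two-group phenotype labels.
#' @param spec A [combiner_spec()].
#' @param gene_test `NULL` for the built-in Welch t test (vectorized), or a
#'   function `(values_matrix, group_indicator) -> numeric P-value vector`
#'   evaluated on the set's genes-by-samples submatrix.
#' @param B Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @return A one-row `test_outcome` tibble (see [permutation_pvalue()]).
#' @export
combine_and_permute <- function(em, set_genes, labels, spec = combiner_spec("FM"),
                                gene_test = NULL, B = 1000L, seed = 1L) {
  stopifnot(inherits(em, "expression_matrix"), inherits(spec, "combiner_spec"))
  check_scalar_number(B, "B", lower = 1)
  missing <- setdiff(set_genes, rownames(em$values))
  if (length(missing)) abort(sprintf("genes absent from the expression matrix: %s",
                                     paste(head(missing, 5L), collapse = ", ")))
  sample_ids <- colnames(em$values)
  g0 <- group_indicator(labels, sample_ids)
  ord <- order(sample_ids)  # canonical column order, as in gsa_test()
  X <- em$values[set_genes, ord, drop = FALSE]
  g0 <- g0[ord]
  n <- length(g0); n1 <- sum(g0)
  G <- draw_permutations(n, n1, B, seed)
  Gall <- unname(cbind(g0, G))
  floor_p <- 1 / (B + 1)
  if (is.null(gene_test)) {
    pmat <- welch_p_matrix(X, Gall)
  } else {
    pmat <- vapply(seq_len(ncol(Gall)),
                   function(k) as.numeric(gene_test(X, Gall[, k])),
                   numeric(nrow(X)))
    if (nrow(X) == 1L) pmat <- matrix(pmat, nrow = 1L)
  }
  pmat <- pmax(pmat, floor_p)
  Tall <- combiner_transform_columns(pmat, spec)
  new_test_outcome(Tall[1L], perm_pvalues(Tall[1L], Tall[-1L], "upper"),
                   B, "upper", seed, perm_stats = Tall[-1L])
}

#' Gene-level gene set analysis over a collection
#'
#' Applies [combine_and_permute()] to every set in a collection, seeding
#' each set's permutation stream with `derive_seed(seed, set_name)` exactly
#' as [gsa_test()] does.
#'
#' @inheritParams combine_and_permute
#' @param sets A [gene_set_collection()].
#' @param normalization Optional label recorded in the output.
#' @return A `gsa_result` tibble, one row per set, with `method` set to the
#'   combiner name (`"FM"`, `"SM"` or `"GM"`).
#' @export
gsa_combine_test <- function(em, sets, labels, spec = combiner_spec("FM"),
                             gene_test = NULL, B = 1000L, seed = 1L,
                             normalization = NULL) {
  if (is.null(normalization)) normalization <- em$provenance
  rows <- purrr::imap(unclass(sets), function(genes, nm) {
    out <- combine_and_permute(em, genes, labels, spec, gene_test, B,
                               derive_seed(seed, nm))
    tibble::tibble(
      set = nm, size = length(genes), method = spec$method,
      statistic = out$statistic, p.value = out$p.value, p.prop = out$p.prop,
      tail = "upper", n_permutations = as.integer(B),
      seed = out$seed, normalization = normalization
    )
  }) |> purrr::list_rbind()
  class(rows) <- c("gsa_result", class(rows))
  rows
}
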