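#' Type I error table over tests, normalizations and design sizes
#'
#' Runs [estimate_type1()] for every combination of `N`, `p`, normalization
#' and test. One dataset is simulated per `(N, p)` cell (seed derived from
#' the global seed and the cell label) and shared across tests and
#' normalizations, mirroring how a single null dataset is scored by every
#' method. Cells are cached as RDS files when `cache_dir` is given, keyed by
#' the full cell configuration, so interrupted grids resume.
#'
#' @param pool An `nb_param_pool`.
#' @param tests Character subset of `c("N", "WW", "KS")`.
#' @param normalizations Character subset of
#'   `c("rpkm", "qqn", "tmm", "voom")`.
#' @param N,p Integer vectors of sample and set sizes.
#' @param n_sets,B,alpha,seed Design parameters shared by all cells.
#' @param estimator Passed to [estimate_type1()].
#' @param cache_dir Optional directory for per-cell caching.
#' @return A tibble of class `type1_grid` over
#'   `(method, normalization, N, p)`; all per-set P-values are kept in the
#'   `"results"` attribute so rejections can be recounted at any level with
#'   [type1_at()] without re-simulation.
#' @export
run_type1_table <- function(pool, tests = c("N", "WW", "KS"),
                            normalizations = c("rpkm", "qqn", "tmm", "voom"),
                            N = c(20L, 40L, 60L), p = c(16L, 60L, 100L),
                            n_sets = 1000L, B = 1000L, alpha = 0.05,
                            seed = 1L,
                            estimator = c("proportion", "conservative"),
                            cache_dir = NULL) {
  estimator <- match.arg(estimator)
  tests <- match.arg(tests, c("N", "WW", "KS"), several.ok = TRUE)
  normalizations <- match.arg(normalizations, c("rpkm", "qqn", "tmm", "voom"),
                              several.ok = TRUE)
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  grid <- tidyr::expand_grid(N = as.integer(N), p = as.integer(p),
                             normalization = normalizations)
  pieces <- purrr::pmap(grid, function(N, p, normalization) {
    key <- sprintf("type1_N%d_p%d_%s_%s_s%d_B%d_seed%d_%s",
                   N, p, normalization, paste(tests, collapse = ""),
                   n_sets, B, seed, estimator)
    cache_file <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(key, ".rds"))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      return(readRDS(cache_file))
    }
    design <- simulation_design(N = N, p = p, gamma = 0, fc = 1,
                                n_sets = n_sets, B = B, alpha = alpha,
                                seed = derive_seed(seed, sprintf("N=%d;p=%d", N, p)))
    cell <- estimate_type1(pool, design, test = tests,
                           normalization = normalization, estimator = estimator)
    cell <- dplyr::mutate(cell, N = N, p = p)
    piece <- list(table = tibble::as_tibble(cell), results = attr(cell, "results") |>
                    dplyr::mutate(N = N, p = p, normalization = normalization))
    if (!is.null(cache_file)) saveRDS(piece, cache_file)
    piece
  })
  out <- purrr::list_rbind(purrr::map(pieces, "table"))
  class(out) <- c("type1_grid", class(out))
  attr(out, "results") <- purrr::list_rbind(purrr::map(pieces, "results"))
  attr(out, "estimator") <- estimator
  out
}

#' Recount rejections of a Type I error grid at another level
#'
#' Uses the per-set P-values stored with a [run_type1_table()] result, so no
#' re-simulation happens.
#'
#' @param x A `type1_grid` with a `"results"` attribute.
#' @param alpha New significance level.
#' @return A tibble like `x` with `type1` recomputed at `alpha`.
#' @export
type1_at <- function(x, alpha) {
  res <- attr(x, "results")
  if (is.null(res)) abort("`x` carries no per-set results; rerun run_type1_table()")
  pcol <- if (identical(attr(x, "estimator"), "conservative")) "p.value" else "p.prop"
  out <- res |>
    dplyr::group_by(.data$method, .data$normalization, .data$N, .data$p) |>
    dplyr::summarise(type1 = mean(.data[[pcol]] <= alpha), .groups = "drop") |>
    dplyr::mutate(alpha = alpha)
  class(out) <- c("type1_grid", class(out))
  out
}

#' Power curves over tests, normalizations and the (FC, gamma) grid
#'
#' Thin orchestration over [estimate_power()]: datasets are simulated once
#' per `(fc, gamma)` cell (matched seeds), then scored under every requested
#' normalization and test.
#'
#' @inheritParams run_type1_table
#' @param fc,gamma Grid of fold changes and DE fractions.
#' @param N,p Scalar design sizes.
#' @return A long tibble of class `power_grid` over
#'   `(fc, gamma, method, normalization)`.
#' @export
run_power_curves <- function(pool, tests = c("N", "WW", "KS"),
                             normalizations = c("rpkm", "qqn", "tmm", "voom"),
                             fc = c(1.2, 1.5, 2, 3),
                             gamma = c(1 / 8, 1 / 4, 1 / 2),
                             N = 20L, p = 16L, n_sets = 1000L, B = 1000L,
                             alpha = 0.05, seed = 1L,
                             estimator = c("proportion", "conservative")) {
  estimator <- match.arg(estimator)
  design <- simulation_design(N = N, p = p, gamma = gamma[1L], fc = fc[1L],
                              n_sets = n_sets, B = B, alpha = alpha, seed = seed)
  out <- purrr::map(normalizations, function(nrm) {
    estimate_power(pool, design, fc = fc, gamma = gamma, test = tests,
                   normalization = nrm, estimator = estimator)
  }) |> purrr::list_rbind()
  class(out) <- c("power_grid", class(out))
  out
}

#' Size, DE-fraction and gene-length profile of detected pathways
#'
#' For every pathway detected at level `alpha`, reports its size, the
#' fraction of its genes called differentially expressed (built-in Welch t
#' test, Benjamini-Hochberg FDR 0.05 over all measured genes), and its mean
#' gene length; and compares the mean gene lengths of detected pathways
#' against all pathways with a two-sided Wilcoxon rank-sum test. A length
#' bias in a test shows up as a small rank-sum P-value.
#'
#' @param results A `gsa_result` tibble (one method).
#' @param em The log-transformed `expression_matrix` the tests ran on.
#' @param sets The [gene_set_collection()] the results refer to.
#' @param labels Two-group phenotype labels.
#' @param gene_lengths Named vector of gene lengths in bp covering the
#'   measured genes.
#' @param alpha Detection level (default 0.05).
#' @param fdr FDR level for the per-gene DE call (default 0.05).
#' @return A list of class `bias_summary`: `pathways` (per-detected-pathway
#'   tibble), `ranksum_p`, `n_detected`, `alpha`.
#' @export
pathway_bias_summary <- function(results, em, sets, labels, gene_lengths,
                                 alpha = 0.05, fdr = 0.05) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!all(results$set %in% names(sets))) {
    abort("results refer to sets missing from the collection")
  }
  gene_p <- default_gene_test(em, labels)
  de_call <- setNames(p.adjust(gene_p$p.value, method = "BH") <= fdr,
                      gene_p$gene_id)
  profile_one <- function(genes) {
    tibble::tibble(
      size = length(genes),
      frac_de = mean(de_call[genes]),
      mean_length = mean(gene_lengths[genes])
    )
  }
  all_profiles <- purrr::imap(unclass(sets), function(genes, nm) {
    dplyr::mutate(profile_one(genes), set = nm, .before = 1L)
  }) |> purrr::list_rbind()
  detected <- results$set[results$p.value <= alpha]
  pathways <- all_profiles[all_profiles$set %in% detected, ]
  ranksum_p <- if (nrow(pathways) == 0L || nrow(pathways) == nrow(all_profiles)) {
    1
  } else {
    wilcox.test(pathways$mean_length,
                all_profiles$mean_length, exact = FALSE)$p.value
  }
  structure(list(pathways = pathways, ranksum_p = ranksum_p,
                 n_detected = nrow(pathways), alpha = alpha),
            class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf("<bias_summary> %d pathways detected at alpha = %g\n",
              x$n_detected, x$alpha))
  cat(sprintf("  rank-sum P (detected vs all mean gene lengths): %.4g\n", x$ranksum_p))
  invisible(x)
}

#' Venn cell counts of pathways detected by several methods
#'
#' Counts, for every non-empty subset of the supplied result tables, how
#' many pathways are detected (`p.value <= alpha`) by exactly that subset of
#' methods. The exclusive cell counts sum to the size of the union of
#' detections.
#'
#' @param result_tables Named list of `gsa_result` tibbles over the same set
#'   collection.
#' @param alpha Detection level.
#' @return A tibble with one logical column per method, plus `n_sets` (the
#'   exclusive count for that membership pattern), sorted by pattern.
#' @export
overlap_counts <- function(result_tables, alpha = 0.05) {
  if (is.null(names(result_tables)) || any(names(result_tables) == "")) {
    abort("`result_tables` must be a named list")
  }
  universes <- purrr::map(result_tables, function(t) sort(unique(t$set)))
  if (length(unique(universes)) != 1L) {
    abort("result tables cover different gene set collections")
  }
  detected <- purrr::map(result_tables, function(t) unique(t$set[t$p.value <= alpha]))
  union_sets <- sort(unique(unlist(detected)))
  membership <- purrr::map(detected, function(d) union_sets %in% d) |>
    tibble::as_tibble()
  if (length(union_sets) == 0L) {
    membership <- tibble::as_tibble(setNames(
      rep(list(logical(0)), length(result_tables)), names(result_tables)))
  }
  membership |>
    dplyr::group_by(dplyr::across(dplyr::everything())) |>
    dplyr::summarise(n_sets = dplyr::n(), .groups = "drop")
}
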