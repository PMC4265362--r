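#' Synthesize a negative-binomial parameter pool
#'
#' Generates a pool of per-gene parameter triples (mean count `mu`,
#' dispersion `phi`, gene length `length` in bp) whose marginal shapes mimic
#' bulk RNA-Seq count data: log-normal mean counts, a dispersion that decays
#' with the mean around a positive asymptote (`phi = 0.04 + 2/mu`, jittered
#' log-normally), and log-normal gene lengths. Anyone holding a pool
#' estimated from real counts can load it with [read_param_pool()] instead;
#' the two are interchangeable everywhere.
#'
#' @param size Pool size (default 10000).
#' @param seed Integer seed.
#' @param mu_meanlog,mu_sdlog,mu_range Log-normal parameters and truncation
#'   range for the mean counts (defaults 4.0, 1.5, `[1, 1e5]`).
#' @param phi_asymptote,phi_slope,phi_sdlog Mean-dispersion trend
#'   `phi = phi_asymptote + phi_slope/mu` and the log-sd of its
#'   multiplicative jitter (defaults 0.04, 2, 0.35).
#' @param len_meanlog,len_sdlog,len_range Log-normal parameters and
#'   truncation range for gene lengths in bp (defaults 7.5, 0.7,
#'   `[200, 1e5]`).
#' @return A tibble of class `nb_param_pool` with columns `mu`, `phi`,
#'   `length`.
#' @export
synth_param_pool <- function(size = 10000L, seed = 1L,
                             mu_meanlog = 4.0, mu_sdlog = 1.5,
                             mu_range = c(1, 1e5),
                             phi_asymptote = 0.04, phi_slope = 2,
                             phi_sdlog = 0.35,
                             len_meanlog = 7.5, len_sdlog = 0.7,
                             len_range = c(200, 1e5)) {
  check_scalar_number(size, "size", lower = 1)
  set.seed(seed)
  mu <- pmin(pmax(rlnorm(size, mu_meanlog, mu_sdlog), mu_range[1L]), mu_range[2L])
  phi <- (phi_asymptote + phi_slope / mu) * rlnorm(size, 0, phi_sdlog)
  len <- round(pmin(pmax(rlnorm(size, len_meanlog, len_sdlog), len_range[1L]),
                    len_range[2L]))
  out <- tibble::tibble(mu = mu, phi = phi, length = as.integer(len))
  class(out) <- c("nb_param_pool", class(out))
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Read a parameter pool from TSV
#'
#' Expects columns `mu`, `phi`, `length` (header required).
#'
#' @param path Path to the TSV file.
#' @return An `nb_param_pool` tibble.
#' @export
read_param_pool <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    mu = readr::col_double(), phi = readr::col_double(),
    length = readr::col_integer()
  ), progress = FALSE)
  if (any(tbl$mu <= 0) || any(tbl$phi < 0) || any(tbl$length <= 0)) {
    abort("pool needs mu > 0, phi >= 0, length > 0")
  }
  class(tbl) <- c("nb_param_pool", class(tbl))
  tbl
}

#' Specify one cell of the simulation study
#'
#' @param N Total number of samples, split `N/2` vs `N/2` between the two
#'   phenotypes. Must be even.
#' @param p Genes per simulated gene set.
#' @param gamma Fraction of truly differentially expressed genes per set, in
#'   `[0, 1]`. The DE count `gamma * p` is rounded down to an even integer so
#'   exactly half the DE genes can be swapped.
#' @param fc Fold change (>= 1) applied to the DE genes' means in the second
#'   phenotype. `fc = 1` is the null.
#' @param n_sets Number of non-overlapping gene sets per simulated dataset.
#' @param B Permutations per set.
#' @param alpha Significance level for rejection counting.
#' @param seed Integer seed for the whole cell.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(N = 20L, p = 16L, gamma = 0, fc = 1,
                              n_sets = 1000L, B = 1000L, alpha = 0.05,
                              seed = 1L) {
  check_scalar_number(N, "N", lower = 4)
  if (N %% 2 != 0) abort("`N` must be even (equal group sizes)")
  check_scalar_number(p, "p", lower = 2)
  check_scalar_number(gamma, "gamma", lower = 0, upper = 1)
  check_scalar_number(fc, "fc", lower = 1)
  check_scalar_number(n_sets, "n_sets", lower = 1)
  check_scalar_number(B, "B", lower = 1)
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  structure(list(N = as.integer(N), p = as.integer(p), gamma = gamma, fc = fc,
                 n_sets = as.integer(n_sets), B = as.integer(B), alpha = alpha,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

n_de_genes <- function(gamma, p) as.integer(2 * floor(gamma * p / 2))

rnb <- function(n, mu, phi) {
  if (phi > 0) rnbinom(n, mu = mu, size = 1 / phi) else rpois(n, mu)
}

#' Simulate counts for one gene set
#'
#' Draws `p` parameter triples from the pool without replacement, generates
#' phenotype-1 counts from `NB(mu_i, phi_i)` (variance
#' `mu * (1 + mu * phi)`; Poisson when `phi = 0`) and phenotype-2 counts
#' from `NB(fc * mu_i, phi_i)` for the first `n_de` genes (`NB(mu_i, phi_i)`
#' otherwise), then swaps the generated counts of the first half of the DE
#' genes between the phenotypes so half the DE genes end up down-regulated
#' and half up-regulated in phenotype 2 -- which also keeps the expected
#' per-sample totals balanced between the phenotypes.
#'
#' @param pool An `nb_param_pool`.
#' @param design A [simulation_design()].
#' @param set_seed Integer seed for this set's draws.
#' @return A list with `counts` (`p x N` integer matrix, phenotype-1 samples
#'   first), `de` (logical DE flags), `lengths`, `mu`, `phi`.
#' @export
simulate_gene_set <- function(pool, design, set_seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  if (nrow(pool) < design$p) abort("pool smaller than the gene set size")
  set.seed(set_seed)
  take <- sample.int(nrow(pool), design$p)
  mu <- pool$mu[take]; phi <- pool$phi[take]; len <- pool$length[take]
  p <- design$p
  half <- design$N %/% 2L
  n_de <- n_de_genes(design$gamma, p)
  y1 <- t(vapply(seq_len(p), function(i) rnb(half, mu[i], phi[i]), numeric(half)))
  mu2 <- mu
  if (n_de > 0L && design$fc > 1) mu2[seq_len(n_de)] <- design$fc * mu[seq_len(n_de)]
  y2 <- t(vapply(seq_len(p), function(i) rnb(half, mu2[i], phi[i]), numeric(half)))
  if (n_de > 1L) {
    swap <- seq_len(n_de %/% 2L)
    tmp <- y1[swap, , drop = FALSE]
    y1[swap, ] <- y2[swap, , drop = FALSE]
    y2[swap, ] <- tmp
  }
  counts <- cbind(y1, y2)
  storage.mode(counts) <- "integer"
  list(counts = counts,
       de = seq_len(p) <= n_de & design$fc > 1,
       lengths = len, mu = mu, phi = phi)
}

#' Simulate a full dataset of non-overlapping gene sets
#'
#' Stacks `n_sets` independently simulated gene sets into one count matrix
#' (so normalization operates across `n_sets * p` genes, a realistic library
#' structure, not per set), together with the matching set collection and
#' phenotype labels. Each set's generator seed is derived from the design
#' seed and the set name.
#'
#' @param pool An `nb_param_pool`.
#' @param design A [simulation_design()].
#' @return A list with `cm` ([count_matrix()]), `sets`
#'   ([gene_set_collection()]), `labels` (named factor, levels `"A"` then
#'   `"B"`), and `de` (tibble of per-gene DE flags).
#' @export
simulate_dataset <- function(pool, design) {
  stopifnot(inherits(design, "simulation_design"))
  set_names <- sprintf("set%04d", seq_len(design$n_sets))
  sims <- purrr::map(set_names, function(nm) {
    simulate_gene_set(pool, design, derive_seed(design$seed, nm))
  })
  gene_ids <- unlist(purrr::map2(set_names, sims, function(nm, s) {
    sprintf("%s.g%03d", nm, seq_len(nrow(s$counts)))
  }))
  counts <- do.call(rbind, purrr::map(sims, "counts"))
  rownames(counts) <- gene_ids
  sample_ids <- sprintf("S%03d", seq_len(design$N))
  colnames(counts) <- sample_ids
  lengths <- setNames(unlist(purrr::map(sims, "lengths")), gene_ids)
  labels <- setNames(factor(rep(c("A", "B"), each = design$N %/% 2L)), sample_ids)
  sets <- gene_set_collection(
    split(gene_ids, rep(set_names, each = design$p))[set_names])
  de <- tibble::tibble(gene_id = gene_ids,
                       set = rep(set_names, each = design$p),
                       de = unlist(purrr::map(sims, "de")))
  list(cm = count_matrix(counts, lengths), sets = sets, labels = labels, de = de)
}

resolve_set_test <- function(test) {
  if (is.function(test)) return(test)
  method <- match.arg(test, c("N", "WW", "KS"), several.ok = TRUE)
  function(em, sets, labels, B, seed) {
    gsa_test(em, sets, labels, method = method, B = B, seed = seed)
  }
}

run_simulated_cell <- function(pool, design, test, normalization, estimator) {
  ds <- simulate_dataset(pool, design)
  em <- normalize_counts(ds$cm, normalization, log = TRUE)
  res <- resolve_set_test(test)(em, ds$sets, ds$labels, B = design$B,
                                seed = design$seed)
  pcol <- if (estimator == "proportion" && "p.prop" %in% names(res)) "p.prop" else "p.value"
  res$reject <- res[[pcol]] <= design$alpha
  res
}

#' Estimate the Type I error rate of a gene-set test by simulation
#'
#' Simulates `n_sets` null gene sets (`fc = 1`) as one combined dataset,
#' normalizes and log-transforms the whole matrix, runs the test on every
#' set, and returns the fraction rejected at `alpha`.
#'
#' @param pool An `nb_param_pool`.
#' @param design A [simulation_design()] with `fc = 1`.
#' @param test Character subset of `c("N", "WW", "KS")`, or a function
#'   `(em, sets, labels, B, seed) -> tibble` with columns `set`, `method`
#'   (optional) and a P-value column.
#' @param normalization One of `"rpkm"`, `"tmm"`, `"qqn"`, `"voom"`.
#' @param estimator `"proportion"` (default) rejects on the classical
#'   plug-in permutation estimate `p.prop` -- the estimator of the
#'   comparative study, anti-conservative for discrete statistics -- or
#'   `"conservative"` to reject on the add-one P-value `p.value`.
#' @return A tibble of class `type1_grid`, one row per method, with columns
#'   `method`, `normalization`, `N`, `p`, `n_sets`, `B`, `alpha`, `type1`;
#'   the per-set results are kept in the `"results"` attribute.
#' @export
estimate_type1 <- function(pool, design, test = "N", normalization = "rpkm",
                           estimator = c("proportion", "conservative")) {
  stopifnot(inherits(design, "simulation_design"))
  estimator <- match.arg(estimator)
  if (design$fc != 1) abort("Type I error runs need `fc = 1` in the design")
  res <- run_simulated_cell(pool, design, test, normalization, estimator)
  if (!"method" %in% names(res)) res$method <- "custom"
  out <- res |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(type1 = mean(.data$reject), .groups = "drop") |>
    dplyr::mutate(normalization = normalization, N = design$N, p = design$p,
                  n_sets = design$n_sets, B = design$B, alpha = design$alpha,
                  .after = "method")
  class(out) <- c("type1_grid", class(out))
  attr(out, "results") <- res
  out
}

#' Estimate power over a fold-change / DE-fraction grid
#'
#' For every `(fc, gamma)` cell, simulates `n_sets` gene sets under the
#' shift alternative (dataset seed derived from the design seed and the cell
#' label, so different normalizations see identical counts at matched
#' seeds), runs the test, and reports the rejection fraction. A cell with
#' `fc = 1` reproduces the matching [estimate_type1()] run.
#'
#' @inheritParams estimate_type1
#' @param fc Numeric vector of fold changes (>= 1).
#' @param gamma Numeric vector of DE-gene fractions.
#' @return A tibble of class `power_grid` with columns `fc`, `gamma`,
#'   `method`, `normalization`, `power` and the design sizes; per-set
#'   results are kept in the `"results"` attribute.
#' @export
estimate_power <- function(pool, design, fc = c(1.2, 1.5, 2, 3),
                           gamma = c(1 / 8, 1 / 4, 1 / 2), test = "N",
                           normalization = "rpkm",
                           estimator = c("proportion", "conservative")) {
  stopifnot(inherits(design, "simulation_design"))
  estimator <- match.arg(estimator)
  grid <- tidyr::expand_grid(fc = fc, gamma = gamma)
  cells <- purrr::pmap(grid, function(fc, gamma) {
    cell <- design
    cell$fc <- fc
    cell$gamma <- gamma
    cell$seed <- derive_seed(design$seed, sprintf("fc=%g;gamma=%g", fc, gamma))
    res <- run_simulated_cell(pool, cell, test, normalization, estimator)
    if (!"method" %in% names(res)) res$method <- "custom"
    res$fc <- fc
    res$gamma <- gamma
    res
  })
  res_all <- purrr::list_rbind(cells)
  out <- res_all |>
    dplyr::group_by(.data$fc, .data$gamma, .data$method) |>
    dplyr::summarise(power = mean(.data$reject), .groups = "drop") |>
    dplyr::mutate(normalization = normalization, N = design$N, p = design$p,
                  n_sets = design$n_sets, B = design$B, alpha = design$alpha)
  class(out) <- c("power_grid", class(out))
  attr(out, "results") <- res_all
  out
}
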