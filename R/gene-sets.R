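#' Construct a gene set collection
#'
#' @param sets Named list of character vectors of gene IDs. Set names must be
#'   unique; gene IDs within one set must be unique.
#' @param descriptions Optional character vector of per-set descriptions,
#'   recycled or named like `sets`.
#' @return An object of class `gene_set_collection` (a named list with a
#'   `descriptions` attribute).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list of gene-ID vectors")
  }
  if (anyDuplicated(names(sets))) abort("duplicate gene set names")
  sets <- lapply(sets, as.character)
  dup <- vapply(sets, anyDuplicated, integer(1)) > 0L
  if (any(dup)) abort(sprintf("duplicated genes within set(s): %s",
                              paste(names(sets)[dup], collapse = ", ")))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = setNames(as.character(descriptions), names(sets)),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("<gene_set_collection> %d sets; sizes %d-%d (median %g)\n",
              length(x), min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(unclass(x)[i], attr(x, "descriptions")[i])
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...` (the MSigDB
#' exchange format). Genes duplicated within a line are dropped with a
#' warning; duplicated set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1L]))
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate gene set name in GMT: %s", nm[duplicated(nm)][1L]))
  }
  desc <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  ndup <- vapply(genes, anyDuplicated, integer(1))
  if (any(ndup > 0L)) {
    warn(sprintf("dropping duplicated genes within set(s): %s",
                 paste(nm[ndup > 0L], collapse = ", ")))
    genes <- lapply(genes, unique)
  }
  gene_set_collection(setNames(genes, nm), desc)
}

#' Filter gene sets against the measured genes and a size window
#'
#' Each set is first intersected with the measured gene universe (genes not
#' present in the expression data are discarded), then kept only if its
#' remaining size lies in `[min_size, max_size]` (both inclusive; defaults
#' 10 and 500, the usual pathway-size window for MSigDB C2).
#'
#' @param sets A [gene_set_collection()].
#' @param measured Character vector of measured gene IDs.
#' @param min_size,max_size Inclusive size bounds after intersection.
#' @return A filtered [gene_set_collection()]. Idempotent.
#' @export
filter_gene_sets <- function(sets, measured, min_size = 10L, max_size = 500L) {
  check_scalar_number(min_size, "min_size", lower = 1)
  check_scalar_number(max_size, "max_size", lower = min_size)
  measured <- as.character(measured)
  trimmed <- lapply(unclass(sets), function(g) g[g %in% measured])
  keep <- lengths(trimmed) >= min_size & lengths(trimmed) <= max_size
  gene_set_collection(trimmed[keep], attr(sets, "descriptions")[keep])
}

# results TSV -----------------------------------------------------------------

results_columns <- c("set", "size", "statistic", "pvalue", "method",
                     "normalization", "n_permutations", "seed")

#' Write a per-set results table to TSV
#'
#' Writes one row per gene set with the fixed column order
#' `set, size, statistic, pvalue, method, normalization, n_permutations,
#' seed` in the input row order; re-running on the same input produces a
#' byte-identical file.
#'
#' @param results A tibble as returned by [gsa_test()] (columns `set`, `size`,
#'   `statistic`, `p.value`, `method`, `normalization`, `n_permutations`,
#'   `seed`; extra columns are dropped).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  tbl <- tibble::as_tibble(results)
  if (nrow(tbl)) {
    if ("p.value" %in% names(tbl) && !"pvalue" %in% names(tbl)) {
      tbl <- dplyr::rename(tbl, pvalue = "p.value")
    }
    missing <- setdiff(results_columns, names(tbl))
    if (length(missing)) {
      abort(sprintf("results are missing column(s): %s", paste(missing, collapse = ", ")))
    }
    tbl <- tbl[results_columns]
  } else {
    tbl <- tibble::as_tibble(setNames(
      rep(list(character(0)), length(results_columns)), results_columns))
  }
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with column `p.value` (and the remaining result columns).
#' @export
read_results <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    set = readr::col_character(),
    size = readr::col_integer(),
    statistic = readr::col_double(),
    pvalue = readr::col_double(),
    method = readr::col_character(),
    normalization = readr::col_character(),
    n_permutations = readr::col_integer(),
    seed = readr::col_integer()
  ), progress = FALSE)
  dplyr::rename(tbl, p.value = "pvalue")
}
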