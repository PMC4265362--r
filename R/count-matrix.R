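#' Construct a count matrix container
#'
#' Bundles a gene-by-sample matrix of non-negative integer read counts with
#' per-gene lengths (base pairs) and per-sample library sizes (column sums).
#' Samples are columns; all downstream geometry treats samples as points in
#' R^p, where p is the number of genes in a gene set.
#'
#' @param counts Integer matrix, genes as rows and samples as columns, with
#'   unique row names (gene IDs) and column names (sample IDs). All entries
#'   must be non-negative and integral.
#' @param gene_lengths Named numeric vector of positive gene lengths in base
#'   pairs. Must cover every gene in `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix), `gene_lengths` (numeric, aligned with rows) and
#'   `library_sizes` (column sums of `counts`).
#' @export
#' @examples
#' cm <- count_matrix(
#'   matrix(c(3L, 1L, 0L, 2L), 2, 2,
#'          dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   c(g1 = 100, g2 = 200)
#' )
#' cm$library_sizes
count_matrix <- function(counts, gene_lengths) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix (genes x samples)")
  }
  gid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(gid) || anyDuplicated(gid)) abort("`counts` needs unique row names (gene IDs)")
  if (is.null(sid) || anyDuplicated(sid)) abort("`counts` needs unique column names (sample IDs)")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("all counts must be non-negative integers")
  }
  if (is.null(names(gene_lengths))) abort("`gene_lengths` must be a named vector")
  missing <- setdiff(gid, names(gene_lengths))
  if (length(missing)) {
    abort(sprintf("no gene length for: %s", paste(head(missing, 5L), collapse = ", ")))
  }
  len <- as.numeric(gene_lengths[gid])
  if (anyNA(len) || any(len <= 0)) abort("gene lengths must be positive")
  storage.mode(counts) <- "integer"
  structure(
    list(
      counts = counts,
      gene_lengths = setNames(len, gid),
      library_sizes = colSums(counts)
    ),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  library sizes: %s%s\n",
              paste(head(x$library_sizes, 5L), collapse = ", "),
              if (ncol(x$counts) > 5L) ", ..." else ""))
  invisible(x)
}

#' Read a count matrix and gene lengths from TSV files
#'
#' The counts file is tab-delimited with a header row of sample IDs and gene
#' IDs in the first column; every remaining cell must be a non-negative
#' integer. The lengths file maps gene ID to gene length in base pairs
#' (two columns, with or without a header).
#'
#' @param path Path to the counts TSV.
#' @param lengths_path Path to the two-column gene-length TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, lengths_path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort("counts file needs a gene-ID column and at least one sample")
  gid <- raw[[1L]]
  if (anyDuplicated(gid)) abort("duplicated gene IDs in counts file")
  sample_ids <- colnames(raw)[-1L]
  mat <- matrix(0L, nrow = length(gid), ncol = length(sample_ids),
                dimnames = list(gid, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad)) {
      abort(sprintf("malformed count '%s' at gene %s, sample %s",
                    v[bad[1L]], gid[bad[1L]], sample_ids[j]))
    }
    mat[, j] <- as.integer(num)
  }
  len_tbl <- readr::read_tsv(lengths_path,
                             col_names = c("gene_id", "length"),
                             col_types = readr::cols(
                               gene_id = readr::col_character(),
                               length = readr::col_double()
                             ),
                             progress = FALSE)
  # tolerate a header row in the lengths file
  if (is.na(suppressWarnings(as.numeric(len_tbl$length[1L]))) ||
      is.na(len_tbl$length[1L])) {
    len_tbl <- len_tbl[-1L, ]
  }
  lengths <- setNames(as.numeric(len_tbl$length), len_tbl$gene_id)
  missing <- setdiff(gid, names(lengths))
  if (length(missing)) {
    abort(sprintf("gene length missing for: %s", paste(head(missing, 5L), collapse = ", ")))
  }
  count_matrix(mat, lengths)
}

#' Read two-group phenotype labels from a TSV file
#'
#' Expects two columns, sample ID and group label, with or without a header.
#'
#' @param path Path to the labels TSV.
#' @return A named factor (names are sample IDs) with exactly two levels.
#' @export
read_labels <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("sample", "group"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (identical(tolower(tbl$sample[1L]), "sample")) tbl <- tbl[-1L, ]
  as_phenotype(setNames(tbl$group, tbl$sample))
}

#' Coerce to two-group phenotype labels
#'
#' @param x Factor or character vector of group labels, named by sample ID
#'   (names optional when the labels are used positionally).
#' @return A factor with exactly two levels, names preserved.
#' @export
as_phenotype <- function(x) {
  f <- if (is.factor(x)) droplevels(x) else factor(x)
  names(f) <- names(x)
  if (nlevels(f) != 2L) abort("phenotype labels must have exactly two distinct groups")
  if (anyDuplicated(names(f)) && !is.null(names(f))) abort("duplicated sample IDs in labels")
  f
}

# Align labels to a vector of sample IDs and return a logical indicator of the
# first factor level. Matching is by name when the labels are named.
group_indicator <- function(labels, sample_ids) {
  f <- as_phenotype(labels)
  if (!is.null(names(f))) {
    if (!all(sample_ids %in% names(f))) {
      abort("labels are missing some sample IDs present in the data")
    }
    f <- f[sample_ids]
  } else if (length(f) != length(sample_ids)) {
    abort("unnamed labels must have one entry per sample")
  }
  g <- f == levels(f)[1L]
  n1 <- sum(g); n2 <- sum(!g)
  if (n1 < 2L || n2 < 2L) abort("each phenotype group needs at least 2 samples")
  g
}
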