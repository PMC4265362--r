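new_expression_matrix <- function(values, provenance, log_transformed) {
  structure(
    list(values = values, provenance = provenance, log_transformed = log_transformed),
    class = "expression_matrix"
  )
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples [%s%s]\n",
              nrow(x$values), ncol(x$values), x$provenance,
              if (x$log_transformed) ", log2(1+x)" else ""))
  invisible(x)
}

#' RPKM normalization
#'
#' Reads per kilobase of gene model per million mapped reads:
#' `1e9 * count / (length_bp * library_size)`, equivalently counts scaled by
#' `1e3 / length_kb` within a sample and `1e6 / library_size` across samples.
#'
#' @param cm A [count_matrix()].
#' @return An `expression_matrix` (not log-transformed).
#' @export
#' @examples
#' cm <- count_matrix(
#'   matrix(c(10L, 999990L, 20L, 1999980L), 2, 2,
#'          dimnames = list(c("g1", "g2"), c("a", "b"))),
#'   c(g1 = 1000, g2 = 5000)
#' )
#' rpkm(cm)$values["g1", ]  # 10 and 10: same rate at double the depth
rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$library_sizes == 0)) abort("zero library size; cannot compute RPKM")
  v <- 1e9 * cm$counts / outer(cm$gene_lengths, cm$library_sizes)
  new_expression_matrix(v, "rpkm", FALSE)
}

#' TMM scaling factors
#'
#' Per-sample trimmed-mean-of-M-values scaling factors (30% two-sided trim on
#' the log-ratios M, 5% on the average log abundances A, precision weighting,
#' reference sample chosen by the upper-quartile rule), geometric-mean
#' centered so the factors multiply to 1. Computed with
#' [edgeR::calcNormFactors()].
#'
#' @param cm A [count_matrix()].
#' @return Named numeric vector of scaling factors, one per sample.
#' @export
tmm_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 2L) abort("TMM needs at least 2 samples")
  if (any(cm$library_sizes == 0)) abort("a sample has all-zero counts")
  f <- edgeR::calcNormFactors(cm$counts, method = "TMM",
                              logratioTrim = 0.3, sumTrim = 0.05)
  setNames(as.numeric(f), colnames(cm$counts))
}

#' TMM followed by RPKM
#'
#' Rescales effective library sizes by the TMM factors ([tmm_factors()]) and
#' then applies the RPKM formula with the effective sizes, so between-sample
#' composition bias is removed before the within-sample length scaling.
#'
#' @param cm A [count_matrix()].
#' @return An `expression_matrix` (not log-transformed).
#' @export
tmm_rpkm <- function(cm) {
  f <- tmm_factors(cm)
  eff <- cm$library_sizes * f
  v <- 1e9 * cm$counts / outer(cm$gene_lengths, eff)
  new_expression_matrix(v, "tmm+rpkm", FALSE)
}

#' Quantile normalization followed by RPKM
#'
#' Replaces each sample's order statistics by the across-sample mean of order
#' statistics (ties resolved by the mid-rank convention of
#' [limma::normalizeQuantiles()]), then applies the per-gene `1e3/length` and
#' per-sample `1e6/library_size` scalings of RPKM using the post-quantile
#' column sums.
#'
#' @param cm A [count_matrix()].
#' @return An `expression_matrix` (not log-transformed).
#' @export
qqn_rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 2L) abort("quantile normalization needs at least 2 samples")
  q <- limma::normalizeQuantiles(cm$counts, ties = TRUE)
  dimnames(q) <- dimnames(cm$counts)
  lib_q <- colSums(q)
  if (any(lib_q == 0)) abort("zero library size after quantile normalization")
  v <- 1e9 * q / outer(cm$gene_lengths, lib_q)
  new_expression_matrix(v, "qqn+rpkm", FALSE)
}

# Offset log-CPM and its exact inverse (on the count scale). The offsets
# (0.5 on the count, 1 on the library size) keep zero counts finite.
offset_logcpm <- function(counts, lib) {
  log2(sweep(counts + 0.5, 2, lib + 1, "/") * 1e6)
}

inv_offset_logcpm <- function(x, lib) {
  pmax(sweep(2^x, 2, (lib + 1) / 1e6, "*") - 0.5, 0)
}

#' Offset log-CPM depth normalization followed by RPKM length scaling
#'
#' Computes the offset log2 counts-per-million
#' `log2((count + 0.5) / (library_size + 1) * 1e6)`, returns it to the linear
#' scale (`2^x`, i.e. offset CPM), and applies the per-kilobase length
#' scaling of RPKM. Depth normalization therefore happens through the CPM
#' denominator; the result differs from plain RPKM only through the offsets,
#' which keep zero counts finite and damp low-count genes. No precision
#' weights are computed.
#'
#' @param cm A [count_matrix()].
#' @return An `expression_matrix` (not log-transformed).
#' @export
voomlike_rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$library_sizes == 0)) abort("zero library size")
  lcpm <- offset_logcpm(cm$counts, cm$library_sizes)
  v <- (2^lcpm) * (1e3 / cm$gene_lengths)
  new_expression_matrix(v, "voom-like+rpkm", FALSE)
}

#' Log-transform an expression matrix
#'
#' Elementwise `log2(1 + x)`, the outlier-damping transform applied to every
#' normalization before the multivariate tests.
#'
#' @param em An `expression_matrix` with non-negative values.
#' @return The transformed `expression_matrix` with `log_transformed = TRUE`.
#' @export
log_transform <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (any(em$values < 0)) abort("log_transform needs non-negative values")
  new_expression_matrix(log2(1 + em$values),
                        paste0(em$provenance, "+log2(1+x)"), TRUE)
}

#' Normalize counts by name
#'
#' Dispatcher over the four normalization chains, optionally followed by the
#' `log2(1 + x)` transform (the default, as used ahead of the multivariate
#' tests).
#'
#' @param cm A [count_matrix()].
#' @param method One of `"rpkm"`, `"tmm"`, `"qqn"`, `"voom"`.
#' @param log Apply [log_transform()] afterwards? Default `TRUE`.
#' @return An `expression_matrix`.
#' @export
normalize_counts <- function(cm, method = c("rpkm", "tmm", "qqn", "voom"),
                             log = TRUE) {
  method <- match.arg(method)
  em <- switch(method,
    rpkm = rpkm(cm),
    tmm = tmm_rpkm(cm),
    qqn = qqn_rpkm(cm),
    voom = voomlike_rpkm(cm)
  )
  if (log) log_transform(em) else em
}
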