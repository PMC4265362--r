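# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# one RNG seed per gene set so results do not depend on evaluation order.
hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 2147483647
  h
}

#' Derive a per-unit random seed from a global seed and a name
#'
#' Combines a global integer seed with a string (typically a gene-set name)
#' into a reproducible 31-bit seed, so that per-set permutation streams are
#' independent of the order in which sets are evaluated.
#'
#' @param seed Integer global seed.
#' @param name Character scalar mixed into the seed.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "KEGG_P53_SIGNALING_PATHWAY")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- hash_string(as.character(name))
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# shared input checks ---------------------------------------------------------

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}
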