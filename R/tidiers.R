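#' Tidy a gene set analysis result
#'
#' Returns the per-set table as a plain tibble (one row per set and
#' method).
#'
#' @param x A `gsa_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gsa_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gsa_result")
  tibble::as_tibble(out)
}

#' Summarise a gene set analysis result
#'
#' @param x A `gsa_result`.
#' @param alpha Detection level for the rejection count.
#' @param ... Unused.
#' @return A one-row-per-method tibble with `n_sets`, `n_detected`,
#'   `detection_rate`, `n_permutations`.
#' @export
glance.gsa_result <- function(x, alpha = 0.05, ...) {
  x |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_sets = dplyr::n(),
      n_detected = sum(.data$p.value <= alpha),
      detection_rate = mean(.data$p.value <= alpha),
      n_permutations = .data$n_permutations[1L],
      .groups = "drop"
    ) |>
    dplyr::mutate(alpha = alpha)
}

#' @export
tidy.test_outcome <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "test_outcome")
  attr(out, "perm_stats") <- NULL
  tibble::as_tibble(out)
}

#' @export
tidy.bias_summary <- function(x, ...) x$pathways

#' @export
glance.bias_summary <- function(x, ...) {
  tibble::tibble(n_detected = x$n_detected, ranksum_p = x$ranksum_p,
                 alpha = x$alpha)
}
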