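#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an r:m estimate into per-classification counts
#'
#' @param x An `rm_estimate`.
#' @param ... Unused.
#' @return Tibble `classification`, `n`, `attributed_to` (how the strict
#'   and inclusive rules treat the class).
#' @export
tidy.rm_estimate <- function(x, ...) {
  x$counts |>
    dplyr::mutate(attributed_to = dplyr::case_when(
      .data$classification == "import" ~ "recombination",
      .data$classification == "unique_single" ~ "mutation",
      .data$classification == "nonunique_single" ~
        "recombination (inclusive rule only)",
      TRUE ~ "by sharing flag (inclusive rule only)"
    ))
}

#' One-row summary of an r:m estimate
#'
#' @param x An `rm_estimate`.
#' @param ... Unused.
#' @return Tibble with `n_variants`, `strict_ratio`, `inclusive_ratio`,
#'   `ratio_low`, `ratio_high`.
#' @export
glance.rm_estimate <- function(x, ...) {
  tibble(
    n_variants = x$n_variants,
    strict_ratio = x$strict_ratio,
    inclusive_ratio = x$inclusive_ratio,
    ratio_low = x$ratio_range[1],
    ratio_high = x$ratio_range[2]
  )
}

#' Tidy clonal complexes into per-ST membership
#'
#' @param x A `clonal_complexes` object.
#' @param ... Unused.
#' @return Tibble `st_id`, `complex_id` (`NA` for singletons),
#'   `is_founder`, `slv_degree`, `frequency`.
#' @export
tidy.clonal_complexes <- function(x, ...) {
  dplyr::bind_rows(
    x$membership,
    x$singletons |>
      dplyr::mutate(complex_id = NA_character_, is_founder = FALSE,
                    slv_degree = 0L)
  ) |>
    dplyr::arrange(.data$st_id)
}

#' One-row summary of a clonal-complex analysis
#'
#' @param x A `clonal_complexes` object.
#' @param ... Unused.
#' @return Tibble `n_complexes`, `n_sts_grouped`, `n_isolates_grouped`,
#'   `n_singletons`.
#' @export
glance.clonal_complexes <- function(x, ...) {
  tibble(
    n_complexes = nrow(x$complexes),
    n_sts_grouped = sum(x$complexes$n_sts),
    n_isolates_grouped = sum(x$complexes$isolate_total),
    n_singletons = nrow(x$singletons)
  )
}

#' Tidy a MaxChi scan into its breakpoint call
#'
#' @param x A `maxchi_scan`.
#' @param ... Unused.
#' @return The one-row call tibble.
#' @export
tidy.maxchi_scan <- function(x, ...) x$call
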