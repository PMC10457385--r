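#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-stride metrics of a gait analysis
#'
#' @param x A `gait_analysis` from [analyze_gait()].
#' @param kept_only Include only strides kept by the median filter
#'   (default); `FALSE` appends the removed strides with a `kept` flag.
#' @param ... Unused.
#' @return A tibble, one row per stride.
#' @method tidy gait_analysis
#' @export
tidy.gait_analysis <- function(x, kept_only = TRUE, ...) {
  if (kept_only) return(tibble::as_tibble(x$strides))
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(x$strides), kept = TRUE),
    dplyr::mutate(tibble::as_tibble(x$removed), kept = FALSE)
  ) |> dplyr::arrange(.data$stride)
}

#' One-row summary of a gait analysis
#'
#' @param x A `gait_analysis` from [analyze_gait()].
#' @param ... Unused.
#' @return A one-row tibble: the register's gait summary plus
#'   `n_strides_removed`.
#' @method glance gait_analysis
#' @export
glance.gait_analysis <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$summary),
                n_strides_removed = nrow(x$removed))
}
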