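#' Tidy a per-sample BRC result
#'
#' @param x A `brc_result` from [compute_sample_brc()].
#' @param ... Unused.
#' @return A tibble with one row per B-scan: `bscan`, `brc`,
#'   `surface_index`, `depth_index`.
#' @method tidy brc_result
#' @export
tidy.brc_result <- function(x, ...) {
  tibble::tibble(
    bscan = seq_along(x$per_bscan),
    brc = x$per_bscan,
    surface_index = x$surface_index,
    depth_index = x$depth_index
  )
}

#' @rdname tidy.brc_result
#' @return `glance()` returns a one-row tibble: `brc`, `n_bscans`,
#'   `center_ascan`, `truth_brc`.
#' @method glance brc_result
#' @export
glance.brc_result <- function(x, ...) {
  tibble::tibble(
    brc = x$brc, n_bscans = length(x$per_bscan),
    center_ascan = x$center_ascan,
    truth_brc = x$truth_brc %||% NA_real_
  )
}

#' Tidy a simulated study
#'
#' @param x A `brc_study` from [replicate_study()].
#' @param ... Unused.
#' @return `tidy()` returns the per-specimen tibble (`sample_id`, `grade`,
#'   `config`, `brc`, `truth_brc`); `glance()` one row per configuration
#'   with the group F test.
#' @method tidy brc_study
#' @export
tidy.brc_study <- function(x, ...) {
  dplyr::select(x$samples, "sample_id", "grade", "config", "brc", "truth_brc")
}

#' @rdname tidy.brc_study
#' @method glance brc_study
#' @export
glance.brc_study <- function(x, ...) {
  if (is.null(x$summary)) {
    return(x$samples |>
             dplyr::group_by(.data$config) |>
             dplyr::group_modify(~ oneway_anova(.x)) |>
             dplyr::ungroup())
  }
  x$summary$anova
}
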