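#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a decomposition into a firing table
#'
#' @param x A `gss_decomposition`.
#' @param ... Unused.
#' @return A tibble with one row per firing of every kept MU: `mu_id`,
#'   `time_s`, `pnr_db`.
#' @method tidy gss_decomposition
#' @export
tidy.gss_decomposition <- function(x, ...) {
  rows <- lapply(x$patterns, function(p) {
    tibble::tibble(mu_id = p$mu_id, time_s = p$times, pnr_db = p$pnr_db)
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a decomposition
#'
#' @param x A `gss_decomposition`.
#' @param ... Unused.
#' @return A tibble with counts and pooled firing statistics of the kept
#'   units.
#' @method glance gss_decomposition
#' @export
glance.gss_decomposition <- function(x, ...) {
  kept <- x$mus[x$mus$kept, , drop = FALSE]
  tibble::tibble(
    n_initial_points = x$n_initial_points,
    n_kept = length(x$patterns),
    mean_pnr_db = mean(kept$pnr_db),
    mean_mdr_hz = mean(kept$mdr_hz),
    mean_cov_isi = mean(kept$cov_isi),
    mean_iterations = mean(kept$iterations)
  )
}

#' Tidy a benchmark into its per-condition summary
#'
#' @param x A `gss_benchmark`.
#' @param ... Unused.
#' @method tidy gss_benchmark
#' @export
tidy.gss_benchmark <- function(x, ...) x$summary

#' Overall benchmark means by method
#'
#' @param x A `gss_benchmark`.
#' @param ... Unused.
#' @method glance gss_benchmark
#' @export
glance.gss_benchmark <- function(x, ...) {
  x$per_mu |>
    dplyr::filter(.data$identified) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_mus = dplyr::n(),
      mean_roa = mean(.data$roa),
      mean_sensitivity = mean(.data$sensitivity),
      mean_precision = mean(.data$precision),
      mean_pnr_db = mean(.data$pnr_db),
      .groups = "drop"
    )
}

#' Firing raster of a decomposition
#'
#' @param object A `gss_decomposition`.
#' @param ... Unused.
#' @return A ggplot: one row of vertical ticks per kept MU.
#' @method autoplot gss_decomposition
#' @export
autoplot.gss_decomposition <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                   y = factor(.data$mu_id))) +
    ggplot2::geom_point(shape = "|", size = 3) +
    ggplot2::labs(x = "time (s)", y = "motor unit",
                  title = "Identified motor-unit firing trains") +
    ggplot2::theme_minimal()
}

#' Reachability profile of an OPTICS ordering
#'
#' @param object An `optics_ordering`.
#' @param ... Unused.
#' @return A ggplot of reachability distance against ordered index; valleys
#'   are candidate clusters.
#' @method autoplot optics_ordering
#' @export
autoplot.optics_ordering <- function(object, ...) {
  rd <- object$reachability
  df <- tibble::tibble(index = seq_along(rd),
                       reachability = ifelse(is.finite(rd), rd, NA))
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$reachability)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ordered point", y = "reachability distance") +
    ggplot2::theme_minimal()
}

#' Benchmark accuracy against signal quality
#'
#' @param object A `gss_benchmark`.
#' @param metric Column of the summary to plot.
#' @param ... Unused.
#' @method autoplot gss_benchmark
#' @export
autoplot.gss_benchmark <- function(object, metric = "mean_roa", ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = factor(.data$snr_db),
                               y = .data[[metric]],
                               colour = .data$method,
                               group = interaction(.data$method,
                                                   .data$mvc))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(linetype = factor(.data$mvc))) +
    ggplot2::labs(x = "SNR (dB)", linetype = "% MVC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
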