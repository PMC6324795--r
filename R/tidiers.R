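# broom-style tidiers and ggplot2 autoplot methods ---------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-compartment composition of a model
#'
#' @param x An `is3_model`.
#' @param ... Unused.
#' @return Tibble with one row per compartment: geometry, region, zone and
#'   channel densities.
#' @export
tidy.is3_model <- function(x, ...) {
  dplyr::left_join(x$morphology, x$channels, by = "id") |>
    dplyr::mutate(zone = ifelse(
      .data$region == "dendrite", dendrite_zone(.data$path_distance),
      NA_character_
    )) |>
    tibble::as_tibble()
}

#' One-row model summary
#'
#' @param x An `is3_model`.
#' @param ... Unused.
#' @return Tibble with the variant, compartment/slot counts, passive
#'   parameters and calibration state.
#' @export
glance.is3_model <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_compartments = nrow(x$morphology),
    n_exc_slots = sum(x$bank$kind == "excitatory"),
    n_inh_slots = sum(x$bank$kind == "inhibitory"),
    g_leak = x$g_leak,
    e_leak = x$e_leak,
    noise_sigma_pA = x$noise$sigma_current,
    calibrated_passive = x$calibration$passive,
    calibrated_noise = x$calibration$noise
  )
}

#' Tidy a sweep result
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return The underlying tibble with the pool label attached.
#' @export
tidy.sweep_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$pool <- assign_pool(out)
  out
}

#' Summarize a sweep result by state
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return One-row tibble with scenario and state counts.
#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(x),
    n_ivl = sum(x$state == "IVL"),
    n_nivl = sum(x$state == "NIVL"),
    n_db = sum(x$state == "DB"),
    n_partial = sum(x$state == "PARTIAL")
  )
}

#' Plot a recorded voltage trace
#'
#' @param object An `ivl_trace`.
#' @param window Optional `c(start, end)` zoom window (ms).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ivl_trace <- function(object, window = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(window)) {
    df <- df[df$time >= window[1] & df$time <= window[2], ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$vm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "Vm (mV)") +
    ggplot2::theme_minimal()
}

#' Render a CBDR matrix
#'
#' @param object A `cbdr_matrix`.
#' @param ... Unused.
#' @return A ggplot raster of the nested 4-D grid.
#' @export
autoplot.cbdr_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object)),
    col = seq_len(ncol(object))
  )
  df$value <- object[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
    fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "value")) +
    ggplot2::labs(
      x = "f_inh (outer) / n_inh (inner)",
      y = "f_exc (outer) / n_exc (inner)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a theta-cycle average with its dispersion band
#'
#' @param object A `cycle_average`.
#' @param ... Unused.
#' @return A ggplot with the mean trace and +/- 1 SD ribbon.
#' @export
autoplot.cycle_average <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phase_ms)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean - .data$sd,
        ymax = .data$mean + .data$sd
      ),
      alpha = 0.3
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "phase within cycle (ms)", y = "mean") +
    ggplot2::theme_minimal()
}

#' Plot a power spectral density
#'
#' @param object A `psd_result`.
#' @param fmax Upper frequency limit shown (Hz).
#' @param ... Unused.
#' @return A ggplot with the 8 Hz bin marked.
#' @export
autoplot.psd_result <- function(object, fmax = 50, ...) {
  df <- object$psd[object$psd$frequency <= fmax & object$psd$frequency > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 8, linetype = "dashed") +
    ggplot2::labs(x = "frequency (Hz)", y = "power (spikes^2/Hz)") +
    ggplot2::theme_minimal()
}
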