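#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's data containers and
#' fitted objects.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name abpore-plots
NULL

#' @rdname abpore-plots
#' @export
autoplot.fluor_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_vline(xintercept = trace_t_add(object), linetype = 2) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)",
                  title = "Dye-influx trace") +
    ggplot2::theme_minimal()
}

#' @rdname abpore-plots
#' @export
autoplot.exp_fit <- function(object, ...) {
  tr <- object$trace
  t_add <- trace_t_add(tr)
  pred <- tibble(
    time = tr$time[tr$time >= t_add],
    intensity = object$f_eq * (1 - exp(-object$k_exp *
                                         (tr$time[tr$time >= t_add] - t_add)))
  )
  autoplot.fluor_trace(tr) +
    ggplot2::geom_line(data = pred, colour = "firebrick") +
    ggplot2::labs(title = sprintf("Single-exponential fit: F_eq = %.3g, k_exp = %.3g 1/s",
                                  object$f_eq, object$k_exp))
}

#' @rdname abpore-plots
#' @export
autoplot.ka_fit <- function(object, ...) {
  ggplot2::ggplot(object$series, ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_abline(slope = object$k_a, intercept = object$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "time after addition (s)",
      y = expression(F[eq] / (group("[", P[b], "]") * (F[eq] - F[t]))),
      title = sprintf("Second-order linearization: k_a = %.3g 1/(M s), R^2 = %.4g",
                      object$k_a, object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname abpore-plots
#' @export
autoplot.ir_pair <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("par", "perp"),
                              names_to = "polarization",
                              values_to = "absorbance")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                     colour = .data$polarization)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)), y = "absorbance") +
    ggplot2::theme_minimal()
}

#' @rdname abpore-plots
#' @export
autoplot.band_fit <- function(object, ...) {
  x <- object$data$wavenumber
  comps <- object$components
  curves <- purrr::map_dfr(seq_len(nrow(comps)), function(i) {
    prof <- pseudo_voigt(x, comps$center[i], comps$fwhm[i], comps$shape[i])
    bind_rows(
      tibble(wavenumber = x, absorbance = comps$amp_par[i] * prof,
             polarization = "par", component = comps$label[i]),
      tibble(wavenumber = x, absorbance = comps$amp_perp[i] * prof,
             polarization = "perp", component = comps$label[i])
    )
  })
  total <- curves |>
    group_by(.data$wavenumber, .data$polarization) |>
    summarise(absorbance = sum(.data$absorbance), .groups = "drop") |>
    mutate(component = "sum")
  meas <- tidyr::pivot_longer(object$data, c("par", "perp"),
                              names_to = "polarization",
                              values_to = "absorbance") |>
    mutate(component = "measured")
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$wavenumber, .data$absorbance,
                               colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = total, linewidth = 0.8) +
    ggplot2::geom_point(data = meas, size = 0.4, colour = "grey30",
                        alpha = 0.5) +
    ggplot2::facet_wrap(~polarization, ncol = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)), y = "absorbance") +
    ggplot2::theme_minimal()
}

#' Strand-tilt solution curve
#'
#' Plots the strand tilt `beta` against the barrel tilt `gamma` from a
#' [strand_tilt()] table, marking unsolvable tilts.
#'
#' @param tilt A tibble from [strand_tilt()].
#' @return A ggplot.
#' @export
plot_strand_tilt <- function(tilt) {
  ggplot2::ggplot(tilt, ggplot2::aes(.data$gamma, .data$beta)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$solvable), na.rm = TRUE) +
    ggplot2::labs(x = "barrel tilt gamma (deg)",
                  y = "strand tilt beta (deg)") +
    ggplot2::theme_minimal()
}
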