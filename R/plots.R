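#' Plot the recorded traces of a run
#'
#' Stacked panels of somatic and dendritic-band membrane potential, mean
#' PIC activation gate, stimulus and muscle force against time — the
#' standard presentation of a closed-loop ramp or warm-up simulation.
#'
#' @param object A `mu_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mu_run <- function(object, ...) {
  long <- tidy.mu_run(object)
  long$channel <- factor(long$channel,
                         levels = c("stim", "v_soma", "v_band", "m_cal",
                                    "force"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time / 1000,
                                     y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel),
                        scales = "free_y", switch = "y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%s ramp, D_path %.1f mm, X_m %d mm",
                                  object$mode, object$d_path_mm,
                                  round(object$x_m))) +
    ggplot2::theme_minimal()
}

#' Plot an input-output curve with its hysteresis loop
#'
#' Force (normalized to the run peak) against the stimulus axis, ascending
#' phase solid and descending phase dashed; counterclockwise separation of
#' the two branches is the PIC signature.
#'
#' @param object An `io_curve` from [build_io_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.io_curve <- function(object, ...) {
  pk <- attr(object, "peak_force")
  df <- dplyr::mutate(tibble::as_tibble(object),
                      force_norm = .data$force / pk)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stim, y = .data$force_norm,
                                   linetype = .data$phase)) +
    ggplot2::geom_path() +
    ggplot2::scale_linetype_manual(values = c(ascending = "solid",
                                              descending = "dashed")) +
    ggplot2::labs(x = "stimulus (nA)", y = "force (normalized)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-trial warm-up peaks
#' @param object A `warmup_report`.
#' @param ... Unused.
#' @export
autoplot.warmup_report <- function(object, ...) {
  qx <- grepl("dendritic", attr(object, "mode"))
  cols <- if (qx) c("peak_v_soma", "peak_v_band") else
    c("peak_rate", "peak_force")
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = dplyr::all_of(cols),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "trial", y = NULL,
                  subtitle = paste0("warm-up: ",
                                    isTRUE(attr(object, "warmup")))) +
    ggplot2::theme_minimal()
}

#' Plot sweep indices against electrotonic length
#'
#' DCT, 1/DCI and DFG against the mean electrotonic length of the hot-spot
#' band, one line per muscle length.
#'
#' @param sweep A [sweep_indices()] result.
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  df <- dplyr::filter(tibble::as_tibble(sweep), !.data$failed)
  df <- dplyr::mutate(df, inv_dci = 1 / .data$dci)
  long <- tidyr::pivot_longer(df, cols = c("dct", "inv_dci", "dfg"),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda_mean,
                                     y = .data$value,
                                     colour = factor(.data$x_m))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$index), scales = "free_y") +
    ggplot2::labs(x = "mean electrotonic length (lambda)", y = NULL,
                  colour = "X_m (mm)") +
    ggplot2::theme_minimal()
}
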