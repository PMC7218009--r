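#' Tidy a motor unit's calibration
#'
#' One row per calibrated parameter, broom-style.
#' @param x A [motor_unit()].
#' @param ... Unused.
#' @export
tidy.motor_unit <- function(x, ...) {
  if (is.null(x$calib$reports)) {
    return(tibble::tibble(parameter = character(0), value = numeric(0),
                          target = numeric(0), achieved = numeric(0),
                          residual = numeric(0), iterations = integer(0)))
  }
  x$calib$reports
}

#' One-row summary of a motor unit
#' @param x A [motor_unit()].
#' @param ... Unused.
#' @export
glance.motor_unit <- function(x, ...) {
  tibble::tibble(
    d_path_mm = x$d_path_mm, halfwidth_mm = x$halfwidth_mm, x_m = x$x_m,
    n_compartments = x$cable$n, n_band_compartments = length(x$band_comp),
    lambda_mean = mean(select_band(x$tree, x$d_path_mm, x$halfwidth_mm,
                                   x$passive)$lambda_dist),
    g_cal = x$calib$g_cal,
    gsyn_peak = x$calib$gsyn_peak,
    calibrated = !is.null(x$calib$reports)
  )
}

#' Tidy a ramp or warm-up run into a long trace table
#' @param x A `mu_run`.
#' @param ... Unused.
#' @export
tidy.mu_run <- function(x, ...) {
  tr <- x$traces
  force <- stats::approx(x$force$time, x$force$force, xout = tr$time,
                         rule = 2)$y
  tidyr::pivot_longer(
    dplyr::mutate(tr, force = force,
                  stim = stats::approx(x$stim_axis$time, x$stim_axis$stim,
                                       xout = tr$time, rule = 2)$y),
    cols = c("v_soma", "v_band", "m_cal", "force", "stim"),
    names_to = "channel", values_to = "value"
  )
}

#' One-row summary of a ramp run
#' @param x A `mu_run`.
#' @param ... Passed to [build_io_curve()].
#' @export
glance.mu_run <- function(x, ...) {
  io <- build_io_curve(x, ...)
  idx <- compute_indices(io)
  idx$firing_type <- classify_firing_type(io, idx)
  idx$n_spikes <- length(x$spikes)
  idx$peak_force <- attr(io, "peak_force")
  idx$mode <- x$mode
  idx$x_m <- x$x_m
  idx$d_path_mm <- x$d_path_mm
  idx
}
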