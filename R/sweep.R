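#' Sweep the PIC hot-spot location and muscle length
#'
#' For every `(D_path, X_m)` grid cell, calibrates the hot-spot density for
#' that band (the afferent and dendritic-drive calibrations are shared
#' across bands), runs the triangular ramp protocol, and computes the
#' characteristic indices. Mirrors the panel structure of the paper-style
#' summary: DCT, DCI, DFG against mean electrotonic length per muscle
#' length.
#'
#' @param tree A [neurite_tree()] (default [synthetic_motoneuron()]).
#' @param dpath_grid Band centres (mm), default `seq(0.1, 1, 0.1)`.
#' @param xm_grid Muscle lengths (mm), default `c(-16, -8, 0)`.
#' @param mode `"somatic"` or `"dendritic"`.
#' @param halfwidth_mm Band half-width (default 0.1).
#' @param base_mu Optional pre-built, pre-calibrated [motor_unit()] whose
#'   shared calibrations (afferent anchors, muscle/calcium time scales)
#'   are reused.
#' @param ... Passed to [motor_unit()].
#' @return A tibble with one row per grid cell: the index report columns
#'   plus `d_path_mm`, `x_m`, `mode`, `lambda_mean`, `g_cal`,
#'   `firing_type`, and `failed` (cells whose simulation errored are
#'   flagged and the sweep continues).
#' @export
sweep_indices <- function(tree = synthetic_motoneuron(),
                          dpath_grid = seq(0.1, 1, by = 0.1),
                          xm_grid = c(-16, -8, 0),
                          mode = c("somatic", "dendritic"),
                          halfwidth_mm = 0.1, base_mu = NULL, ...) {
  mode <- match.arg(mode)
  rows <- list()
  shared <- NULL
  for (d in dpath_grid) {
    cell <- tryCatch({
      mu <- motor_unit(tree, d_path_mm = d, halfwidth_mm = halfwidth_mm, ...)
      if (is.null(shared)) {
        if (!is.null(base_mu) && !is.null(base_mu$calib$gaff_anchors)) {
          shared <- base_mu$calib
        } else {
          tmp <- calibrate_gaff(mu)
          tmp <- calibrate_ahp_twitch(tmp)
          shared <- tmp$calib
        }
      }
      mu$calib$gaff_anchors <- shared$gaff_anchors
      mu$calib$tau_ca <- shared$tau_ca
      mu$calib$muscle_time_scale <- shared$muscle_time_scale
      mu <- calibrate_gcal(mu)
      if (mode == "dendritic") mu <- calibrate_gsyn_peak(mu)
      lam <- mean(select_band(tree, d, halfwidth_mm, mu$passive)$lambda_dist)
      purrr::map_dfr(xm_grid, function(xm) {
        r <- run_ramp(mu, mode, x_m = xm)
        io <- build_io_curve(r)
        idx <- compute_indices(io)
        idx$firing_type <- classify_firing_type(io, idx)
        idx$d_path_mm <- d
        idx$x_m <- xm
        idx$lambda_mean <- lam
        idx$g_cal <- mu$calib$g_cal
        idx
      })
    }, error = function(e) {
      tibble::tibble(d_path_mm = d, x_m = NA_real_, failed = TRUE,
                     error = conditionMessage(e))
    })
    rows[[length(rows) + 1L]] <- cell
  }
  out <- dplyr::bind_rows(rows)
  if (!"failed" %in% names(out)) out$failed <- FALSE
  out$failed[is.na(out$failed)] <- FALSE
  out$mode <- mode
  class(out) <- c("sweep_result", class(out))
  out
}

#' Warm-up presence across the hot-spot / muscle-length grid
#'
#' Runs the warm-up protocol for each `(D_path, X_m)` cell and reports the
#' per-trial peaks and the warm-up flag.
#'
#' @inheritParams sweep_indices
#' @param dpath_grid Band centres (default `c(0.6, 0.8, 1.0)`).
#' @param xm_grid Muscle lengths (default `c(-16, -8, 0)`).
#' @param mode `"somatic"` or `"dendritic"`.
#' @return A tibble with one row per cell: `d_path_mm`, `x_m`, `warmup`.
#' @export
sweep_warmup <- function(tree = synthetic_motoneuron(),
                         dpath_grid = c(0.6, 0.8, 1.0),
                         xm_grid = c(-16, -8, 0),
                         mode = c("somatic", "dendritic"),
                         base_mu = NULL, ...) {
  mode <- match.arg(mode)
  shared <- if (!is.null(base_mu)) base_mu$calib else NULL
  rows <- list()
  for (d in dpath_grid) {
    mu <- motor_unit(tree, d_path_mm = d, ...)
    if (is.null(shared)) {
      tmp <- calibrate_gaff(mu)
      tmp <- calibrate_ahp_twitch(tmp)
      shared <- tmp$calib
    }
    mu$calib$gaff_anchors <- shared$gaff_anchors
    mu$calib$tau_ca <- shared$tau_ca
    mu$calib$muscle_time_scale <- shared$muscle_time_scale
    mu <- calibrate_gcal(mu)
    for (xm in xm_grid) {
      r <- run_warmup(mu, mode, x_m = xm)
      wm <- warmup_metrics(r)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        d_path_mm = d, x_m = xm, mode = mode,
        warmup = attr(wm, "warmup"),
        peaks = list(wm)
      )
    }
  }
  dplyr::bind_rows(rows)
}
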