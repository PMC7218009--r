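#' Afferent conductance density at a muscle length
#'
#' Piecewise-linear interpolation through the calibrated
#' `(X_m, G_aff)` anchors at the physiologically minimal (-16 mm), optimal
#' (-8 mm) and maximal (0 mm) muscle lengths. The anchor at -16 mm is 0 by
#' construction (no afferent drive at the shortest length); the other two
#' are set by [calibrate_gaff()] so that the effective synaptic current
#' reaching the soma matches the target values (2.5 and 5 nA).
#'
#' @param x_m Muscle length (mm, in `[-16, 0]`).
#' @param anchors A tibble with columns `x_m` and `g_aff` (uS/cm^2),
#'   ordered by `x_m`; default is the pre-calibration placeholder.
#' @return Conductance density (uS/cm^2).
#' @export
gaff_of_length <- function(x_m, anchors = default_gaff_anchors()) {
  check_xm(x_m)
  stats::approx(anchors$x_m, anchors$g_aff, xout = x_m, rule = 1)$y
}

#' @rdname gaff_of_length
#' @export
default_gaff_anchors <- function() {
  tibble::tibble(x_m = c(-16, -8, 0), g_aff = c(0, 9.3, 19))
}

#' Place muscle-spindle afferent synapses on a compartmental model
#'
#' Every compartment with midpoint path length below `max_path_mm`
#' (default 1.4 mm), plus the soma, receives an afferent synapse slot; the
#' synapses are uniform in density and activated synchronously, so total
#' synaptic conductance is density times the summed membrane area.
#'
#' @param cable A [compartmentalize()]d model.
#' @param max_path_mm Maximal path length receiving afferents (default 1.4).
#' @param e_rev_mv Synaptic reversal potential (default 0, excitatory).
#' @param delay_ms Afferent conduction delay applied to time-varying drive
#'   (default 10).
#' @return An `afferent_map`: tibble of `comp`, `path_mm`, `area_cm2` with
#'   attributes `e_rev_mv` and `delay_ms`.
#' @export
place_afferents <- function(cable, max_path_mm = 1.4, e_rev_mv = 0,
                            delay_ms = 10) {
  comps <- cable$comps
  sel <- comps$kind == "soma" |
    (comps$kind == "dendrite" & comps$path_mm < max_path_mm)
  map <- tibble::tibble(comp = comps$comp[sel], path_mm = comps$path_mm[sel],
                        area_cm2 = comps$area_cm2[sel])
  attr(map, "e_rev_mv") <- e_rev_mv
  attr(map, "delay_ms") <- delay_ms
  class(map) <- c("afferent_map", class(map))
  map
}
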