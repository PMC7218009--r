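# Shared fixtures, built once per test run.

# uniform passive set (no somatic shunt, no resistivity gradient) for
# closed-form cable comparisons
uniform_passive <- function(rm = 10, ri = 100, cm = 1) {
  passive_params(rm_soma_kohm_cm2 = rm, rm_dend_kohm_cm2 = rm,
                 ri_ohm_cm = ri, cm_uf_cm2 = cm)
}

# single unbranched cable of given length/diameter hanging off a tiny soma
single_cable_tree <- function(length_um = 1500, diam_um = 4,
                              soma_um = 48.8) {
  neurite_tree(tibble::tibble(
    id = 1:2, parent = c(NA, 1L), kind = c("soma", "dendrite"),
    length = c(soma_um, length_um),
    diam_prox = c(soma_um, diam_um), diam_dist = c(soma_um, diam_um)
  ))
}

# constructed io_curve with explicit branches (for index/threshold tests)
make_io <- function(stim, asc_force, des_force, asc_rate, des_rate,
                    recruitment = NA, derecruitment = NA) {
  io <- dplyr::bind_rows(
    tibble::tibble(stim = stim, phase = "ascending", force = asc_force,
                   rate = asc_rate),
    tibble::tibble(stim = stim, phase = "descending", force = des_force,
                   rate = des_rate)
  )
  attr(io, "peak_force") <- max(io$force)
  attr(io, "stim_peak") <- max(stim)
  attr(io, "recruitment") <- recruitment
  attr(io, "derecruitment") <- derecruitment
  class(io) <- c("io_curve", class(io))
  io
}

# calibrated default motor unit, shared across expensive tests;
# built lazily once per test session
.mu_cache <- new.env(parent = emptyenv())
calibrated_unit <- function() {
  if (is.null(.mu_cache$mu)) {
    mu <- motor_unit(d_path_mm = 0.6, x_m = -16)
    .mu_cache$mu <- calibrate_motor_unit(mu)
  }
  .mu_cache$mu
}
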