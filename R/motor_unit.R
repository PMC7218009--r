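#' Assemble a closed-loop motor unit
#'
#' Bundles a motoneuron morphology (discretized to a branched cable), a
#' dendritic PIC hot-spot band at path length `d_path_mm`, muscle-spindle
#' afferent synapses over the proximal membrane (< 1.4 mm), and the
#' three-module muscle unit at length `x_m`. Free parameters (hot-spot
#' conductance density, afferent anchor densities, dendritic excitation
#' peak, calcium-pool and muscle time constants) are set afterwards by
#' [calibrate_motor_unit()].
#'
#' @param tree A [neurite_tree()]; default [synthetic_motoneuron()].
#' @param d_path_mm Centre of the PIC channel band (mm path length).
#' @param halfwidth_mm Band half-width (mm, default 0.1).
#' @param x_m Muscle length (mm in `[-16, 0]`, default -8).
#' @param passive A [passive_params()] set.
#' @param channels Channel set from [default_channels()].
#' @param muscle A [muscle_params()] set.
#' @param ca_pool A [calcium_pool()].
#' @param max_seg_lambda Spatial discretization bound (default 0.15).
#' @param dt Integration step (ms, default 0.025).
#' @return An object of class `motor_unit`.
#' @export
motor_unit <- function(tree = synthetic_motoneuron(), d_path_mm = 0.6,
                       halfwidth_mm = 0.1, x_m = -8,
                       passive = passive_params(),
                       channels = default_channels(),
                       muscle = muscle_params(), ca_pool = calcium_pool(),
                       max_seg_lambda = 0.15, dt = 0.025) {
  check_xm(x_m)
  cable <- compartmentalize(tree, passive, max_seg_lambda)
  comps <- cable$comps
  lo <- d_path_mm - halfwidth_mm
  hi <- d_path_mm + halfwidth_mm
  band_comp <- comps$comp[comps$kind == "dendrite" &
                            comps$path_mm >= lo & comps$path_mm <= hi]
  if (length(band_comp) == 0) {
    stop("empty band: no dendritic compartment midpoint lies in [",
         lo, ", ", hi, "] mm", call. = FALSE)
  }
  structure(list(
    tree = tree, cable = cable, passive = passive, channels = channels,
    muscle = muscle, ca_pool = ca_pool,
    d_path_mm = d_path_mm, halfwidth_mm = halfwidth_mm, x_m = x_m,
    band_comp = band_comp, afferents = place_afferents(cable),
    dt = dt,
    calib = list(g_cal = NA_real_, gaff_anchors = NULL,
                 gsyn_peak = NA_real_, in_per_gsyn = NA_real_,
                 reports = NULL)
  ), class = "motor_unit")
}

#' @export
print.motor_unit <- function(x, ...) {
  cat("<motor_unit> D_path ", x$d_path_mm, " +/- ", x$halfwidth_mm,
      " mm (", length(x$band_comp), " hot-spot compartments), X_m ",
      x$x_m, " mm\n", sep = "")
  cal <- x$calib
  if (is.null(cal$reports)) {
    cat("  uncalibrated\n")
  } else {
    cat("  G_CaL ", signif(cal$g_cal, 3), " mS/cm^2; G_aff anchors ",
        paste(signif(cal$gaff_anchors$g_aff, 3), collapse = "/"),
        " uS/cm^2; G_syn peak ", signif(cal$gsyn_peak, 3), " mS/cm^2\n",
        sep = "")
  }
  invisible(x)
}

soma_comp <- function(mu) mu$cable$comps$comp[mu$cable$comps$kind == "soma"]
axon_comps <- function(mu) {
  mu$cable$comps$comp[mu$cable$comps$kind %in% c("hillock", "initial_segment")]
}

# Channel placement for an engine run.
# active_set: "all" (every channel), "none" (fully passive),
# "dendrite_only" (only the dendritic CaL band: voltage clamp calibration
# and the QX-314 condition), or a character vector of channel names.
mu_channel_maps <- function(mu, active_set = "all", g_cal = mu$calib$g_cal) {
  ch <- mu$channels
  placement <- attr(ch, "placement")
  gain <- attr(ch, "axon_gain")
  keep <- switch(active_set[1],
    all = names(ch),
    none = character(0),
    dendrite_only = "ca_l",
    active_set
  )
  sc <- soma_comp(mu)
  ax <- axon_comps(mu)
  place <- list(); gd <- list()
  for (nm in keep) {
    where <- placement[[nm]]
    if (where == "soma") {
      place[[nm]] <- sc
      gd[[nm]] <- ch[[nm]]$g
    } else if (where == "soma_axon") {
      place[[nm]] <- c(sc, ax)
      gmul <- if (!is.null(gain) && nm %in% names(gain)) gain[[nm]] else 1
      gd[[nm]] <- c(rep(ch[[nm]]$g, length(sc)),
                    rep(ch[[nm]]$g * gmul, length(ax)))
    } else if (where == "dendrite_band") {
      if (is.na(g_cal)) next
      place[[nm]] <- mu$band_comp
      gd[[nm]] <- g_cal
    }
  }
  list(place = place, g = gd)
}

# afferent drive at fixed density (uS/cm^2) as an engine drive
gaff_drive <- function(mu, wave) {
  am <- mu$afferents
  drive_list(am$comp - 1L, am$area_cm2, attr(am, "e_rev_mv"), wave)
}

# dendritic excitatory drive on the PIC band (waveform in mS/cm^2)
gsyn_drive <- function(mu, wave) {
  comps <- mu$cable$comps
  area <- comps$area_cm2[match(mu$band_comp, comps$comp)]
  drive_list(mu$band_comp - 1L, area * 1000, 0, wave)
}

mu_engine <- function(mu, active_set = "all", g_cal = mu$calib$g_cal,
                      drives = list(), istim = NULL, clamp = NULL,
                      v_init = NULL, dt = mu$dt) {
  maps <- mu_channel_maps(mu, active_set, g_cal)
  ca_pool <- mu$ca_pool
  if (!is.null(mu$calib$tau_ca)) ca_pool$tau_ms <- mu$calib$tau_ca
  assemble_engine(mu$cable, mu$channels, maps$place, maps$g, dt,
                  drives = drives, istim = istim, clamp = clamp,
                  v_init = v_init, band_comp = mu$band_comp,
                  ca_pool_pars = ca_pool)
}

# settle to rest with the given constant afferent density; returns the
# final voltage vector
mu_rest <- function(mu, gaff_dens, active_set = "all",
                    g_cal = mu$calib$g_cal, settle_ms = 1000, dt = 0.05) {
  drv <- list()
  if (gaff_dens > 0) {
    drv <- list(gaff_drive(mu, waveform(c(0, settle_ms),
                                        rep(gaff_dens, 2))))
  }
  eng <- mu_engine(mu, active_set, g_cal, drives = drv, dt = dt)
  ts <- run_engine(eng, settle_ms, dt = dt, record_every = 200L)
  ts$v_final
}

# ---- protocols ------------------------------------------------------------

#' Stimulation protocol specification
#'
#' Somatic mode: triangular intracellular current at the soma, 0 to
#' `peak_nA` (20 nA) at `t_peak_ms` (5 s) and back over twice `t_peak_ms`.
#' Dendritic mode: triangular excitatory conductance over the PIC band,
#' 0 to the calibrated peak (reference 1.2 mS/cm^2) at 10 s and back over
#' 20 s. Warm-up somatic: repeated 2-s triangles, -5 nA floor to +10 nA
#' peak, with ~1 s inter-trial gaps held at the floor. Warm-up dendritic:
#' sinusoidal afferent conductance between the shortest- and
#' longest-length calibrated densities (2 s period) with a -1 / -0.5 nA
#' somatic step and all voltage-gated channels on soma, hillock and
#' initial segment blocked (the QX-314 condition).
#'
#' @param mode One of `"somatic_ramp"`, `"dendritic_ramp"`,
#'   `"warmup_somatic"`, `"warmup_dendritic"`.
#' @param peak_nA Somatic ramp peak (default 20).
#' @param t_peak_ms Somatic ramp peak time (default 5000).
#' @param n_trials Warm-up triangle count (default 4).
#' @param gap_ms Warm-up inter-trial gap (default 1000).
#' @param qx314 Block somatic/axonal voltage-gated channels (only valid,
#'   and on by default, in `warmup_dendritic`).
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(mode = c("somatic_ramp", "dendritic_ramp",
                                   "warmup_somatic", "warmup_dendritic"),
                          peak_nA = 20, t_peak_ms = 5000, n_trials = 4,
                          gap_ms = 1000, qx314 = NULL) {
  mode <- match.arg(mode)
  if (is.null(qx314)) qx314 <- mode == "warmup_dendritic"
  if (qx314 && mode != "warmup_dendritic") {
    stop("the QX-314 block applies only to the dendritic warm-up protocol",
         call. = FALSE)
  }
  structure(list(mode = mode, peak_nA = peak_nA, t_peak_ms = t_peak_ms,
                 n_trials = n_trials, gap_ms = gap_ms, qx314 = qx314),
            class = "protocol_spec")
}

mu_check_calibrated <- function(mu, need_gsyn = FALSE) {
  if (is.null(mu$calib$gaff_anchors) || is.na(mu$calib$g_cal)) {
    stop("motor unit is not calibrated; run calibrate_motor_unit() first",
         call. = FALSE)
  }
  if (need_gsyn && is.na(mu$calib$gsyn_peak)) {
    stop("dendritic drive is not calibrated; run calibrate_gsyn_peak()",
         call. = FALSE)
  }
}

new_mu_run <- function(mu, traces, spikes, force, mode, x_m, stim_axis,
                       extra = list()) {
  structure(c(list(traces = traces, spikes = spikes, force = force,
                   mode = mode, x_m = x_m, d_path_mm = mu$d_path_mm,
                   stim_axis = stim_axis), extra),
            class = "mu_run")
}

#' @export
print.mu_run <- function(x, ...) {
  cat("<mu_run> ", x$mode, " at D_path ", x$d_path_mm, " mm, X_m ", x$x_m,
      " mm: ", length(x$spikes), " spikes, peak force ",
      signif(max(x$force$force), 3), "\n", sep = "")
  invisible(x)
}

#' Run a triangular ramp protocol on a calibrated motor unit
#'
#' Somatic mode injects the triangular current at the soma (peak 20 nA at
#' 5 s, 10 s total); dendritic mode drives the excitatory synapses placed
#' on the PIC band with the calibrated triangular conductance (peak at
#' 10 s, 20 s total). Spindle drive is held at the density calibrated for
#' `x_m`; motoneuron spikes reach the muscle after the 10 ms conduction
#' delay.
#'
#' @param mu A calibrated [motor_unit()].
#' @param mode `"somatic"` or `"dendritic"`.
#' @param x_m Muscle length (default: the unit's `x_m`).
#' @param protocol Optional [protocol_spec()] override.
#' @return A `mu_run`: traces, spike times, force trace and the stimulus
#'   axis (I_S for somatic mode; I_N for dendritic mode).
#' @export
run_ramp <- function(mu, mode = c("somatic", "dendritic"), x_m = mu$x_m,
                     protocol = NULL) {
  mode <- match.arg(mode)
  check_xm(x_m)
  mu_check_calibrated(mu, need_gsyn = mode == "dendritic")
  gaff_dens <- gaff_of_length(x_m, mu$calib$gaff_anchors)
  if (mode == "somatic") {
    if (is.null(protocol)) protocol <- protocol_spec("somatic_ramp")
    duration <- 2 * protocol$t_peak_ms
    stim_wave <- waveform(c(0, protocol$t_peak_ms, duration),
                          c(0, protocol$peak_nA, 0))
    istim <- drive_list(soma_comp(mu) - 1L, 1, 0, stim_wave)
    istim$comp_at <- as.integer(soma_comp(mu) - 1L)
    drv <- list()
    if (gaff_dens > 0) {
      drv <- list(gaff_drive(mu, waveform(c(0, duration),
                                          rep(gaff_dens, 2))))
    }
    v0 <- mu_rest(mu, gaff_dens)
    eng <- mu_engine(mu, "all", drives = drv, istim = istim, v_init = v0)
    ts <- run_engine(eng, duration, dt = mu$dt)
    axis_val <- stats::approx(stim_wave$t, stim_wave$y,
                              xout = ts$traces$time)$y
    axis <- tibble::tibble(time = ts$traces$time, stim = axis_val)
  } else {
    duration <- 20000
    gsyn_wave <- waveform(c(0, duration / 2, duration),
                          c(0, mu$calib$gsyn_peak, 0))
    drv <- list(gsyn_drive(mu, gsyn_wave))
    if (gaff_dens > 0) {
      drv <- c(drv, list(gaff_drive(mu, waveform(c(0, duration),
                                                 rep(gaff_dens, 2)))))
    }
    v0 <- mu_rest(mu, gaff_dens)
    eng <- mu_engine(mu, "all", drives = drv, v_init = v0)
    ts <- run_engine(eng, duration, dt = mu$dt)
    g_t <- stats::approx(gsyn_wave$t, gsyn_wave$y, xout = ts$traces$time)$y
    axis <- tibble::tibble(time = ts$traces$time,
                           stim = g_t * mu$calib$in_per_gsyn)
  }
  force <- simulate_muscle(ts$spikes + 10, x_m, duration,
                           params = scaled_muscle(mu))
  new_mu_run(mu, ts$traces, ts$spikes, force, mode, x_m, axis,
             extra = list(duration = duration))
}

#' Run a warm-up protocol
#'
#' @inheritParams run_ramp
#' @param mode `"somatic"` (repeated current triangles) or `"dendritic"`
#'   (sinusoidal afferent drive under the QX-314 block).
#' @return A `mu_run` with a `trials` tibble giving per-trial (or
#'   per-cycle) windows.
#' @export
run_warmup <- function(mu, mode = c("somatic", "dendritic"), x_m = mu$x_m,
                       protocol = NULL) {
  mode <- match.arg(mode)
  check_xm(x_m)
  mu_check_calibrated(mu)
  gaff_dens <- gaff_of_length(x_m, mu$calib$gaff_anchors)
  if (mode == "somatic") {
    if (is.null(protocol)) protocol <- protocol_spec("warmup_somatic")
    n <- protocol$n_trials
    gap <- protocol$gap_ms
    starts <- (seq_len(n) - 1) * (2000 + gap)
    tt <- c(0); yy <- c(-5)
    for (s in starts) {
      tt <- c(tt, s, s + 1000, s + 2000)
      yy <- c(yy, -5, 10, -5)
    }
    duration <- max(starts) + 2000 + 1000
    tt <- c(tt, duration); yy <- c(yy, -5)
    istim <- drive_list(soma_comp(mu) - 1L, 1, 0, waveform(tt, yy))
    istim$comp_at <- as.integer(soma_comp(mu) - 1L)
    drv <- list()
    if (gaff_dens > 0) {
      drv <- list(gaff_drive(mu, waveform(c(0, duration),
                                          rep(gaff_dens, 2))))
    }
    v0 <- mu_rest(mu, gaff_dens)
    eng <- mu_engine(mu, "all", drives = drv, istim = istim, v_init = v0)
    ts <- run_engine(eng, duration, dt = mu$dt)
    trials <- tibble::tibble(trial = seq_len(n), start = starts,
                             end = starts + 2000)
    axis <- tibble::tibble(time = ts$traces$time, stim = ts$traces$i_stim)
  } else {
    if (is.null(protocol)) protocol <- protocol_spec("warmup_dendritic")
    n_cycles <- 8
    period <- 2000
    duration <- n_cycles * period
    delay <- attr(mu$afferents, "delay_ms")
    g_max <- max(mu$calib$gaff_anchors$g_aff)
    tgrid <- seq(0, duration, by = 10)
    gval <- g_max / 2 * (1 - cos(2 * pi * pmax(tgrid - delay, 0) / period))
    drv <- list(gaff_drive(mu, waveform(tgrid, gval)))
    istim <- drive_list(soma_comp(mu) - 1L, 1, 0,
                        waveform(c(0, 4000, 4000 + mu$dt, duration),
                                 c(-1, -1, -0.5, -0.5)))
    istim$comp_at <- as.integer(soma_comp(mu) - 1L)
    v0 <- mu_rest(mu, 0, active_set = "dendrite_only")
    eng <- mu_engine(mu, "dendrite_only", drives = drv, istim = istim,
                     v_init = v0)
    ts <- run_engine(eng, duration, dt = mu$dt)
    trials <- tibble::tibble(trial = seq_len(n_cycles),
                             start = (seq_len(n_cycles) - 1) * period,
                             end = seq_len(n_cycles) * period)
    axis <- tibble::tibble(time = ts$traces$time, stim = ts$traces$i_stim)
  }
  force <- simulate_muscle(ts$spikes + 10, x_m, duration,
                           params = scaled_muscle(mu))
  new_mu_run(mu, ts$traces, ts$spikes, force, paste0("warmup_", mode), x_m,
             axis, extra = list(trials = trials, duration = duration,
                                qx314 = mode == "dendritic"))
}

scaled_muscle <- function(mu) {
  p <- mu$muscle
  if (!is.null(mu$calib$muscle_time_scale)) {
    p$time_scale <- mu$calib$muscle_time_scale
  }
  p
}
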