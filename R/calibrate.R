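#' Measure the effective synaptic current at the soma
#'
#' Holds the soma at rest under an ideal voltage clamp with all dendrites
#' passive while a synaptic conductance is active, and reports
#' `I_N(t)` as the clamp-current deflection from baseline (positive for
#' excitation). With the cell clamped at its passive resting potential the
#' baseline clamp current is zero, so `I_N(t) = -I_clamp(t)`.
#'
#' @param mu A [motor_unit()].
#' @param gaff_dens Constant afferent density (uS/cm^2), or `NULL`.
#' @param gsyn_wave Optional conductance waveform (mS/cm^2) on the PIC
#'   band, e.g. the triangular ramp.
#' @param duration Run duration (ms).
#' @param dt Clamp-run time step (ms, default 0.05; no spikes occur under
#'   clamp so the step is verified convergent at this value).
#' @return A tibble with `time` and `i_n` (nA).
#' @export
measure_effective_synaptic_current <- function(mu, gaff_dens = NULL,
                                               gsyn_wave = NULL,
                                               duration = 400, dt = 0.05) {
  e_rest <- mu$passive$e_leak_mv
  drv <- list()
  if (!is.null(gaff_dens) && gaff_dens > 0) {
    drv <- c(drv, list(gaff_drive(mu, waveform(c(0, duration),
                                               rep(gaff_dens, 2)))))
  }
  if (!is.null(gsyn_wave)) drv <- c(drv, list(gsyn_drive(mu, gsyn_wave)))
  clamp <- drive_list(0, 1, 0, waveform(c(0, duration), rep(e_rest, 2)))
  eng <- mu_engine(mu, "none", g_cal = 0, drives = drv, clamp = clamp,
                   v_init = e_rest, dt = dt)
  ts <- run_engine(eng, duration, dt = dt, record_every = max(1L, round(1 / dt)))
  tibble::tibble(time = ts$traces$time, i_n = -ts$traces$i_clamp)
}

# steady-state I_N for a constant drive
steady_in <- function(mu, gaff_dens = NULL, gsyn_dens = NULL,
                      duration = 400, dt = 0.05) {
  gw <- if (!is.null(gsyn_dens))
    waveform(c(0, duration), rep(gsyn_dens, 2)) else NULL
  tr <- measure_effective_synaptic_current(mu, gaff_dens, gw, duration, dt)
  tail(tr$i_n, 1)
}

new_report <- function(parameter, value, target, achieved, iterations) {
  tibble::tibble(parameter = parameter, value = value, target = target,
                 achieved = achieved,
                 residual = ifelse(target == 0, abs(achieved - target),
                                   abs(achieved - target) / abs(target)),
                 iterations = iterations)
}

bisect_to_target <- function(f, target, lo, hi, tol = 0.02, max_iter = 60) {
  f_lo <- f(lo)
  f_hi <- f(hi)
  it <- 2L
  while (f_hi < target && hi < 1024 && it < max_iter) {
    lo <- hi; f_lo <- f_hi
    hi <- hi * 2
    f_hi <- f(hi)
    it <- it + 1L
  }
  if (f_hi < target) {
    stop("calibration failure: target ", target,
         " unreachable at maximal parameter value ", hi, call. = FALSE)
  }
  x <- hi; fx <- f_hi
  while (abs(fx - target) > tol * abs(target) && it < max_iter) {
    x <- (lo + hi) / 2
    fx <- f(x)
    if (fx < target) lo <- x else hi <- x
    it <- it + 1L
  }
  list(x = x, fx = fx, iterations = it)
}

#' Calibrate the dendritic PIC conductance density
#'
#' Scalar search on the hot-spot Cav1.3 density so that the
#' leak-subtracted peak inward clamp-current deflection during a slow
#' somatic voltage ramp (-70 to -30 mV over 5 s, CaL the only active
#' channel) equals the target effective calcium current approaching the
#' soma (22 nA). A monotone bracket is established by doubling before
#' bisection.
#'
#' @param mu A [motor_unit()].
#' @param target_nA Target peak deflection (default 22).
#' @param tol Relative tolerance (default 0.02).
#' @param max_iter Iteration cap (default 60).
#' @return `mu` with `calib$g_cal` set and a report row appended.
#' @export
calibrate_gcal <- function(mu, target_nA = 22, tol = 0.02, max_iter = 60) {
  base <- clamp_base_run(mu)
  defl <- function(g) peak_cal_deflection(mu, g, base_i_clamp = base)
  if (target_nA == 0) {
    mu$calib$g_cal <- 0
    mu$calib$reports <- dplyr::bind_rows(
      mu$calib$reports, new_report("g_cal", 0, 0, 0, 0L))
    return(mu)
  }
  res <- bisect_to_target(defl, target_nA, lo = 0, hi = 1, tol = tol,
                          max_iter = max_iter)
  mu$calib$g_cal <- res$x
  mu$calib$reports <- dplyr::bind_rows(
    mu$calib$reports,
    new_report("g_cal", res$x, target_nA, res$fx, res$iterations))
  mu
}

#' Leak-subtracted peak clamp deflection for a given CaL density
#'
#' Runs the slow somatic clamp ramp twice (with and without the hot-spot
#' conductance) and returns the peak inward difference current in nA.
#' @param mu A [motor_unit()].
#' @param g_cal CaL density (mS/cm^2).
#' @param dt Clamp-run step (ms, default 0.05).
#' @param base_i_clamp Optional precomputed passive (`g_cal = 0`) clamp
#'   trace, reused across bisection iterations.
#' @export
peak_cal_deflection <- function(mu, g_cal, dt = 0.05, base_i_clamp = NULL) {
  ramp <- clamp_ramp_trace(mu, g_cal, dt, base_i_clamp = base_i_clamp)
  max(ramp$deflection)
}

clamp_base_run <- function(mu, dt = 0.05, v_from = -70, v_to = -30,
                           ramp_ms = 5000) {
  clamp <- drive_list(0, 1, 0, waveform(c(0, ramp_ms), c(v_from, v_to)))
  base <- run_engine(mu_engine(mu, "none", g_cal = 0, clamp = clamp,
                               v_init = v_from, dt = dt),
                     ramp_ms, dt = dt, record_every = round(1 / dt))
  base$traces$i_clamp
}

clamp_ramp_trace <- function(mu, g_cal, dt = 0.05, v_from = -70,
                             v_to = -30, ramp_ms = 5000,
                             base_i_clamp = NULL) {
  clamp <- drive_list(0, 1, 0, waveform(c(0, ramp_ms), c(v_from, v_to)))
  if (is.null(base_i_clamp)) {
    base_i_clamp <- clamp_base_run(mu, dt, v_from, v_to, ramp_ms)
  }
  act <- run_engine(mu_engine(mu, "dendrite_only", g_cal = g_cal,
                              clamp = clamp, v_init = v_from, dt = dt),
                    ramp_ms, dt = dt, record_every = round(1 / dt))
  tibble::tibble(time = act$traces$time,
                 v_command = stats::approx(c(0, ramp_ms), c(v_from, v_to),
                                           xout = act$traces$time)$y,
                 i_clamp_passive = base_i_clamp,
                 i_clamp_cal = act$traces$i_clamp,
                 deflection = base_i_clamp - act$traces$i_clamp)
}

#' Calibrate the spindle afferent conductance anchors
#'
#' For each anchor length, bisection on the uniform afferent density so
#' that the measured effective synaptic current `I_N` at the clamped soma
#' equals the experimental anchor (0 nA at -16 mm, 2.5 nA at -8 mm,
#' 5 nA at 0 mm). The -16 mm anchor is 0 by definition.
#'
#' @param mu A [motor_unit()].
#' @param targets Named anchor currents (nA) at `x_m = -8` and `0`.
#' @param tol Relative tolerance (default 0.02).
#' @return `mu` with `calib$gaff_anchors` set and report rows appended.
#' @export
calibrate_gaff <- function(mu, targets = c(`-8` = 2.5, `0` = 5),
                           tol = 0.02) {
  anchors <- tibble::tibble(x_m = -16, g_aff = 0)
  reports <- new_report("g_aff[-16]", 0, 0, 0, 0L)
  for (xm_chr in names(targets)) {
    tgt <- targets[[xm_chr]]
    res <- bisect_to_target(function(g) steady_in(mu, gaff_dens = g),
                            tgt, lo = 0, hi = 8, tol = tol)
    anchors <- dplyr::bind_rows(anchors,
                                tibble::tibble(x_m = as.numeric(xm_chr),
                                               g_aff = res$x))
    reports <- dplyr::bind_rows(
      reports, new_report(paste0("g_aff[", xm_chr, "]"), res$x, tgt,
                          res$fx, res$iterations))
  }
  mu$calib$gaff_anchors <- dplyr::arrange(anchors, .data$x_m)
  mu$calib$reports <- dplyr::bind_rows(mu$calib$reports, reports)
  mu
}

#' Calibrate the dendritic excitation peak
#'
#' Sets the peak of the triangular synaptic conductance over the PIC band
#' so that the maximal effective synaptic current under somatic voltage
#' clamp with passive dendrites is `target_nA` (16 nA). The passive tree
#' is linear in the conductance at these densities, so the slope
#' `I_N / G_syn` measured at a reference density determines the peak; a
#' verification measurement at the calibrated peak is reported.
#'
#' @param mu A [motor_unit()].
#' @param target_nA Target peak `I_N` (default 16).
#' @param reference Reference density for the slope measurement
#'   (mS/cm^2, default 1.2).
#' @return `mu` with `calib$gsyn_peak` and `calib$in_per_gsyn` set.
#' @export
calibrate_gsyn_peak <- function(mu, target_nA = 16, reference = 1.2) {
  if (target_nA == 0) {
    mu$calib$gsyn_peak <- 0
    mu$calib$in_per_gsyn <- NA_real_
    mu$calib$reports <- dplyr::bind_rows(
      mu$calib$reports, new_report("gsyn_peak", 0, 0, 0, 1L))
    return(mu)
  }
  peak <- reference
  achieved <- steady_in(mu, gsyn_dens = peak)
  it <- 1L
  # the conductance-to-current map is close to linear but saturates
  # slightly with driving force; a fixed-point rescale converges fast
  while (abs(achieved - target_nA) > 0.02 * target_nA && it < 20L) {
    peak <- peak * target_nA / achieved
    achieved <- steady_in(mu, gsyn_dens = peak)
    it <- it + 1L
  }
  mu$calib$gsyn_peak <- peak
  mu$calib$in_per_gsyn <- achieved / peak
  mu$calib$reports <- dplyr::bind_rows(
    mu$calib$reports,
    new_report("gsyn_peak", peak, target_nA, achieved, it))
  mu
}

# ---- AHP / twitch speed coupling ------------------------------------------

#' Elicit a single somatic spike and measure the AHP duration
#'
#' A brief suprathreshold pulse is injected at the soma from rest; the AHP
#' duration is the time from the spike until the membrane potential
#' recovers to within 1 mV of the pre-pulse baseline after the
#' afterhyperpolarization trough.
#'
#' @param mu A [motor_unit()].
#' @param tau_ca Calcium-pool removal time constant override (ms).
#' @param x_m Muscle length whose afferent drive is present (default: the
#'   unit's; requires calibrated anchors, else 0 drive is used).
#' @return A list with `duration_ms`, `trough_mv`, `v_rest`, `spike_ms`.
#' @export
measure_ahp <- function(mu, tau_ca = NULL, x_m = mu$x_m) {
  if (!is.null(tau_ca)) mu$calib$tau_ca <- tau_ca
  gaff_dens <- if (!is.null(mu$calib$gaff_anchors))
    gaff_of_length(x_m, mu$calib$gaff_anchors) else 0
  v0 <- mu_rest(mu, gaff_dens, g_cal = 0)
  duration <- 1600
  pulse_at <- 100
  wavet <- c(0, pulse_at, pulse_at + mu$dt, pulse_at + 1,
             pulse_at + 1 + mu$dt, duration)
  wavey <- c(0, 0, 30, 30, 0, 0)
  istim <- drive_list(soma_comp(mu) - 1L, 1, 0, waveform(wavet, wavey))
  istim$comp_at <- as.integer(soma_comp(mu) - 1L)
  drv <- list()
  if (gaff_dens > 0) {
    drv <- list(gaff_drive(mu, waveform(c(0, duration), rep(gaff_dens, 2))))
  }
  eng <- mu_engine(mu, "all", g_cal = 0, drives = drv, istim = istim,
                   v_init = v0)
  ts <- run_engine(eng, duration, dt = mu$dt, record_every = 8L)
  tr <- ts$traces
  if (length(ts$spikes) == 0) {
    stop("AHP pulse failed to elicit a spike", call. = FALSE)
  }
  spike_ms <- ts$spikes[1]
  v_rest <- tr$v_soma[max(which(tr$time <= pulse_at - 5))]
  post <- tr[tr$time > spike_ms + 2, ]
  itr <- which.min(post$v_soma)
  rec <- which(post$v_soma[itr:nrow(post)] >= v_rest - 1)
  if (length(rec) == 0) {
    stop("membrane did not recover to within 1 mV of rest; extend the run",
         call. = FALSE)
  }
  t_end <- post$time[itr + rec[1] - 1]
  list(duration_ms = t_end - spike_ms, trough_mv = min(post$v_soma),
       v_rest = v_rest, spike_ms = spike_ms)
}

#' Calibrate the AHP-twitch speed coupling
#'
#' Matches the afterhyperpolarization duration of the motoneuron spike and
#' the twitch duration of the muscle, both to ~250 ms at the optimal
#' muscle length, as observed for slow motor units. The somatic
#' calcium-pool removal time constant is found by bisection on the AHP
#' duration (monotone); the muscle time-scale factor is found by a secant
#' iteration on the twitch duration.
#'
#' @param mu A [motor_unit()].
#' @param target_ms Common duration target (default 250).
#' @param tol Relative tolerance (default 0.05).
#' @param max_iter Iteration cap per search (default 40).
#' @return `mu` with `calib$tau_ca` and `calib$muscle_time_scale` set.
#' @export
calibrate_ahp_twitch <- function(mu, target_ms = 250, tol = 0.05,
                                 max_iter = 40) {
  # muscle twitch: duration is nearly proportional to the time scale
  twitch_dur <- function(s) {
    p <- mu$muscle
    p$time_scale <- s
    tw <- simulate_muscle(10, mu$muscle$x_opt_mm, 2500, params = p)
    twitch_metrics(tw)$duration
  }
  s <- 1
  d <- twitch_dur(s)
  it <- 1L
  while (abs(d - target_ms) > tol / 2 * target_ms && it < max_iter) {
    s <- s * target_ms / d
    d <- twitch_dur(s)
    it <- it + 1L
  }
  mu$calib$muscle_time_scale <- s
  mu$calib$reports <- dplyr::bind_rows(
    mu$calib$reports,
    new_report("muscle_time_scale", s, target_ms, d, it))

  # somatic calcium pool: AHP duration is monotone in tau_ca
  ahp_dur <- function(tau) measure_ahp(mu, tau_ca = tau,
                                       x_m = mu$muscle$x_opt_mm)$duration_ms
  res <- bisect_to_target(ahp_dur, target_ms, lo = 10, hi = 160,
                          tol = tol / 2, max_iter = max_iter)
  mu$calib$tau_ca <- res$x
  mu$calib$reports <- dplyr::bind_rows(
    mu$calib$reports,
    new_report("tau_ca", res$x, target_ms, res$fx, res$iterations))
  mu
}

#' Run all calibrations in dependency order
#'
#' Afferent anchors and the dendritic excitation peak are measured on the
#' passive tree; the hot-spot CaL density is then pinned by the clamp-ramp
#' target; finally the AHP-twitch speed coupling sets the somatic calcium
#' pool and muscle time constants.
#'
#' @param mu A [motor_unit()].
#' @param gcal_target_nA Effective calcium-current target (default 22).
#' @param in_anchors Afferent `I_N` anchor targets (nA).
#' @param gsyn_target_nA Peak `I_N` target for dendritic drive (default 16).
#' @param ahp_twitch_ms AHP/twitch duration target (default 250).
#' @return A calibrated `motor_unit`.
#' @export
calibrate_motor_unit <- function(mu, gcal_target_nA = 22,
                                 in_anchors = c(`-8` = 2.5, `0` = 5),
                                 gsyn_target_nA = 16,
                                 ahp_twitch_ms = 250) {
  mu <- calibrate_gaff(mu, in_anchors)
  mu <- calibrate_gsyn_peak(mu, gsyn_target_nA)
  mu <- calibrate_gcal(mu, gcal_target_nA)
  mu <- calibrate_ahp_twitch(mu, ahp_twitch_ms)
  mu
}
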