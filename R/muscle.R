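#' Muscle unit parameters
#'
#' Parameters of the three-module muscle model for a slow (soleus-like) cat
#' motor unit: module 1 transforms motoneuron action potentials into
#' sarcoplasmic calcium (saturable release per spike, first-order reuptake),
#' module 2 transforms calcium into activation (bimolecular calcium-troponin
#' binding followed by a Hill function with a length-dependent
#' half-activation), and module 3 transforms activation into isometric force
#' (force-length scaling and a first-order rise/relaxation filter).
#'
#' Muscle length `X_m` is expressed in mm relative to the maximal
#' physiological length: -16 mm (shortest), -8 mm (optimal, peak tetanic
#' force), 0 mm (longest). The force-length factor is an asymmetric
#' Gaussian with `FL(-8) = 1`; its values at the range ends
#' (`fl_short`, `fl_long`) satisfy the ordering constraints of cat soleus.
#' The half-activation `K_A(X_m)` increases linearly as the muscle shortens
#' (a shorter muscle is harder to activate), which makes the short-length
#' force deficit rate-dependent: near-saturating tetanic calcium masks the
#' `K_A` shift while twitch and subtetanic (<20 Hz) contractions expose it.
#'
#' @param f_max_n Maximal tetanic force at optimal length (N), used only to
#'   scale the normalized force output.
#' @param x_opt_mm Optimal muscle length (mm, default -8).
#' @param fl_short,fl_long Force-length factor at -16 and 0 mm.
#' @param ca_release Calcium release increment per spike (normalized).
#' @param ca_sat Release saturation constant (normalized calcium units).
#' @param tau_ca_ms Sarcoplasmic calcium reuptake time constant (ms).
#' @param k_on,k_off Calcium-troponin binding/unbinding rates (1/ms).
#' @param n_hill Hill coefficient of the activation curve.
#' @param k_a_opt Half-activation (troponin occupancy) at optimal length.
#' @param k_a_slope Fractional increase of `K_A` per 8 mm of shortening.
#' @param tau_force_ms Force low-pass time constant (ms).
#' @param time_scale Dimensionless factor applied to all four time scales
#'   (`tau_ca_ms`, `1/k_on`, `1/k_off`, `tau_force_ms`); the knob used by
#'   the AHP-twitch speed-coupling calibration.
#' @return A list of class `muscle_params`.
#' @export
muscle_params <- function(f_max_n = 1, x_opt_mm = -8,
                          fl_short = 0.55, fl_long = 0.85,
                          ca_release = 1, ca_sat = 10, tau_ca_ms = 50,
                          k_on = 0.02, k_off = 0.01,
                          n_hill = 3, k_a_opt = 0.45, k_a_slope = 0.25,
                          tau_force_ms = 40, time_scale = 1) {
  stopifnot(tau_ca_ms > 0, k_on > 0, k_off > 0, tau_force_ms > 0,
            ca_sat > 0, ca_release > 0, n_hill > 0,
            k_a_opt > 0, k_a_slope >= 0, k_a_slope < 1,
            fl_short > 0, fl_short < 1, fl_long > 0, fl_long < 1,
            time_scale > 0)
  structure(as.list(environment()), class = "muscle_params")
}

check_xm <- function(x_m) {
  if (any(x_m < -16 | x_m > 0)) {
    stop("X_m must lie in [-16, 0] mm", call. = FALSE)
  }
  invisible(x_m)
}

#' Force-length factor
#'
#' Asymmetric Gaussian centred at the optimal length with the prescribed
#' values at the short (-16 mm) and long (0 mm) ends of the physiological
#' range.
#' @param x_m Muscle length (mm, in `[-16, 0]`).
#' @param params A [muscle_params()].
#' @export
force_length <- function(x_m, params = muscle_params()) {
  check_xm(x_m)
  dx <- x_m - params$x_opt_mm
  w_short <- abs(params$x_opt_mm - (-16)) / sqrt(log(1 / params$fl_short))
  w_long <- abs(0 - params$x_opt_mm) / sqrt(log(1 / params$fl_long))
  w <- ifelse(dx < 0, w_short, w_long)
  exp(-(dx / w)^2)
}

#' Length-dependent half-activation of the Hill curve
#' @inheritParams force_length
#' @export
k_a_of_length <- function(x_m, params = muscle_params()) {
  check_xm(x_m)
  params$k_a_opt * (1 - params$k_a_slope * (x_m - params$x_opt_mm) / 8)
}

# effective (time-scaled) rate constants
muscle_rates <- function(params) {
  s <- params$time_scale
  list(tau_ca = params$tau_ca_ms * s, k_on = params$k_on / s,
       k_off = params$k_off / s, tau_f = params$tau_force_ms * s)
}

#' Module 1: sarcoplasmic calcium update for one time step
#'
#' Each spike adds a saturable release increment
#' `R (1 - Ca/Ca_sat)`; between spikes calcium decays first-order with the
#' reuptake time constant.
#'
#' @param ca Current normalized calcium.
#' @param spikes_in_step Number of spikes arriving in this step.
#' @param dt Time step (ms), positive.
#' @param params A [muscle_params()].
#' @export
calcium_from_spikes <- function(ca, spikes_in_step, dt, params = muscle_params()) {
  stopifnot(dt > 0)
  rt <- muscle_rates(params)
  if (spikes_in_step > 0) {
    for (i in seq_len(spikes_in_step)) {
      ca <- ca + params$ca_release * (1 - ca / params$ca_sat)
    }
  }
  ca * exp(-dt / rt$tau_ca)
}

#' Module 2: troponin occupancy and activation update for one time step
#'
#' `d(CaT)/dt = k_on Ca (1 - CaT) - k_off CaT`, integrated exactly at
#' frozen calcium; activation is the Hill function
#' `A = CaT^n / (CaT^n + K_A(X_m)^n)`.
#'
#' @param cat_frac Current calcium-troponin occupancy in `[0, 1]`.
#' @param ca Current normalized calcium.
#' @param x_m Muscle length (mm).
#' @param dt Time step (ms).
#' @param params A [muscle_params()].
#' @return List with updated `cat_frac` and `a`.
#' @export
activation_from_calcium <- function(cat_frac, ca, x_m, dt,
                                    params = muscle_params()) {
  rt <- muscle_rates(params)
  ktot <- rt$k_on * ca + rt$k_off
  cat_inf <- rt$k_on * ca / ktot
  cat_frac <- cat_inf + (cat_frac - cat_inf) * exp(-ktot * dt)
  ka <- k_a_of_length(x_m, params)
  a <- cat_frac^params$n_hill / (cat_frac^params$n_hill + ka^params$n_hill)
  list(cat_frac = cat_frac, a = a)
}

#' Module 3: force update for one time step
#'
#' Normalized force relaxes toward `A * FL(X_m)` with the force filter time
#' constant; output is normalized to the maximal tetanic force at optimal
#' length.
#'
#' @param f_t Current normalized force.
#' @param a Current activation.
#' @param x_m Muscle length (mm).
#' @param dt Time step (ms).
#' @param params A [muscle_params()].
#' @export
force_from_activation <- function(f_t, a, x_m, dt, params = muscle_params()) {
  rt <- muscle_rates(params)
  target <- a * force_length(x_m, params)
  target + (f_t - target) * exp(-dt / rt$tau_f)
}

#' Simulate the muscle unit response to a spike train
#'
#' Chains the three module updates per time step during an isometric
#' contraction at constant length `x_m`.
#'
#' @param spikes Spike arrival times at the muscle (ms), strictly
#'   increasing. Apply the efferent conduction delay (10 ms) before calling
#'   if the spikes come from the motoneuron.
#' @param x_m Muscle length (mm, in `[-16, 0]`).
#' @param duration Duration (ms).
#' @param dt Time step (ms, default 0.1).
#' @param params A [muscle_params()].
#' @return A tibble with columns `time`, `ca`, `cat_frac`, `a`, `force`
#'   (normalized) of class `muscle_trace`.
#' @export
simulate_muscle <- function(spikes, x_m, duration, dt = 0.1,
                            params = muscle_params()) {
  check_xm(x_m)
  if (length(spikes) > 1 && any(diff(spikes) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  if (any(spikes < 0)) stop("spike times must be non-negative", call. = FALSE)
  rt <- muscle_rates(params)
  n <- ceiling(duration / dt)
  spk_bin <- tabulate(pmin(floor(spikes / dt) + 1, n), nbins = n)
  fl <- force_length(x_m, params)
  ka <- k_a_of_length(x_m, params)
  nh <- params$n_hill
  dec_ca <- exp(-dt / rt$tau_ca)
  dec_f <- exp(-dt / rt$tau_f)
  ca <- 0; cat_f <- 0; f <- 0
  out_ca <- numeric(n + 1); out_cat <- numeric(n + 1)
  out_a <- numeric(n + 1); out_f <- numeric(n + 1)
  for (i in seq_len(n)) {
    if (spk_bin[i] > 0) {
      for (k in seq_len(spk_bin[i])) {
        ca <- ca + params$ca_release * (1 - ca / params$ca_sat)
      }
    }
    ca <- ca * dec_ca
    ktot <- rt$k_on * ca + rt$k_off
    cat_inf <- rt$k_on * ca / ktot
    cat_f <- cat_inf + (cat_f - cat_inf) * exp(-ktot * dt)
    a <- cat_f^nh / (cat_f^nh + ka^nh)
    target <- a * fl
    f <- target + (f - target) * dec_f
    out_ca[i + 1] <- ca; out_cat[i + 1] <- cat_f
    out_a[i + 1] <- a; out_f[i + 1] <- f
  }
  structure(tibble::tibble(
    time = seq(0, n * dt, by = dt), ca = out_ca, cat_frac = out_cat,
    a = out_a, force = out_f
  ), class = c("muscle_trace", "tbl_df", "tbl", "data.frame"), x_m = x_m)
}

#' Twitch metrics from a single-spike force trace
#'
#' Twitch duration is measured from force onset (first sample exceeding 1%
#' of the twitch peak) until force decays below 10% of the twitch peak;
#' both thresholds are relative, so the metrics are invariant to amplitude
#' scaling.
#'
#' @param force_trace A tibble with `time` and `force` columns produced by
#'   [simulate_muscle()] from a single spike.
#' @param n_spikes Number of spikes that produced the trace (for contract
#'   checking; default 1).
#' @return A tibble with `peak`, `time_to_peak`, `duration` (ms), or with
#'   `NA`s and `twitch = FALSE` when the trace never rises above zero.
#' @export
twitch_metrics <- function(force_trace, n_spikes = 1) {
  if (n_spikes != 1) {
    stop("twitch_metrics requires a single-spike trace (got ", n_spikes,
         " spikes)", call. = FALSE)
  }
  f <- force_trace$force
  t <- force_trace$time
  pk <- max(f)
  if (pk <= 0) {
    return(tibble::tibble(peak = NA_real_, time_to_peak = NA_real_,
                          duration = NA_real_, twitch = FALSE))
  }
  ipk <- which.max(f)
  onset <- which(f > 0.01 * pk)[1]
  after <- which(f[ipk:length(f)] < 0.10 * pk)
  if (length(after) == 0) {
    stop("force has not decayed below 10% of peak within the trace;",
         " extend the simulation", call. = FALSE)
  }
  dec <- t[ipk + after[1] - 1]
  tibble::tibble(peak = pk, time_to_peak = t[ipk] - t[onset],
                 duration = dec - t[onset], twitch = TRUE)
}

#' Mean force over the plateau of a stimulation response
#' @param force_trace A `muscle_trace`.
#' @param from_ms Discard this initial transient (default: second half).
#' @keywords internal
plateau_force <- function(force_trace, from_ms = max(force_trace$time) / 2) {
  mean(force_trace$force[force_trace$time >= from_ms])
}
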