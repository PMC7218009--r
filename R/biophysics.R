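#' Gate kinetics: Boltzmann steady state with a bell/sigmoid time constant
#'
#' Each voltage-gated channel gate follows first-order kinetics toward a
#' Boltzmann steady state
#' `m_inf(V) = 1 / (1 + exp(-(V - v_half) / k))` (activation; a negative `k`
#' gives an inactivation gate) with a voltage-dependent time constant
#' `tau(V) = tau_base + tau_amp / (1 + exp((V - tau_vhalf) / tau_k))`.
#' With `tau_k > 0` the time constant is large below `tau_vhalf` and relaxes
#' to `tau_base` above it — the form used for the slowly deactivating
#' Cav1.3 gate.
#'
#' @param v_half Half-activation voltage (mV).
#' @param k Slope factor (mV); sign sets activation vs inactivation.
#' @param tau_base Minimal time constant (ms).
#' @param tau_amp Added amplitude of the voltage-dependent component (ms).
#' @param tau_vhalf,tau_k Voltage dependence of the time constant (mV).
#' @param tau_k2 If given, the time constant is bell-shaped,
#'   `tau_base + tau_amp / (exp((V - tau_vhalf)/tau_k) +
#'   exp(-(V - tau_vhalf)/tau_k2))`, the form used for sodium inactivation
#'   and delayed-rectifier activation in cat motoneuron models.
#' @param exponent Integer power applied to the gate in the conductance.
#' @return A list of class `gate_spec`.
#' @export
gate_spec <- function(v_half, k, tau_base = 1, tau_amp = 0,
                      tau_vhalf = v_half, tau_k = 10, tau_k2 = NA,
                      exponent = 1L) {
  stopifnot(k != 0, tau_base > 0, tau_amp >= 0, exponent >= 1)
  structure(list(v_half = v_half, k = k, tau_base = tau_base,
                 tau_amp = tau_amp, tau_vhalf = tau_vhalf, tau_k = tau_k,
                 tau_k2 = tau_k2, exponent = as.integer(exponent)),
            class = "gate_spec")
}

#' Steady-state activation of a gate
#' @param gate A [gate_spec()].
#' @param v Membrane potential (mV), vectorized.
#' @return Open fraction in `[0, 1]`.
#' @export
steady_state_activation <- function(gate, v) {
  stopifnot(all(is.finite(v)))
  1 / (1 + exp(-(v - gate$v_half) / gate$k))
}

#' Gate time constant (ms)
#' @inheritParams steady_state_activation
#' @export
gate_tau <- function(gate, v) {
  if (!is.null(gate$tau_k2) && !is.na(gate$tau_k2)) {
    gate$tau_base + gate$tau_amp /
      (exp((v - gate$tau_vhalf) / gate$tau_k) +
         exp(-(v - gate$tau_vhalf) / gate$tau_k2))
  } else {
    gate$tau_base + gate$tau_amp / (1 + exp((v - gate$tau_vhalf) / gate$tau_k))
  }
}

#' Advance a gate one step by exact exponential relaxation
#'
#' At frozen voltage the gate ODE is linear, so the update
#' `m' = m_inf + (m - m_inf) exp(-dt / tau)` is exact — the same
#' exponential-Euler rule the compiled cable engine applies per
#' compartment per step.
#'
#' @param gate A [gate_spec()].
#' @param v Membrane potential (mV).
#' @param m Current open fraction in `[0, 1]`.
#' @param dt Time step (ms), must be positive.
#' @export
gate_step <- function(gate, v, m, dt) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  stopifnot(all(m >= 0), all(m <= 1))
  minf <- steady_state_activation(gate, v)
  minf + (m - minf) * exp(-dt / gate_tau(gate, v))
}

#' Channel specification
#'
#' An ohmic channel `I = g * prod(gate^exponent) * (V - e_rev)` in density
#' units (conductance mS/cm^2, current mA/cm^2; inward current negative).
#' The calcium-dependent potassium channel carries no voltage gate: set
#' `ca_gated = TRUE` and it is gated by a Hill function of somatic calcium,
#' `Ca^n / (Ca^n + kd^n)`.
#'
#' @param name Channel name.
#' @param g Peak conductance density (mS/cm^2).
#' @param e_rev Reversal potential (mV).
#' @param gates List of [gate_spec()] (empty for `ca_gated` channels).
#' @param ca_gated Gated by intracellular calcium instead of voltage.
#' @param ca_source Does this channel's current feed the somatic calcium
#'   pool?
#' @param ca_hill_n,ca_kd Hill coefficient and half-activation (mM) for
#'   `ca_gated` channels.
#' @return A list of class `channel_spec`.
#' @export
channel_spec <- function(name, g, e_rev, gates = list(), ca_gated = FALSE,
                         ca_source = FALSE, ca_hill_n = 2, ca_kd = 2e-4) {
  stopifnot(g >= 0)
  if (ca_gated && length(gates) > 0) {
    stop("a calcium-gated channel carries no voltage gates", call. = FALSE)
  }
  structure(list(name = name, g = g, e_rev = e_rev, gates = gates,
                 ca_gated = ca_gated, ca_source = ca_source,
                 ca_hill_n = ca_hill_n, ca_kd = ca_kd),
            class = "channel_spec")
}

#' Instantaneous channel current density
#'
#' @param spec A [channel_spec()].
#' @param v Membrane potential (mV).
#' @param gates Numeric vector of gate open fractions, one per gate in
#'   `spec` (ignored for calcium-gated channels).
#' @param ca Somatic calcium (mM), used only by calcium-gated channels.
#' @return Current density (mA/cm^2); inward currents are negative.
#' @export
channel_current <- function(spec, v, gates = numeric(0), ca = 0) {
  if (spec$ca_gated) {
    open <- ca^spec$ca_hill_n / (ca^spec$ca_hill_n + spec$ca_kd^spec$ca_hill_n)
  } else {
    if (length(gates) != length(spec$gates)) {
      stop("channel '", spec$name, "' expects ", length(spec$gates),
           " gate values, got ", length(gates), call. = FALSE)
    }
    open <- 1
    for (i in seq_along(spec$gates)) {
      open <- open * gates[i]^spec$gates[[i]]$exponent
    }
  }
  spec$g * 1e-3 * open * (v - spec$e_rev)  # mS/cm^2 * mV = uA/cm^2 -> mA/cm^2
}

#' Somatic calcium pool
#'
#' Thin-shell first-order pool:
#' `d[Ca]/dt = -f * I_Ca - ([Ca] - ca_rest) / tau_ms`, with `I_Ca` the total
#' calcium current at the soma in nA (inward negative, so influx raises
#' `[Ca]`). `tau_ms` is the free parameter adjusted by the AHP-twitch
#' speed-coupling calibration.
#'
#' @param f_influx Influx scaling (mM per nA ms).
#' @param tau_ms Removal time constant (ms).
#' @param ca_rest Resting concentration (mM).
#' @export
calcium_pool <- function(f_influx = 2.2e-5, tau_ms = 60, ca_rest = 5e-5) {
  stopifnot(tau_ms > 0, f_influx >= 0, ca_rest >= 0)
  structure(list(f_influx = f_influx, tau_ms = tau_ms, ca_rest = ca_rest),
            class = "calcium_pool")
}

#' Default channel set for the motoneuron
#'
#' Somatic action-potential machinery (fast Na, delayed-rectifier K, N-type
#' Ca, Ca-dependent K, persistent Na), a higher-density Na/K complement on
#' the hillock and initial segment, and the low-voltage-activated dendritic
#' L-type (Cav1.3) PIC channel. The Cav1.3 activation gate is slow below
#' -60 mV (time constant rising toward seconds) so that residual PIC
#' activation can carry over between repeated stimuli, and fast
#' (tens of ms) near firing threshold.
#'
#' Densities are in mS/cm^2. `g` for `ca_l` here is a placeholder: the
#' hot-spot density is set per band by [calibrate_gcal()].
#'
#' @return Named list of [channel_spec()] objects with a `placement`
#'   attribute mapping each channel to `soma`, `axon` (hillock + initial
#'   segment) or `dendrite_band`.
#' @export
default_channels <- function() {
  ch <- list(
    na_f = channel_spec(
      "na_f", g = 300, e_rev = 55,
      gates = list(
        gate_spec(v_half = -43, k = 7.8, tau_base = 0.05, exponent = 3L),
        gate_spec(v_half = -55, k = -7, tau_base = 0.2, tau_amp = 30,
                  tau_vhalf = -50, tau_k = 15, tau_k2 = 16, exponent = 1L)
      )
    ),
    k_dr = channel_spec(
      "k_dr", g = 100, e_rev = -80,
      gates = list(
        gate_spec(v_half = -28, k = 15, tau_base = 0.5, tau_amp = 7,
                  tau_vhalf = -40, tau_k = 40, tau_k2 = 50, exponent = 4L)
      )
    ),
    ca_n = channel_spec(
      "ca_n", g = 5, e_rev = 80, ca_source = TRUE,
      gates = list(
        gate_spec(v_half = -30, k = 5, tau_base = 4, exponent = 2L),
        gate_spec(v_half = -45, k = -5, tau_base = 40, exponent = 1L)
      )
    ),
    k_ca = channel_spec(
      "k_ca", g = 16, e_rev = -80, ca_gated = TRUE,
      ca_hill_n = 2, ca_kd = 2e-4
    ),
    na_p = channel_spec(
      "na_p", g = 0.5, e_rev = 55,
      gates = list(
        gate_spec(v_half = -50, k = 4, tau_base = 2, exponent = 1L)
      )
    ),
    ca_l = channel_spec(
      "ca_l", g = 0, e_rev = 60,
      gates = list(
        gate_spec(v_half = -52, k = 4, tau_base = 40, tau_amp = 1960,
                  tau_vhalf = -63, tau_k = 2, exponent = 1L)
      )
    )
  )
  attr(ch, "placement") <- c(
    na_f = "soma_axon", k_dr = "soma_axon", ca_n = "soma",
    k_ca = "soma", na_p = "soma", ca_l = "dendrite_band"
  )
  # axon (hillock + initial segment) density multiplier for soma_axon channels
  attr(ch, "axon_gain") <- c(na_f = 5, k_dr = 2.5)
  ch
}
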