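#' Discretize a morphology into a compartmental cable model
#'
#' Splits every section into compartments whose electrotonic extent at a
#' 100 Hz-equivalent space constant is below `max_seg_lambda`. The AC space
#' constant is `lambda_DC / (1 + (2 pi f tau_m)^2)^(1/4)` with
#' `tau_m = R_m C_m`, so the grid refines where the membrane is fast.
#' Compartments are ordered root (soma) first with every parent preceding
#' its children, the traversal order the Hines solver requires.
#'
#' @param tree A [neurite_tree()].
#' @param passive A [passive_params()] set.
#' @param max_seg_lambda Upper bound on per-compartment electrotonic length
#'   (default 0.15, must lie in (0, 0.3]).
#' @return An object of class `cable_model`: a list with the compartment
#'   tibble (`comps`), the source `tree` and `passive` set.
#' @export
compartmentalize <- function(tree, passive = passive_params(),
                             max_seg_lambda = 0.15) {
  stopifnot(max_seg_lambda > 0, max_seg_lambda <= 0.3)
  s <- tree$sections
  start <- section_path_start(tree)
  tau_m <- function(rm_kohm) rm_kohm * passive$cm_uf_cm2          # ms
  ac_factor <- function(rm_kohm) (1 + (2 * pi * 0.1 * tau_m(rm_kohm))^2)^0.25

  rows <- vector("list", nrow(s))
  last_comp_of <- integer(nrow(s))  # section row -> its distal compartment id
  comp_id <- 0L
  for (i in seq_len(nrow(s))) {
    sec <- s[i, ]
    if (sec$kind == "soma") {
      n_seg <- 1L
    } else {
      p_mid <- (start[i] + sec$length / 2) / 1000
      d_mid <- (sec$diam_prox + sec$diam_dist) / 2
      rm <- rm_at_path(passive, p_mid, sec$kind)
      lam100_um <- lambda_at(passive, d_mid, p_mid, sec$kind) /
        ac_factor(rm) * 1000
      n_seg <- max(1L, ceiling((sec$length / lam100_um) / max_seg_lambda))
    }
    edges <- seq(0, sec$length, length.out = n_seg + 1)
    mids <- (edges[-1] + edges[-(n_seg + 1)]) / 2
    arc <- mids / sec$length
    len <- diff(edges)
    d <- diam_at_arc(sec, arc)
    p_mm <- (start[i] + mids) / 1000
    rm <- rm_at_path(passive, p_mm, sec$kind)
    area_cm2 <- pi * d * len * 1e-8
    if (sec$kind == "soma") area_cm2 <- section_area(sec$length, sec$diam_prox,
                                                     sec$diam_dist) * 1e-8
    parent_comp <- integer(n_seg)
    parent_comp[1] <- if (is.na(sec$parent)) 0L else
      last_comp_of[match(sec$parent, s$id)]
    if (n_seg > 1) parent_comp[2:n_seg] <- comp_id + seq_len(n_seg - 1)
    rows[[i]] <- tibble::tibble(
      comp = comp_id + seq_len(n_seg), section = sec$id, kind = sec$kind,
      arc = arc, length_um = len, diam_um = d, area_cm2 = area_cm2,
      path_mm = p_mm, rm_kohm = rm, parent_comp = parent_comp
    )
    comp_id <- comp_id + n_seg
    last_comp_of[i] <- comp_id
  }
  comps <- dplyr::bind_rows(rows)

  # half-compartment axial resistances (Ohm) and coupling conductances (uS)
  r_half <- 4 * passive$ri_ohm_cm * (comps$length_um * 1e-4 / 2) /
    (pi * (comps$diam_um * 1e-4)^2)
  g_ax <- numeric(nrow(comps))
  has_parent <- comps$parent_comp > 0
  g_ax[has_parent] <- 1e6 / (r_half[comps$comp[has_parent]] +
                               r_half[comps$parent_comp[has_parent]])
  comps$g_ax_uS <- g_ax
  comps$g_leak_uS <- comps$area_cm2 / comps$rm_kohm * 1000  # mS/cm2 * cm2 -> uS
  comps$cm_nF <- comps$area_cm2 * passive$cm_uf_cm2 * 1000  # nF: nF*mV/ms = nA

  structure(list(comps = comps, tree = tree, passive = passive,
                 n = nrow(comps)),
            class = "cable_model")
}

#' @export
print.cable_model <- function(x, ...) {
  cat("<cable_model> ", x$n, " compartments (",
      sum(x$comps$kind == "dendrite"), " dendritic), total area ",
      signif(sum(x$comps$area_cm2), 4), " cm^2\n", sep = "")
  invisible(x)
}

# ---- engine assembly ------------------------------------------------------

v_grid_spec <- function() list(v0 = -120, dv = 0.05, n = 3601L)

gate_tables <- function(gate, dt) {
  gs <- v_grid_spec()
  v <- gs$v0 + gs$dv * (seq_len(gs$n) - 1)
  list(inf = steady_state_activation(gate, v),
       expdt = exp(-dt / gate_tau(gate, v)),
       v0 = gs$v0, dv = gs$dv, exponent = gate$exponent)
}

# piecewise-linear waveform helper
waveform <- function(t_ms, y) {
  stopifnot(length(t_ms) == length(y), !is.unsorted(t_ms))
  tibble::tibble(t = t_ms, y = y)
}

drive_list <- function(comp0, mult, e_rev, wave) {
  list(comp = as.integer(comp0), mult = mult, e_rev = e_rev,
       t = wave$t, y = wave$y)
}

# Build the list consumed by the compiled engine.
# chan_place: named list channel -> integer compartment ids (1-based);
# chan_g: named list channel -> density mS/cm^2 (scalar or per-comp).
assemble_engine <- function(cable, channels, chan_place, chan_g, dt,
                            drives = list(), istim = NULL, clamp = NULL,
                            v_init = NULL, band_comp = integer(0),
                            ca_pool_pars = calcium_pool(), theta = 1) {
  comps <- cable$comps
  e_leak <- rep(cable$passive$e_leak_mv, cable$n)
  chans <- list()
  for (nm in names(chan_place)) {
    idx <- chan_place[[nm]]
    if (length(idx) == 0) next
    spec <- channels[[nm]]
    g_dens <- chan_g[[nm]]
    if (length(g_dens) == 1) g_dens <- rep(g_dens, length(idx))
    g_uS <- g_dens * comps$area_cm2[idx] * 1000
    chans[[length(chans) + 1L]] <- list(
      name = spec$name, comp = as.integer(idx - 1L), g_uS = g_uS,
      e_rev = spec$e_rev, ca_gated = spec$ca_gated,
      ca_source = spec$ca_source, ca_hill_n = spec$ca_hill_n,
      ca_kd = spec$ca_kd,
      gates = lapply(spec$gates, gate_tables, dt = dt)
    )
  }
  if (is.null(v_init)) v_init <- rep(cable$passive$e_leak_mv, cable$n)
  if (length(v_init) == 1) v_init <- rep(v_init, cable$n)
  # fold drives with a time-constant waveform into the static conductance
  g_static <- numeric(cable$n)
  b_static <- numeric(cable$n)
  keep <- vapply(drives, function(d) {
    if (length(d$y) > 0 && diff(range(d$y)) == 0) {
      idx <- d$comp + 1L
      g_static[idx] <<- g_static[idx] + d$y[1] * d$mult
      b_static[idx] <<- b_static[idx] + d$y[1] * d$mult * d$e_rev
      FALSE
    } else TRUE
  }, logical(1))
  drives <- drives[keep]
  e_static <- ifelse(g_static > 0, b_static / pmax(g_static, 1e-300), 0)
  list(
    parent = as.integer(comps$parent_comp - 1L),
    cm_nF = comps$cm_nF, g_leak_uS = comps$g_leak_uS, e_leak = e_leak,
    g_ax_uS = comps$g_ax_uS, v_init = v_init,
    g_static_uS = g_static, e_static = e_static,
    channels = chans, drives = drives, istim = istim, clamp = clamp,
    ca_pool = ca_pool_pars, band_comp = as.integer(band_comp - 1L),
    theta = theta
  )
}

engine_traces <- function(raw, dt, record_every) {
  tr <- tibble::tibble(
    time = raw$time, v_soma = raw$v_soma, v_band = raw$v_band,
    m_cal = raw$m_cal, ca = raw$ca, i_stim = raw$i_stim,
    i_clamp = raw$i_clamp
  )
  structure(list(traces = tr, spikes = raw$spikes, v_final = raw$v_final,
                 v_full = raw$v_full, dt = dt,
                 record_dt = dt * record_every),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", nrow(x$traces), " samples every ", x$record_dt,
      " ms; ", length(x$spikes), " spikes\n", sep = "")
  invisible(x)
}

#' Run the cable engine
#'
#' Low-level entry point: integrates an assembled engine model for
#' `duration` ms at fixed step `dt` with the Crank-Nicolson branched solve
#' and exponential-Euler gates. Spike times are upward 0 mV crossings at
#' the soma with a 1 ms lockout.
#'
#' @param eng Engine model list from the internal assembler.
#' @param duration Duration (ms); must be a multiple of `dt`.
#' @param dt Fixed time step (ms, default 0.025).
#' @param record_every Record every this many steps (default 40 = 1 ms).
#' @param record_full Also record the full voltage matrix.
#' @return A `trace_set`: tibble of recorded channels plus spike times.
#' @keywords internal
run_engine <- function(eng, duration, dt = 0.025, record_every = 40L,
                       record_full = FALSE) {
  stopifnot(abs(duration / dt - round(duration / dt)) < 1e-9)
  raw <- engine_run(eng, duration, dt, as.integer(record_every), record_full)
  engine_traces(raw, dt, record_every)
}

#' Integrate a passive cable under a constant current step
#'
#' Convenience wrapper used to validate the integrator against closed-form
#' cable solutions: injects a constant current at one compartment of the
#' passive model and records the full voltage matrix.
#'
#' @param cable A [compartmentalize()]d model.
#' @param inj_comp Compartment id receiving the step.
#' @param i_nA Step amplitude (nA).
#' @param duration Duration (ms).
#' @param dt Time step (ms, default 0.025).
#' @param theta Implicitness of the voltage solve (1 = backward Euler,
#'   0.5 = Crank-Nicolson).
#' @return A `trace_set` with `v_full` (time x compartment matrix).
#' @export
cable_step_response <- function(cable, inj_comp, i_nA, duration,
                                dt = 0.025, theta = 1) {
  istim <- drive_list(inj_comp - 1L, 1, 0,
                      waveform(c(0, duration), rep(i_nA, 2)))
  istim$comp_at <- as.integer(inj_comp - 1L)
  eng <- assemble_engine(cable, list(), list(), list(), dt, istim = istim,
                         theta = theta)
  run_engine(eng, duration, dt = dt, record_every = max(1L, round(1 / dt)),
             record_full = TRUE)
}

#' Passive steady-state voltage under point current injection
#'
#' Direct linear solve of the passive (leak + axial) system; used as the
#' implementation for input resistance and as an attenuation oracle.
#'
#' @param cable A [compartmentalize()]d model.
#' @param inj_comp Compartment id receiving current.
#' @param inj_nA Injected current (nA).
#' @param g_extra Optional extra membrane conductance (uS) per compartment.
#' @return Voltage deflection vector (mV) relative to rest.
#' @keywords internal
passive_steady <- function(cable, inj_comp, inj_nA, g_extra = NULL) {
  comps <- cable$comps
  n <- cable$n
  G <- matrix(0, n, n)
  diag(G) <- comps$g_leak_uS
  if (!is.null(g_extra)) diag(G) <- diag(G) + g_extra
  for (i in which(comps$parent_comp > 0)) {
    p <- comps$parent_comp[i]
    g <- comps$g_ax_uS[i]
    G[i, i] <- G[i, i] + g
    G[p, p] <- G[p, p] + g
    G[i, p] <- G[i, p] - g
    G[p, i] <- G[p, i] - g
  }
  b <- numeric(n)
  b[inj_comp] <- inj_nA
  solve(G, b)
}

#' Input resistance at a compartment
#'
#' Steady-state voltage deflection per unit current for a small
#' (-0.1 nA) injection with all active conductances frozen at rest
#' (passive mode).
#'
#' @param cable A [compartmentalize()]d model.
#' @param comp Compartment id (see `cable$comps`).
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(cable, comp) {
  dv <- passive_steady(cable, comp, -0.1)
  dv[comp] / (-0.1)  # mV / nA = MOhm
}
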