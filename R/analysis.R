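#' Instantaneous firing rate from spike times
#'
#' The rate `1000 / ISI` (Hz) is assigned at the second spike of each pair.
#'
#' @param spikes Spike times (ms), strictly increasing.
#' @return A tibble with `time` and `rate`; empty when fewer than two
#'   spikes.
#' @export
instantaneous_rate <- function(spikes) {
  if (length(spikes) < 2) {
    return(tibble::tibble(time = numeric(0), rate = numeric(0)))
  }
  if (any(diff(spikes) <= 0)) {
    stop("spike times must be strictly increasing", call. = FALSE)
  }
  tibble::tibble(time = spikes[-1], rate = 1000 / diff(spikes))
}

#' Build the input-output curve of a ramp run
#'
#' Resamples force and firing rate against the stimulus axis (injected
#' somatic current `I_S` or effective synaptic current `I_N`), separately
#' for the ascending and descending stimulation phases, on a regular
#' stimulus grid.
#'
#' @param run A `mu_run` from [run_ramp()], or a list with `stim_axis`
#'   (tibble `time`, `stim`), `force` (tibble `time`, `force`) and
#'   `spikes`.
#' @param grid_nA Stimulus resampling step (default 0.05 nA). Ties at grid
#'   boundaries resolve toward the earlier time.
#' @return An `io_curve`: tibble with `stim`, `phase`
#'   (`"ascending"`/`"descending"`), `force`, `rate`; attributes
#'   `peak_force`, `mode`, `stim_peak`.
#' @export
build_io_curve <- function(run, grid_nA = 0.05) {
  ax <- run$stim_axis
  if (is.null(ax) || all(is.na(ax$stim))) {
    stop("run carries no stimulus axis; for dendritic mode the G_syn to ",
         "I_N map must be calibrated first", call. = FALSE)
  }
  ipk <- which.max(ax$stim)
  t_peak <- ax$time[ipk]
  stim_peak <- ax$stim[ipk]
  force_at <- stats::approx(run$force$time, run$force$force,
                            xout = ax$time, rule = 2)$y
  rate <- instantaneous_rate(run$spikes)
  rate_at <- if (nrow(rate) > 0) {
    stats::approx(rate$time, rate$rate, xout = ax$time, rule = 2,
                  method = "constant")$y
  } else rep(0, nrow(ax))
  rate_at[ax$time < if (nrow(rate) > 0) rate$time[1] else Inf] <- 0
  if (length(run$spikes) > 0) {
    rate_at[ax$time > tail(run$spikes, 1)] <- 0
  }

  grid <- seq(0, max(0, stim_peak), by = grid_nA)
  resample <- function(sel) {
    tt <- ax$time[sel]; ss <- ax$stim[sel]
    o <- order(ss, tt)  # earlier time wins ties on the grid
    ss <- ss[o]; tt <- tt[o]
    keep <- !duplicated(ss)
    tibble::tibble(
      stim = grid,
      force = stats::approx(ss[keep], force_at[sel][o][keep], xout = grid,
                            rule = 2)$y,
      rate = stats::approx(ss[keep], rate_at[sel][o][keep], xout = grid,
                           rule = 2)$y
    )
  }
  asc <- resample(seq_len(nrow(ax)) <= ipk)
  des <- resample(seq_len(nrow(ax)) >= ipk)
  io <- dplyr::bind_rows(
    dplyr::mutate(asc, phase = "ascending"),
    dplyr::mutate(des, phase = "descending")
  )
  attr(io, "peak_force") <- max(force_at)
  attr(io, "mode") <- run$mode
  attr(io, "stim_peak") <- stim_peak
  attr(io, "recruitment") <- if (length(run$spikes) > 0)
    stats::approx(ax$time, ax$stim, xout = run$spikes[1], rule = 2)$y
  else NA_real_
  attr(io, "derecruitment") <- if (length(run$spikes) > 0)
    stats::approx(ax$time, ax$stim, xout = tail(run$spikes, 1), rule = 2)$y
  else NA_real_
  class(io) <- c("io_curve", class(io))
  io
}

#' Threshold currents of an input-output curve
#'
#' Recruitment/derecruitment are the stimulus values at the first/last
#' somatic spike; force initiation/cessation are the stimulus values at
#' which the ascending/descending force first/last exceeds
#' `force_onset_frac` of the run's peak force.
#'
#' @param io An [build_io_curve()] result.
#' @param force_onset_frac Relative force-onset threshold (default 0.01).
#' @return A one-row tibble: `recruitment`, `derecruitment`,
#'   `force_initiation`, `force_cessation` (nA; `NA` with zero spikes).
#' @export
thresholds <- function(io, force_onset_frac = 0.01) {
  pk <- attr(io, "peak_force")
  if (is.na(pk) || pk <= 0) {
    stop("peak force is zero; thresholds undefined", call. = FALSE)
  }
  thr <- force_onset_frac * pk
  asc <- io[io$phase == "ascending", ]
  des <- io[io$phase == "descending", ]
  init <- asc$stim[which(asc$force >= thr)]
  cess <- des$stim[which(des$force >= thr)]
  tibble::tibble(
    recruitment = attr(io, "recruitment"),
    derecruitment = attr(io, "derecruitment"),
    force_initiation = if (length(init) > 0) min(init) else NA_real_,
    force_cessation = if (length(cess) > 0) min(cess) else NA_real_
  )
}

#' Stimulus at the onset of PIC-driven firing acceleration
#'
#' Scans the ascending-phase frequency-stimulus relation for the first
#' stimulus at which the local slope exceeds `slope_factor` times the
#' initial (primary-range) slope and stays above it for at least
#' `sustain_nA` of stimulus; returns `NA` when no sustained acceleration
#' exists (e.g. a linear f-I curve).
#'
#' @param io An [build_io_curve()] result.
#' @param slope_factor Acceleration detection factor (default 2).
#' @param sustain_nA Minimal stimulus extent of the acceleration
#'   (default 0.5 nA).
#' @return Stimulus value (nA) or `NA`.
#' @export
pic_onset_current <- function(io, slope_factor = 2, sustain_nA = 0.5) {
  asc <- io[io$phase == "ascending" & io$rate > 0, ]
  if (nrow(asc) < 10) return(NA_real_)
  # windowed slope: rate change over a `sustain_nA` look-ahead, so that the
  # piecewise-constant instantaneous-rate signal is differentiated at the
  # scale the sustain criterion demands
  dstim <- stats::median(diff(asc$stim))
  w <- max(2L, ceiling(sustain_nA / dstim))
  n <- nrow(asc)
  if (n <= 2 * w) return(NA_real_)
  idx <- seq_len(n - w)
  slope <- (asc$rate[idx + w] - asc$rate[idx]) /
    (asc$stim[idx + w] - asc$stim[idx])
  # primary-range slope: median windowed slope over the first quarter of
  # the firing range (robust to the initial rate transient)
  n0 <- max(3L, floor(length(slope) / 4))
  s0 <- stats::median(slope[seq_len(n0)])
  thr <- slope_factor * max(s0, 1e-6)
  # sustained: both this window and the following (non-overlapping) window
  # must exceed the threshold, so an isolated bump narrower than the
  # sustain span is rejected
  cand <- seq_len(max(0, length(slope) - w))
  hit <- cand[slope[cand] > thr & slope[cand + w] > thr]
  hit <- hit[hit > n0]  # acceleration must follow an established primary range
  if (length(hit) == 0) return(NA_real_)
  asc$stim[hit[1]]
}

#' Characteristic input-output indices of a ramp run
#'
#' * `dct` — difference in current threshold for force production between
#'   the ascending and descending phases (force initiation minus force
#'   cessation); positive values mean counterclockwise hysteresis
#'   (self-sustained force).
#' * `dci` — stimulus interval from force initiation to 63% of the
#'   ascending-phase peak force; `1/dci` indexes the rate of force
#'   development.
#' * `dfg` — descending-minus-ascending force read at the PIC-onset
#'   stimulus; zero when there is no bistable transition (no sustained
#'   acceleration, or acceleration already present at recruitment).
#'
#' @param io An [build_io_curve()] result.
#' @param force_onset_frac Relative force-onset threshold (default 0.01).
#' @param recruit_coincide_nA PIC onset within this margin of recruitment
#'   counts as "onset at recruitment" (default 0.5 nA).
#' @return A one-row `index_report` tibble.
#' @export
compute_indices <- function(io, force_onset_frac = 0.01,
                            recruit_coincide_nA = 0.5) {
  th <- thresholds(io, force_onset_frac)
  asc <- io[io$phase == "ascending", ]
  des <- io[io$phase == "descending", ]
  pk_asc <- max(asc$force)
  dct <- th$force_initiation - th$force_cessation
  # 63% point on the ascending branch by linear interpolation
  i63 <- which(asc$force >= 0.63 * pk_asc)[1]
  stim63 <- if (is.na(i63)) NA_real_ else {
    if (i63 == 1) asc$stim[1] else {
      f0 <- asc$force[i63 - 1]; f1 <- asc$force[i63]
      asc$stim[i63 - 1] + (0.63 * pk_asc - f0) / (f1 - f0) *
        (asc$stim[i63] - asc$stim[i63 - 1])
    }
  }
  dci <- stim63 - th$force_initiation
  pic_on <- pic_onset_current(io)
  bistable <- !is.na(pic_on) &&
    (pic_on - th$recruitment) > recruit_coincide_nA
  dfg <- if (bistable) {
    f_asc <- stats::approx(asc$stim, asc$force, xout = pic_on, rule = 2)$y
    f_des <- stats::approx(des$stim, des$force, xout = pic_on, rule = 2)$y
    max(0, f_des - f_asc)
  } else 0
  out <- tibble::tibble(
    recruitment = th$recruitment, derecruitment = th$derecruitment,
    force_initiation = th$force_initiation,
    force_cessation = th$force_cessation,
    pic_onset = pic_on, dct = dct, dci = dci, dfg = dfg,
    bistable = bistable
  )
  class(out) <- c("index_report", class(out))
  out
}

#' Classify the firing pattern of a ramp response
#'
#' Type I: linear frequency-current relation without hysteresis.
#' Type IV: firing acceleration above recruitment with counterclockwise
#' hysteresis. Type III: acceleration already at recruitment with
#' (expanded) hysteresis. Everything else is `"other"`.
#'
#' @param io An [build_io_curve()] result.
#' @param report The matching [compute_indices()] row.
#' @param dct_zero_nA Hysteresis below this magnitude counts as zero
#'   (default 0.5 nA).
#' @return One of `"I"`, `"III"`, `"IV"`, `"other"`.
#' @export
classify_firing_type <- function(io, report, dct_zero_nA = 0.5) {
  accel <- !is.na(report$pic_onset)
  hyst <- !is.na(report$dct) && report$dct > dct_zero_nA
  at_recruit <- accel &&
    (report$pic_onset - report$recruitment) <= 0.5
  if (!accel && !hyst) return("I")
  if (accel && !at_recruit && hyst) return("IV")
  if (accel && at_recruit && hyst) return("III")
  "other"
}

#' Per-trial warm-up metrics
#'
#' Extracts per-trial (or per-cycle) peak responses from a warm-up run and
#' flags warm-up when the peak series increases strictly across all trials
#' by more than a 1% relative margin per step. In somatic mode the peaks
#' are firing rate and muscle force; in the dendritic (QX-314) mode they
#' are the somatic and dendritic-site peak membrane potentials.
#'
#' @param run A `mu_run` from [run_warmup()].
#' @param margin Relative increase required per trial (default 0.01).
#' @return A `warmup_report`: per-trial tibble with attribute `warmup`
#'   (logical flag) and `mode`.
#' @export
warmup_metrics <- function(run, margin = 0.01) {
  trials <- run$trials
  if (is.null(trials) || nrow(trials) < 3) {
    stop("warm-up metrics need at least 3 trials or cycles", call. = FALSE)
  }
  qx <- isTRUE(run$qx314)
  rows <- purrr::pmap_dfr(trials, function(trial, start, end) {
    tr <- run$traces[run$traces$time >= start & run$traces$time < end, ]
    fo <- run$force[run$force$time >= start & run$force$time < end + 100, ]
    # rate from within-trial spikes only, so inter-trial gaps never form ISIs
    rr <- instantaneous_rate(run$spikes[run$spikes >= start &
                                          run$spikes < end])
    tibble::tibble(
      trial = trial,
      peak_rate = if (nrow(rr) > 0) max(rr$rate) else 0,
      peak_force = if (nrow(fo) > 0) max(fo$force) else 0,
      peak_v_soma = max(tr$v_soma),
      peak_v_band = max(tr$v_band)
    )
  })
  increasing <- function(x) {
    if (any(!is.finite(x)) || any(x <= 0)) return(FALSE)
    all(diff(x) / utils::head(x, -1) > margin)
  }
  flag <- if (qx) {
    # potentials are negative-referenced; compare depolarization above the
    # first-cycle baseline
    vs <- rows$peak_v_soma - min(run$traces$v_soma)
    vb <- rows$peak_v_band - min(run$traces$v_band)
    increasing(vs) && increasing(vb)
  } else {
    increasing(rows$peak_rate) && increasing(rows$peak_force)
  }
  attr(rows, "warmup") <- flag
  attr(rows, "mode") <- run$mode
  class(rows) <- c("warmup_report", class(rows))
  rows
}
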