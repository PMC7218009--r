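test_that("sarcoplasmic calcium release saturates and decays exponentially", {
  p <- muscle_params()
  expect_equal(calcium_from_spikes(0, 0, dt = 1, p), 0)
  # single spike: jump by R (from 0) then first-order decay
  ca1 <- calcium_from_spikes(0, 1, dt = 1e-9, p)
  expect_equal(ca1, p$ca_release, tolerance = 1e-6)
  ca2 <- calcium_from_spikes(0, 1, dt = p$tau_ca_ms, p)
  expect_equal(ca2, p$ca_release * exp(-1), tolerance = 1e-6)
  # 100 Hz train plateaus below the saturation constant
  tr <- simulate_muscle(seq(10, 3000, by = 10), -8, 3200, params = p)
  expect_lt(max(tr$ca), p$ca_sat)
  expect_gt(max(tr$ca), p$ca_release)  # summation above a single release
})

test_that("activation is the Hill function of troponin occupancy", {
  p <- muscle_params()
  out0 <- activation_from_calcium(0, ca = 0, x_m = -8, dt = 1, p)
  expect_equal(out0$a, 0)
  # occupancy at the half-activation point gives A = 0.5
  ka <- k_a_of_length(-8, p)
  a_half <- ka^p$n_hill / (ka^p$n_hill + ka^p$n_hill)
  expect_equal(a_half, 0.5)
  # shorter muscle is harder to activate for the same calcium history
  tr16 <- simulate_muscle(seq(10, 2000, by = 100), -16, 2500, params = p)
  tr8 <- simulate_muscle(seq(10, 2000, by = 100), -8, 2500, params = p)
  expect_equal(tr16$cat_frac, tr8$cat_frac, tolerance = 1e-12)
  expect_lt(max(tr16$a), max(tr8$a))
  expect_true(all(k_a_of_length(seq(-16, 0, 2), p) ==
                    sort(k_a_of_length(seq(-16, 0, 2), p), decreasing = TRUE)))
})

test_that("force output scales with the force-length factor", {
  p <- muscle_params()
  expect_equal(force_length(-8, p), 1)
  expect_equal(force_length(-16, p), p$fl_short)
  expect_equal(force_length(0, p), p$fl_long)
  expect_error(force_length(-20, p), "X_m")
  # first-order rise toward A * FL
  f <- 0
  for (i in 1:4000) f <- force_from_activation(f, a = 1, x_m = -8, dt = 1, p)
  expect_equal(f, 1, tolerance = 1e-3)
  # identical activation at two lengths: forces in FL ratio
  spikes <- seq(10, 2000, by = 50)
  f0 <- simulate_muscle(spikes, 0, 2500, params = p)
  f8 <- simulate_muscle(spikes, -8, 2500, params = p)
  # same CaT would be needed for a strict ratio; compare with matched A by
  # rescaling through the length-specific activation
  expect_lt(max(f0$force), max(f8$force))
})

test_that("simulate_muscle honours its contracts", {
  p <- muscle_params()
  expect_error(simulate_muscle(10, -20, 100, params = p), "X_m")
  expect_error(simulate_muscle(c(10, 5), -8, 100, params = p),
               "strictly increasing")
  z <- simulate_muscle(numeric(0), -8, 500, params = p)
  expect_true(all(z$force == 0))
  # 100 Hz fused tetanus at optimum: ripple < 5% of the mean
  tet <- simulate_muscle(seq(10, 2500, by = 10), -8, 3000, params = p)
  sec <- tet$force[tet$time > 1500 & tet$time < 2400]
  expect_lt((max(sec) - min(sec)) / mean(sec), 0.05)
  # subtetanic mean force below tetanic
  sub <- simulate_muscle(seq(10, 2500, by = 100), -8, 3000, params = p)
  expect_lt(mean(sub$force[sub$time > 1500]), mean(sec))
})

test_that("force-frequency relation is monotone at every length", {
  p <- muscle_params()
  for (xm in c(-16, -8, 0)) {
    forces <- vapply(c(1, 5, 10, 20, 50, 100), function(hz) {
      tr <- simulate_muscle(seq(10, 3000, by = 1000 / hz), xm, 3500,
                            params = p)
      motorunit:::plateau_force(tr, 1500)
    }, numeric(1))
    expect_true(all(diff(forces) > -1e-9), label = paste("X_m", xm))
  }
})

test_that("tetanic force peaks at the optimal length", {
  p <- muscle_params()
  tet <- function(xm) {
    tr <- simulate_muscle(seq(10, 2500, by = 10), xm, 3000, params = p)
    motorunit:::plateau_force(tr, 1500)
  }
  expect_gt(tet(-8), tet(-16))
  expect_gt(tet(-8), tet(0))
})

test_that("short-length degradation is stronger at low rates", {
  p <- muscle_params()
  rel <- function(hz) {
    f <- function(xm) {
      tr <- simulate_muscle(seq(10, 3000, by = 1000 / hz), xm, 3500,
                            params = p)
      motorunit:::plateau_force(tr, 1500)
    }
    f(-16) / f(-8)
  }
  expect_lt(rel(10), rel(100))
})

test_that("twitch metrics use relative thresholds", {
  p <- muscle_params()
  tw <- simulate_muscle(10, -8, 2000, params = p)
  m <- twitch_metrics(tw)
  expect_true(m$twitch)
  expect_gt(m$duration, 150)
  expect_lt(m$duration, 400)
  # scale invariance of the duration
  tw2 <- dplyr::mutate(tw, force = force * 2)
  expect_equal(twitch_metrics(tw2)$duration, m$duration)
  # all-zero trace: explicit no-twitch result
  z <- twitch_metrics(tibble::tibble(time = 0:10, force = numeric(11)))
  expect_false(z$twitch)
  expect_error(twitch_metrics(tw, n_spikes = 3), "single-spike")
})
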