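calib <- hpts_calibration(r_min = 0.2, r_max = 2.0, pka = 7.2)
sys <- vesicle_system()

test_that("ratio/pH conversion is a strict monotone bijection", {
  # midpoint ratio reads back the probe pKa
  expect_equal(ratio_to_ph((0.2 + 2.0) / 2, calib), 7.2)
  # round trip to 1e-12 across the dynamic range
  ph <- seq(6.0, 8.4, by = 0.05)
  expect_equal(ratio_to_ph(ph_to_ratio(ph, calib), calib), ph,
    tolerance = 1e-12
  )
  # monotone in R
  r <- seq(0.21, 1.99, length.out = 50)
  expect_true(all(diff(ratio_to_ph(r, calib)) > 0))
  expect_error(ratio_to_ph(2.5, calib), "calibration range")
})

test_that("proton influx matches a charge-balance titration oracle", {
  expect_equal(proton_influx(rep(7.0, 5), sys), rep(0, 5))

  # add strong acid to the buffered interior, predict final pH with the
  # independent electroneutrality solver, and require the influx map to
  # return the acid added
  for (c_x in c(1e-5, 1e-4, 5e-4)) {
    ph_end <- oracle_ph_after_strong_acid(0.010, 7.48, 7.0, c_x)
    expect_equal(proton_influx(ph_end, sys), c_x, tolerance = 1e-6)
  }

  # vanishing buffer reduces to the free-ion difference
  tiny <- vesicle_system(buffer_conc = 1e-12, buffer_pka = 7.0, ph0 = 6.9)
  dh <- proton_influx(6.8, tiny, ph_ref = 6.9)
  free_only <- (10^-6.8 - 10^-6.9) - (10^(6.8 - 14) - 10^(6.9 - 14))
  expect_equal(dh, free_only, tolerance = 1e-6)

  # the influx chain is invariant to re-zeroing time
  t <- seq(0, 60, by = 0.5)
  y <- 1e-6 * t
  expect_equal(
    initial_rate(t + 100, y, window = 30, t0 = 100)$rate,
    initial_rate(t, y, window = 30, t0 = 0)$rate,
    tolerance = 1e-10
  )
})

test_that("initial rates are exact for lines and limits of exponentials", {
  t <- seq(0, 60, by = 0.5)
  expect_equal(initial_rate(t, 3e-6 * t, window = 30)$rate, 3e-6,
    tolerance = 1e-12
  )

  # single-exponential A(1 - exp(-kt)): slope -> A*k as window -> 0
  a <- 2e-4
  k <- 0.05
  t2 <- seq(0, 1, by = 0.02)
  r <- initial_rate(t2, a * (1 - exp(-k * t2)), window = 1 / (100 * k))
  expect_equal(r$rate, a * k, tolerance = 0.01)

  # zero-mean noise leaves the slope unbiased within 3 SE
  ok <- vapply(1:50, function(s) {
    set.seed(s)
    y <- 2e-6 * t + stats::rnorm(length(t), sd = 5e-6)
    fit <- initial_rate(t, y, window = 60)
    abs(fit$rate - 2e-6) <= 3 * fit$se
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  expect_error(
    initial_rate(t, 3e-6 * t, window = 30, t0 = -5),
    "before the first sample"
  )
  expect_error(initial_rate(t, 3e-6 * t, window = 1), "5 samples")
})

test_that("per-carrier normalisation follows the stated scaling laws", {
  expect_equal(per_carrier_rate(0, sys, 0.01)$per_carrier, 0)

  base <- per_carrier_rate(1e-5, sys, 0.01)$per_carrier
  # linear in rate
  expect_equal(per_carrier_rate(2e-5, sys, 0.01)$per_carrier, 2 * base,
    tolerance = 1e-12
  )
  # inverse in carrier mole fraction
  expect_equal(per_carrier_rate(1e-5, sys, 0.02)$per_carrier, base / 2,
    tolerance = 1e-12
  )
  # bulk-concentration shortcut agrees with per-vesicle counting
  bulk <- per_carrier_rate(1e-5, sys, 0.01,
    lipid_conc = 1e-4, mode = "bulk"
  )$per_carrier
  expect_equal(bulk, base, tolerance = 1e-10)

  expect_error(
    vesicle_system(diameter = 7e-9, bilayer_thickness = 3.7e-9),
    "inner radius"
  )
})

test_that("the full trace chain recovers a known per-carrier rate", {
  # noiseless round trip, small window relative to the saturation time
  tr <- simulate_transport_trace(
    2.1, sys, calib,
    time = seq(0, 1, by = 4e-4), noise = 0
  )
  res <- transport_rate_from_trace(
    tr$time, tr$ratio, calib, sys, 0.01,
    window = 0.004
  )
  expect_equal(res$per_carrier, 2.1, tolerance = 0.01)

  # with ratio noise the estimate stays within 3 SE of truth
  tr_n <- simulate_transport_trace(
    2.1, sys, calib,
    time = seq(0, 1, by = 4e-4), noise = 0.002, seed = 4
  )
  res_n <- transport_rate_from_trace(
    tr_n$time, tr_n$ratio, calib, sys, 0.01,
    window = 0.02
  )
  pc_se <- per_carrier_rate(res_n$rate_se, sys, 0.01)$per_carrier
  expect_lt(abs(res_n$per_carrier - 2.1), 3 * pc_se + 0.1 * 2.1)

  # zero transport gives a flat trace at the initial ratio
  flat <- simulate_transport_trace(0, sys, calib, time = 0:30, noise = 0)
  expect_equal(stats::sd(flat$ratio), 0)
  expect_equal(flat$ratio[1], ph_to_ratio(7.0, calib))
})
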