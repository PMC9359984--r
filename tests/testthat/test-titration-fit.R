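test_that("predicted observables honour baseline, saturation and midpoint", {
  p <- list(ka = 1e4, baseline = 2, endpoint = 5)
  expect_equal(predict_observable(0, 1e-6, p), 2)

  # saturation: enormous affinity with guest far over host
  p_sat <- list(ka = 1e12, baseline = 2, endpoint = 5)
  expect_equal(predict_observable(1e-2, 1e-6, p_sat), 5, tolerance = 1e-6)

  # half-saturation at free guest = 1/ka when host is negligible
  p_mid <- list(ka = 1e3, baseline = 1, endpoint = 3)
  obs <- predict_observable(1e-3, 1e-12, p_mid)
  expect_equal(obs, 2, tolerance = 1e-6)

  # 1:1 predictions are monotone in guest_total
  g <- c(0, 10^seq(-6, -2, length.out = 20))
  obs <- predict_observable(g, 1e-6, p)
  expect_true(all(diff(obs) > 0))

  expect_error(
    predict_observable(1e-3, 1e-6, list(ka = 1), model = "1:1"),
    "baseline"
  )
})

test_that("slow-exchange integrals give the hand-checked constant", {
  # equal integrals at equimolar host/guest: bound = free = G/2
  ka <- ka_from_slow_exchange(1, 1, 3e-4, 3e-4)
  expect_equal(ka, (1.5e-4) / (1.5e-4 * 1.5e-4), tolerance = 1e-12)

  expect_equal(ka_from_slow_exchange(1, 0, 3e-4, 3e-4), 0)
  expect_error(ka_from_slow_exchange(0.01, 1, 3e-4, 2e-4), "over-consumed")

  # round trip through the generator, noiseless
  truth <- list(ka = 5e3, host_total = 3e-4, noise = 0)
  df <- simulate_titration("nmr_integrals", truth, seed = 1)
  ka_back <- vapply(seq_len(nrow(df)), function(i) {
    ka_from_slow_exchange(
      df$integral_free[i], df$integral_bound[i], 3e-4, df$guest_total[i]
    )
  }, numeric(1))
  expect_equal(ka_back, rep(5e3, nrow(df)), tolerance = 1e-6)
})

test_that("noiseless 1:1 titrations are recovered to 0.1%", {
  for (ka in c(10, 1e2, 1e4, 1e6)) {
    tr <- simulate_titration("fluorescence", make_flu_truth(ka), seed = 1)
    fit <- fit_titration(tr)
    expect_equal(fit$estimates$ka, ka, tolerance = 1e-3)
    expect_equal(fit$estimates$baseline, 1, tolerance = 1e-4)
    expect_equal(fit$estimates$endpoint, 3, tolerance = 1e-3)
  }
  # fast-exchange NMR observable, host depletion regime
  truth <- list(
    ka = 2000, baseline = 8, endpoint = 8.6, host_total = 3e-4,
    guest_grid = c(0, 10^seq(-4.5, -1.7, length.out = 14)), noise = 0
  )
  tr <- simulate_titration("nmr_shift", truth, seed = 1)
  expect_equal(fit_titration(tr)$estimates$ka, 2000, tolerance = 1e-3)
})

test_that("1% noise leaves the median log10-Ka error below 0.05", {
  errs <- vapply(1:50, function(s) {
    tr <- simulate_titration(
      "fluorescence", make_flu_truth(5e4, noise = 0.01),
      seed = s
    )
    abs(log10(fit_titration(tr)$estimates$ka / 5e4))
  }, numeric(1))
  expect_lte(median(errs), 0.05)
})

test_that("a flat titration is flagged unidentifiable", {
  truth <- make_flu_truth(1e4, f0 = 2, f1 = 2, noise = 0.0)
  tr <- simulate_titration("fluorescence", truth, seed = 5)
  tr$data$observable <- tr$data$observable +
    stats::rnorm(nrow(tr$data), sd = 1e-3)
  fit <- fit_titration(tr)
  expect_true("unidentifiable" %in% fit$flags)
})

test_that("fits are invariant to affine rescaling of the observable", {
  tr <- simulate_titration(
    "fluorescence", make_flu_truth(3e3, noise = 0.01),
    seed = 9
  )
  f1 <- fit_titration(tr)
  tr2 <- tr
  tr2$data$observable <- 40 * tr$data$observable - 7
  f2 <- fit_titration(tr2)
  expect_equal(f1$estimates$ka, f2$estimates$ka, tolerance = 1e-9)
})

test_that("1:2 model fits recover both stepwise constants noiselessly", {
  truth <- list(
    k1 = 1e4, k2 = 500, baseline = 1, endpoint_hg = 2.2,
    endpoint_hg2 = 3.4, host_total = 1e-4,
    guest_grid = c(0, 10^seq(-5.5, -1.5, length.out = 17)), noise = 0
  )
  tr <- simulate_titration("fluorescence", truth, seed = 1)
  fit <- fit_titration(tr, model = "1:2")
  expect_equal(fit$estimates$ka, 1e4, tolerance = 1e-2)
  expect_equal(fit$estimates$k2, 500, tolerance = 1e-2)
})

test_that("competition fits recover the competitor constant", {
  truth <- list(
    ka_s = 5.4e4, ka_x = 32, x_total = 0.2, baseline = 1, endpoint = 3,
    host_total = 5e-8,
    guest_grid = c(0, 10^seq(-5.5, -2.3, length.out = 14)), noise = 0.01
  )
  tr <- simulate_titration("competition", truth, seed = 21)
  res <- fit_competition_ka(tr, ka_s = 5.4e4)
  expect_lt(abs(res$estimates$ka_x - 32), 3 * res$se$ka_x)

  # no competitor: apparent equals intrinsic, flagged zero
  truth0 <- truth
  truth0$ka_x <- 0
  truth0$x_total <- 0
  tr0 <- simulate_titration("competition", truth0, seed = 3)
  res0 <- fit_competition_ka(tr0, ka_s = 5.4e4)
  expect_equal(res0$estimates$ka_x, 0)
  expect_true("no_detectable_competition" %in% res0$flags)
})

test_that("doubling the competitor changes ka_x only through noise", {
  kx_at <- function(x_total, seed) {
    truth <- list(
      ka_s = 5.4e4, ka_x = 32, x_total = x_total, baseline = 1,
      endpoint = 3, host_total = 5e-8,
      guest_grid = c(0, 10^seq(-5.5, -2.0, length.out = 14)), noise = 0.01
    )
    tr <- simulate_titration("competition", truth, seed = seed)
    fit_competition_ka(tr, ka_s = 5.4e4)$estimates$ka_x
  }
  a <- median(vapply(1:10, function(s) kx_at(0.1, s), numeric(1)))
  b <- median(vapply(1:10, function(s) kx_at(0.2, s), numeric(1)))
  expect_equal(a, b, tolerance = 0.15)
})

test_that("the BaSO4 competition method recovers very strong binding", {
  ksp <- 1.08e-10
  truth <- list(
    ka = 7.4e9, host_total = 3e-4, sulfate_total = 4e-4, ksp = ksp,
    counterion_grid = 4e-4 + 10^seq(-3.5, 0, length.out = 12), noise = 0
  )
  df <- simulate_titration("baso4", truth, seed = 1)
  fit <- fit_baso4_competition(
    df$counterion_total, df$bound_fraction, 3e-4, 4e-4, ksp
  )
  expect_equal(fit$estimates$ka, 7.4e9, tolerance = 0.01)

  # half-saturation identity: theta = 0.5 implies ka = 1/s_free there
  i <- which.min(abs(fit$fitted - 0.5))
  sp <- anionbind:::free_sulfate_coupled(
    4e-4, truth$counterion_grid[i], 3e-4, fit$estimates$ka, ksp
  )
  expect_equal(
    fit$estimates$ka * sp$s_free / (1 + fit$estimates$ka * sp$s_free),
    fit$fitted[i],
    tolerance = 1e-9
  )

  # saturated plateau: only a lower bound is claimed
  fit_sat <- fit_baso4_competition(
    c(5e-4, 6e-4, 7e-4), c(1, 1, 1), 3e-4, 4e-4, ksp
  )
  expect_true("lower_bound" %in% fit_sat$flags)

  # all points undersaturated: method inapplicable
  expect_error(
    fit_baso4_competition(
      c(1e-9, 2e-9, 3e-9), c(0.9, 0.9, 0.9), 3e-4, 4e-4, ksp
    ),
    "precipitation never engaged"
  )
})

test_that("replicate aggregation gives mean and sample SD", {
  mk <- function(ka) {
    structure(
      list(
        estimates = list(ka = ka, baseline = 1),
        se = list(ka = 1, baseline = 0.1), model = "1:1"
      ),
      class = "binding_fit"
    )
  }
  agg <- aggregate_replicates(list(mk(19), mk(21)))
  expect_equal(agg$estimates$ka, 20)
  expect_equal(agg$se$ka, stats::sd(c(19, 21)))

  same <- aggregate_replicates(list(mk(5), mk(5), mk(5)))
  expect_equal(same$se$ka, 0)

  single <- aggregate_replicates(list(mk(7)))
  expect_true("sd_unavailable" %in% single$flags)
  expect_true(is.na(single$se$ka))

  bad <- mk(3)
  bad$model <- "1:2"
  expect_error(aggregate_replicates(list(mk(1), bad)), "mix different models")
})

test_that("generate-then-fit recovers truth within 3 SE in >= 95% of runs", {
  hits <- vapply(1:100, function(s) {
    tr <- simulate_titration(
      "fluorescence", make_flu_truth(2e3, noise = 0.01),
      seed = s
    )
    fit <- fit_titration(tr)
    abs(fit$estimates$ka - 2e3) <= 3 * fit$se$ka
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
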