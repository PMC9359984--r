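test_that("1:1 solver handles degenerate and oracle-checked cases", {
  # zero affinity: nothing binds
  st <- solve_1to1(1e-4, 1e-4, 0)
  expect_equal(st$complexes$HG, 0)
  expect_equal(st$free_host, 1e-4)

  # bisection oracle on the free-guest mass balance
  g_free <- oracle_1to1_free_guest(1e-4, 1e-4, 1e4)
  st <- solve_1to1(1e-4, 1e-4, 1e4)
  expect_equal(st$free_guests$G, g_free, tolerance = 1e-10)
  expect_equal(st$complexes$HG, 1e-4 - g_free, tolerance = 1e-8)
  expect_gt(st$complexes$HG, 3.7e-5)
  expect_lt(st$complexes$HG, 3.9e-5)

  # excess-guest limit: host far below guest, bound fraction -> Langmuir
  st <- solve_1to1(5e-8, 0.2, 370)
  theta <- st$complexes$HG / 5e-8
  expect_equal(theta, 370 * 0.2 / (1 + 370 * 0.2), tolerance = 1e-6)
  expect_equal(st$free_guests$G, 0.2, tolerance = 1e-6)

  expect_error(solve_1to1(-1e-4, 1e-4, 10), "host_total")
})

test_that("1:2 solver reduces to 1:1 at k2 = 0 and matches a root scan", {
  a <- solve_1to2(1e-3, 1e-2, 100, 0)
  b <- solve_1to1(1e-3, 1e-2, 100)
  expect_equal(a$complexes$HG, b$complexes$HG, tolerance = 1e-12)
  expect_equal(a$complexes$HG2, 0)

  g_free <- oracle_1to2_free_guest(1e-3, 1e-2, 100, 10)
  st <- solve_1to2(1e-3, 1e-2, 100, 10)
  expect_equal(st$free_guests$G, g_free, tolerance = 1e-8)

  st0 <- solve_1to2(1e-3, 0, 100, 10)
  expect_equal(st0$free_host, 1e-3)
  expect_equal(st0$complexes$HG, 0)
  expect_equal(st0$complexes$HG2, 0)
})

test_that("competition solver: absent competitor, symmetry, grid oracle", {
  a <- solve_competition(1e-4, 1e-3, 5e-3, 2e4, 0)
  b <- solve_1to1(1e-4, 1e-3, 2e4)
  expect_equal(a$complexes$HS, b$complexes$HG, tolerance = 1e-12)
  expect_equal(a$complexes$HX, 0)

  # swapping the two guests swaps the complex labels exactly
  fwd <- solve_competition(1e-5, 2e-4, 8e-4, 5e3, 700)
  rev <- solve_competition(1e-5, 8e-4, 2e-4, 700, 5e3)
  expect_equal(fwd$complexes$HS, rev$complexes$HX, tolerance = 1e-10)
  expect_equal(fwd$complexes$HX, rev$complexes$HS, tolerance = 1e-10)

  # 2-D grid-refinement oracle in the micelle competition regime
  orc <- oracle_competition(5e-8, 1e-3, 0.2, 54000, 32)
  st <- solve_competition(5e-8, 1e-3, 0.2, 54000, 32)
  expect_equal(st$free_guests$S, orc$s, tolerance = 1e-6)
  expect_equal(st$free_guests$X, orc$x, tolerance = 1e-6)
})

test_that("apparent-constant algebra round-trips and guards its domain", {
  expect_equal(apparent_ka_under_competition(5e4, 0, 0.1), 5e4)
  # algebraic round trip
  for (kx in c(0.5, 32, 4500)) {
    app <- apparent_ka_under_competition(5.4e4, kx, 0.066)
    expect_equal(invert_competition(5.4e4, app, 0.066), kx,
      tolerance = 1e-12
    )
  }
  expect_error(invert_competition(100, 200, 0.1), "apparent affinity")

  # with host far below both guests, a 1:1 fit of competition-model curves
  # returns the analytic apparent constant
  ka_s <- 5e3
  ka_x <- 40
  x0 <- 0.05
  ka_app <- apparent_ka_under_competition(ka_s, ka_x, x0)
  grid <- c(0, 10^seq(-4.5, -1.5, length.out = 14))
  theta <- vapply(grid, function(g) {
    st <- solve_competition(1e-9, g, x0, ka_s, ka_x)
    st$complexes$HS / 1e-9
  }, numeric(1))
  ser <- titration_series(grid, 1 + 2 * theta, "fluorescence_intensity",
    host_total = 1e-9
  )
  fit <- fit_titration(ser)
  expect_equal(fit$estimates$ka, ka_app, tolerance = 0.01)
})

test_that("precipitation equilibrium buffers free sulfate at ksp", {
  ksp <- 1.08e-10
  # undersaturated: nothing precipitates
  st <- free_sulfate_with_precipitation(1e-6, 1e-6, ksp)
  expect_equal(st$precipitate, 0)
  expect_equal(st$free_guests$SO4, 1e-6)

  # saturated: ion product pinned at ksp exactly
  st <- free_sulfate_with_precipitation(1e-3, 5e-3, ksp)
  expect_gt(st$precipitate, 0)
  expect_equal(st$free_guests$SO4 * st$free_guests$Ba, ksp,
    tolerance = 1e-10
  )

  # large counterion excess E: free sulfate -> ksp / E
  e_xs <- 0.5
  st <- free_sulfate_with_precipitation(1e-3, 1e-3 + e_xs, ksp)
  expect_equal(st$free_guests$SO4, ksp / e_xs, tolerance = 1e-3)
})

test_that("mass balances close to 1e-10 on randomized instances", {
  set.seed(42)
  for (i in 1:100) {
    h0 <- 10^stats::runif(1, -8, -2)
    g0 <- 10^stats::runif(1, -7, -1)
    ka <- 10^stats::runif(1, 0, 8)
    st <- solve_1to1(h0, g0, ka)
    expect_lt(abs(st$free_host + st$complexes$HG - h0) / h0, 1e-10)
    expect_lt(abs(st$free_guests$G + st$complexes$HG - g0) / g0, 1e-10)

    k2 <- 10^stats::runif(1, -2, 5)
    st2 <- solve_1to2(h0, g0, ka, k2)
    expect_lt(
      abs(st2$free_host + st2$complexes$HG + st2$complexes$HG2 - h0) / h0,
      1e-10
    )
    expect_lt(
      abs(st2$free_guests$G + st2$complexes$HG + 2 * st2$complexes$HG2 -
        g0) / g0,
      1e-10
    )

    x0 <- 10^stats::runif(1, -6, -1)
    kx <- 10^stats::runif(1, 0, 6)
    stc <- solve_competition(h0, g0, x0, ka, kx)
    expect_lt(
      abs(stc$free_host + stc$complexes$HS + stc$complexes$HX - h0) / h0,
      1e-10
    )
    expect_lt(abs(stc$free_guests$S + stc$complexes$HS - g0) / g0, 1e-10)
    expect_lt(abs(stc$free_guests$X + stc$complexes$HX - x0) / x0, 1e-10)
  }
})

test_that("bound fraction is monotone in guest total and in ka", {
  set.seed(7)
  for (i in 1:20) {
    h0 <- 10^stats::runif(1, -7, -3)
    ka <- 10^stats::runif(1, 1, 6)
    g <- sort(10^stats::runif(6, -6, -1))
    th <- vapply(g, function(gt) {
      solve_1to1(h0, gt, ka)$complexes$HG / h0
    }, numeric(1))
    expect_true(all(diff(th) >= -1e-12))

    kas <- sort(10^stats::runif(6, 0, 7))
    th2 <- vapply(kas, function(k) {
      solve_1to1(h0, g[3], k)$complexes$HG / h0
    }, numeric(1))
    expect_true(all(diff(th2) >= -1e-12))
  }
})

test_that("solvers agree with brute-force bisection on random instances", {
  set.seed(11)
  for (i in 1:100) {
    h0 <- 10^stats::runif(1, -7, -3)
    g0 <- 10^stats::runif(1, -6, -2)
    ka <- 10^stats::runif(1, 0, 7)
    g_free <- oracle_1to1_free_guest(h0, g0, ka)
    st <- solve_1to1(h0, g0, ka)
    expect_lt(abs(st$free_guests$G - g_free) / g0, 1e-8)
  }
})
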