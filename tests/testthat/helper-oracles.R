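# Independent brute-force oracles used to cross-check the closed-form /
# Newton speciation solvers. These deliberately share no code with the
# package internals: plain bisection and grid refinement on the raw
# mass-balance residuals.

# 1:1 binding - bisection on the free-guest mass balance over [0, G0].
oracle_1to1_free_guest <- function(h0, g0, ka, iters = 200) {
  if (ka == 0 || g0 == 0 || h0 == 0) {
    return(g0)
  }
  resid <- function(g) g + h0 * ka * g / (1 + ka * g) - g0
  lo <- 0
  hi <- g0
  for (i in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    if (resid(mid) < 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

# 1:2 binding - dense grid scan to bracket, then bisection on the cubic
# guest balance.
oracle_1to2_free_guest <- function(h0, g0, k1, k2, iters = 200) {
  resid <- function(g) {
    den <- 1 + k1 * g + k1 * k2 * g^2
    g + h0 * (k1 * g + 2 * k1 * k2 * g^2) / den - g0
  }
  grid <- seq(0, g0, length.out = 1000)
  r <- vapply(grid, resid, numeric(1))
  i <- which(r[-1] >= 0 & r[-length(r)] <= 0)[1]
  lo <- grid[i]
  hi <- grid[i + 1]
  for (j in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    if (resid(mid) < 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

# competition - 2-D grid refinement on both mass-balance residuals.
oracle_competition <- function(h0, s0, x0, kas, kax, rounds = 40) {
  s_lo <- 0
  s_hi <- s0
  x_lo <- 0
  x_hi <- x0
  cost <- function(s, x) {
    h <- h0 / (1 + kas * s + kax * x)
    rs <- s + h * kas * s - s0
    rx <- x + h * kax * x - x0
    rs^2 / max(s0, 1e-300)^2 + rx^2 / max(x0, 1e-300)^2
  }
  for (r in seq_len(rounds)) {
    sg <- seq(s_lo, s_hi, length.out = 21)
    xg <- seq(x_lo, x_hi, length.out = 21)
    cc <- outer(sg, xg, Vectorize(cost))
    idx <- arrayInd(which.min(cc), dim(cc))
    i <- idx[1]
    j <- idx[2]
    s_lo <- sg[max(i - 1, 1)]
    s_hi <- sg[min(i + 1, 21)]
    x_lo <- xg[max(j - 1, 1)]
    x_hi <- xg[min(j + 1, 21)]
  }
  list(s = 0.5 * (s_lo + s_hi), x = 0.5 * (x_lo + x_hi))
}

# Charge-balance titration oracle: final pH of a buffer (conjugate-base
# salt NaA, concentration b_tot at initial ph0) after adding c_x mol/L of
# a strong monoprotic acid. Solves full electroneutrality with explicit
# Na+, A-, H+, OH- and X- species.
oracle_ph_after_strong_acid <- function(b_tot, pka, ph0, c_x) {
  ka <- 10^(-pka)
  kw <- 1e-14
  frac_a <- function(h) ka / (ka + h) # A- fraction of total buffer
  h0 <- 10^(-ph0)
  na <- b_tot * frac_a(h0) + kw / h0 - h0 # electroneutrality at t = 0
  bal <- function(ph) {
    h <- 10^(-ph)
    na + h - b_tot * frac_a(h) - kw / h - c_x
  }
  stats::uniroot(bal, c(ph0 - 3, ph0 + 1e-9), tol = 1e-14)$root
}

# convenience: noiseless 1:1 fluorescence truth for recovery tests
make_flu_truth <- function(ka, host = 5e-8, f0 = 1, f1 = 3, n = 15,
                           gmax = NULL, noise = 0) {
  if (is.null(gmax)) gmax <- 60 / ka
  list(
    ka = ka, baseline = f0, endpoint = f1, host_total = host,
    guest_grid = c(0, 10^seq(log10(gmax) - 2.5, log10(gmax),
      length.out = n - 1
    )),
    noise = noise
  )
}
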