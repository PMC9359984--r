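#' Equilibrium speciation solvers for host-guest binding
#'
#' These solvers compute exact free and bound concentrations for the binding
#' models used throughout the package: 1:1 and 1:2 host-guest association,
#' two-guest competitive 1:1 binding at a single cavity, and sulfate
#' speciation buffered by precipitation of a sparingly soluble salt
#' (e.g. BaSO4). All concentrations are molar; association constants are
#' stepwise and in M^-1. Activities are taken equal to concentrations
#' (constant ionic-strength conditions).
#'
#' Every solver closes the host and guest mass balances to a relative error
#' of 1e-10 or better; this is asserted internally.
#'
#' @name speciation
NULL

new_speciation_state <- function(free_host, free_guests, complexes,
                                 precipitate = 0) {
  structure(
    list(
      free_host = free_host,
      free_guests = free_guests,
      complexes = complexes,
      precipitate = precipitate
    ),
    class = "speciation_state"
  )
}

#' @export
print.speciation_state <- function(x, ...) {
  cat("Equilibrium speciation state (mol L^-1)\n")
  cat(sprintf("  free host: %.6g\n", x$free_host))
  for (g in names(x$free_guests)) {
    cat(sprintf("  free %s: %.6g\n", g, x$free_guests[[g]]))
  }
  for (cpx in names(x$complexes)) {
    cat(sprintf("  [%s]: %.6g\n", cpx, x$complexes[[cpx]]))
  }
  if (x$precipitate > 0) {
    cat(sprintf("  precipitate: %.6g mol/L\n", x$precipitate))
  }
  invisible(x)
}

check_mass_balance <- function(reconstructed, total, what) {
  if (total > 0 && rel_err(reconstructed, total) > 1e-10) {
    stop(sprintf(
      "internal error: %s mass balance violated (rel err %.3g)",
      what, rel_err(reconstructed, total)
    ), call. = FALSE)
  }
}

#' Solve 1:1 host-guest speciation
#'
#' Closed-form solution of the quadratic mass balance for a single 1:1
#' complex HG with association constant `ka = [HG]/([H][G])`.
#'
#' @param host_total Total host concentration (M).
#' @param guest_total Total guest concentration (M).
#' @param ka Association constant (M^-1).
#' @return A `speciation_state` with components `free_host`, `free_guests`
#'   (named list with `"G"`), and `complexes` (named list with `"HG"`).
#' @examples
#' st <- solve_1to1(1e-4, 1e-4, 1e4)
#' st$complexes$HG
#' @export
solve_1to1 <- function(host_total, guest_total, ka) {
  check_nonneg(host_total, "host_total")
  check_nonneg(guest_total, "guest_total")
  check_nonneg(ka, "ka")

  if (ka == 0 || host_total == 0 || guest_total == 0) {
    hg <- 0
  } else {
    # ka*c^2 - (ka*(H0+G0)+1)*c + ka*H0*G0 = 0; smaller root, in the
    # numerically stable form 2q/(b + sqrt(b^2 - 4pq)) to avoid cancellation.
    b <- ka * (host_total + guest_total) + 1
    disc <- sqrt(b^2 - 4 * ka^2 * host_total * guest_total)
    hg <- 2 * ka * host_total * guest_total / (b + disc)
  }
  hg <- min(hg, host_total, guest_total)
  st <- new_speciation_state(
    free_host = host_total - hg,
    free_guests = list(G = guest_total - hg),
    complexes = list(HG = hg)
  )
  check_mass_balance(st$free_host + hg, host_total, "host")
  check_mass_balance(st$free_guests$G + hg, guest_total, "guest")
  st
}

#' Solve 1:2 host-guest speciation
#'
#' Speciation with stepwise complexes HG and HG2,
#' `k1 = [HG]/([H][G])`, `k2 = [HG2]/([HG][G])`. The free-guest
#' concentration is the unique root of the cubic guest mass balance on
#' `[0, guest_total]`.
#'
#' @inheritParams solve_1to1
#' @param k1,k2 Stepwise association constants (M^-1).
#' @return A `speciation_state` with complexes `HG` and `HG2`.
#' @export
solve_1to2 <- function(host_total, guest_total, k1, k2) {
  check_nonneg(host_total, "host_total")
  check_nonneg(guest_total, "guest_total")
  check_nonneg(k1, "k1")
  check_nonneg(k2, "k2")

  if (k2 == 0) {
    st <- solve_1to1(host_total, guest_total, k1)
    st$complexes$HG2 <- 0
    return(st)
  }
  if (guest_total == 0 || host_total == 0) {
    g <- guest_total
  } else {
    resid <- function(g) {
      denom <- 1 + k1 * g + k1 * k2 * g^2
      bound <- host_total * (k1 * g + 2 * k1 * k2 * g^2) / denom
      g + bound - guest_total
    }
    if (resid(0) > 0 || resid(guest_total) < 0) {
      stop("internal error: no sign change for the 1:2 guest balance",
        call. = FALSE
      )
    }
    g <- stats::uniroot(resid, c(0, guest_total),
      tol = .ABS_TOL_M, maxiter = .MAX_ITER
    )$root
    # Newton polish: uniroot's tol floor can leave ~1e-12 relative slack.
    for (i in 1:5) {
      denom <- 1 + k1 * g + k1 * k2 * g^2
      dbound <- host_total * (
        (k1 + 4 * k1 * k2 * g) * denom -
          (k1 * g + 2 * k1 * k2 * g^2) * (k1 + 2 * k1 * k2 * g)
      ) / denom^2
      step <- resid(g) / (1 + dbound)
      g_new <- min(max(g - step, 0), guest_total)
      if (abs(g_new - g) < .ABS_TOL_M + .REL_TOL * g) {
        g <- g_new
        break
      }
      g <- g_new
    }
  }
  denom <- 1 + k1 * g + k1 * k2 * g^2
  h <- host_total / denom
  hg <- h * k1 * g
  hg2 <- hg * k2 * g
  st <- new_speciation_state(
    free_host = h,
    free_guests = list(G = g),
    complexes = list(HG = hg, HG2 = hg2)
  )
  check_mass_balance(h + hg + hg2, host_total, "host")
  check_mass_balance(g + hg + 2 * hg2, guest_total, "guest")
  st
}

#' Solve two-guest competitive 1:1 speciation
#'
#' Two guests S and X compete for the single host cavity, forming mutually
#' exclusive 1:1 complexes HS and HX. The solver reduces the two-unknown
#' mass-balance system to a single bracketed root in free S: for a trial
#' free-S value the X balance is an exactly solvable quadratic.
#'
#' @param host_total Total host concentration (M).
#' @param s_total,x_total Total concentrations of the two guests (M).
#' @param ka_s,ka_x Association constants of S and X (M^-1).
#' @return A `speciation_state` with free guests `S`, `X` and complexes
#'   `HS`, `HX`.
#' @export
solve_competition <- function(host_total, s_total, x_total, ka_s, ka_x) {
  check_nonneg(host_total, "host_total")
  check_nonneg(s_total, "s_total")
  check_nonneg(x_total, "x_total")
  check_nonneg(ka_s, "ka_s")
  check_nonneg(ka_x, "ka_x")

  # Free X given free S: x + H0*Kx*x/(D + Kx*x) = X0 with D = 1 + Ks*s.
  free_x_given_s <- function(s) {
    if (ka_x == 0 || x_total == 0) {
      return(x_total)
    }
    d <- 1 + ka_s * s
    b <- d + ka_x * (host_total - x_total)
    # ka_x*x^2 + b*x - d*X0 = 0, positive root; pick the cancellation-free
    # form depending on the sign of b.
    disc <- sqrt(b^2 + 4 * ka_x * d * x_total)
    if (b >= 0) {
      2 * d * x_total / (b + disc)
    } else {
      (disc - b) / (2 * ka_x)
    }
  }
  resid_s <- function(s) {
    x <- free_x_given_s(s)
    h <- host_total / (1 + ka_s * s + ka_x * x)
    s + h * ka_s * s - s_total
  }
  if (s_total == 0 || ka_s == 0) {
    s <- s_total
  } else {
    # Bisection on log10(free S): the residual is monotone increasing,
    # negative as s -> 0 and non-negative at s_total. Working in log space
    # keeps full relative precision when binding depletes S by many orders
    # of magnitude (strong host excess, large ka_s).
    m_lo <- log10(s_total) - 30
    m_hi <- log10(s_total)
    for (i in seq_len(.MAX_ITER)) {
      m <- 0.5 * (m_lo + m_hi)
      if (resid_s(10^m) < 0) m_lo <- m else m_hi <- m
      if (m_hi - m_lo < 1e-15) break
    }
    s <- 10^(0.5 * (m_lo + m_hi))
  }
  x <- free_x_given_s(s)
  h <- host_total / (1 + ka_s * s + ka_x * x)
  hs <- h * ka_s * s
  hx <- h * ka_x * x
  st <- new_speciation_state(
    free_host = h,
    free_guests = list(S = s, X = x),
    complexes = list(HS = hs, HX = hx)
  )
  check_mass_balance(h + hs + hx, host_total, "host")
  check_mass_balance(s + hs, s_total, "guest S")
  check_mass_balance(x + hx, x_total, "guest X")
  st
}

#' Apparent association constant under competition
#'
#' With a competitor X present at free concentration `x_free`, the reporter
#' guest's association constant is attenuated to
#' `ka_s_app = ka_s / (1 + ka_x * x_free)`. `invert_competition()` solves
#' this relation for the competitor's constant, which is how competition
#' (displacement) titrations yield affinities of spectroscopically silent
#' or quenching anions.
#'
#' @param ka_s Intrinsic association constant of the reporter guest (M^-1).
#' @param ka_x Association constant of the competitor (M^-1).
#' @param x_free Free competitor concentration (M).
#' @return `apparent_ka_under_competition()`: the apparent constant (M^-1).
#' @export
apparent_ka_under_competition <- function(ka_s, ka_x, x_free) {
  check_nonneg(ka_s, "ka_s")
  check_nonneg(ka_x, "ka_x")
  check_nonneg(x_free, "x_free")
  ka_s / (1 + ka_x * x_free)
}

#' @rdname apparent_ka_under_competition
#' @param ka_s_app Apparent (attenuated) constant of the reporter (M^-1);
#'   must not exceed `ka_s`.
#' @return `invert_competition()`: the competitor constant `ka_x` (M^-1).
#' @export
invert_competition <- function(ka_s, ka_s_app, x_free) {
  check_positive(ka_s, "ka_s")
  check_positive(ka_s_app, "ka_s_app")
  check_positive(x_free, "x_free")
  if (ka_s_app > ka_s) {
    stop_domain(
      "ka_s_app",
      "competitor cannot raise apparent affinity under this model"
    )
  }
  (ka_s / ka_s_app - 1) / x_free
}

#' Free sulfate buffered by precipitation of a sparingly soluble salt
#'
#' Models the BaSO4 precipitation method: when the ion product exceeds
#' `ksp`, solid BaSO4 forms until `[Ba][SO4] = ksp` exactly, buffering the
#' free sulfate at very low, counterion-controlled values so that
#' sub-nanomolar sulfate affinities become measurable.
#'
#' @param sulfate_total Total sulfate (M).
#' @param counterion_total Total precipitating counterion, e.g. Ba2+ (M).
#' @param ksp Solubility product (M^2).
#' @return A `speciation_state` with free guests `SO4`, `Ba` and the
#'   precipitate amount (mol per litre of solution).
#' @export
free_sulfate_with_precipitation <- function(sulfate_total, counterion_total,
                                            ksp) {
  check_nonneg(sulfate_total, "sulfate_total")
  check_nonneg(counterion_total, "counterion_total")
  check_positive(ksp, "ksp")

  if (sulfate_total * counterion_total <= ksp) {
    p <- 0
    s <- sulfate_total
    ba <- counterion_total
  } else {
    # Solve directly for the minority free ion to avoid cancellation when
    # nearly all of it precipitates: with d = B0 - S0,
    # s^2 + d*s - ksp = 0 has the stable positive root
    # s = 2*ksp / (d + sqrt(d^2 + 4*ksp)).
    d <- counterion_total - sulfate_total
    if (d >= 0) {
      s <- 2 * ksp / (d + sqrt(d^2 + 4 * ksp))
      ba <- ksp / s
    } else {
      ba <- 2 * ksp / (-d + sqrt(d^2 + 4 * ksp))
      s <- ksp / ba
    }
    p <- sulfate_total - s
    if (rel_err(s * ba, ksp) > 1e-10) {
      stop("internal error: ion product does not match ksp after solve",
        call. = FALSE
      )
    }
  }
  new_speciation_state(
    free_host = NA_real_,
    free_guests = list(SO4 = s, Ba = ba),
    complexes = list(),
    precipitate = p
  )
}
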