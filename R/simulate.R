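#' Synthetic-data generators
#'
#' Every experiment class handled by the package can be simulated with
#' known ground truth and seeded Gaussian noise, so each analysis stage is
#' verifiable by parameter recovery without external data. The forward
#' models are exactly the equations the fitting functions use; noise is
#' i.i.d. Gaussian with standard deviation `noise` times the signal range
#' (homoscedastic, matching the unit-weight fitting default). All outputs
#' carry a `truth` attribute echoing the generating parameters and seed.
#'
#' @name synthetic_data
NULL

add_noise <- function(clean, noise) {
  if (noise == 0) {
    return(clean)
  }
  rng <- diff(range(clean))
  if (rng == 0) rng <- max(abs(clean), 1)
  clean + stats::rnorm(length(clean), sd = noise * rng)
}

default_guest_grid <- function(ka, n = 15) {
  # geometric-ish grid spanning well below to well above 1/ka
  c(0, 1 / ka * 10^seq(-1.2, 1.8, length.out = n - 1))
}

#' Simulate a titration experiment
#'
#' @param kind One of `"fluorescence"`, `"nmr_shift"`, `"nmr_integrals"`,
#'   `"baso4"`, `"competition"`.
#' @param truth A named list of generating parameters. Common fields:
#'   `host_total` (M), `guest_grid` (M, increasing, with 0 allowed first),
#'   `noise` (fraction of signal range), plus per kind:
#'   \describe{
#'     \item{fluorescence / nmr_shift}{`ka` (M^-1), `baseline`, `endpoint`
#'       (observable units). 1:2 data can be generated by supplying `k1`,
#'       `k2`, `endpoint_hg`, `endpoint_hg2` instead of `ka`/`endpoint`.}
#'     \item{nmr_integrals}{`ka`; returns free/bound integral pairs.}
#'     \item{baso4}{`ka`, `sulfate_total`, `ksp`, `counterion_grid` (M).}
#'     \item{competition}{`ka_s`, `ka_x`, `x_total`, `baseline`,
#'       `endpoint`, and optionally `psi0` (V), `z_s`, `z_x`,
#'       `temperature`; with a non-zero `psi0` the generated observable
#'       reflects surface-referenced (Boltzmann-corrected) guest
#'       concentrations.}
#'   }
#' @param seed Integer seed; the output is bit-identical for equal seeds.
#' @return For `fluorescence`, `nmr_shift` and `competition`: a
#'   [titration_series()]. For `nmr_integrals` and `baso4`: a data.frame.
#'   All carry the generating `truth` (with the seed) as an attribute.
#' @export
simulate_titration <- function(kind = c(
                                 "fluorescence", "nmr_shift",
                                 "nmr_integrals", "baso4", "competition"
                               ),
                               truth, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.list(truth))
  truth$seed <- as.integer(seed)
  set.seed(truth$seed)
  noise <- if (is.null(truth$noise)) 0 else truth$noise
  check_nonneg(noise, "truth$noise")

  out <- switch(kind,
    fluorescence = ,
    nmr_shift = {
      needed_11 <- c("ka", "baseline", "endpoint", "host_total")
      needed_12 <- c(
        "k1", "k2", "baseline", "endpoint_hg", "endpoint_hg2", "host_total"
      )
      if (all(needed_11 %in% names(truth))) {
        grid <- if (is.null(truth$guest_grid)) {
          default_guest_grid(truth$ka)
        } else {
          truth$guest_grid
        }
        clean <- predict_observable(
          grid, truth$host_total,
          list(
            ka = truth$ka, baseline = truth$baseline,
            endpoint = truth$endpoint
          ),
          model = "1:1"
        )
      } else if (all(needed_12 %in% names(truth))) {
        grid <- if (is.null(truth$guest_grid)) {
          default_guest_grid(truth$k1)
        } else {
          truth$guest_grid
        }
        clean <- predict_observable(
          grid, truth$host_total,
          truth[c("k1", "k2", "baseline", "endpoint_hg", "endpoint_hg2")],
          model = "1:2"
        )
      } else {
        stop(sprintf(
          "truth for kind '%s' needs {%s} or {%s}", kind,
          paste(needed_11, collapse = ", "),
          paste(needed_12, collapse = ", ")
        ), call. = FALSE)
      }
      titration_series(
        guest_total = grid,
        observable = add_noise(clean, noise),
        observable_kind = if (kind == "fluorescence") {
          "fluorescence_intensity"
        } else {
          "nmr_shift_ppm"
        },
        host_total = truth$host_total,
        medium = if (is.null(truth$medium)) "synthetic" else truth$medium
      )
    },
    nmr_integrals = {
      needed <- c("ka", "host_total")
      if (!all(needed %in% names(truth))) {
        stop("truth for nmr_integrals needs ka and host_total", call. = FALSE)
      }
      grid <- if (is.null(truth$guest_grid)) {
        default_guest_grid(truth$ka)[-1]
      } else {
        truth$guest_grid
      }
      theta <- vapply(grid, function(g) {
        st <- solve_1to1(truth$host_total, g, truth$ka)
        st$complexes$HG / truth$host_total
      }, numeric(1))
      i_bound <- add_noise(theta, noise)
      i_free <- add_noise(1 - theta, noise)
      data.frame(
        guest_total = grid,
        integral_free = pmax(i_free, 0),
        integral_bound = pmax(i_bound, 0)
      )
    },
    baso4 = {
      needed <- c("ka", "host_total", "sulfate_total", "ksp", "counterion_grid")
      if (!all(needed %in% names(truth))) {
        stop(sprintf(
          "truth for baso4 needs {%s}", paste(needed, collapse = ", ")
        ), call. = FALSE)
      }
      theta <- vapply(truth$counterion_grid, function(ba0) {
        sp <- free_sulfate_coupled(
          truth$sulfate_total, ba0, truth$host_total, truth$ka, truth$ksp
        )
        truth$ka * sp$s_free / (1 + truth$ka * sp$s_free)
      }, numeric(1))
      data.frame(
        counterion_total = truth$counterion_grid,
        bound_fraction = pmin(pmax(add_noise(theta, noise), 0), 1)
      )
    },
    competition = {
      needed <- c(
        "ka_s", "ka_x", "x_total", "baseline", "endpoint", "host_total"
      )
      if (!all(needed %in% names(truth))) {
        stop(sprintf(
          "truth for competition needs {%s}", paste(needed, collapse = ", ")
        ), call. = FALSE)
      }
      psi0 <- if (is.null(truth$psi0)) 0 else truth$psi0
      z_s <- if (is.null(truth$z_s)) -2L else truth$z_s
      z_x <- if (is.null(truth$z_x)) -1L else truth$z_x
      temp <- if (is.null(truth$temperature)) 298.15 else truth$temperature
      grid <- if (is.null(truth$guest_grid)) {
        default_guest_grid(truth$ka_s / (1 + truth$ka_x * truth$x_total))
      } else {
        truth$guest_grid
      }
      b_s <- boltzmann_factor(psi0, z_s, temp)
      b_x <- boltzmann_factor(psi0, z_x, temp)
      theta <- vapply(grid, function(s_bulk) {
        st <- solve_competition(
          truth$host_total, s_bulk * b_s, truth$x_total * b_x,
          truth$ka_s, truth$ka_x
        )
        st$complexes$HS / truth$host_total
      }, numeric(1))
      clean <- truth$baseline + (truth$endpoint - truth$baseline) * theta
      titration_series(
        guest_total = grid,
        observable = add_noise(clean, noise),
        observable_kind = "fluorescence_intensity",
        host_total = truth$host_total,
        medium = if (is.null(truth$medium)) "synthetic" else truth$medium,
        fixed_competitor = list(
          label = if (is.null(truth$x_label)) "X" else truth$x_label,
          total = truth$x_total
        ),
        temperature = temp
      )
    }
  )
  attr(out, "truth") <- truth
  out
}

#' Simulate a spin-label quenching profile
#'
#' Generates relative fluorescence `F/F0` for a set of quenchers at known
#' depths, from either the symmetrised transverse-Gaussian distribution
#' model (default; the forward model of [fit_depth_distribution()]) or
#' the parallax quenching model
#' `F/F0 = exp(-pi*C*(Rc^2 - (z - d)^2))` (the forward model inverted by
#' [parallax_depth()]).
#'
#' @param z True most probable fluorophore depth (Angstrom from bilayer
#'   centre).
#' @param sigma_d Transverse dispersion (Angstrom; Gaussian profile only).
#' @param strength Quenching strength S (Gaussian profile only).
#' @param quenchers Named numeric vector of quencher depths (Angstrom);
#'   default [quencher_depths()].
#' @param density Quencher surface density C (molecules Angstrom^-2).
#' @param noise Noise fraction of the F/F0 range.
#' @param seed Integer seed.
#' @param profile `"gaussian"` or `"parallax"`.
#' @param rc Critical quenching radius (Angstrom; parallax profile only).
#' @return List of [quenching_measurement()]s with a `truth` attribute.
#' @export
simulate_quenching <- function(z, sigma_d = 3, strength = 10,
                               quenchers = quencher_depths(),
                               density = quencher_surface_density(0.1),
                               noise = 0, seed = 1L,
                               profile = c("gaussian", "parallax"),
                               rc = NULL) {
  profile <- match.arg(profile)
  check_nonneg(abs(z), "z")
  check_positive(sigma_d, "sigma_d")
  check_positive(strength, "strength")
  set.seed(as.integer(seed))
  d <- as.numeric(quenchers)
  clean <- if (profile == "gaussian") {
    exp(-gaussian_quench_profile(d, abs(z), sigma_d, strength))
  } else {
    if (is.null(rc)) rc <- max(abs(abs(z) - d)) + 3
    exp(-pi * density * (rc^2 - (abs(z) - d)^2))
  }
  f <- add_noise(clean, noise)
  f <- pmin(pmax(f, 1e-6), 1)
  truth <- list(
    z = z, sigma_d = sigma_d, strength = strength, density = density,
    noise = noise, seed = as.integer(seed), profile = profile, rc = rc
  )
  out <- lapply(seq_along(d), function(i) {
    quenching_measurement(
      quencher = if (!is.null(names(quenchers))) names(quenchers)[i] else
        paste0("q", i),
      f_over_f0 = f[i], density = density, depth = d[i]
    )
  })
  attr(out, "truth") <- truth
  out
}

#' Simulate an HPTS transport trace
#'
#' Inverts the transport-analysis chain: a per-carrier turnover truth is
#' converted to an initial intravesicular proton-influx rate, the influx
#' follows a single-exponential approach to a plateau (a phenomenological
#' stand-in for the self-limiting pH gradient; the analysis uses initial
#' rates only), and the pH course is mapped back to the HPTS excitation
#' ratio through the calibration.
#'
#' @param per_carrier True turnover (anions s^-1 carrier^-1).
#' @param system A [vesicle_system()].
#' @param calib An [hpts_calibration()].
#' @param carrier_mole_fraction Carrier-to-lipid mole fraction.
#' @param time Time grid (s), strictly increasing from 0.
#' @param plateau_dph pH drop at the transport plateau (pH units).
#' @param noise Noise fraction of the ratio-signal range.
#' @param seed Integer seed.
#' @return A data.frame `time`, `ratio` with a `truth` attribute.
#' @export
simulate_transport_trace <- function(per_carrier, system, calib,
                                     carrier_mole_fraction = 0.01,
                                     time = seq(0, 60, by = 0.1),
                                     plateau_dph = 0.3,
                                     noise = 0, seed = 1L) {
  stopifnot(inherits(system, "vesicle_system"))
  stopifnot(inherits(calib, "hpts_calibration"))
  check_nonneg(per_carrier, "per_carrier")
  check_positive(plateau_dph, "plateau_dph")
  if (any(diff(time) <= 0) || time[1] < 0) {
    stop_domain("time", "must be strictly increasing and start at >= 0")
  }
  set.seed(as.integer(seed))

  carriers <- carrier_mole_fraction * lipids_per_vesicle(system)
  rate0 <- per_carrier * carriers / (inner_volume_litres(system) * .AVOGADRO)
  h_max <- proton_influx(system$ph0 - plateau_dph, system)
  influx <- if (rate0 == 0) {
    rep(0, length(time))
  } else {
    k <- rate0 / h_max
    h_max * (1 - exp(-k * time))
  }
  ph <- vapply(influx, function(h) {
    if (h == 0) {
      return(system$ph0)
    }
    stats::uniroot(
      function(p) proton_influx(p, system) - h,
      c(system$ph0 - plateau_dph - 1e-6, system$ph0 + 1e-9),
      tol = 1e-13, maxiter = 200L
    )$root
  }, numeric(1))
  ratio <- add_noise(ph_to_ratio(ph, calib), noise)
  eps <- 1e-9 * (calib$r_max - calib$r_min)
  ratio <- pmin(pmax(ratio, calib$r_min + eps), calib$r_max - eps)
  out <- data.frame(time = time, ratio = ratio)
  attr(out, "truth") <- list(
    per_carrier = per_carrier, rate0 = rate0,
    carrier_mole_fraction = carrier_mole_fraction,
    plateau_dph = plateau_dph, noise = noise, seed = as.integer(seed)
  )
  out
}
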