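#' Electrolyte composition for diffuse-double-layer calculations
#'
#' @param labels Character vector of species labels.
#' @param z Integer vector of charges.
#' @param conc Numeric vector of bulk concentrations (M).
#' @param temperature Temperature (K).
#' @param eps_r Relative permittivity of the medium (water at 25 C by
#'   default).
#' @return An object of class `electrolyte`.
#' @examples
#' # 0.2 M NaCl-type 1:1 electrolyte
#' el <- electrolyte(c("Na", "Cl"), c(1L, -1L), c(0.2, 0.2))
#' debye_length(el)
#' @export
electrolyte <- function(labels, z, conc, temperature = 298.15,
                        eps_r = 78.4) {
  stopifnot(length(labels) == length(z), length(z) == length(conc))
  if (any(conc < 0)) stop_domain("conc", "must be non-negative")
  if (any(z != round(z))) stop_domain("z", "charges must be integers")
  net <- sum(z * conc)
  if (abs(net) > 1e-12) {
    stop_domain("conc", sprintf(
      "electrolyte not electroneutral (sum z*c = %.3g M)", net
    ))
  }
  check_positive(temperature, "temperature")
  check_positive(eps_r, "eps_r")
  structure(
    list(
      species = data.frame(
        label = labels, z = as.integer(z), conc = as.numeric(conc),
        stringsAsFactors = FALSE
      ),
      temperature = temperature,
      eps_r = eps_r
    ),
    class = "electrolyte"
  )
}

#' @rdname electrolyte
#' @param el An `electrolyte`.
#' @return `ionic_strength()`: mol/L; `debye_length()`: metres.
#' @export
ionic_strength <- function(el) {
  stopifnot(inherits(el, "electrolyte"))
  0.5 * sum(el$species$conc * el$species$z^2)
}

#' @rdname electrolyte
#' @export
debye_length <- function(el) {
  stopifnot(inherits(el, "electrolyte"))
  rt <- .GAS_R * el$temperature
  eps <- el$eps_r * .EPS0
  # concentrations to mol m^-3
  s <- sum(el$species$conc * 1000 * el$species$z^2)
  sqrt(eps * rt / (.FARADAY^2 * s))
}

# Magnitude of the electric field -d(psi)/dx at local potential psi in the
# planar Poisson-Boltzmann double layer (V m^-1); the bracketed sum is
# non-negative for any electroneutral electrolyte.
pb_field <- function(psi, el) {
  rt <- .GAS_R * el$temperature
  eps <- el$eps_r * .EPS0
  # Debye-Huckel limit for very small |psi|, where the exponential sum
  # cancels catastrophically in floating point.
  if (abs(psi) * .FARADAY * max(abs(el$species$z)) / rt < 1e-6) {
    s2 <- sum(el$species$conc * 1000 * el$species$z^2)
    return(abs(psi) * sqrt(.FARADAY^2 * s2 / (eps * rt)))
  }
  s <- sum(el$species$conc * 1000 *
    (exp(-el$species$z * .FARADAY * psi / rt) - 1))
  if (s < 0) {
    if (s < -1e-9 * max(sum(el$species$conc * 1000), 1)) {
      stop("internal error: negative Poisson-Boltzmann integrand",
        call. = FALSE
      )
    }
    s <- 0
  }
  sqrt(2 * rt / eps * s)
}

#' Grahame relation: surface charge density from surface potential
#'
#' For a planar diffuse double layer,
#' `sigma = sign(psi0) * sqrt(2*eps*eps0*R*T * sum_i c_i*(exp(-z_i*F*psi0/RT) - 1))`
#' with bulk concentrations in mol m^-3. Valid for arbitrary electrolyte
#' mixtures; reduces to the familiar `sinh` form for a symmetric z:z
#' electrolyte.
#'
#' @param psi0 Surface potential (V).
#' @param el An [electrolyte()].
#' @return Surface charge density (C m^-2).
#' @export
grahame_charge_density <- function(psi0, el) {
  stopifnot(inherits(el, "electrolyte"))
  if (!is.finite(psi0)) stop_domain("psi0", "must be finite")
  if (psi0 == 0) {
    return(0)
  }
  eps <- el$eps_r * .EPS0
  sign(psi0) * eps * pb_field(psi0, el)
}

# Distance between the potentials psi_a (closer to the surface, larger
# magnitude) and psi_b along the planar PB decay, by quadrature of
# dx = d(psi)/E(psi).
pb_distance <- function(psi_a, psi_b, el) {
  if (psi_a == psi_b) {
    return(0)
  }
  f <- function(p) vapply(p, function(pi) 1 / pb_field(pi, el), numeric(1))
  lims <- sort(c(psi_a, psi_b))
  stats::integrate(f, lims[1], lims[2],
    rel.tol = 1e-12, subdivisions = 500L
  )$value
}

#' Surface potential from a zeta potential (Gouy-Chapman model)
#'
#' The zeta potential is the potential at the hydrodynamic shear plane, a
#' small distance out from the surface. This solves the planar
#' Poisson-Boltzmann decay for the surface potential `psi0` such that
#' `psi(shear_plane_distance) = zeta`. With a shear distance of 0 the
#' surface potential equals zeta.
#'
#' @param zeta Zeta potential (V); magnitude must be below 0.3 V.
#' @param shear_plane_distance Distance from surface to shear plane (m).
#'   Default 2 Angstrom.
#' @param el An [electrolyte()].
#' @return Surface potential (V), same sign as `zeta`,
#'   `|psi0| >= |zeta|`.
#' @export
surface_potential_from_zeta <- function(zeta, el,
                                        shear_plane_distance = 2e-10) {
  stopifnot(inherits(el, "electrolyte"))
  if (abs(zeta) >= 0.3) {
    stop_domain("zeta", "|zeta| must be < 0.3 V")
  }
  check_nonneg(shear_plane_distance, "shear_plane_distance")
  if (zeta == 0 || shear_plane_distance == 0) {
    return(zeta)
  }
  g <- function(psi0) {
    pb_distance(psi0, zeta, el) - shear_plane_distance
  }
  hi <- sign(zeta) * 0.5
  lo <- zeta * (1 + 1e-9)
  if (g(hi) < 0) {
    stop("no surface potential within +/-0.5 V reproduces this zeta",
      call. = FALSE
    )
  }
  stats::uniroot(g, sort(c(lo, hi)), tol = 1e-14, maxiter = 200L)$root
}

#' Potential profile of the planar diffuse double layer
#'
#' Potential at distance `x` from a surface held at `psi0`, from the same
#' quadrature of the planar Poisson-Boltzmann decay used by
#' [surface_potential_from_zeta()] (the two are exact inverses).
#'
#' @param psi0 Surface potential (V).
#' @param x Distance from the surface (m).
#' @param el An [electrolyte()].
#' @return Potential (V) at `x`.
#' @export
potential_at_distance <- function(psi0, x, el) {
  stopifnot(inherits(el, "electrolyte"))
  check_nonneg(x, "x")
  if (x == 0 || psi0 == 0) {
    return(psi0)
  }
  g <- function(p) pb_distance(psi0, p, el) - x
  # psi(x) lies strictly between 0 and psi0
  lo <- psi0 * 1e-12
  stats::uniroot(g, sort(c(lo, psi0 * (1 - 1e-12))),
    tol = 1e-16, maxiter = 200L
  )$root
}

#' Boltzmann factor for an ion at a charged interface
#'
#' `B = exp(-z*F*psi0/(R*T))`, the ratio of an ion's concentration at the
#' surface to its bulk value. Anions are depleted (B < 1) and cations
#' enriched at a negatively charged surface.
#'
#' @param psi0 Surface potential (V).
#' @param z Ion charge.
#' @param temperature Temperature (K).
#' @return Dimensionless factor `c_surface / c_bulk`.
#' @export
boltzmann_factor <- function(psi0, z, temperature = 298.15) {
  if (!is.finite(psi0)) stop_domain("psi0", "must be finite")
  check_positive(temperature, "temperature")
  exp(-z * .FARADAY * psi0 / (.GAS_R * temperature))
}

#' Surface-referenced ion concentrations
#'
#' Multiplies each bulk concentration by that ion's Boltzmann factor at
#' the given surface potential. Used to refer titrant and competitor
#' concentrations to the membrane surface before fitting, so that fitted
#' binding constants are intrinsic rather than attenuated by
#' electrostatic screening.
#'
#' @param species A data.frame with columns `label`, `z`, `conc` (M), or
#'   an [electrolyte()].
#' @param psi0 Surface potential (V).
#' @param temperature Temperature (K).
#' @return The same data.frame with `conc` replaced by surface values and
#'   an added `boltzmann` column.
#' @export
surface_referenced_concentrations <- function(species, psi0,
                                              temperature = 298.15) {
  if (inherits(species, "electrolyte")) species <- species$species
  stopifnot(all(c("label", "z", "conc") %in% names(species)))
  b <- vapply(species$z, boltzmann_factor,
    numeric(1),
    psi0 = psi0, temperature = temperature
  )
  species$boltzmann <- b
  species$conc <- species$conc * b
  species
}

#' Interface model: surface potential plus its electrolyte context
#'
#' Bundles a surface potential (typically back-calculated from a zeta
#' potential) with the electrolyte composition and temperature, for use by
#' the competition-fit correction chain.
#'
#' @param psi0 Surface potential (V).
#' @param el An [electrolyte()].
#' @param zeta Optional zeta potential (V) the surface potential was
#'   derived from.
#' @param shear_plane_distance Shear-plane distance used (m).
#' @return An object of class `interface_model`.
#' @export
interface_model <- function(psi0, el, zeta = NULL,
                            shear_plane_distance = 2e-10) {
  stopifnot(inherits(el, "electrolyte"))
  if (!is.null(zeta) && abs(psi0) < abs(zeta) &&
    sign(psi0) == sign(zeta)) {
    stop_domain("psi0", "|psi0| must be >= |zeta| (potential decays outward)")
  }
  structure(
    list(
      psi0 = psi0,
      zeta = zeta,
      shear_plane_distance = shear_plane_distance,
      electrolyte = el,
      temperature = el$temperature
    ),
    class = "interface_model"
  )
}
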