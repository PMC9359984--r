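#' HPTS ratiometric calibration
#'
#' Calibration constants for the ratiometric pH probe HPTS (pyranine):
#' the limiting excitation ratios `R = I(460)/I(403)` at the acidic and
#' basic extremes and the probe's apparent pKa. These are explicit
#' experiment-specific inputs, never silently assumed.
#'
#' @param r_min,r_max Limiting ratios (`r_min < r_max`).
#' @param pka Apparent pKa of HPTS (default 7.2).
#' @return An object of class `hpts_calibration`.
#' @export
hpts_calibration <- function(r_min = 0.2, r_max = 2.0, pka = 7.2) {
  if (r_min >= r_max) stop_domain("r_min", "must be < r_max")
  check_positive(r_max, "r_max")
  structure(
    list(r_min = r_min, r_max = r_max, pka = pka),
    class = "hpts_calibration"
  )
}

#' Vesicle and buffer parameters for the transport assay
#'
#' Geometry and internal-buffer description of the vesicle preparation
#' used by the salt-pulse HPTS assay: large unilamellar vesicles (default
#' 200 nm diameter) with HEPES-buffered interior.
#'
#' @param buffer_conc Internal buffer concentration (M); default 10 mM
#'   HEPES.
#' @param buffer_pka Buffer pKa; default 7.48 (HEPES, 25 C).
#' @param ph0 Initial internal pH.
#' @param diameter Outer vesicle diameter (m).
#' @param area_per_lipid Area per lipid (m^2); default 0.68 nm^2 (POPC).
#' @param bilayer_thickness Bilayer thickness (m); default 3.7 nm.
#' @return An object of class `vesicle_system`.
#' @export
vesicle_system <- function(buffer_conc = 0.010, buffer_pka = 7.48,
                           ph0 = 7.0, diameter = 200e-9,
                           area_per_lipid = 0.68e-18,
                           bilayer_thickness = 3.7e-9) {
  check_positive(buffer_conc, "buffer_conc")
  check_positive(diameter, "diameter")
  check_positive(area_per_lipid, "area_per_lipid")
  check_positive(bilayer_thickness, "bilayer_thickness")
  if (abs(ph0 - buffer_pka) > 1.5) {
    stop_domain("ph0", "must lie within buffer_pka +/- 1.5")
  }
  if (diameter / 2 <= bilayer_thickness) {
    stop_domain("diameter", "inner radius would be <= 0")
  }
  structure(
    list(
      buffer_conc = buffer_conc, buffer_pka = buffer_pka, ph0 = ph0,
      diameter = diameter, area_per_lipid = area_per_lipid,
      bilayer_thickness = bilayer_thickness
    ),
    class = "vesicle_system"
  )
}

#' Convert an HPTS excitation ratio to pH (and back)
#'
#' `pH = pKa + log10((R - R_min)/(R_max - R))`; strictly increasing in R.
#'
#' @param r Ratio value(s), strictly inside `(r_min, r_max)`.
#' @param calib An [hpts_calibration()].
#' @return `ratio_to_ph()`: pH value(s).
#' @export
ratio_to_ph <- function(r, calib) {
  stopifnot(inherits(calib, "hpts_calibration"))
  if (any(r <= calib$r_min | r >= calib$r_max)) {
    stop_domain(
      "r",
      sprintf(
        "ratio outside the calibration range (%.3g, %.3g); clip or recalibrate",
        calib$r_min, calib$r_max
      )
    )
  }
  calib$pka + log10((r - calib$r_min) / (calib$r_max - r))
}

#' @rdname ratio_to_ph
#' @param ph pH value(s).
#' @return `ph_to_ratio()`: ratio value(s).
#' @export
ph_to_ratio <- function(ph, calib) {
  stopifnot(inherits(calib, "hpts_calibration"))
  f <- 10^(ph - calib$pka)
  (calib$r_min + calib$r_max * f) / (1 + f)
}

# protonated fraction of a monoprotic buffer at a given pH
buffer_protonated_fraction <- function(ph, pka) {
  1 / (1 + 10^(ph - pka))
}

#' Intravesicular proton influx from a pH trace
#'
#' Converts the internal pH time course into the cumulative proton influx
#' `Delta[H]_in(t)` (mol per litre of vesicle interior), accounting for
#' buffering:
#' `Delta[H]_in = C_buf*(alpha(pH_t) - alpha(pH_0)) + ([H+]_t - [H+]_0)
#'  - ([OH-]_t - [OH-]_0)` with `alpha` the protonated-buffer fraction.
#' Acidification gives positive influx.
#'
#' @param ph Numeric vector of internal pH values over time.
#' @param system A [vesicle_system()] (supplies buffer concentration, pKa
#'   and the reference pH `ph0`).
#' @param ph_ref Reference pH; defaults to `system$ph0`.
#' @return Numeric vector of `Delta[H]_in` (M, intravesicular basis).
#' @export
proton_influx <- function(ph, system, ph_ref = system$ph0) {
  stopifnot(inherits(system, "vesicle_system"))
  if (any(abs(ph - system$buffer_pka) > 1.5)) {
    stop_domain("ph", "outside the buffer validity range (pKa +/- 1.5)")
  }
  a <- buffer_protonated_fraction(ph, system$buffer_pka)
  a0 <- buffer_protonated_fraction(ph_ref, system$buffer_pka)
  system$buffer_conc * (a - a0) +
    (10^(-ph) - 10^(-ph_ref)) -
    (10^(ph - 14) - 10^(ph_ref - 14))
}

#' Initial rate of proton influx
#'
#' Ordinary least-squares slope of `Delta[H]_in` against time over a
#' window starting at the salt-pulse timestamp.
#'
#' @param time Time stamps (s), strictly increasing.
#' @param influx `Delta[H]_in` values (M), same length.
#' @param window Window length (s) after `t0` used for the regression.
#' @param t0 Salt-pulse timestamp (s); the window is `[t0, t0 + window]`.
#' @return List with `rate` (M s^-1), `se`, `n`, `window`.
#' @export
initial_rate <- function(time, influx, window = 30, t0 = 0) {
  if (any(diff(time) <= 0)) stop_domain("time", "must be strictly increasing")
  if (length(time) != length(influx)) {
    stop_domain("influx", "length mismatch with time")
  }
  check_positive(window, "window")
  if (t0 < time[1]) {
    stop_domain("t0", "window starts before the first sample (salt pulse)")
  }
  sel <- time >= t0 & time <= t0 + window
  if (sum(sel) < 5L) {
    stop_domain("window", "needs at least 5 samples inside the window")
  }
  fit <- stats::lm(influx[sel] ~ time[sel])
  # summary.lm warns on exactly linear (noise-free) traces; harmless here
  co <- suppressWarnings(summary(fit)$coefficients)
  list(
    rate = unname(co[2, 1]), se = unname(co[2, 2]),
    n = sum(sel), window = window
  )
}

# lipids per vesicle: both leaflet areas divided by the area per lipid
lipids_per_vesicle <- function(system) {
  r_out <- system$diameter / 2
  r_in <- r_out - system$bilayer_thickness
  4 * pi * (r_out^2 + r_in^2) / system$area_per_lipid
}

inner_volume_litres <- function(system) {
  r_in <- system$diameter / 2 - system$bilayer_thickness
  (4 / 3) * pi * r_in^3 * 1000
}

#' Per-carrier transport rate
#'
#' Normalises an intravesicular proton-influx rate to single-carrier
#' turnover (anions per second per carrier, one anion per proton under
#' H+/anion symport). The default per-vesicle mode counts lipids from the
#' vesicle geometry (`lipids = (4*pi*r_out^2 + 4*pi*r_in^2)/a_lipid`),
#' carriers from the carrier mole fraction, and protons from the inner
#' aqueous volume. The `"bulk"` mode computes the same normalisation from
#' suspension-level concentrations (intravesicular volume fraction over
#' bulk carrier concentration); the two agree for uniform vesicles.
#'
#' @param rate Proton influx rate (M s^-1, intravesicular basis).
#' @param system A [vesicle_system()].
#' @param carrier_mole_fraction Carrier-to-lipid mole fraction.
#' @param lipid_conc Bulk lipid concentration (M); required for
#'   `mode = "bulk"`.
#' @param mode `"per_vesicle"` (default) or `"bulk"`.
#' @return List with `per_carrier` (anions s^-1 carrier^-1) and `mode`.
#' @export
per_carrier_rate <- function(rate, system, carrier_mole_fraction,
                             lipid_conc = NULL,
                             mode = c("per_vesicle", "bulk")) {
  mode <- match.arg(mode)
  stopifnot(inherits(system, "vesicle_system"))
  check_positive(carrier_mole_fraction, "carrier_mole_fraction")
  r_in <- system$diameter / 2 - system$bilayer_thickness
  if (r_in <= 0) stop_domain("system", "inner radius <= 0")

  n_lipids <- lipids_per_vesicle(system)
  v_in <- inner_volume_litres(system)
  if (mode == "per_vesicle") {
    carriers <- carrier_mole_fraction * n_lipids
    h_per_s <- rate * v_in * .AVOGADRO
    per_carrier <- h_per_s / carriers
  } else {
    if (is.null(lipid_conc)) {
      stop_domain("lipid_conc", "required for bulk mode")
    }
    check_positive(lipid_conc, "lipid_conc")
    # intravesicular volume per litre of suspension
    vesicles_per_l <- lipid_conc * .AVOGADRO / n_lipids
    v_in_fraction <- vesicles_per_l * v_in
    carrier_conc <- carrier_mole_fraction * lipid_conc
    per_carrier <- rate * v_in_fraction / carrier_conc
  }
  list(per_carrier = per_carrier, mode = mode)
}

#' Full transport-rate extraction from an HPTS trace
#'
#' Convenience chain: ratio trace -> pH -> proton influx -> initial rate
#' -> per-carrier turnover.
#'
#' @param time,ratio The HPTS trace (s; dimensionless ratio).
#' @param calib An [hpts_calibration()].
#' @param system A [vesicle_system()].
#' @param carrier_mole_fraction Carrier-to-lipid mole fraction.
#' @param window,t0 Passed to [initial_rate()].
#' @param mode,lipid_conc Passed to [per_carrier_rate()].
#' @return List with `per_carrier`, `rate` (M s^-1), `rate_se`, `window`,
#'   `mode`.
#' @export
transport_rate_from_trace <- function(time, ratio, calib, system,
                                      carrier_mole_fraction,
                                      window = 30, t0 = 0,
                                      mode = "per_vesicle",
                                      lipid_conc = NULL) {
  ph <- ratio_to_ph(ratio, calib)
  influx <- proton_influx(ph, system, ph_ref = ph[1])
  r <- initial_rate(time, influx, window = window, t0 = t0)
  pc <- per_carrier_rate(r$rate, system, carrier_mole_fraction,
    lipid_conc = lipid_conc, mode = mode
  )
  list(
    per_carrier = pc$per_carrier, rate = r$rate, rate_se = r$se,
    window = window, mode = pc$mode
  )
}
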