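#' Construct a titration series
#'
#' Container for one titration experiment: a grid of total guest (titrant)
#' concentrations with the measured observable at each point, plus the
#' metadata needed to fit a binding model (host concentration, medium,
#' optional fixed competitor, temperature).
#'
#' @param guest_total Numeric vector of total guest concentrations (M),
#'   non-negative and strictly increasing.
#' @param observable Numeric vector of measured values, same length.
#' @param observable_kind One of `"fluorescence_intensity"`,
#'   `"nmr_shift_ppm"` or `"nmr_integral_pair"`.
#' @param host_total Total host (receptor) concentration (M).
#' @param medium Free-text medium label (e.g. `"DMSO"`, `"C12E8"`,
#'   `"POPC"`).
#' @param fixed_competitor Optional list `list(label =, total =)` giving a
#'   competitor anion held at fixed total concentration (M).
#' @param temperature Temperature (K).
#' @param sigma Optional per-point observable standard deviations (same
#'   units as `observable`); used as weights `1/sigma^2` when fitting.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(guest_total, observable,
                             observable_kind = c(
                               "fluorescence_intensity", "nmr_shift_ppm",
                               "nmr_integral_pair"
                             ),
                             host_total, medium = "unspecified",
                             fixed_competitor = NULL,
                             temperature = 298.15, sigma = NULL) {
  observable_kind <- match.arg(observable_kind)
  if (length(guest_total) != length(observable)) {
    stop_domain("observable", "must have the same length as guest_total")
  }
  if (any(!is.finite(guest_total)) || any(guest_total < 0)) {
    stop_domain("guest_total", "must be finite and non-negative")
  }
  if (any(diff(guest_total) <= 0)) {
    stop_domain("guest_total", "must be strictly increasing")
  }
  check_nonneg(host_total, "host_total")
  if (!is.null(sigma)) {
    if (length(sigma) != length(observable) || any(sigma <= 0)) {
      stop_domain("sigma", "must be positive and match observable length")
    }
  }
  if (!is.null(fixed_competitor)) {
    if (!is.list(fixed_competitor) ||
      !all(c("label", "total") %in% names(fixed_competitor))) {
      stop_domain("fixed_competitor", "must be list(label =, total =)")
    }
    check_nonneg(fixed_competitor$total, "fixed_competitor$total")
  }
  structure(
    list(
      data = data.frame(
        guest_total = as.numeric(guest_total),
        observable = as.numeric(observable),
        sigma = if (is.null(sigma)) NA_real_ else as.numeric(sigma)
      ),
      observable_kind = observable_kind,
      host_total = host_total,
      medium = medium,
      fixed_competitor = fixed_competitor,
      temperature = temperature
    ),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "Titration series: %d points, %s, host %.3g M, medium %s\n",
    nrow(x$data), x$observable_kind, x$host_total, x$medium
  ))
  if (!is.null(x$fixed_competitor)) {
    cat(sprintf(
      "  fixed competitor: %s at %.3g M\n",
      x$fixed_competitor$label, x$fixed_competitor$total
    ))
  }
  invisible(x)
}
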