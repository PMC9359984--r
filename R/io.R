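#' CSV readers and validators
#'
#' All experiment classes are exchanged as comma-separated UTF-8 files
#' with a header row. Units are fixed per schema (concentrations in M
#' unless a column name carries an explicit unit suffix such as
#' `zeta_mV`; depths in Angstrom; time in seconds) and converted at the
#' boundary only. Validation reports every violation with its data-row
#' number.
#'
#' @name io_csv
NULL

read_csv_strict <- function(path, required, optional = character()) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!grepl(",", first, fixed = TRUE) && grepl(";", first, fixed = TRUE)) {
    stop(
      "file appears to be semicolon-delimited; the schema requires ",
      "comma-separated values",
      call. = FALSE
    )
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf(
      "missing required column(s): %s", paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra)) {
    stop(sprintf(
      "unknown column(s): %s", paste(extra, collapse = ", ")
    ), call. = FALSE)
  }
  df
}

violation <- function(rows, msg) {
  sprintf("row %s: %s", paste(rows, collapse = ","), msg)
}

fail_schema <- function(violations, path) {
  stop(sprintf(
    "schema violations in %s:\n  %s", path,
    paste(violations, collapse = "\n  ")
  ), call. = FALSE)
}

#' Read a titration CSV
#'
#' Schema `titration.csv`: columns `guest_total_M`, `observable`,
#' `observable_kind`, optional `sigma`. Experiment metadata that is not
#' per-point (host concentration, medium, fixed competitor, temperature)
#' comes from the run configuration and is passed as arguments.
#'
#' @param path File path.
#' @param host_total Total host concentration (M).
#' @param medium Medium label.
#' @param fixed_competitor Optional `list(label =, total =)`.
#' @param temperature Temperature (K).
#' @return A [titration_series()].
#' @export
read_titration_csv <- function(path, host_total, medium = "unspecified",
                               fixed_competitor = NULL,
                               temperature = 298.15) {
  df <- read_csv_strict(
    path,
    required = c("guest_total_M", "observable", "observable_kind"),
    optional = "sigma"
  )
  v <- character()
  bad <- which(!is.finite(df$guest_total_M) | df$guest_total_M < 0)
  if (length(bad)) v <- c(v, violation(bad, "guest_total_M must be >= 0"))
  if (is.unsorted(df$guest_total_M, strictly = TRUE)) {
    v <- c(v, "guest_total_M must be strictly increasing; sort rows by titrant")
  }
  kinds <- unique(df$observable_kind)
  if (length(kinds) != 1L) {
    v <- c(v, "observable_kind must be constant within one file")
  }
  if (length(v)) fail_schema(v, path)
  titration_series(
    guest_total = df$guest_total_M,
    observable = df$observable,
    observable_kind = kinds,
    host_total = host_total,
    medium = medium,
    fixed_competitor = fixed_competitor,
    temperature = temperature,
    sigma = if ("sigma" %in% names(df)) df$sigma else NULL
  )
}

#' Write a titration series to CSV
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  df <- data.frame(
    guest_total_M = series$data$guest_total,
    observable = series$data$observable,
    observable_kind = series$observable_kind
  )
  if (!all(is.na(series$data$sigma))) df$sigma <- series$data$sigma
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a zeta-potential CSV
#'
#' Schema `zeta.csv`: columns `condition`, `zeta_mV`, `temperature_K`.
#' Millivolts in the file are converted to volts on read.
#'
#' @param path File path.
#' @return A data.frame with `condition`, `zeta` (V), `temperature` (K).
#' @export
read_zeta_csv <- function(path) {
  df <- read_csv_strict(
    path,
    required = c("condition", "zeta_mV", "temperature_K")
  )
  v <- character()
  bad <- which(!is.finite(df$zeta_mV) | abs(df$zeta_mV) >= 300)
  if (length(bad)) v <- c(v, violation(bad, "|zeta_mV| must be < 300"))
  bad <- which(!is.finite(df$temperature_K) | df$temperature_K <= 0)
  if (length(bad)) v <- c(v, violation(bad, "temperature_K must be > 0"))
  if (length(v)) fail_schema(v, path)
  data.frame(
    condition = df$condition,
    zeta = df$zeta_mV / 1000,
    temperature = df$temperature_K
  )
}

#' Read a spin-label quenching CSV
#'
#' Schema `quenching.csv`: columns `quencher`, `F_over_F0`,
#' `mole_fraction`, optional `depth_A` override. Depths are resolved from
#' [quencher_depths()] when the override column is absent.
#'
#' @param path File path.
#' @param area_per_lipid Area per lipid (Angstrom^2) used to convert mole
#'   fractions to surface densities.
#' @return A list of [quenching_measurement()]s.
#' @export
read_quenching_csv <- function(path, area_per_lipid = 68) {
  df <- read_csv_strict(
    path,
    required = c("quencher", "F_over_F0", "mole_fraction"),
    optional = "depth_A"
  )
  v <- character()
  bad <- which(!is.finite(df$F_over_F0) | df$F_over_F0 <= 0 |
    df$F_over_F0 > 1)
  if (length(bad)) v <- c(v, violation(bad, "F_over_F0 must be in (0, 1]"))
  bad <- which(!is.finite(df$mole_fraction) | df$mole_fraction <= 0)
  if (length(bad)) v <- c(v, violation(bad, "mole_fraction must be > 0"))
  if (length(v)) fail_schema(v, path)
  lapply(seq_len(nrow(df)), function(i) {
    quenching_measurement(
      quencher = df$quencher[i],
      f_over_f0 = df$F_over_F0[i],
      density = quencher_surface_density(df$mole_fraction[i], area_per_lipid),
      depth = if ("depth_A" %in% names(df) && is.finite(df$depth_A[i])) {
        df$depth_A[i]
      } else {
        NULL
      }
    )
  })
}

#' Read an HPTS trace CSV
#'
#' Schema `trace.csv`: either `time_s, ratio` or `time_s, I460, I403`
#' (the ratio is formed as `I460/I403` on read).
#'
#' @param path File path.
#' @return A data.frame with `time` (s) and `ratio`.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  header <- strsplit(readLines(path, n = 1L, warn = FALSE), ",")[[1]]
  if (all(c("I460", "I403") %in% header)) {
    df <- read_csv_strict(path, required = c("time_s", "I460", "I403"))
    ratio <- df$I460 / df$I403
  } else {
    df <- read_csv_strict(path, required = c("time_s", "ratio"))
    ratio <- df$ratio
  }
  v <- character()
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    v <- c(v, "time_s must be strictly increasing")
  }
  bad <- which(!is.finite(ratio) | ratio <= 0)
  if (length(bad)) v <- c(v, violation(bad, "ratio must be finite and > 0"))
  if (length(v)) fail_schema(v, path)
  data.frame(time = df$time_s, ratio = ratio)
}

.run_config_keys <- c(
  "experiment", "files", "model", "fixed_parameters", "host_total_M",
  "medium", "temperature_K", "eps_r", "ksp_M2", "shear_plane_distance_m",
  "quencher_depths_A", "area_per_lipid_A2", "calibration", "geometry",
  "electrolyte", "correct", "window_s", "seed", "output_dir"
)

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, and returns it
#' with an `assumptions` element collecting every physical-constant
#' override (Ksp, shear-plane distance, quencher depths, calibration,
#' geometry) so downstream reports can echo them verbatim.
#'
#' @param path YAML file path.
#' @return A named list (class `run_config`).
#' @export
load_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read run configurations",
      call. = FALSE
    )
  }
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .run_config_keys)
  if (length(unknown)) {
    stop(sprintf(
      "unknown run-config key(s): %s (known: %s)",
      paste(unknown, collapse = ", "),
      paste(.run_config_keys, collapse = ", ")
    ), call. = FALSE)
  }
  cfg$assumptions <- cfg[intersect(
    c(
      "ksp_M2", "shear_plane_distance_m", "quencher_depths_A",
      "area_per_lipid_A2", "calibration", "geometry", "eps_r"
    ),
    names(cfg)
  )]
  class(cfg) <- "run_config"
  cfg
}
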