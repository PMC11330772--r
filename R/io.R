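# Delimited-text readers/writers (canonical dialect: comma separated, dot
# decimals, UTF-8, mandatory header with unit-suffixed column names),
# the extinction-coefficient registry and JSON reports.

read_strict_csv <- function(path, required_cols) {
  if (!file.exists(path)) stop_input(sprintf("File not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) {
    stop_input(sprintf("%s: need a header row and at least one data row.", path))
  }
  header <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  missing_cols <- setdiff(required_cols, header)
  if (length(missing_cols) > 0) {
    stop_input(sprintf("%s line 1: missing required column(s) %s.", path,
                       paste0("`", missing_cols, "`", collapse = ", ")))
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    cells <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1]])
    if (length(cells) != length(header)) {
      stop_input(sprintf("%s line %d: %d cells but %d header columns.",
                         path, i, length(cells), length(header)))
    }
    vals <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(vals) & !(cells %in% c("NA", "", "nd")))
    if (length(bad) > 0) {
      stop_input(sprintf("%s line %d: non-numeric value '%s' in column `%s`.",
                         path, i, cells[bad[1]], header[bad[1]]))
    }
    vals
  })
  out <- as_tibble(setNames(as.data.frame(do.call(rbind, rows)), header))
  out
}

write_plain_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write bi-substrate initial-rate tables
#'
#' Canonical CSV with columns `alcohol_uM, acceptor_uM, rate_per_s,
#' replicate`. Reading validates the header and every cell and reports
#' parse failures with file and line context; `write` then `read` round
#' trips losslessly.
#'
#' @param path File path.
#' @param data A [bisubstrate_data()] tibble (for writing).
#' @return `read_bisubstrate_csv()` returns a validated
#'   [bisubstrate_data()] tibble; the writer returns `path` invisibly.
#' @export
read_bisubstrate_csv <- function(path) {
  df <- read_strict_csv(path, c("alcohol_uM", "acceptor_uM", "rate_per_s"))
  if (!"replicate" %in% names(df)) df$replicate <- 1
  bisubstrate_data(df$alcohol_uM, df$acceptor_uM, df$rate_per_s,
                   replicate = df$replicate)
}

#' @rdname read_bisubstrate_csv
#' @export
write_bisubstrate_csv <- function(data, path) {
  validate_bisubstrate(data)
  write_plain_csv(
    data[, c("alcohol_uM", "acceptor_uM", "rate_per_s", "replicate")], path)
}

#' Read and write kobs series tables
#'
#' Canonical CSV with columns `conc_uM, kobs_per_s, se` (`se` optional).
#'
#' @param path File path.
#' @param role Series role assigned on reading (see [kobs_series()]).
#' @param series A [kobs_series()] tibble (for writing).
#' @return A validated [kobs_series()] on reading.
#' @export
read_kobs_csv <- function(path, role = c("reductant", "electron_acceptor",
                                         "dead_end_ligand")) {
  df <- read_strict_csv(path, c("conc_uM", "kobs_per_s"))
  kobs_series(df$conc_uM, df$kobs_per_s,
              se = if ("se" %in% names(df)) df$se else NA_real_,
              role = match.arg(role))
}

#' @rdname read_kobs_csv
#' @export
write_kobs_csv <- function(series, path) {
  write_plain_csv(as_tibble(series)[, c("conc_uM", "kobs_per_s", "se")], path)
}

#' Read and write time-resolved spectra matrices
#'
#' Layout: first header cell `time_s`, remaining header cells the
#' wavelengths (nm); first column the times (s); body the absorbances
#' (AU).
#'
#' @param path File path.
#' @param data A [spectra_matrix()] (for writing).
#' @return A [spectra_matrix()] on reading.
#' @export
read_spectra_csv <- function(path) {
  df <- read_strict_csv(path, "time_s")
  wl <- suppressWarnings(as.numeric(setdiff(names(df), "time_s")))
  if (anyNA(wl)) {
    stop_input(sprintf("%s line 1: wavelength headers must be numeric.", path))
  }
  spectra_matrix(df$time_s, wl,
                 as.matrix(df[, setdiff(names(df), "time_s")]))
}

#' @rdname read_spectra_csv
#' @export
write_spectra_csv <- function(data, path) {
  stopifnot(inherits(data, "spectra_matrix"))
  df <- as.data.frame(data$absorbance)
  names(df) <- data$wavelengths
  df <- cbind(time_s = data$times, df)
  write_plain_csv(df, path)
}

#' Read and write ITC injection tables
#'
#' Canonical CSV with columns `injection, volume_uL, heat_ucal`. The cell
#' and syringe concentrations are experiment metadata, not per-injection
#' data, and are supplied as arguments on reading.
#'
#' @param path File path.
#' @param cell_conc_uM,syringe_conc_uM,cell_volume_uL,temperature_K
#'   Experiment metadata (see [itc_experiment()]).
#' @param exp An [itc_experiment()] with heats (for writing).
#' @return An [itc_experiment()] on reading.
#' @export
read_itc_csv <- function(path, cell_conc_uM, syringe_conc_uM,
                         cell_volume_uL = 200, temperature_K = 298.15) {
  df <- read_strict_csv(path, c("injection", "volume_uL", "heat_ucal"))
  itc_experiment(cell_conc_uM, syringe_conc_uM, cell_volume_uL,
                 df$volume_uL, temperature_K, df$heat_ucal)
}

#' @rdname read_itc_csv
#' @export
write_itc_csv <- function(exp, path) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (is.null(exp$heats_ucal)) stop_input("Experiment carries no heats.")
  write_plain_csv(
    tibble(injection = seq_along(exp$injection_volumes_uL),
           volume_uL = exp$injection_volumes_uL,
           heat_ucal = exp$heats_ucal),
    path)
}

#' Extinction-coefficient registry for the coupled assays
#'
#' Difference extinction coefficients used to convert absorbance slopes
#' into product-formation or acceptor-reduction rates: aldehyde formation
#' followed in the UV for each alcohol, and BQ reduction at 247 nm (the
#' composite values fold in the aldehyde absorptivity at that
#' wavelength).
#'
#' @return Tibble with `context`, `wavelength_nm`, `delta_eps` (M^-1
#'   cm^-1) and a `note`.
#' @export
extinction_table <- function() {
  tibble(
    context = c("4-methoxybenzaldehyde formation",
                "3-Cl-4-methoxybenzaldehyde formation",
                "BQ reduction (4-methoxybenzyl assay)",
                "BQ reduction (3-Cl-4-methoxybenzyl assay)",
                "BQ to hydroquinone"),
    wavelength_nm = c(285, 295, 247, 247, 247),
    delta_eps = c(16950, 15000, 17833, 18067, 20200),
    note = c("product appearance", "product appearance",
             "composite: BQ reduction minus aldehyde absorptivity",
             "composite: BQ reduction minus aldehyde absorptivity",
             "pure BQ/hydroquinone difference")
  )
}

#' Convert an absorbance slope to a concentration rate
#'
#' `rate = dA/dt / (delta_eps * pathlength)`, returned in uM/s.
#'
#' @param dA_per_s Absorbance slope, AU/s.
#' @param delta_eps Difference extinction coefficient, M^-1 cm^-1 (> 0).
#' @param pathlength_cm Optical pathlength, cm.
#' @return Rate in uM/s.
#' @examples
#' absorbance_to_rate(0.01695, 16950)  # 1 uM/s
#' @export
absorbance_to_rate <- function(dA_per_s, delta_eps, pathlength_cm = 1) {
  check_positive(delta_eps, "delta_eps")
  check_scalar(pathlength_cm, "pathlength_cm")
  dA_per_s / (delta_eps * pathlength_cm) * 1e6
}

#' Write an analysis report as JSON
#'
#' Serializes a fitted object (via its [tidy()]/[glance()] methods) or a
#' plain list to JSON, stamping the package version. Numbers are written
#' at full precision.
#'
#' @param x A fitted object with `tidy()`/`glance()` methods, or a list.
#' @param path Output path.
#' @param seed Optional seed to record for provenance.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, seed = NULL) {
  body <- if (is.list(x) && is.null(attr(x, "class"))) {
    x
  } else {
    list(parameters = tidy(x), diagnostics = glance(x))
  }
  report <- list(
    generated_by = paste0("flavokin ",
                          as.character(utils::packageVersion("flavokin"))),
    seed = seed,
    results = body
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
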