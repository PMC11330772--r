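# Internal helpers: argument checking, unit conversion, information criteria.

stop_input <- function(msg, ...) {
  abort(msg, class = "flavokin_input_error", ...)
}

stop_fit <- function(msg, ...) {
  abort(msg, class = "flavokin_fit_error", ...)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_input(sprintf("`%s` must be numeric and non-missing.", name))
  }
  bad <- if (strict) any(x <= 0) else any(x < 0)
  if (bad) {
    stop_input(sprintf(
      "`%s` must be %s (got %s).", name,
      if (strict) "strictly positive" else "non-negative",
      paste(signif(head(x[if (strict) x <= 0 else x < 0], 3), 4), collapse = ", ")
    ))
  }
  invisible(x)
}

check_scalar <- function(x, name, strict = TRUE) {
  if (length(x) != 1L) stop_input(sprintf("`%s` must be a single value.", name))
  check_positive(x, name, strict = strict)
}

#' Corrected Akaike information criterion for a least-squares fit
#'
#' Computed from the residual sum of squares under the usual Gaussian
#' working likelihood: `AICc = n log(RSS/n) + 2k + 2k(k+1)/(n-k-1)`, where
#' `k` counts the fitted mean parameters plus the noise variance.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations.
#' @param n_par Number of fitted mean parameters (the variance is added
#'   internally).
#' @return A single numeric AICc value; `Inf` when `n <= n_par + 2`.
#' @export
aicc_from_rss <- function(rss, n, n_par) {
  k <- n_par + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Convert an oxygen gas-mixture percentage to dissolved concentration
#'
#' Assays equilibrated with an O2/N2 gas mixture are usually reported as
#' percent O2. Dissolved concentration follows Henry's law, scaled so that
#' air saturation (21% O2) corresponds to `air_sat_uM`. The default
#' 258 uM is the air-saturation value for dilute aqueous buffer at 25 C;
#' it must be adjusted for other temperatures or ionic strengths.
#'
#' @param percent_o2 Percent O2 in the equilibrating gas (0-100).
#' @param air_sat_uM Dissolved O2 (uM) at 21% O2 saturation.
#' @return Dissolved O2 concentration in uM.
#' @examples
#' percent_o2_to_uM(c(4, 10, 21, 44, 100))
#' @export
percent_o2_to_uM <- function(percent_o2, air_sat_uM = 258) {
  check_positive(percent_o2, "percent_o2", strict = FALSE)
  check_scalar(air_sat_uM, "air_sat_uM")
  percent_o2 / 21 * air_sat_uM
}

# kcat [s^-1] over Km [uM] reported as s^-1 mM^-1 (factor 1000 at the
# reporting boundary; concentrations stay in uM internally).
efficiency_s_mM <- function(kcat, Km_uM) 1000 * kcat / Km_uM

# Deterministic noise application. `seed` is always an explicit argument;
# no global RNG state is touched.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
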