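# Secondary transient-state analysis: observed stopped-flow rate constants
# versus ligand concentration for the reductive half-reaction (hyperbolic),
# the oxidative half-reaction (linear) and dead-end ligand binding (linear).

#' Assemble a kobs-vs-concentration series
#'
#' Observed pseudo-first-order rate constants from stopped-flow transients,
#' averaged over replicates, as a function of the varied ligand
#' concentration. The `role` determines which secondary model applies:
#' reductant (hyperbolic), electron acceptor (linear reoxidation) or
#' dead-end ligand (linear binding).
#'
#' @param conc_uM Ligand concentration, uM.
#' @param kobs_per_s Observed rate constant, s^-1.
#' @param se Optional standard error of each kobs, s^-1.
#' @param role One of `"reductant"`, `"electron_acceptor"`,
#'   `"dead_end_ligand"`.
#' @param enzyme,ligand,temperature_C Metadata attributes.
#' @return A tibble with columns `conc_uM`, `kobs_per_s`, `se`, and a
#'   `role` attribute.
#' @export
kobs_series <- function(conc_uM, kobs_per_s, se = NA_real_,
                        role = c("reductant", "electron_acceptor",
                                 "dead_end_ligand"),
                        enzyme = NA_character_, ligand = NA_character_,
                        temperature_C = NA_real_) {
  role <- match.arg(role)
  check_positive(conc_uM, "conc_uM")
  check_positive(kobs_per_s, "kobs_per_s")
  out <- tibble(conc_uM = as.numeric(conc_uM),
                kobs_per_s = as.numeric(kobs_per_s),
                se = as.numeric(se))
  attr(out, "role") <- role
  attr(out, "meta") <- list(enzyme = enzyme, ligand = ligand,
                            temperature_C = temperature_C)
  out
}

series_role <- function(series, expected, fn) {
  role <- attr(series, "role")
  if (!is.null(role) && role != expected) {
    warn(sprintf("`%s()` expects a series with role '%s' (got '%s').",
                 fn, expected, role))
  }
  invisible(series)
}

#' Fit the hyperbolic reduction model to a kobs series
#'
#' Least-squares fit of `kobs = kred * A / (Kd + A) + krev` to observed
#' flavin-reduction rate constants. `kred` is the limiting reduction rate,
#' `Kd` the alcohol dissociation constant and `krev` the reverse
#' hydride-transfer rate. When the 95% confidence interval of `krev`
#' includes zero the fit is flagged `krev_zero`, the usual situation for an
#' effectively irreversible hydride transfer. When the largest observed
#' kobs does not reach 70% of the fitted `kred`, saturation was not
#' approached and `Kd` is flagged unreliable.
#'
#' @param series A kobs series (see [kobs_series()]) with at least 4
#'   distinct concentrations.
#' @param fix_krev_zero If `TRUE`, constrain `krev = 0`.
#' @return Object of class `reduction_fit`; `tidy()` includes the
#'   reduction efficiency `kred/Kd` in s^-1 mM^-1.
#' @export
fit_reduction <- function(series, fix_krev_zero = FALSE) {
  series <- as_tibble(series)
  series_role(series, "reductant", "fit_reduction")
  if (n_distinct(series$conc_uM) < 4) {
    stop_input("Hyperbolic reduction fits need >= 4 distinct concentrations.")
  }
  kmax <- max(series$kobs_per_s)
  half <- approx(series$kobs_per_s, series$conc_uM, xout = kmax / 2,
                 ties = "ordered")$y
  start <- list(kred = kmax * 1.2,
                Kd = if (is.finite(half) && half > 0) half else median(series$conc_uM),
                krev = min(series$kobs_per_s) / 2)
  if (fix_krev_zero) {
    formula <- kobs_per_s ~ kred * conc_uM / (Kd + conc_uM)
    start$krev <- NULL
    lower <- c(1e-9, 1e-9)
  } else {
    formula <- kobs_per_s ~ kred * conc_uM / (Kd + conc_uM) + krev
    lower <- c(1e-9, 1e-9, 0)
  }
  fit <- fit_one_nls(series, formula, start, lower)
  if (is.null(fit)) {
    for (i in seq_len(5)) {
      st <- with_seed_(2000L + i,
                       lapply(start, function(v) v * exp(rnorm(1, 0, 0.5))))
      fit <- fit_one_nls(series, formula, st, lower)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit)) stop_fit("Hyperbolic reduction fit did not converge.")

  est <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  krev <- if (fix_krev_zero) 0 else est[["krev"]]
  krev_se <- if (fix_krev_zero) 0 else se[["krev"]]
  flags <- character(0)
  if (fix_krev_zero || krev - 1.96 * krev_se <= 0) flags <- c(flags, "krev_zero")
  if (kmax < 0.7 * est[["kred"]]) {
    flags <- c(flags, "saturation_not_reached")
    warn(paste("Largest observed kobs is below 70% of fitted kred;",
               "Kd (and kred) are poorly determined - only kred/Kd is reliable."))
  }

  structure(
    list(
      params = tibble(
        term = c("kred", "Kd_alcohol", "krev"),
        estimate = c(est[["kred"]], est[["Kd"]], krev),
        std.error = c(se[["kred"]], se[["Kd"]], krev_se),
        units = c("s^-1", "uM", "s^-1")
      ),
      eff_red = efficiency_s_mM(est[["kred"]], est[["Kd"]]),
      flags = flags,
      data = series,
      fitted = predict(fit),
      rss = sum(resid(fit)^2),
      n = nrow(series),
      nls = fit
    ),
    class = "reduction_fit"
  )
}

#' @export
print.reduction_fit <- function(x, ...) {
  cat("Reductive half-reaction fit: kobs = kred*A/(Kd + A) + krev\n")
  p <- x$params
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-10s %10.4g +/- %.3g %s\n",
                p$term[i], p$estimate[i], p$std.error[i], p$units[i]))
  }
  cat(sprintf("  kred/Kd = %.4g s^-1 mM^-1\n", x$eff_red))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.reduction_fit <- function(x, ...) {
  bind_rows(x$params,
            tibble(term = "eff_red", estimate = x$eff_red,
                   std.error = NA_real_, units = "s^-1 mM^-1"))
}

#' @export
glance.reduction_fit <- function(x, ...) {
  tibble(nobs = x$n, rss = x$rss,
         sigma = sqrt(x$rss / max(x$n - 3, 1)),
         flags = paste(x$flags, collapse = ";"))
}

# Weighted (1/se^2 when available) straight-line fit of kobs on conc in mM.
linear_kobs_fit <- function(series) {
  d <- mutate(as_tibble(series), conc_mM = .data$conc_uM / 1000)
  w <- if (all(is.finite(d$se)) && all(d$se > 0)) 1 / d$se^2 else NULL
  fit <- lm(kobs_per_s ~ conc_mM, data = d, weights = w)
  # noiseless fixtures trigger summary.lm's "perfect fit" warning
  s <- suppressWarnings(summary(fit)$coefficients)
  list(fit = fit,
       slope = s["conc_mM", "Estimate"], slope_se = s["conc_mM", "Std. Error"],
       intercept = s["(Intercept)", "Estimate"],
       intercept_se = s["(Intercept)", "Std. Error"],
       rss = sum(resid(fit)^2), n = nrow(d))
}

#' Fit the linear reoxidation model to a kobs series
#'
#' Linear regression of observed flavin-reoxidation rate constants on
#' electron-acceptor concentration, `kobs = app_kox * [acceptor] + krev`.
#' The slope is the apparent second-order reoxidation constant (s^-1
#' mM^-1); the y-intercept `krev` is reported as measured, without a
#' mechanistic interpretation. Weighted by `1/se^2` when per-point errors
#' are supplied.
#'
#' @param series A kobs series with role `"electron_acceptor"` and at
#'   least 3 distinct concentrations.
#' @return Object of class `reoxidation_fit`.
#' @export
fit_reoxidation <- function(series) {
  series <- as_tibble(series)
  series_role(series, "electron_acceptor", "fit_reoxidation")
  if (n_distinct(series$conc_uM) < 3) {
    stop_input("Linear reoxidation fits need >= 3 distinct concentrations.")
  }
  lf <- linear_kobs_fit(series)
  structure(
    list(
      params = tibble(
        term = c("app_kox", "krev_intercept"),
        estimate = c(lf$slope, lf$intercept),
        std.error = c(lf$slope_se, lf$intercept_se),
        units = c("s^-1 mM^-1", "s^-1")
      ),
      data = series, rss = lf$rss, n = lf$n, lm = lf$fit
    ),
    class = "reoxidation_fit"
  )
}

#' @export
print.reoxidation_fit <- function(x, ...) {
  cat("Oxidative half-reaction fit: kobs = app_kox*[acceptor] + krev\n")
  p <- x$params
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-15s %10.4g +/- %.3g %s\n",
                p$term[i], p$estimate[i], p$std.error[i], p$units[i]))
  }
  invisible(x)
}

#' @export
tidy.reoxidation_fit <- function(x, ...) x$params

#' @export
glance.reoxidation_fit <- function(x, ...) {
  tibble(nobs = x$n, rss = x$rss, sigma = sqrt(x$rss / max(x$n - 2, 1)))
}

#' Fit one-step binding kinetics to a kobs series
#'
#' Linear regression of the observed relaxation rate on ligand
#' concentration, `kobs = kon * [L] + koff`, for dead-end ligand (e.g.
#' product-analogue benzoic acid) binding. The equilibrium dissociation
#' constant is derived as `Kd = koff / kon` with its standard error
#' propagated to first order (relative variances add). When the 95%
#' confidence interval of `koff` includes zero, no dissociation was
#' detected under the assay conditions and `Kd` is reported as `NA` with
#' the flag `koff_nd` - an explicit "not detected" sentinel, never zero.
#'
#' @param series A kobs series with role `"dead_end_ligand"`.
#' @return Object of class `binding_fit` with `kon` (s^-1 mM^-1), `koff`
#'   (s^-1) and `Kd_acid` (uM, `NA` when not detected).
#' @export
fit_binding_kinetics <- function(series) {
  series <- as_tibble(series)
  series_role(series, "dead_end_ligand", "fit_binding_kinetics")
  if (n_distinct(series$conc_uM) < 3) {
    stop_input("Linear binding fits need >= 3 distinct concentrations.")
  }
  lf <- linear_kobs_fit(series)
  if (lf$intercept < -2 * lf$intercept_se) {
    stop_fit(paste(
      "Fitted koff is negative beyond 2 standard errors; the series is",
      "inconsistent with one-step binding kinetics."
    ))
  }
  kon <- lf$slope; koff <- lf$intercept
  nd <- koff - 1.96 * lf$intercept_se <= 0
  if (nd) {
    Kd <- NA_real_; Kd_se <- NA_real_
  } else {
    Kd <- koff / kon * 1000   # s^-1 over s^-1 mM^-1 -> mM -> uM
    Kd_se <- Kd * sqrt((lf$intercept_se / koff)^2 + (lf$slope_se / kon)^2)
  }
  structure(
    list(
      params = tibble(
        term = c("kon", "koff", "Kd_acid"),
        estimate = c(kon, koff, Kd),
        std.error = c(lf$slope_se, lf$intercept_se, Kd_se),
        units = c("s^-1 mM^-1", "s^-1", "uM")
      ),
      koff_nd = nd,
      data = series, rss = lf$rss, n = lf$n, lm = lf$fit
    ),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Ligand-binding kinetics fit: kobs = kon*[L] + koff\n")
  p <- x$params
  for (i in seq_len(nrow(p))) {
    val <- if (is.na(p$estimate[i])) "nd" else
      sprintf("%10.4g +/- %.3g", p$estimate[i], p$std.error[i])
    cat(sprintf("  %-8s %s %s\n", p$term[i], val, p$units[i]))
  }
  if (x$koff_nd) cat("  koff not distinguishable from 0: no dissociation detected.\n")
  invisible(x)
}

#' @export
tidy.binding_fit <- function(x, ...) x$params

#' @export
glance.binding_fit <- function(x, ...) {
  tibble(nobs = x$n, rss = x$rss, koff_nd = x$koff_nd)
}
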