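# One-site isothermal titration calorimetry: Wiseman isotherm simulation
# under the perfusion (constant cell volume) mixing convention, nonlinear
# fitting, and the standard thermodynamic relations.

#' Describe an ITC titration experiment
#'
#' @param cell_conc_uM Macromolecule concentration in the cell, uM.
#' @param syringe_conc_uM Ligand concentration in the syringe, uM.
#' @param cell_volume_uL Working cell volume, uL (default 200, typical of
#'   a low-volume titration calorimeter).
#' @param injection_volumes_uL Vector of injection volumes, uL.
#' @param temperature_K Assay temperature, K.
#' @param heats_ucal Optional observed/simulated per-injection heats, ucal.
#' @return Object of class `itc_experiment`.
#' @export
itc_experiment <- function(cell_conc_uM, syringe_conc_uM,
                           cell_volume_uL = 200,
                           injection_volumes_uL = rep(2, 19),
                           temperature_K = 298.15,
                           heats_ucal = NULL) {
  check_scalar(cell_conc_uM, "cell_conc_uM")
  check_scalar(syringe_conc_uM, "syringe_conc_uM")
  check_scalar(cell_volume_uL, "cell_volume_uL")
  check_positive(injection_volumes_uL, "injection_volumes_uL")
  check_scalar(temperature_K, "temperature_K")
  if (!is.null(heats_ucal) &&
      length(heats_ucal) != length(injection_volumes_uL)) {
    stop_input("`heats_ucal` must have one value per injection.")
  }
  structure(
    list(cell_conc_uM = cell_conc_uM, syringe_conc_uM = syringe_conc_uM,
         cell_volume_uL = cell_volume_uL,
         injection_volumes_uL = injection_volumes_uL,
         temperature_K = temperature_K, heats_ucal = heats_ucal),
    class = "itc_experiment"
  )
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf(
    "ITC titration: cell %.3g uM (%.0f uL), syringe %.3g uM, %d injections, %.2f K\n",
    x$cell_conc_uM, x$cell_volume_uL, x$syringe_conc_uM,
    length(x$injection_volumes_uL), x$temperature_K))
  if (!is.null(x$heats_ucal)) cat("  heats recorded\n")
  invisible(x)
}

# Running concentrations and bound ligand across a titration.
itc_titration_state <- function(Ka_per_M, n, exp) {
  V0 <- exp$cell_volume_uL
  Kd_uM <- 1e6 / Ka_per_M
  nI <- length(exp$injection_volumes_uL)
  M <- X <- B <- numeric(nI)
  m <- exp$cell_conc_uM; x <- 0
  for (i in seq_len(nI)) {
    v <- exp$injection_volumes_uL[i]
    d <- 1 - v / V0
    m <- m * d
    x <- x * d + exp$syringe_conc_uM * v / V0
    sites <- n * m
    b <- sites + x + Kd_uM
    bound <- (b - sqrt(b^2 - 4 * sites * x)) / 2
    if (bound < -1e-9 || bound > min(sites, x) + 1e-6) {
      stop_fit("Unphysical bound fraction in the binding polynomial.")
    }
    M[i] <- m; X[i] <- x; B[i] <- max(bound, 0)
  }
  list(M = M, X = X, B = B)
}

#' Simulate per-injection heats of a one-site titration
#'
#' Per-injection heat from the single-site binding polynomial: after each
#' injection both species are diluted by `(1 - v/V0)` (perfusion
#' convention, cell volume constant), the ligand is topped up by the
#' injected amount, and the bound concentration is the root of the usual
#' quadratic. The heat of injection `i` is
#' `dH * V0 * (B_i - (1 - v/V0) * B_{i-1})`, i.e. the enthalpy of the
#' newly formed complex after accounting for the complex displaced by
#' dilution.
#'
#' @param Ka_per_M Association constant, M^-1.
#' @param dH_kcal_mol Binding enthalpy, kcal/mol.
#' @param n Stoichiometry (sites per macromolecule).
#' @param exp An [itc_experiment()].
#' @return Numeric vector of per-injection heats, ucal.
#' @examples
#' ex <- itc_experiment(6, 50)
#' one_site_heats(1 / 0.05e-6, -21.4, 1, ex)
#' @export
one_site_heats <- function(Ka_per_M, dH_kcal_mol, n, exp) {
  stopifnot(inherits(exp, "itc_experiment"))
  check_scalar(Ka_per_M, "Ka_per_M")
  check_scalar(n, "n")
  st <- itc_titration_state(Ka_per_M, n, exp)
  d <- 1 - exp$injection_volumes_uL / exp$cell_volume_uL
  B_prev <- c(0, head(st$B, -1))
  # ucal = kcal/mol * uL*1e-6 L * uM*1e-6 M * 1e9 ucal/kcal
  dH_kcal_mol * exp$cell_volume_uL * (st$B - d * B_prev) * 1e-3
}

#' Thermodynamic relations for a one-site interaction
#'
#' `dG = R T ln(Kd)` (Kd in molar) and `-TdS = dG - dH`, with
#' `R = 1.987e-3 kcal mol^-1 K^-1`. These are the standard identities
#' linking the fitted association constant and enthalpy to the full
#' thermodynamic signature.
#'
#' @param Kd_uM Dissociation constant, uM.
#' @param dH_kcal_mol Binding enthalpy, kcal/mol.
#' @param temperature_K Temperature, K (default 298.15).
#' @return Tibble with `dG_kcal_mol` and `TdS_neg_kcal_mol` (-TdS).
#' @examples
#' thermo_relations(27.1, -25.1)
#' @export
thermo_relations <- function(Kd_uM, dH_kcal_mol, temperature_K = 298.15) {
  check_positive(Kd_uM, "Kd_uM")
  R <- 1.987e-3
  dG <- R * temperature_K * log(Kd_uM * 1e-6)
  tibble(dG_kcal_mol = dG, TdS_neg_kcal_mol = dG - dH_kcal_mol)
}

#' Fit the one-site binding model to an ITC titration
#'
#' Nonlinear least squares on the per-injection heats with parameters
#' `log10(Ka)`, `dH` and `n`, started from a grid of association constants
#' (c-values from 0.1 to 10^4) with `dH` and `n` seeded from the initial
#' heats and the equivalence point. The derived quantities `Kd`, `dG` and
#' `-TdS` follow from [thermo_relations()]. A low-c warning (`c < 1`,
#' shallow isotherm, Ka and n poorly separable) and a high-c warning
#' (`c > 1000`, sigmoid sharper than the injection spacing resolves, Ka
#' effectively a lower bound) are attached as flags.
#'
#' @param exp An [itc_experiment()] carrying `heats_ucal`.
#' @param discard_first Drop the first injection before fitting (common
#'   practice against syringe diffusion artifacts; off by default).
#' @return Object of class `itc_fit`; `tidy()` returns fitted and derived
#'   parameters with units.
#' @export
fit_itc <- function(exp, discard_first = FALSE) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (is.null(exp$heats_ucal)) stop_input("`exp` carries no heats to fit.")
  keep <- seq_along(exp$heats_ucal)
  if (discard_first) keep <- keep[-1]
  if (length(keep) < 8) {
    stop_input("Need at least 8 informative injections for a one-site fit.")
  }
  y <- exp$heats_ucal

  predict_heats <- function(log10Ka, dH, n) {
    one_site_heats(10^log10Ka, dH, n, exp)
  }
  obj <- function(p) {
    h <- tryCatch(predict_heats(p[1], p[2], p[3]), error = function(e) NULL)
    if (is.null(h) || any(!is.finite(h))) return(1e12)
    sum((y[keep] - h[keep])^2)
  }

  # equivalence point ~ where |heat| has dropped to half its initial value
  mol_ratio <- cumsum(exp$injection_volumes_uL * exp$syringe_conc_uM) /
    (exp$cell_volume_uL * exp$cell_conc_uM)
  h_abs <- abs(y)
  below <- which(h_abs < h_abs[1] / 2)
  n0 <- if (length(below)) mol_ratio[below[1]] else 1
  n0 <- min(max(n0, 0.2), 5)
  # ucal over injected nmol gives kcal/mol directly
  dH0 <- y[1] * 1000 / (exp$injection_volumes_uL[1] * exp$syringe_conc_uM)

  c_grid <- c(0.1, 1, 10, 100, 1e3, 1e4)
  starts <- lapply(c_grid, function(cv) {
    c(log10(cv / (n0 * exp$cell_conc_uM * 1e-6)), dH0, n0)
  })
  fits <- lapply(starts, function(s) {
    o <- tryCatch(
      optim(s, obj, method = "L-BFGS-B",
            lower = c(2, -500, 0.05), upper = c(12, 500, 10),
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    o
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) stop_fit("One-site ITC fit did not converge.")
  vals <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(vals)]]
  p <- best$par

  # polish + standard errors via nls on the same parameterization
  dfit <- tibble(idx = keep, y = y[keep])
  nls_fit <- fit_one_nls(
    dfit,
    y ~ one_site_heats(10^log10Ka, dH, n, exp)[idx],
    list(log10Ka = p[1], dH = p[2], n = p[3]),
    c(2, -500, 0.05)
  )
  if (!is.null(nls_fit) && sum(resid(nls_fit)^2) <= best$value + 1e-9) {
    p <- coef(nls_fit)
    se <- summary(nls_fit)$coefficients[, "Std. Error"]
  } else {
    se <- rep(NA_real_, 3)
  }
  Ka <- 10^p[[1]]; dH <- p[[2]]; n_fit <- p[[3]]
  Kd_uM <- 1e6 / Ka
  th <- thermo_relations(Kd_uM, dH, exp$temperature_K)
  c_value <- n_fit * Ka * exp$cell_conc_uM * 1e-6

  flags <- character(0)
  if (c_value < 1) {
    flags <- c(flags, "low_c")
    warn(sprintf("Wiseman c = %.2g < 1: shallow isotherm, Ka and n are poorly separable.", c_value))
  }
  if (c_value > 1000) {
    flags <- c(flags, "high_c")
    warn(sprintf("Wiseman c = %.3g > 1000: isotherm is step-like, fitted Ka is effectively a lower bound.", c_value))
  }

  fitted <- predict_heats(log10(Ka), dH, n_fit)
  rss <- sum((y[keep] - fitted[keep])^2)
  # dH standard error on the natural scale; Ka SE via delta method
  se_named <- if (!all(is.na(se))) se else setNames(rep(NA_real_, 3),
                                                    c("log10Ka", "dH", "n"))
  Ka_se <- if (is.finite(se_named[["log10Ka"]])) {
    Ka * log(10) * se_named[["log10Ka"]]
  } else NA_real_

  structure(
    list(
      params = tibble(
        term = c("Ka", "dH", "n", "Kd", "dG", "TdS_neg", "c_value"),
        estimate = c(Ka, dH, n_fit, Kd_uM, th$dG_kcal_mol,
                     th$TdS_neg_kcal_mol, c_value),
        std.error = c(Ka_se, se_named[["dH"]], se_named[["n"]],
                      rep(NA_real_, 4)),
        units = c("M^-1", "kcal/mol", "", "uM", "kcal/mol", "kcal/mol", "")
      ),
      flags = flags, fitted = fitted, rss = rss,
      n_injections = length(keep), exp = exp
    ),
    class = "itc_fit"
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-site ITC fit\n")
  p <- x$params
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-8s %12.5g %s %s\n", p$term[i], p$estimate[i], p$units[i],
                if (is.finite(p$std.error[i]))
                  sprintf("(+/- %.3g)", p$std.error[i]) else ""))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.itc_fit <- function(x, ...) x$params

#' @export
glance.itc_fit <- function(x, ...) {
  tibble(nobs = x$n_injections, rss = x$rss,
         flags = paste(x$flags, collapse = ";"))
}
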