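# Global analysis of time-resolved absorbance matrices by variable
# projection: for candidate first-order rate constants the species spectra
# are the linear least-squares solution, so the nonlinear search runs over
# the one or two rates only. This is the standard separable treatment of
# stopped-flow photodiode-array data.

#' Construct a time-resolved spectra matrix
#'
#' @param times Strictly increasing acquisition times, s (non-negative).
#' @param wavelengths Strictly increasing wavelengths, nm.
#' @param absorbance Numeric matrix, `length(times)` rows by
#'   `length(wavelengths)` columns, in AU.
#' @return An object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(times, wavelengths, absorbance) {
  absorbance <- as.matrix(absorbance)
  if (any(times < 0)) stop_input("`times` must be non-negative.")
  if (is.unsorted(times, strictly = TRUE)) {
    stop_input("`times` must be strictly increasing.")
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop_input("`wavelengths` must be strictly increasing.")
  }
  if (!all(dim(absorbance) == c(length(times), length(wavelengths)))) {
    stop_input(sprintf(
      "`absorbance` must be %d x %d (times x wavelengths); got %d x %d.",
      length(times), length(wavelengths), nrow(absorbance), ncol(absorbance)
    ))
  }
  if (!all(is.finite(absorbance))) {
    stop_input("`absorbance` must contain only finite values.")
  }
  structure(list(times = as.numeric(times),
                 wavelengths = as.numeric(wavelengths),
                 absorbance = absorbance),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("Time-resolved spectra: %d times (%.4g-%.4g s) x %d wavelengths (%g-%g nm)\n",
              length(x$times), min(x$times), max(x$times),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Tidy a spectra matrix into long format
#' @param x A `spectra_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `time_s`, `wavelength_nm`, `absorbance`.
#' @export
tidy.spectra_matrix <- function(x, ...) {
  tibble(
    time_s = rep(x$times, times = length(x$wavelengths)),
    wavelength_nm = rep(x$wavelengths, each = length(x$times)),
    absorbance = as.vector(x$absorbance)
  )
}

#' Concentration-fraction profiles of sequential first-order schemes
#'
#' Closed-form solutions of the irreversible chains A -> B (one rate) and
#' A -> B -> C (two rates) starting from pure A. For near-equal rates the
#' two-step intermediate uses the confluent limit `k1 * t * exp(-k1 * t)`,
#' which the general two-exponential expression approaches as `k2 -> k1`.
#'
#' @param rates Vector of 1 (A->B) or 2 (A->B->C) first-order rate
#'   constants, s^-1.
#' @param times Time points, s.
#' @return Matrix `length(times)` x `n_species` of concentration fractions
#'   (rows sum to 1), columns named `A`, `B` (, `C`).
#' @examples
#' species_profiles(100, c(0, log(2) / 100))
#' @export
species_profiles <- function(rates, times) {
  check_positive(rates, "rates")
  if (!length(rates) %in% 1:2) stop_input("`rates` must have length 1 or 2.")
  check_positive(times, "times", strict = FALSE)
  if (length(rates) == 1) {
    cA <- exp(-rates[1] * times)
    return(cbind(A = cA, B = 1 - cA))
  }
  k1 <- rates[1]; k2 <- rates[2]
  cA <- exp(-k1 * times)
  if (abs(k1 - k2) < 1e-8 * max(k1, k2)) {
    cB <- k1 * times * exp(-k1 * times)
  } else {
    cB <- k1 / (k2 - k1) * (exp(-k1 * times) - exp(-k2 * times))
  }
  cbind(A = cA, B = cB, C = 1 - cA - cB)
}

# RSS of the separable model at given rates; spectra solved by projection.
varpro_solve <- function(rates, data) {
  C <- species_profiles(rates, data$times)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) return(NULL)
  S <- qr.coef(qrC, data$absorbance)
  R <- data$absorbance - C %*% S
  list(C = C, S = S, rss = sum(R^2), resid = R)
}

varpro_rss <- function(log_rates, data) {
  sol <- varpro_solve(exp(log_rates), data)
  if (is.null(sol)) return(1e12)
  sol$rss
}

# Numerical Hessian of the profiled RSS on the log-rate scale.
rss_hessian <- function(log_rates, data, h = 1e-4) {
  p <- length(log_rates)
  H <- matrix(NA_real_, p, p)
  f0 <- varpro_rss(log_rates, data)
  for (i in seq_len(p)) {
    for (j in seq_len(i)) {
      ei <- ej <- rep(0, p); ei[i] <- h; ej[j] <- h
      if (i == j) {
        H[i, i] <- (varpro_rss(log_rates + ei, data) - 2 * f0 +
                      varpro_rss(log_rates - ei, data)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (varpro_rss(log_rates + ei + ej, data) -
             varpro_rss(log_rates + ei - ej, data) -
             varpro_rss(log_rates - ei + ej, data) +
             varpro_rss(log_rates - ei - ej, data)) / (4 * h^2)
      }
    }
  }
  H
}

#' Global fit of a sequential first-order scheme to a spectra matrix
#'
#' Fits A -> B (`n_steps = 1`) or A -> B -> C (`n_steps = 2`) to all
#' wavelengths simultaneously by variable projection: for trial rate
#' constants the species spectra are the exact linear least-squares
#' solution, and the rates are optimized over this profiled objective
#' (coarse log-spaced scan followed by quasi-Newton refinement). Species
#' spectra are not constrained non-negative by default - difference
#' spectra legitimately dip below zero - but `nonneg = TRUE` activates a
#' clipped alternating refinement.
#'
#' @param data A [spectra_matrix()].
#' @param n_steps 1 or 2 kinetic steps (2 or 3 species).
#' @param nonneg Constrain species spectra to be non-negative.
#' @return Object of class `global_fit` with elements `rates` (tibble of
#'   estimates and standard errors, ordered k1 >= k2), `species_spectra`
#'   (long tibble), `residual_rms` (AU), `aicc`, `singular_values`,
#'   `flags`.
#' @export
global_fit <- function(data, n_steps = 1, nonneg = FALSE) {
  stopifnot(inherits(data, "spectra_matrix"))
  n_species <- n_steps + 1
  if (length(data$times) < 3 * n_species) {
    stop_input(sprintf("Need at least %d time points for a %d-species fit.",
                       3 * n_species, n_species))
  }
  tpos <- data$times[data$times > 0]
  if (length(tpos) == 0) stop_input("All times are zero; nothing to fit.")
  lo <- log(0.05 / max(data$times))
  hi <- log(20 / min(tpos))

  if (n_steps == 1) {
    grid <- seq(lo, hi, length.out = 80)
    rss <- vapply(grid, function(g) varpro_rss(g, data), numeric(1))
    best <- grid[which.min(rss)]
    opt <- nlminb(best, varpro_rss, data = data, lower = lo - 2, upper = hi + 2,
                  control = list(rel.tol = 1e-14, x.tol = 1e-12))
    log_rates <- opt$par
  } else {
    g <- seq(lo, hi, length.out = 24)
    grid <- expand.grid(g1 = g, g2 = g)
    grid <- grid[grid$g1 >= grid$g2, ]
    rss <- mapply(function(a, b) varpro_rss(c(a, b), data), grid$g1, grid$g2)
    st <- as.numeric(grid[which.min(rss), ])
    opt <- nlminb(st, varpro_rss, data = data,
                  lower = rep(lo - 2, 2), upper = rep(hi + 2, 2),
                  control = list(rel.tol = 1e-14, x.tol = 1e-12))
    log_rates <- opt$par
    # enforce the reporting convention k1 >= k2 (the swapped solution is
    # an equivalent optimum with remixed spectra)
    if (exp(log_rates[1]) < exp(log_rates[2])) log_rates <- rev(log_rates)
  }
  if (opt$convergence != 0 && !is.finite(opt$objective)) {
    stop_fit("Global fit did not converge; inspect the rate scan.")
  }
  rates <- exp(log_rates)
  sol <- varpro_solve(rates, data)
  if (is.null(sol)) {
    stop_fit("Profile basis is rank deficient at the optimum (degenerate rates).")
  }
  if (nonneg) {
    S <- pmax(sol$S, 0)
    sol$S <- S
    sol$resid <- data$absorbance - sol$C %*% S
    sol$rss <- sum(sol$resid^2)
  }

  N <- length(data$absorbance)
  n_lin <- n_species * length(data$wavelengths)
  aicc <- aicc_from_rss(sol$rss, N, length(rates) + n_lin)

  # standard errors from the curvature of the profiled objective
  se <- rep(NA_real_, length(rates))
  sigma2 <- sol$rss / max(N - length(rates) - n_lin, 1)
  H <- rss_hessian(log_rates, data)
  cov_log <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
  if (!is.null(cov_log) && all(diag(cov_log) >= 0)) {
    se <- rates * sqrt(diag(cov_log))
  }

  # flag unidentifiable second steps: either the rates coalesce or a
  # species contributes next to nothing to the signal
  flags <- character(0)
  contrib <- vapply(seq_len(n_species), function(i) {
    sd(sol$C[, i]) * sqrt(sum(sol$S[i, ]^2))
  }, numeric(1))
  if (n_steps == 2) {
    if (rates[1] / rates[2] < 1.05 || min(contrib) / max(contrib) < 1e-3) {
      flags <- c(flags, "k2_unidentifiable")
      warn("Second kinetic step is unidentifiable (coalescent rates or degenerate species spectrum).")
    }
  }
  # no kinetic evolution: all species spectra coincide (rank-1 data)
  scale_au <- max(1e-12, max(abs(data$absorbance)))
  spread <- max(apply(sol$S, 2, function(col) diff(range(col))))
  if (max(contrib) < 1e-10 * scale_au || spread < 1e-7 * scale_au) {
    flags <- c(flags, "zero_amplitude")
  }

  sv <- svd(data$absorbance, nu = 0, nv = 0)$d
  labels <- c("A", "B", "C")[seq_len(n_species)]
  spectra <- tibble(
    wavelength_nm = rep(data$wavelengths, each = n_species),
    species = rep(labels, times = length(data$wavelengths)),
    epsilon_like = as.vector(sol$S)
  )

  structure(
    list(
      n_steps = n_steps, n_species = n_species,
      rates = tibble(term = paste0("k", seq_along(rates)),
                     estimate = rates, std.error = se, units = "s^-1"),
      species_spectra = spectra,
      concentrations = sol$C,
      residual_rms = sqrt(sol$rss / N),
      rss = sol$rss, aicc = aicc,
      singular_values = sv,
      flags = flags,
      data = data
    ),
    class = "global_fit"
  )
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Global spectral fit: %d-step scheme (%s)\n", x$n_steps,
              paste(c("A", "B", "C")[seq_len(x$n_species)], collapse = " -> ")))
  r <- x$rates
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %s = %.5g +/- %.3g s^-1\n", r$term[i], r$estimate[i],
                r$std.error[i]))
  }
  cat(sprintf("  residual rms %.3g AU, AICc %.2f\n", x$residual_rms, x$aicc))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.global_fit <- function(x, ...) x$rates

#' @export
glance.global_fit <- function(x, ...) {
  tibble(n_steps = x$n_steps, rss = x$rss, residual_rms = x$residual_rms,
         aicc = x$aicc, flags = paste(x$flags, collapse = ";"))
}

#' Estimate the number of spectrally distinct species
#'
#' Counts singular values of the absorbance matrix above a noise floor of
#' `multiplier * noise_sd * sqrt(max(n_times, n_wavelengths))`, the usual
#' order of the largest singular value of an i.i.d. Gaussian noise matrix.
#' With `noise_sd = 0` a relative machine tolerance is used, so the exact
#' algebraic rank is returned for noiseless data.
#'
#' @param data A [spectra_matrix()].
#' @param noise_sd Per-element noise standard deviation, AU.
#' @param multiplier Safety factor on the noise floor (default 5).
#' @return Integer estimated rank (number of species).
#' @export
estimate_rank <- function(data, noise_sd = 0, multiplier = 5) {
  stopifnot(inherits(data, "spectra_matrix"))
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  sv <- svd(data$absorbance, nu = 0, nv = 0)$d
  floor_noise <- multiplier * noise_sd * sqrt(max(dim(data$absorbance)))
  floor_mach <- max(sv) * max(dim(data$absorbance)) * .Machine$double.eps * 100
  sum(sv > max(floor_noise, floor_mach))
}

#' Select between one-step and two-step spectral schemes
#'
#' Fits both A -> B and A -> B -> C by [global_fit()] and prefers the
#' two-step scheme only when its AICc improves on the one-step scheme by
#' more than `aicc_margin` *and* the singular-value rank estimate supports
#' a third species. Degenerate (rank-1, no-evolution) matrices return the
#' one-step fit with a zero-amplitude flag.
#'
#' @param data A [spectra_matrix()].
#' @param noise_sd Noise level for the rank estimate, AU.
#' @param aicc_margin Required AICc improvement (default 10).
#' @return List with `chosen` (1 or 2), `rank_estimate`, `fit_1`, `fit_2`
#'   (NULL if it failed), `delta_aicc`.
#' @export
select_step_model <- function(data, noise_sd = 0, aicc_margin = 10) {
  fit1 <- global_fit(data, 1)
  fit2 <- tryCatch(suppressWarnings(global_fit(data, 2)),
                   error = function(e) NULL)
  rank_est <- estimate_rank(data, noise_sd)
  delta <- if (is.null(fit2)) NA_real_ else fit1$aicc - fit2$aicc
  chosen <- if (!is.null(fit2) &&
                length(fit2$flags) == 0 &&
                isTRUE(delta > aicc_margin) &&
                rank_est >= 3) 2L else 1L
  list(chosen = chosen, rank_estimate = rank_est,
       fit_1 = fit1, fit_2 = fit2, delta_aicc = delta)
}

#' Fit exponentials to a single-wavelength stopped-flow trace
#'
#' Sum-of-exponentials least squares with offset,
#' `y(t) = c0 + sum_i a_i exp(-k_i t)`, for monochromator traces. The
#' rates come from a variable-projection search (amplitudes and offset
#' solved linearly) and standard errors from a full nonlinear refit at the
#' optimum. Rates are reported fastest first. A warning is issued when the
#' two rates of a biexponential are separated by less than a factor of 3,
#' where exponentials are strongly collinear.
#'
#' @param trace Data frame with columns `time_s` and `value` (>= 10 rows).
#' @param n_exp 1 or 2 exponential phases.
#' @return Object of class `mono_fit` with a `params` tibble (offset,
#'   amplitudes, rates, standard errors).
#' @export
monochromator_fit <- function(trace, n_exp = 1) {
  trace <- as_tibble(trace)
  if (!all(c("time_s", "value") %in% names(trace))) {
    stop_input("`trace` needs columns `time_s` and `value`.")
  }
  if (nrow(trace) < 10) stop_input("Need at least 10 time points.")
  if (!n_exp %in% 1:2) stop_input("`n_exp` must be 1 or 2.")
  t <- trace$time_s; y <- trace$value

  if (sd(y) < 1e-12 * max(1, abs(mean(y)))) {
    params <- tibble(
      term = c("offset", paste0("a", seq_len(n_exp)), paste0("k", seq_len(n_exp))),
      estimate = c(mean(y), rep(0, n_exp), rep(NA_real_, n_exp)),
      std.error = NA_real_
    )
    return(structure(list(params = params, flags = "zero_amplitude",
                          rss = 0, n = length(y), data = trace),
                     class = "mono_fit"))
  }

  basis_rss <- function(log_k) {
    X <- cbind(1, sapply(exp(log_k), function(k) exp(-k * t)))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) return(1e12)
    sum(qr.resid(qrX, y)^2)
  }
  tpos <- t[t > 0]
  lo <- log(0.05 / max(t)); hi <- log(20 / min(tpos))
  if (n_exp == 1) {
    grid <- seq(lo, hi, length.out = 80)
    best <- grid[which.min(vapply(grid, basis_rss, numeric(1)))]
    opt <- nlminb(best, basis_rss, lower = lo - 2, upper = hi + 2)
  } else {
    g <- seq(lo, hi, length.out = 24)
    grid <- expand.grid(g1 = g, g2 = g); grid <- grid[grid$g1 > grid$g2, ]
    rss <- mapply(function(a, b) basis_rss(c(a, b)), grid$g1, grid$g2)
    opt <- nlminb(as.numeric(grid[which.min(rss), ]), basis_rss,
                  lower = rep(lo - 2, 2), upper = rep(hi + 2, 2))
  }
  k <- sort(exp(opt$par), decreasing = TRUE)

  d <- tibble(t = t, y = y)
  if (n_exp == 1) {
    X <- cbind(1, exp(-k[1] * t))
    ab <- qr.solve(X, y)
    fit <- fit_one_nls(d, y ~ c0 + a1 * exp(-k1 * t),
                       list(c0 = ab[1], a1 = ab[2], k1 = k[1]),
                       c(-Inf, -Inf, 1e-12))
  } else {
    X <- cbind(1, exp(-k[1] * t), exp(-k[2] * t))
    ab <- qr.solve(X, y)
    fit <- fit_one_nls(d, y ~ c0 + a1 * exp(-k1 * t) + a2 * exp(-k2 * t),
                       list(c0 = ab[1], a1 = ab[2], a2 = ab[3],
                            k1 = k[1], k2 = k[2]),
                       c(-Inf, -Inf, -Inf, 1e-12, 1e-12))
  }
  if (is.null(fit)) stop_fit("Exponential trace fit did not converge.")
  est <- coef(fit); se <- summary(fit)$coefficients[, "Std. Error"]

  flags <- character(0)
  if (n_exp == 2 && est[["k1"]] / est[["k2"]] < 3) {
    flags <- c(flags, "rate_separation_lt_3x")
    warn("Biexponential rates are separated by less than 3x; amplitudes and rates are strongly correlated.")
  }
  structure(
    list(params = tibble(term = names(est), estimate = unname(est),
                         std.error = unname(se[names(est)])),
         flags = flags, rss = sum(resid(fit)^2), n = length(y),
         fitted = predict(fit), data = trace, nls = fit),
    class = "mono_fit"
  )
}

#' @export
print.mono_fit <- function(x, ...) {
  cat("Exponential trace fit\n")
  p <- x$params
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-7s %10.5g +/- %.3g\n", p$term[i], p$estimate[i],
                p$std.error[i]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.mono_fit <- function(x, ...) x$params

#' @export
glance.mono_fit <- function(x, ...) {
  tibble(nobs = x$n, rss = x$rss, flags = paste(x$flags, collapse = ";"))
}
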