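# ggplot2 displays for each result type. All autoplot() methods return a
# ggplot object the caller can restyle.

#' @export
autoplot.bisubstrate_fit <- function(object, ...) {
  d <- mutate(object$data, fitted = object$fitted)
  curve <- d %>%
    group_by(.data$acceptor_uM) %>%
    summarise(A = list(seq(min(.data$alcohol_uM), max(.data$alcohol_uM),
                           length.out = 80)),
              .groups = "drop") %>%
    tidyr::unnest("A")
  p <- object$params$estimate
  names(p) <- object$params$term
  curve$rate <- if (object$model == "pingpong") {
    pingpong_rate(curve$A, curve$acceptor_uM,
                  p["kcat"], p["Km_alcohol"], p["Km_acceptor"])
  } else {
    sequential_rate(curve$A, curve$acceptor_uM,
                    p["kcat"], p["Km_alcohol"], p["Km_acceptor"],
                    p["Kd_alcohol"])
  }
  ggplot(d, aes(x = .data$alcohol_uM, y = .data$rate_per_s,
                colour = factor(.data$acceptor_uM))) +
    geom_point() +
    geom_line(data = curve, aes(x = .data$A, y = .data$rate)) +
    labs(x = "[alcohol] (uM)", y = expression(v[0] / e ~ (s^-1)),
         colour = "[acceptor] (uM)",
         title = sprintf("Bi-substrate fit (%s)", object$model)) +
    theme_bw()
}

#' @export
autoplot.hanes_woolf <- function(object, ...) {
  ggplot(as_tibble(object)) +
    geom_abline(aes(slope = .data$slope, intercept = .data$intercept,
                    colour = factor(.data$acceptor_uM))) +
    geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::expand_limits(x = 0, y = 0) +
    labs(x = "[A] (uM)", y = "[A]/v0 (uM s)", colour = "[acceptor] (uM)",
         title = "Hanes-Woolf lines per acceptor level") +
    theme_bw()
}

kobs_fit_plot <- function(data, fitted_fun, title, xlab) {
  grid <- tibble(conc_uM = seq(min(data$conc_uM), max(data$conc_uM),
                               length.out = 100))
  grid$kobs <- fitted_fun(grid$conc_uM)
  ggplot(data, aes(x = .data$conc_uM, y = .data$kobs_per_s)) +
    geom_point() +
    geom_line(data = grid, aes(y = .data$kobs)) +
    labs(x = xlab, y = expression(k[obs] ~ (s^-1)), title = title) +
    theme_bw()
}

#' @export
autoplot.reduction_fit <- function(object, ...) {
  p <- setNames(object$params$estimate, object$params$term)
  kobs_fit_plot(object$data,
                function(x) p["kred"] * x / (p["Kd_alcohol"] + x) + p["krev"],
                "Reductive half-reaction", "[alcohol] (uM)")
}

#' @export
autoplot.reoxidation_fit <- function(object, ...) {
  p <- setNames(object$params$estimate, object$params$term)
  kobs_fit_plot(object$data,
                function(x) p["app_kox"] * x / 1000 + p["krev_intercept"],
                "Oxidative half-reaction", "[acceptor] (uM)")
}

#' @export
autoplot.binding_fit <- function(object, ...) {
  p <- setNames(object$params$estimate, object$params$term)
  kobs_fit_plot(object$data,
                function(x) p["kon"] * x / 1000 + p["koff"],
                "Ligand-binding kinetics", "[L] (uM)")
}

#' @export
autoplot.spectra_matrix <- function(object, ...) {
  d <- tidy(object)
  pick <- unique(round(seq(1, length(object$times), length.out = 10)))
  d <- filter(d, .data$time_s %in% object$times[pick])
  ggplot(d, aes(x = .data$wavelength_nm, y = .data$absorbance,
                group = .data$time_s, colour = .data$time_s)) +
    geom_line() +
    labs(x = "wavelength (nm)", y = "absorbance (AU)", colour = "time (s)",
         title = "Time-resolved spectra") +
    theme_bw()
}

#' @export
autoplot.global_fit <- function(object, ...) {
  ggplot(object$species_spectra,
         aes(x = .data$wavelength_nm, y = .data$epsilon_like,
             colour = .data$species)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "wavelength (nm)", y = "species spectrum (AU)",
         title = sprintf("Global fit, %d-step scheme", object$n_steps)) +
    theme_bw()
}

#' @export
autoplot.mono_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- if (is.null(object$fitted)) mean(d$value) else object$fitted
  ggplot(d, aes(x = .data$time_s)) +
    geom_point(aes(y = .data$value), size = 0.8) +
    geom_line(aes(y = .data$fitted), colour = "red") +
    scale_x_log10() +
    labs(x = "time (s)", y = "signal (AU)", title = "Exponential trace fit") +
    theme_bw()
}

#' @export
autoplot.turnover_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$A462)) +
    geom_line() +
    labs(x = "time (s)", y = "A462 (AU)",
         title = "Flavin band-I absorbance during turnover") +
    theme_bw()
}

#' @export
autoplot.itc_fit <- function(object, ...) {
  ex <- object$exp
  mol_ratio <- cumsum(ex$injection_volumes_uL * ex$syringe_conc_uM) /
    (ex$cell_volume_uL * ex$cell_conc_uM)
  inj_nmol <- ex$injection_volumes_uL * ex$syringe_conc_uM * 1e-3
  d <- tibble(mol_ratio = mol_ratio,
              observed = ex$heats_ucal / inj_nmol,
              fitted = object$fitted / inj_nmol)
  ggplot(d, aes(x = .data$mol_ratio)) +
    geom_point(aes(y = .data$observed)) +
    geom_line(aes(y = .data$fitted), colour = "red") +
    labs(x = "molar ratio (ligand/macromolecule)",
         y = "kcal per mol of injectant",
         title = "One-site ITC isotherm") +
    theme_bw()
}
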