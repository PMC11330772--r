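# Seeded synthetic-data generators. These stand in for the instruments:
# each generator produces data with exactly the statistical structure the
# corresponding fitter assumes (plus configurable noise), so every
# analysis stage has an offline oracle. Seeds are explicit arguments and
# never touch the global RNG state.

apply_noise <- function(y, noise_sd, kind = c("multiplicative", "additive"),
                        seed = NULL) {
  kind <- match.arg(kind)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (noise_sd == 0) return(y)
  with_seed_(seed, {
    eps <- rnorm(length(y), 0, noise_sd)
    if (kind == "multiplicative") y * (1 + eps) else y + eps
  })
}

#' Generate a synthetic bi-substrate initial-rate dataset
#'
#' Rates over the Cartesian (alcohol, acceptor) grid from the ping-pong
#' law, or the sequential law when `Kd_alcohol` is given, with
#' multiplicative Gaussian noise (relative sd `noise_sd`; the default 2%
#' is typical initial-rate scatter). With `replicates > 1` each grid
#' point is drawn that many times.
#'
#' @param kcat,Km_alcohol,Km_acceptor Generating parameters (s^-1, uM, uM).
#' @param Kd_alcohol If non-NULL, generate from the sequential law with
#'   this alcohol dissociation constant (uM).
#' @param A,B Alcohol and acceptor concentration levels, uM.
#' @param noise_sd Relative noise standard deviation.
#' @param seed Integer seed (NULL for no seeding); identical seeds give
#'   identical datasets.
#' @param replicates Replicate draws per grid point.
#' @return A [bisubstrate_data()] tibble with a `generator` attribute
#'   stamping the generating parameters.
#' @export
gen_bisubstrate <- function(kcat, Km_alcohol, Km_acceptor, Kd_alcohol = NULL,
                            A, B, noise_sd = 0.02, seed = NULL,
                            replicates = 1L) {
  grid <- expand.grid(alcohol_uM = A, acceptor_uM = B,
                      replicate = seq_len(replicates))
  mu <- if (is.null(Kd_alcohol)) {
    pingpong_rate(grid$alcohol_uM, grid$acceptor_uM,
                  kcat, Km_alcohol, Km_acceptor)
  } else {
    sequential_rate(grid$alcohol_uM, grid$acceptor_uM,
                    kcat, Km_alcohol, Km_acceptor, Kd_alcohol)
  }
  rate <- apply_noise(mu, noise_sd, "multiplicative", seed)
  out <- bisubstrate_data(grid$alcohol_uM, grid$acceptor_uM, rate,
                          replicate = grid$replicate)
  attr(out, "generator") <- list(
    model = if (is.null(Kd_alcohol)) "pingpong" else "sequential",
    kcat = kcat, Km_alcohol = Km_alcohol, Km_acceptor = Km_acceptor,
    Kd_alcohol = Kd_alcohol, noise_sd = noise_sd, seed = seed
  )
  out
}

#' Generate a synthetic kobs-vs-concentration series
#'
#' Observed rate constants from the hyperbolic reduction law
#' (`role = "reductant"`), the linear reoxidation law
#' (`"electron_acceptor"`) or the linear binding law
#' (`"dead_end_ligand"`), with multiplicative Gaussian noise. With
#' `replicates > 1` the reported kobs at each concentration is the mean
#' of that many independent noisy draws (mirroring the usual averaging of
#' 3-5 stopped-flow shots), so its scatter shrinks by `sqrt(replicates)`.
#'
#' @param conc_uM Ligand concentration levels, uM.
#' @param role Which secondary model generates the series.
#' @param kred,Kd,krev Hyperbolic parameters (reductant role).
#' @param app_kox Linear slope, s^-1 mM^-1 (electron-acceptor role).
#' @param kon,koff Linear binding parameters (dead-end-ligand role).
#' @param noise_sd Relative noise sd (default 3%).
#' @param seed Integer seed.
#' @param replicates Averaged replicate draws per concentration.
#' @return A [kobs_series()] tibble with a `generator` attribute.
#' @export
gen_kobs <- function(conc_uM,
                     role = c("reductant", "electron_acceptor",
                              "dead_end_ligand"),
                     kred = NULL, Kd = NULL, krev = 0,
                     app_kox = NULL, kon = NULL, koff = 0,
                     noise_sd = 0.03, seed = NULL, replicates = 1L) {
  role <- match.arg(role)
  mu <- switch(role,
    reductant = hyperbolic_kobs(conc_uM, kred, Kd, krev),
    electron_acceptor = reoxidation_kobs(conc_uM, app_kox, krev),
    dead_end_ligand = binding_kobs(conc_uM, kon, koff)
  )
  draws <- with_seed_(seed, {
    matrix(rnorm(length(mu) * replicates, 0, noise_sd),
           nrow = length(mu))
  })
  if (noise_sd == 0) draws[] <- 0
  obs <- rowMeans(mu * (1 + draws))
  se <- if (replicates > 1) apply(mu * (1 + draws), 1, sd) / sqrt(replicates)
        else NA_real_
  out <- kobs_series(conc_uM, obs, se = se, role = role)
  attr(out, "generator") <- list(role = role, kred = kred, Kd = Kd,
                                 krev = krev, app_kox = app_kox, kon = kon,
                                 koff = koff, noise_sd = noise_sd,
                                 seed = seed, replicates = replicates)
  out
}

#' Flavin-like absorbance band templates
#'
#' Smooth sum-of-Gaussian spectra emulating the visible absorbance of an
#' FAD cofactor: the oxidized state with band I near 462 nm and band II
#' near 385 nm, a reduced state with low, broad residual absorbance, and
#' an optional intermediate (their midpoint, slightly red-shifted).
#' Amplitudes are molar extinction coefficients (M^-1 cm^-1) of
#' band-I-class magnitude; they are template defaults, not measured
#' values, and can be overridden.
#'
#' @param band1_nm,band2_nm Band centers, nm.
#' @param eps_band1 Band-I peak extinction, M^-1 cm^-1.
#' @param eps_reduced Residual extinction of the reduced state at band I.
#' @return A list of functions `oxidized(wl)`, `reduced(wl)`,
#'   `intermediate(wl)` mapping wavelength (nm) to extinction
#'   (M^-1 cm^-1), all non-negative.
#' @export
flavin_template <- function(band1_nm = 462, band2_nm = 385,
                            eps_band1 = 11300, eps_reduced = 1500) {
  gauss <- function(wl, c0, s, a) a * exp(-0.5 * ((wl - c0) / s)^2)
  oxidized <- function(wl) {
    gauss(wl, band1_nm, 28, eps_band1) +
      gauss(wl, band2_nm, 26, 0.85 * eps_band1) +
      gauss(wl, 350, 60, 0.3 * eps_band1)
  }
  reduced <- function(wl) {
    gauss(wl, 410, 80, eps_reduced) + gauss(wl, 350, 60, 2 * eps_reduced)
  }
  intermediate <- function(wl) 0.5 * (oxidized(wl + 5) + reduced(wl))
  list(oxidized = oxidized, reduced = reduced, intermediate = intermediate)
}

#' Generate a synthetic time-resolved spectra matrix
#'
#' Builds `D = C(t) S(lambda) + noise` from the first-order scheme
#' profiles and flavin-template species spectra. For a reduction
#' experiment the species run oxidized -> (intermediate ->) reduced; a
#' reoxidation experiment reverses the order. Noise is additive Gaussian
#' per element (default 0.002 AU, a realistic diode-array floor). Default
#' times are log-spaced over 0.003-0.15 s, the span of a stopped-flow
#' flavin-reduction transient.
#'
#' @param rates One or two first-order rate constants, s^-1.
#' @param times Acquisition times, s.
#' @param wavelengths Wavelength axis, nm.
#' @param template A [flavin_template()].
#' @param direction `"reduction"` or `"reoxidation"`.
#' @param enzyme_uM Enzyme concentration (scales AU), uM.
#' @param pathlength_cm Optical pathlength, cm.
#' @param noise_sd Additive noise sd, AU.
#' @param seed Integer seed.
#' @return A [spectra_matrix()] with a `generator` attribute.
#' @export
gen_spectra <- function(rates,
                        times = exp(seq(log(0.003), log(0.15),
                                        length.out = 40)),
                        wavelengths = seq(400, 700, by = 5),
                        template = flavin_template(),
                        direction = c("reduction", "reoxidation"),
                        enzyme_uM = 10, pathlength_cm = 1,
                        noise_sd = 0.002, seed = NULL) {
  direction <- match.arg(direction)
  n_species <- length(rates) + 1
  C <- species_profiles(rates, times)
  state_seq <- if (n_species == 2) c("oxidized", "reduced") else
    c("oxidized", "intermediate", "reduced")
  if (direction == "reoxidation") state_seq <- rev(state_seq)
  S <- t(vapply(state_seq,
                function(s) template[[s]](wavelengths) * enzyme_uM * 1e-6 *
                  pathlength_cm,
                numeric(length(wavelengths))))
  D <- C %*% S
  D <- apply_noise(D, noise_sd, "additive", seed)
  out <- spectra_matrix(times, wavelengths, D)
  attr(out, "generator") <- list(rates = rates, direction = direction,
                                 enzyme_uM = enzyme_uM, noise_sd = noise_sd,
                                 seed = seed)
  out
}

#' Generate a synthetic ITC titration
#'
#' Heats from [one_site_heats()] plus additive Gaussian noise scaled to
#' the largest heat magnitude (default 2%).
#'
#' @param Kd_uM Dissociation constant of the simulated interaction, uM.
#' @param dH_kcal_mol Binding enthalpy, kcal/mol.
#' @param n Stoichiometry.
#' @param exp An [itc_experiment()] design (heats ignored).
#' @param noise_frac Noise sd as a fraction of `max(abs(heats))`.
#' @param seed Integer seed.
#' @return The [itc_experiment()] with simulated `heats_ucal` and a
#'   `generator` attribute.
#' @export
gen_itc <- function(Kd_uM, dH_kcal_mol, n = 1, exp = itc_experiment(6, 50),
                    noise_frac = 0.02, seed = NULL) {
  check_scalar(Kd_uM, "Kd_uM")
  mu <- one_site_heats(1e6 / Kd_uM, dH_kcal_mol, n, exp)
  heats <- apply_noise(mu, noise_frac * max(abs(mu)), "additive", seed)
  out <- itc_experiment(exp$cell_conc_uM, exp$syringe_conc_uM,
                        exp$cell_volume_uL, exp$injection_volumes_uL,
                        exp$temperature_K, heats)
  attr(out, "generator") <- list(Kd_uM = Kd_uM, dH_kcal_mol = dH_kcal_mol,
                                 n = n, noise_frac = noise_frac, seed = seed)
  out
}
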