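#' Bi-substrate steady-state rate laws
#'
#' Turnover (`v0/e`, s^-1) of a two-substrate flavoenzyme reaction as a
#' function of alcohol (`A`) and electron-acceptor (`B`) concentrations.
#' `pingpong_rate()` is the substituted-enzyme (ping-pong) law
#' \deqn{v_0/e = k_{cat} A B / (K_{mB} A + K_{mA} B + A B)}
#' in which the reduced enzyme releases the aldehyde before the acceptor
#' reacts; `sequential_rate()` adds the ternary-complex term
#' \eqn{K_d K_{mB}} to the denominator, with `Kd_alcohol` the dissociation
#' constant of the enzyme:alcohol complex. Setting `Kd_alcohol = 0` recovers
#' the ping-pong law, which is therefore the nested limit of the sequential
#' one.
#'
#' @param A Alcohol concentration, uM. Vectorized.
#' @param B Electron-acceptor concentration, uM. Vectorized.
#' @param kcat Maximum turnover, s^-1.
#' @param Km_alcohol,Km_acceptor Michaelis constants, uM.
#' @param Kd_alcohol Alcohol dissociation constant, uM (sequential only).
#' @return Turnover in s^-1; 0 where `A` or `B` is 0.
#' @examples
#' pingpong_rate(100, 176, kcat = 201, Km_alcohol = 50, Km_acceptor = 176)
#' @export
pingpong_rate <- function(A, B, kcat, Km_alcohol, Km_acceptor) {
  check_positive(A, "A", strict = FALSE)
  check_positive(B, "B", strict = FALSE)
  check_scalar(kcat, "kcat")
  check_scalar(Km_alcohol, "Km_alcohol")
  check_scalar(Km_acceptor, "Km_acceptor")
  num <- kcat * A * B
  den <- Km_acceptor * A + Km_alcohol * B + A * B
  ifelse(num == 0, 0, num / den)
}

#' @rdname pingpong_rate
#' @export
sequential_rate <- function(A, B, kcat, Km_alcohol, Km_acceptor, Kd_alcohol) {
  if (missing(Kd_alcohol) || is.null(Kd_alcohol)) {
    stop_input("`Kd_alcohol` is required for the sequential rate law.")
  }
  check_positive(A, "A", strict = FALSE)
  check_positive(B, "B", strict = FALSE)
  check_scalar(kcat, "kcat")
  check_scalar(Km_alcohol, "Km_alcohol")
  check_scalar(Km_acceptor, "Km_acceptor")
  check_scalar(Kd_alcohol, "Kd_alcohol", strict = FALSE)
  num <- kcat * A * B
  den <- Km_acceptor * A + Km_alcohol * B + A * B + Kd_alcohol * Km_acceptor
  ifelse(num == 0, 0, num / den)
}

#' Hyperbolic dependence of the flavin-reduction rate on alcohol
#'
#' Observed pseudo-first-order rate constant for the reductive half-reaction
#' when an enzyme:substrate complex forms before hydride transfer:
#' \deqn{k_{obs} = k_{red} A / (K_d + A) + k_{rev}}
#' `kred` is the limiting reduction rate at saturating alcohol, `Kd` the
#' alcohol dissociation constant and `krev` the reverse hydride-transfer
#' rate (frequently indistinguishable from zero).
#'
#' @param A Alcohol concentration, uM. Vectorized.
#' @param kred Limiting reduction rate, s^-1.
#' @param Kd Alcohol dissociation constant, uM.
#' @param krev Reverse rate, s^-1 (default 0).
#' @return kobs in s^-1.
#' @examples
#' hyperbolic_kobs(5000, kred = 117, Kd = 765)
#' @export
hyperbolic_kobs <- function(A, kred, Kd, krev = 0) {
  check_positive(A, "A", strict = FALSE)
  check_scalar(kred, "kred")
  check_scalar(Kd, "Kd")
  check_scalar(krev, "krev", strict = FALSE)
  kred * A / (Kd + A) + krev
}

#' Linear kobs laws for reoxidation and ligand binding
#'
#' `reoxidation_kobs()` gives the observed flavin-reoxidation rate as a
#' linear function of electron-acceptor concentration,
#' `kobs = app_kox * [acceptor] + krev`, with `app_kox` the apparent
#' second-order reoxidation constant. `binding_kobs()` is the analogous
#' relaxation rate for one-step ligand binding,
#' `kobs = kon * [L] + koff`.
#'
#' @param conc_uM Ligand/acceptor concentration, uM. Vectorized.
#' @param app_kox,kon Second-order rate constants, s^-1 mM^-1.
#' @param krev,koff Zero-concentration intercepts, s^-1.
#' @return kobs in s^-1.
#' @examples
#' reoxidation_kobs(100, app_kox = 216, krev = 14)
#' binding_kobs(1000, kon = 10, koff = 18)
#' @export
reoxidation_kobs <- function(conc_uM, app_kox, krev = 0) {
  check_positive(conc_uM, "conc_uM", strict = FALSE)
  check_scalar(app_kox, "app_kox")
  check_scalar(krev, "krev", strict = FALSE)
  app_kox * conc_uM / 1000 + krev
}

#' @rdname reoxidation_kobs
#' @export
binding_kobs <- function(conc_uM, kon, koff = 0) {
  check_positive(conc_uM, "conc_uM", strict = FALSE)
  check_scalar(kon, "kon")
  check_scalar(koff, "koff", strict = FALSE)
  kon * conc_uM / 1000 + koff
}
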