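pe_bq_cycle <- function(...) {
  catalytic_cycle(kred = 251, Kd_alcohol = 80, app_kox = 792,
                  alcohol_uM = 2000, acceptor_uM = 300, enzyme_uM = 10,
                  branch = "BQ", ...)
}

test_that("conservation laws hold to 1e-9 across model variants", {
  models <- list(
    minimal = pe_bq_cycle(),
    release = pe_bq_cycle(krel = 60),
    explicit = catalytic_cycle(kred = 251, app_kox = 792,
                               kon_S = 500, koff_S = 40,
                               alcohol_uM = 2000, acceptor_uM = 300,
                               enzyme_uM = 10)
  )
  for (m in models) {
    tr <- simulate_turnover(m, 0.5)
    states <- attr(tr, "states")
    etot <- rowSums(as.matrix(tr[states]))
    expect_lt(max(abs(etot - 10)) / 10, 1e-9)
    bound_S <- if ("EoxS" %in% states) tr$EoxS else 0
    alc <- tr$alcohol + tr$aldehyde + bound_S
    expect_lt(max(abs(alc - alc[1])) / alc[1], 1e-9)
    bound_Q <- if ("EoxQ" %in% states) tr$EoxQ else 0
    acc <- tr$acceptor + tr$reduced_acceptor + bound_Q
    expect_lt(max(abs(acc - acc[1])) / acc[1], 1e-9)
  }
})

test_that("closed-form steady state matches the harmonic-flux solution", {
  # symmetric rates partition the enzyme evenly
  m <- catalytic_cycle(kred = 100, Kd_alcohol = 1, app_kox = 1000,
                       alcohol_uM = 1e9, acceptor_uM = 100, enzyme_uM = 1)
  ss <- steady_state_closed_form(m)
  expect_equal(ss$fraction_oxidized, 0.5, tolerance = 1e-6)
  # saturating alcohol with 0.3 mM BQ: ka = 251, kb = 792*0.3 = 237.6
  m2 <- pe_bq_cycle()
  ss2 <- steady_state_closed_form(m2, A = 1e12, B = 300)
  expect_equal(ss2$fraction_oxidized, 237.6 / (251 + 237.6), tolerance = 1e-6)
  expect_equal(ss2$turnover_per_s, 251 * 237.6 / (251 + 237.6),
               tolerance = 1e-6)
  # a very fast release step reduces to the 2-state formula
  ss3 <- steady_state_closed_form(pe_bq_cycle(krel = 1e9), A = 1e12, B = 300)
  expect_equal(ss3$turnover_per_s, ss2$turnover_per_s, tolerance = 1e-6)
  # blocked flux is a defined zero-turnover state
  ss0 <- steady_state_closed_form(m2, A = 0, B = 300)
  expect_equal(ss0$turnover_per_s, 0)
  expect_equal(ss0$fraction_oxidized, 1)
})

test_that("ODE steady flux equals the closed form on clamped pools", {
  for (m in list(pe_bq_cycle(), pe_bq_cycle(krel = 60))) {
    tr <- simulate_turnover(m, 0.5, clamp_pools = TRUE)
    rf <- redox_fraction(tr)
    ss <- steady_state_closed_form(m)
    expect_lt(abs(rf$fraction_oxidized_species - ss$fraction_oxidized), 1e-4)
  }
})

test_that("A462-derived and species-derived fractions agree for a 2-state model", {
  tr <- simulate_turnover(pe_bq_cycle(), 0.5, clamp_pools = TRUE)
  rf <- redox_fraction(tr)
  expect_lt(abs(rf$fraction_oxidized_A462 - rf$fraction_oxidized_species),
            1e-6)
})

test_that("fast reoxidation keeps the enzyme almost fully oxidized", {
  m <- catalytic_cycle(kred = 10, Kd_alcohol = 100, app_kox = 5000,
                       alcohol_uM = 1000, acceptor_uM = 5000, enzyme_uM = 10)
  rf <- redox_fraction(simulate_turnover(m, 1, clamp_pools = TRUE))
  expect_gt(rf$fraction_oxidized_species, 0.97)
})

test_that("fraction oxidized responds monotonically to the half-reaction rates", {
  base <- list(kred = 100, Kd_alcohol = 500, alcohol_uM = 1000,
               acceptor_uM = 200, enzyme_uM = 5)
  frac_at <- function(app_kox, A) {
    m <- catalytic_cycle(kred = base$kred, Kd_alcohol = base$Kd_alcohol,
                         app_kox = app_kox, alcohol_uM = base$alcohol_uM,
                         acceptor_uM = base$acceptor_uM,
                         enzyme_uM = base$enzyme_uM)
    steady_state_closed_form(m, A = A)$fraction_oxidized
  }
  f_kox <- sapply(c(100, 300, 1000, 3000), frac_at, A = 1000)
  expect_true(all(diff(f_kox) > 0))
  f_A <- sapply(c(100, 500, 2000, 8000), function(a) frac_at(500, a))
  expect_true(all(diff(f_A) < 0))
})

test_that("single-turnover and no-substrate limits behave stoichiometrically", {
  # no acceptor: one reduction each, then the cycle stops fully reduced
  m0 <- catalytic_cycle(kred = 251, Kd_alcohol = 80, app_kox = 792,
                        alcohol_uM = 2000, acceptor_uM = 0, enzyme_uM = 10)
  tr0 <- simulate_turnover(m0, 1)
  expect_equal(utils::tail(tr0$Ered, 1), 10, tolerance = 1e-6)
  expect_equal(utils::tail(tr0$aldehyde, 1), 10, tolerance = 1e-6)
  # no alcohol: nothing happens
  mA <- catalytic_cycle(kred = 251, Kd_alcohol = 80, app_kox = 792,
                        alcohol_uM = 0, acceptor_uM = 300, enzyme_uM = 10)
  trA <- simulate_turnover(mA, 1)
  expect_equal(range(trA$A462), rep(trA$A462[1], 2), tolerance = 1e-9)
  # excess alcohol over acceptor: BQ is exhausted first and every BQ
  # consumed is matched by an aldehyde (plus the trapped reduced enzyme)
  trB <- simulate_turnover(pe_bq_cycle(), 2)
  expect_lt(utils::tail(trB$acceptor, 1), 1e-3)
  expect_gt(utils::tail(trB$alcohol, 1), 1500)
  expect_equal(utils::tail(trB$aldehyde, 1), 300 + 10, tolerance = 1e-3)
})

test_that("the minimal cycle's apparent kinetics are exactly ping-pong", {
  m <- pe_bq_cycle()
  d <- scan_apparent_kinetics(m, c(50, 100, 200, 400, 800),
                              c(50, 100, 200, 400, 800))
  fit <- fit_bisubstrate(d, "pingpong")
  expect_lt(fit$rss, 1e-18)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(est[["kcat"]], 251, tolerance = 1e-9)
  expect_equal(est[["Km_alcohol"]], 80, tolerance = 1e-9)
  # apparent Km for the acceptor is kcat/app_kox expressed in uM
  expect_equal(est[["Km_acceptor"]], 1000 * 251 / 792, tolerance = 1e-9)
  hw <- hanes_woolf(d)
  expect_lt(sd(hw$intercept) / mean(hw$intercept), 1e-9)
  expect_error(scan_apparent_kinetics(m, 100, c(50, 100)) |>
                 fit_bisubstrate("pingpong"),
               class = "flavokin_input_error")
})

test_that("mixing constants from different temperatures warns", {
  expect_warning(
    catalytic_cycle(kred = 117, Kd_alcohol = 765, app_kox = 216,
                    alcohol_uM = 1000, acceptor_uM = 258, enzyme_uM = 10,
                    temperatures_C = c(kred = 25, app_kox = 12)),
    "temperatures")
})
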