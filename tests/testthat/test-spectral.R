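test_that("species profiles satisfy the closed-form solutions", {
  p <- species_profiles(100, c(0, log(2) / 100))
  expect_equal(p[1, ], c(A = 1, B = 0))
  expect_equal(p[2, "A"], c(A = 0.5))
  # confluent limit for equal rates: c_B = k t exp(-k t)
  p3 <- species_profiles(c(50, 50), 1 / 50)
  expect_equal(unname(p3[1, "B"]), exp(-1), tolerance = 1e-6)
  # fractions always sum to one
  tt <- seq(0, 0.5, length.out = 30)
  expect_equal(rowSums(species_profiles(c(200, 20), tt)), rep(1, 30))
})

test_that("global fit recovers noiseless rates and reconstructs the matrix", {
  m <- gen_spectra(100, noise_sd = 0)
  g <- global_fit(m, 1)
  expect_lt(abs(g$rates$estimate[1] - 100) / 100, 1e-6)
  expect_lt(g$residual_rms, 1e-9)

  m3 <- gen_spectra(c(200, 20), noise_sd = 0)
  g3 <- global_fit(m3, 2)
  expect_lt(abs(g3$rates$estimate[1] - 200) / 200, 1e-6)
  expect_lt(abs(g3$rates$estimate[2] - 20) / 20, 1e-6)
  expect_lt(g3$residual_rms, 1e-9)
  # reporting convention: faster rate first
  expect_true(g3$rates$estimate[1] >= g3$rates$estimate[2])
})

test_that("overparameterized two-step fits are flagged", {
  m <- gen_spectra(100, noise_sd = 0)
  expect_warning(g <- global_fit(m, 2), "unidentifiable")
  expect_true("k2_unidentifiable" %in% g$flags)
})

test_that("rank estimation counts species above the noise floor", {
  expect_identical(estimate_rank(gen_spectra(c(200, 20), noise_sd = 0)), 3L)
  expect_identical(estimate_rank(gen_spectra(100, noise_sd = 0)), 2L)
  m <- gen_spectra(100, noise_sd = 0.002, seed = 21)
  expect_identical(estimate_rank(m, noise_sd = 0.002), 2L)
  # no spectral evolution: both species share one spectrum, rank 1
  tpl <- flavin_template()
  flat <- spectra_matrix(seq(0.01, 0.1, by = 0.01), seq(400, 700, 10),
                         matrix(rep(tpl$oxidized(seq(400, 700, 10)) * 1e-5,
                                    each = 10), nrow = 10))
  expect_identical(estimate_rank(flat), 1L)
})

test_that("step-model selection matches the generating scheme", {
  expect_identical(select_step_model(gen_spectra(100, noise_sd = 0))$chosen, 1L)
  sel <- select_step_model(gen_spectra(c(200, 20), noise_sd = 0))
  expect_identical(sel$chosen, 2L)
  expect_gt(sel$delta_aicc, 10)
})

test_that("rank-1 matrices degrade to a flagged one-step fit", {
  tpl <- flavin_template()
  wl <- seq(400, 700, 10)
  flat <- spectra_matrix(seq(0.01, 0.1, by = 0.01), wl,
                         matrix(rep(tpl$oxidized(wl) * 1e-5, each = 10),
                                nrow = 10))
  sel <- select_step_model(flat)
  expect_identical(sel$chosen, 1L)
  expect_true("zero_amplitude" %in% sel$fit_1$flags)
})

test_that("monochromator traces are fitted with correct rates and amplitudes", {
  t <- exp(seq(log(0.001), log(0.3), length.out = 60))
  y1 <- 0.02 + 0.09 * exp(-100 * t)
  f1 <- monochromator_fit(tibble::tibble(time_s = t, value = y1), 1)
  est <- setNames(f1$params$estimate, f1$params$term)
  expect_equal(est[["k1"]], 100, tolerance = 1e-6)
  expect_equal(est[["a1"]], 0.09, tolerance = 1e-6)

  # biexponential, 85/15 amplitude split, 1% noise; a realistic
  # monochromator acquisition has hundreds of points per transient
  t2 <- exp(seq(log(0.001), log(0.3), length.out = 400))
  amp <- 0.1
  mu <- 0.02 + 0.85 * amp * exp(-200 * t2) + 0.15 * amp * exp(-20 * t2)
  y2 <- mu * (1 + withr::with_seed(31, rnorm(length(t2), 0, 0.01)))
  f2 <- monochromator_fit(tibble::tibble(time_s = t2, value = y2), 2)
  est2 <- setNames(f2$params$estimate, f2$params$term)
  expect_lt(abs(est2[["k1"]] - 200) / 200, 0.05)
  expect_lt(abs(est2[["k2"]] - 20) / 20, 0.05)
  expect_true(est2[["k1"]] >= est2[["k2"]])
})

test_that("degenerate traces are handled: constant signal and close rates", {
  t <- seq(0.001, 0.2, length.out = 20)
  f <- monochromator_fit(tibble::tibble(time_s = t, value = rep(0.1, 20)), 1)
  expect_true("zero_amplitude" %in% f$flags)
  expect_equal(f$params$estimate[f$params$term == "a1"], 0)

  y <- 0.02 + 0.05 * exp(-50 * t) + 0.05 * exp(-30 * t)
  expect_warning(monochromator_fit(tibble::tibble(time_s = t, value = y), 2),
                 "3x")
})

test_that("global and single-trace fits agree on shared synthetic data", {
  m <- gen_spectra(120, noise_sd = 5e-4, seed = 12)
  g <- global_fit(m, 1)
  i462 <- which.min(abs(m$wavelengths - 462))
  f <- monochromator_fit(
    tibble::tibble(time_s = m$times, value = m$absorbance[, i462]), 1)
  kg <- g$rates$estimate[1]
  km <- f$params$estimate[f$params$term == "k1"]
  se <- sqrt(sum(c(g$rates$std.error[1],
                   f$params$std.error[f$params$term == "k1"])^2, na.rm = TRUE))
  expect_lt(abs(kg - km), max(3 * se, 0.02 * kg))
})

test_that("first-order fits are invariant to a time-origin shift", {
  m <- gen_spectra(c(200, 20), noise_sd = 0)
  k0 <- global_fit(m, 2)$rates$estimate
  shifted <- spectra_matrix(m$times + 0.05, m$wavelengths, m$absorbance)
  k1 <- global_fit(shifted, 2)$rates$estimate
  expect_equal(k1, k0, tolerance = 1e-9)
})

test_that("spectra matrices validate their axes and entries", {
  expect_error(spectra_matrix(c(0.2, 0.1), 1:3, matrix(0, 2, 3)),
               class = "flavokin_input_error")
  expect_error(spectra_matrix(c(0.1, 0.2), 1:3, matrix(0, 3, 2)),
               class = "flavokin_input_error")
  expect_error(spectra_matrix(c(0.1, 0.2), 1:3, matrix(c(1, NA), 2, 3)),
               class = "flavokin_input_error")
})
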