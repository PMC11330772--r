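test_that("hyperbolic reduction fit recovers noiseless parameters exactly", {
  fit <- fit_reduction(red_series())
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_lt(abs(est["kred"] - 117) / 117, 1e-6)
  expect_lt(abs(est["Kd_alcohol"] - 765) / 765, 1e-5)
  expect_true("krev_zero" %in% fit$flags)
})

test_that("reduction fit recovers noisy reference parameters within tolerance", {
  fit <- fit_reduction(red_series(0.03, seed = 2))
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_lt(abs(est["kred"] - 117) / 117, 0.05)
  expect_lt(abs(est["Kd_alcohol"] - 765) / 765, 0.15)
})

test_that("a series far below saturation is flagged unreliable", {
  s <- gen_kobs(seq(5, 76, length.out = 6), "reductant",
                kred = 117, Kd = 765, noise_sd = 0.01, seed = 4)
  expect_warning(fit <- fit_reduction(s), "70%")
  expect_true("saturation_not_reached" %in% fit$flags)
  # the linear-regime slope kred/Kd is still well determined
  expect_lt(abs(fit$eff_red - 117 / 765 * 1000) / (117 / 765 * 1000), 0.1)
})

test_that("linear reoxidation fit returns slope in s^-1 mM^-1 and intercept", {
  s <- gen_kobs(seq(50, 400, length.out = 5), "electron_acceptor",
                app_kox = 216, krev = 14, noise_sd = 0)
  fit <- fit_reoxidation(s)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(est[["app_kox"]], 216, tolerance = 1e-9)
  expect_equal(est[["krev_intercept"]], 14, tolerance = 1e-9)
  expect_error(
    fit_reoxidation(kobs_series(c(100, 200), c(30, 50),
                                role = "electron_acceptor")),
    class = "flavokin_input_error")
})

test_that("binding kinetics fit recovers kon/koff and the kinetic Kd", {
  L <- seq(500, 8000, length.out = 6)
  fit <- fit_binding_kinetics(
    gen_kobs(L, "dead_end_ligand", kon = 10, koff = 18, noise_sd = 0))
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_lt(abs(est["kon"] - 10) / 10, 1e-6)
  expect_lt(abs(est["koff"] - 18) / 18, 1e-6)
  # Kd = koff/kon: 13 s^-1 over 47 s^-1 mM^-1 = 276.6 uM
  fit2 <- fit_binding_kinetics(
    gen_kobs(L, "dead_end_ligand", kon = 47, koff = 13, noise_sd = 0))
  expect_equal(fit2$params$estimate[fit2$params$term == "Kd_acid"],
               13 / 47 * 1000, tolerance = 1e-9)
})

test_that("undetectable dissociation is reported as nd, never zero", {
  # tiny true koff drowned by noise: intercept CI includes 0
  s <- gen_kobs(seq(1000, 8000, length.out = 6), "dead_end_ligand",
                kon = 37, koff = 0.2, noise_sd = 0.05, seed = 9)
  fit <- fit_binding_kinetics(s)
  expect_true(fit$koff_nd)
  expect_true(is.na(fit$params$estimate[fit$params$term == "Kd_acid"]))
})

test_that("strongly negative intercepts raise a data-inconsistency error", {
  conc <- seq(3000, 8000, length.out = 6)
  kobs <- 2 * conc / 1000 - 4   # intercept -4, essentially no scatter
  s <- kobs_series(conc, kobs, role = "dead_end_ligand")
  expect_error(fit_binding_kinetics(s), class = "flavokin_fit_error")
})

test_that("first-order Kd error propagation agrees with a seed bootstrap", {
  L <- seq(500, 8000, length.out = 8)
  fit <- fit_binding_kinetics(
    gen_kobs(L, "dead_end_ligand", kon = 47, koff = 13,
             noise_sd = 0.03, seed = 1))
  se_prop <- fit$params$std.error[fit$params$term == "Kd_acid"]
  kds <- sapply(1:200, function(s) {
    f <- fit_binding_kinetics(
      gen_kobs(L, "dead_end_ligand", kon = 47, koff = 13,
               noise_sd = 0.03, seed = 10000 + s))
    f$params$estimate[f$params$term == "Kd_acid"]
  })
  se_boot <- sd(kds, na.rm = TRUE)
  expect_lt(abs(se_prop - se_boot) / se_boot, 0.6)
})

test_that("replicate averaging shrinks kobs scatter by sqrt(replicates)", {
  draws <- function(reps) {
    sapply(1:400, function(s) {
      gen_kobs(1000, "reductant", kred = 117, Kd = 765,
               noise_sd = 0.05, seed = 5000 + s,
               replicates = reps)$kobs_per_s
    })
  }
  ratio <- sd(draws(1)) / sd(draws(4))
  expect_equal(ratio, 2, tolerance = 0.25)
})
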