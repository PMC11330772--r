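test_that("thermodynamic relations reproduce the reference signatures", {
  th <- thermo_relations(27.1, -25.1)
  expect_equal(th$dG_kcal_mol, -6.2, tolerance = 0.01)
  expect_equal(th$TdS_neg_kcal_mol, 18.9, tolerance = 0.01)
  th2 <- thermo_relations(0.05, -21.4)
  expect_equal(th2$dG_kcal_mol, -9.9, tolerance = 0.01)
  expect_equal(th2$TdS_neg_kcal_mol, 11.5, tolerance = 0.01)
  # 1 M standard state is the zero of dG
  expect_equal(thermo_relations(1e6, -10)$dG_kcal_mol, 0)
})

test_that("one-site heats obey stoichiometric and saturation limits", {
  ex <- itc_experiment(6, 50)
  expect_equal(one_site_heats(1e7, 0, 1, ex), rep(0, 19))
  # tight binding: the first injection's ligand is fully bound,
  # heat ~ dH x injected moles = -21.4 * 0.1 nmol = -2.14 ucal
  h <- one_site_heats(1 / 0.05e-6, -21.4, 1, ex)
  expect_equal(h[1], -2.14, tolerance = 0.02)
  # total heat ~ n * dH * cell moles (1.2 nmol), within dilution losses
  expect_equal(sum(h), -21.4 * 1.2, tolerance = 0.15)
  # heat magnitude decreases monotonically past the equivalence point
  expect_true(all(diff(abs(h[10:19])) < 0))
})

test_that("noiseless simulate-fit round trip recovers Ka, dH and n", {
  ex <- itc_experiment(6, 50)
  sim <- gen_itc(0.5, -15, 1.1, ex, noise_frac = 0)
  fit <- fit_itc(sim)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_lt(abs(est["Kd"] - 0.5) / 0.5, 1e-4)
  expect_lt(abs(est["dH"] - (-15)) / 15, 1e-5)
  expect_lt(abs(est["n"] - 1.1) / 1.1, 1e-5)
})

test_that("tight-binding titration recovers Kd within 2x and dH within 5%", {
  sim <- gen_itc(0.05, -21.4, 1, itc_experiment(6, 50),
                 noise_frac = 0.02, seed = 7)
  fit <- fit_itc(sim)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_lt(est[["Kd"]], 0.1)
  expect_gt(est[["Kd"]], 0.025)
  expect_lt(abs(est[["dH"]] - (-21.4)) / 21.4, 0.05)
})

test_that("low-c titration recovers dH and warns about identifiability", {
  sim <- gen_itc(27.1, -25.1, 1, itc_experiment(15, 100),
                 noise_frac = 0.02, seed = 7)
  expect_warning(fit <- fit_itc(sim), "c = ")
  expect_true("low_c" %in% fit$flags)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_lt(abs(est[["dH"]] - (-25.1)) / 25.1, 0.05)
})

test_that("derived thermodynamics are internally consistent by construction", {
  sim <- gen_itc(1, -12, 1, itc_experiment(6, 50), noise_frac = 0.01,
                 seed = 3)
  fit <- fit_itc(sim)
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_equal(est[["Kd"]], 1e6 / est[["Ka"]], tolerance = 1e-12)
  expect_equal(est[["dG"]],
               1.987e-3 * 298.15 * log(est[["Kd"]] * 1e-6),
               tolerance = 1e-12)
  expect_equal(est[["TdS_neg"]], est[["dG"]] - est[["dH"]],
               tolerance = 1e-12)
})

test_that("experiment validation rejects malformed designs", {
  expect_error(itc_experiment(6, 50, injection_volumes_uL = c(2, -1)),
               class = "flavokin_input_error")
  expect_error(itc_experiment(6, 50, heats_ucal = 1:3),
               class = "flavokin_input_error")
  short <- itc_experiment(6, 50, injection_volumes_uL = rep(2, 5),
                          heats_ucal = rep(-1, 5))
  expect_error(fit_itc(short), class = "flavokin_input_error")
})
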