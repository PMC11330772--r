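test_that("noiseless bi-substrate data return the generating parameters", {
  fit <- fit_bisubstrate(pe_o2_grid(), "pingpong")
  est <- setNames(fit$params$estimate, fit$params$term)
  expect_lt(abs(est["kcat"] - 201) / 201, 1e-6)
  expect_lt(abs(est["Km_alcohol"] - 50) / 50, 1e-6)
  expect_lt(abs(est["Km_acceptor"] - 176) / 176, 1e-6)

  d_seq <- gen_bisubstrate(201, 50, 176, Kd_alcohol = 80,
                           A = grid_A(), B = grid_B(), noise_sd = 0)
  fit_seq <- fit_bisubstrate(d_seq, "sequential")
  est2 <- setNames(fit_seq$params$estimate, fit_seq$params$term)
  expect_lt(abs(est2["Kd_alcohol"] - 80) / 80, 1e-5)
  expect_lt(abs(est2["kcat"] - 201) / 201, 1e-6)
})

test_that("catalytic efficiencies are the kcat/Km ratios in s^-1 mM^-1", {
  fit <- fit_bisubstrate(pe_o2_grid(0.02, seed = 5), "pingpong")
  est <- setNames(fit$params$estimate, fit$params$term)
  eff <- setNames(fit$efficiencies$estimate, fit$efficiencies$term)
  expect_equal(eff[["eff_alcohol"]], 1000 * est[["kcat"]] / est[["Km_alcohol"]])
  expect_equal(eff[["eff_acceptor"]], 1000 * est[["kcat"]] / est[["Km_acceptor"]])
})

test_that("degenerate concentration grids are rejected", {
  d <- pe_o2_grid()
  expect_error(fit_bisubstrate(dplyr::filter(d, acceptor_uM == 176)),
               class = "flavokin_input_error")
  expect_error(fit_bisubstrate(dplyr::filter(d, alcohol_uM %in% c(10, 50))),
               class = "flavokin_input_error")
  expect_error(bisubstrate_data(c(-5, 10), 20, 1),
               class = "flavokin_input_error")
})

test_that("Hanes-Woolf intercepts are acceptor-independent for ping-pong data", {
  hw <- hanes_woolf(pe_o2_grid())
  expect_equal(hw$intercept, rep(50 / 201, nrow(hw)), tolerance = 1e-9)
  expect_lt(sd(hw$intercept) / mean(hw$intercept), 1e-9)
})

test_that("Hanes-Woolf intercepts grow as acceptor drops for sequential data", {
  Kd <- 80; KmB <- 176
  d <- gen_bisubstrate(201, 50, KmB, Kd_alcohol = Kd,
                       A = grid_A(), B = grid_B(), noise_sd = 0)
  hw <- dplyr::arrange(hanes_woolf(d), acceptor_uM)
  expect_true(all(diff(hw$intercept) < 0))
  # algebraic intercept: (KmA + Kd*KmB/B)/kcat
  expect_equal(hw$intercept, (50 + Kd * KmB / hw$acceptor_uM) / 201,
               tolerance = 1e-9)
})

test_that("mechanism discrimination identifies the generating mechanism", {
  expect_identical(
    discriminate_mechanism(pe_o2_grid(0.02, seed = 3))$chosen_model,
    "pingpong")
  # sequential with Kd >> KmA is clearly non-ping-pong
  d_seq <- gen_bisubstrate(201, 50, 176, Kd_alcohol = 500,
                           A = grid_A(), B = grid_B(),
                           noise_sd = 0.02, seed = 3)
  v <- discriminate_mechanism(d_seq)
  expect_identical(v$chosen_model, "sequential")
  # noiseless data give a decisive AICc margin for the generating model
  v0 <- discriminate_mechanism(
    gen_bisubstrate(201, 50, 176, Kd_alcohol = 500,
                    A = grid_A(), B = grid_B(), noise_sd = 0))
  expect_identical(v0$chosen_model, "sequential")
  expect_gt(-v0$delta_aicc, 10)
})

test_that("parameter recovery at 2% noise has small median bias", {
  est <- sapply(1:20, function(s) {
    f <- fit_bisubstrate(pe_o2_grid(0.02, seed = s), "pingpong")
    setNames(f$params$estimate, f$params$term)
  })
  truth <- c(kcat = 201, Km_alcohol = 50, Km_acceptor = 176)
  bias <- abs(apply(est, 1, median) - truth) / truth
  expect_true(all(bias < 0.02))
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_bisubstrate(pe_o2_grid(0.02, seed = 1), "pingpong")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "units") %in% names(td)))
  expect_true(all(c("kcat", "eff_alcohol") %in% td$term))
  gl <- glance(fit)
  expect_identical(gl$model, "pingpong")
  expect_identical(gl$nobs, nrow(fit$data))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(hanes_woolf(pe_o2_grid())), "ggplot")
})
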