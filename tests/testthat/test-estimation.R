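test_that("log-linear regression recovers the slope of exact decay data", {
  tt <- c(0, 12, 24, 48, 72)
  s <- conc_series(tt, 2 * exp(-0.0244 * tt), "ng/mL")
  fit <- fit_kelim(s)
  expect_equal(fit$estimate, 0.0244, tolerance = 1e-12)
  expect_equal(fit$residual_ss, 0, tolerance = 1e-20)
  expect_equal(fit$n_points, 5L)
  expect_equal(fit$unit, "1/h")
})

test_that("fit_kelim rejects unusable series", {
  expect_error(fit_kelim(conc_series(0, 1, "ng/mL")), "at least 2")
  expect_error(
    fit_kelim(conc_series(c(0, 10), c(1, 0), "ng/mL")),
    "strictly positive"
  )
})

test_that("terminal slope of a simulated cycle reproduces the generating k_elim", {
  # machine-precision round trip through the closed-form decay phase
  for (p in tbl1) {
    reg <- standard_cycle()
    tt <- seq(510, 590, by = 10)
    s <- conc_series(tt, patchpk:::predict_analytic(p, reg, tt), p$conc_unit)
    fit <- fit_kelim(s)
    expect_equal(fit$estimate, p$k_elim, tolerance = 1e-9)
  }
})

test_that("derive_vd round-trips the published clearance and half-life", {
  k_fit <- fit_kelim(conc_series(
    seq(0, 96, by = 12), 1.5 * exp(-(log(2) / 28.4) * seq(0, 96, by = 12)),
    "ng/mL"
  ))$estimate
  expect_equal(derive_vd(7.89, k_fit), 323300, tolerance = 1e-3)
})

test_that("noiseless trajectory fitting recovers the attenuation constant", {
  pars <- tbl1$NGMN
  reg <- standard_cycle()
  des <- sampling_design(pars, reg,
                         sample_times = seq(24, 480, length.out = 20),
                         noise_cv = 0, seed = 1)
  fit <- fit_decay_const(generate_observations(des), pars, reg)
  expect_equal(fit$estimate, 0.0028, tolerance = 0.01)
  expect_true(fit$converged)
  expect_equal(fit$unit, "1/day")
  expect_lt(fit$residual_ss, 1e-12)
})

test_that("degenerate all-zero observations pin the fit at the bound", {
  pars <- tbl1$NGMN
  reg <- standard_cycle()
  obs <- conc_series(seq(12, 480, by = 24), rep(0, 20), "ng/mL")
  fit <- fit_decay_const(obs, pars, reg)
  expect_false(fit$converged)
  expect_equal(fit$estimate, 10 * 0.0028) # upper bound of the search
})

test_that("attenuation fit is invariant to joint rescaling of dose and data", {
  pars <- tbl1$NGMN
  reg <- standard_cycle()
  tt <- seq(24, 480, length.out = 15)
  des <- sampling_design(pars, reg, sample_times = tt,
                         noise_cv = 0.05, seed = 11)
  obs <- generate_observations(des)
  fit1 <- fit_decay_const(obs, pars, reg)

  scaled_pars <- drug_params("NGMN",
    k_o = 7 * pars$k_o, Cl = pars$Cl, t_half = pars$t_half,
    k_elim = pars$k_elim, V_d = pars$V_d, decay_const = pars$decay_const,
    conc_unit = pars$conc_unit, therapeutic_low = pars$therapeutic_low,
    therapeutic_high = pars$therapeutic_high
  )
  scaled_obs <- conc_series(obs$times, 7 * obs$values, obs$unit)
  fit7 <- fit_decay_const(scaled_obs, scaled_pars, reg)
  expect_equal(fit7$estimate, fit1$estimate, tolerance = 1e-5)
  expect_equal(fit7$residual_ss, 49 * fit1$residual_ss, tolerance = 1e-6)
})

test_that("fit_decay_const validates inputs", {
  pars <- tbl1$NGMN
  reg <- standard_cycle()
  expect_error(
    fit_decay_const(conc_series(1, 1, "pg/mL"), pars, reg),
    "unit"
  )
  expect_error(
    fit_decay_const(conc_series(c(100, 700), c(1, 1), "ng/mL"), pars, reg),
    "horizon"
  )
})
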