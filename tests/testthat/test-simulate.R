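test_that("absorption rate matches the direct arithmetic of the constants", {
  ngmn <- tbl1$NGMN
  # zero-age rate: k_o / V_d = 150,000 ng/day over 323,300 mL, per hour
  expect_equal(absorption_rate(ngmn, 0, 1), 150 * 1000 / 323300 / 24)
  expect_equal(absorption_rate(ngmn, 0, 1) * 24, 0.464, tolerance = 1e-3)
  # no patch attached
  expect_equal(absorption_rate(ngmn, 100, 0), 0)
  # monotone decay towards 0 with patch age
  ages <- seq(0, 1e6, by = 5e4)
  r <- absorption_rate(ngmn, ages, 1)
  expect_true(all(diff(r) < 0))
  expect_lt(r[length(r)], 1e-8)
  expect_error(absorption_rate(ngmn, -1, 1), "non-negative")
  expect_error(absorption_rate(ngmn, 1, 2), "\\[0, 1\\]")
})

test_that("elimination rate is first order in concentration", {
  expect_equal(elimination_rate(tbl1$NGMN, 1), 0.0244)
  expect_equal(elimination_rate(tbl1$NGMN, 0), 0)
  expect_equal(elimination_rate(tbl1$EE, 50), 1.925)
  expect_error(elimination_rate(tbl1$NGMN, -1), "non-negative")
})

test_that("a non-releasing patch leaves pure exponential decay", {
  p <- toy_params(k_o = 0)
  g <- sim_grid(0.5, 200)
  s <- simulate_analytic(p, standard_cycle(), g, c0 = 3)
  expect_equal(s$values, 3 * exp(-p$k_elim * g$times))
  sd <- simulate_difference(p, standard_cycle(), g, c0 = 3)
  expect_equal(sd$values, 3 * (1 - p$k_elim * 0.5)^(seq_along(g$times) - 1))
})

test_that("degenerate zero-horizon simulation returns the initial state", {
  g <- sim_grid(0.1, 0)
  s <- simulate_difference(tbl1$NGMN, standard_cycle(), g, c0 = 0)
  expect_equal(length(s), 1L)
  expect_equal(s$values, 0)
})

test_that("constant absorption drives the closed form to k0_rate / k_elim", {
  p <- toy_params(decay_const = 0)
  reg <- one_patch(4000)
  s <- simulate_analytic(p, reg, sim_grid(1, 4000))
  expect_equal(s$values[length(s)], p$k0_rate / p$k_elim, tolerance = 1e-8)
})

test_that("difference scheme converges first order to the closed form", {
  reg <- standard_cycle()
  dev <- vapply(c(0.1, 0.05), function(dt) {
    g <- sim_grid(dt, 600)
    max(abs(simulate_difference(tbl1$NGMN, reg, g)$values -
              simulate_analytic(tbl1$NGMN, reg, g)$values))
  }, numeric(1))
  expect_lt(dev[2], dev[1])
  expect_equal(dev[1] / dev[2], 2, tolerance = 0.1)
})

test_that("simulated trajectories are non-negative across scenario space", {
  regs <- list(standard_cycle(), delayed_replacement(3),
               detachment(72, 0.5, 24), detachment(192, 0, 24, TRUE))
  for (reg in regs) {
    for (p in tbl1) {
      g <- sim_grid(0.25, reg$horizon)
      expect_true(all(simulate_difference(p, reg, g)$values >= 0))
      expect_true(all(simulate_analytic(p, reg, g)$values >= 0))
    }
  }
})

test_that("the model is linear in dose and in attached area", {
  reg <- standard_cycle()
  g <- sim_grid(0.2, 600)
  base <- simulate_difference(tbl1$NGMN, reg, g)

  doubled <- tbl1$NGMN
  doubled <- drug_params("NGMN",
    k_o = 2 * doubled$k_o, Cl = doubled$Cl, t_half = doubled$t_half,
    k_elim = doubled$k_elim, V_d = doubled$V_d,
    decay_const = doubled$decay_const, conc_unit = doubled$conc_unit,
    therapeutic_low = doubled$therapeutic_low,
    therapeutic_high = doubled$therapeutic_high
  )
  expect_equal(simulate_difference(doubled, reg, g)$values, 2 * base$values)

  # half the contact area from t = 0 halves the whole trajectory
  half_reg <- regimen(
    rbind(patch_event(0, "apply_new", 0.5),
          patch_event(168, "replace", 1),
          patch_event(336, "replace", 1),
          patch_event(504, "remove")),
    horizon = 600
  )
  half_reg$events$area_fraction[2:3] <- 0.5 # replacements also half-attached
  half <- simulate_difference(tbl1$NGMN, regimen(half_reg$events, 600), g)
  expect_equal(half$values, 0.5 * base$values)
})

test_that("patch age resets on replacement but not on reattachment", {
  p <- toy_params(decay_const = 0.5, decay_unit = "1/h") # fast attenuation
  # same timeline, differing only in how the patch comes back at t = 60
  back_new <- regimen(rbind(patch_event(0, "apply_new"),
                            patch_event(40, "detach", 0),
                            patch_event(60, "apply_new")), horizon = 100)
  back_old <- regimen(rbind(patch_event(0, "apply_new"),
                            patch_event(40, "detach", 0),
                            patch_event(60, "reattach")), horizon = 100)
  g <- sim_grid(0.1, 100)
  cn <- simulate_analytic(p, back_new, g)$values
  co <- simulate_analytic(p, back_old, g)$values
  i70 <- which(g$times == 70)
  # the fresh patch delivers at full zero-age rate, the old one barely
  expect_gt(cn[i70], co[i70])
  ab_new <- absorption_rate(p, patch_age = 0)
  ab_old <- absorption_rate(p, patch_age = 60)
  expect_gt(ab_new / ab_old, 1e10)
})

test_that("unstable step sizes are rejected rather than clipped", {
  p <- toy_params(k_elim = 1.5) # 1/k = 0.67 h < dt = 1 h
  expect_error(
    simulate_difference(p, one_patch(100), sim_grid(1, 100)),
    "unstable"
  )
  expect_error(sim_grid(2, 100), "dt")
  expect_error(sim_grid(0.3, 100.05), "whole number")
})

test_that("grid horizon cannot exceed the regimen horizon", {
  expect_error(
    simulate_difference(tbl1$NGMN, standard_cycle(), sim_grid(0.5, 1000)),
    "horizon"
  )
})
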