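test_that("AUC of simple shapes matches hand arithmetic", {
  s <- conc_series(seq(0, 168, by = 1), rep(2.5, 169), "ng/mL")
  expect_equal(auc(s, 0, 168), 2.5 * 168)
  # triangle: C rises linearly 0 -> 1 over 0 -> 100
  tri <- conc_series(c(0, 100), c(0, 1), "ng/mL")
  expect_equal(auc(tri, 0, 100), 50)
  expect_equal(auc(tri, 0, 50), 12.5) # mean height 0.25 over 50 h
  expect_error(auc(tri, 50, 10), "less than")
  expect_error(auc(tri, -10, 50), "within")
})

test_that("AUC is exactly additive over abutting windows", {
  g <- sim_grid(0.1, 600)
  s <- simulate_difference(tbl1$NGMN, standard_cycle(), g)
  # grid-aligned and non-aligned split points
  for (a in c(168, 250.55, 333.333)) {
    expect_equal(auc(s, 0, a) + auc(s, a, 504), auc(s, 0, 504))
  }
})

test_that("css is the time average and equals any constant series' value", {
  s <- conc_series(seq(0, 504, by = 4), rep(0.9, 127), "ng/mL")
  expect_equal(css(s), 0.9)
  expect_equal(css(s, window = c(10, 20)), 0.9)
  lin <- conc_series(c(336, 504), c(0, 1), "ng/mL")
  expect_equal(css(lin), 0.5)
})

test_that("weekly AUC decomposition is consistent with the total", {
  g <- sim_grid(0.1, 600)
  s <- simulate_difference(tbl1$EE, standard_cycle(), g)
  wk <- weekly_auc(s)
  expect_length(wk$weekly, 3)
  expect_equal(sum(wk$weekly), auc(s, 0, 504))
  expect_equal(wk$mean, mean(wk$weekly))
})

test_that("range crossings locate constructed band exits by interpolation", {
  # entirely inside the band
  s_in <- conc_series(c(0, 100, 200), c(0.8, 1.0, 0.9), "ng/mL")
  r <- range_crossings(s_in, 0.6, 1.2)
  expect_equal(nrow(r$risk_windows), 0)
  expect_equal(nrow(r$over_windows), 0)
  expect_equal(r$time_in_range, 200)

  # single downward crossing of 0.6 exactly at t = 100, never returns
  s_dn <- conc_series(c(0, 50, 150, 200), c(1.0, 0.9, 0.3, 0.1), "ng/mL")
  r <- range_crossings(s_dn, 0.6, 1.2)
  expect_equal(nrow(r$risk_windows), 1)
  expect_equal(r$risk_windows$start, 100)
  expect_equal(r$risk_windows$end, 200)

  # symmetric excursion above the band
  s_up <- conc_series(c(0, 10, 20), c(1.0, 1.4, 1.0), "ng/mL")
  r <- range_crossings(s_up, 0.6, 1.2)
  expect_equal(nrow(r$over_windows), 1)
  expect_equal(r$over_windows$start, 5)
  expect_equal(r$over_windows$end, 15)
  expect_error(range_crossings(s_up, 2, 1), "less than")
})

test_that("below, in-range and above durations partition the span", {
  reg <- delayed_replacement(3)
  g <- sim_grid(0.1, reg$horizon)
  for (p in list(tbl1$NGMN, tbl1$EE)) {
    s <- simulate_difference(p, reg, g)
    r <- range_crossings(s, p$therapeutic_low, p$therapeutic_high,
                         span = c(0, 504))
    expect_equal(r$time_below + r$time_in_range + r$time_above, 504)
    if (nrow(r$risk_windows) > 1) {
      expect_true(all(diff(as.vector(t(r$risk_windows))) >= 0)) # ordered, disjoint
    }
  }
})

test_that("pk_summary assembles the conventional report", {
  g <- sim_grid(0.1, 600)
  s <- simulate_difference(tbl1$NGMN, standard_cycle(), g)
  sm <- pk_summary(s, tbl1$NGMN)
  expect_s3_class(sm, "pk_summary")
  expect_equal(sm$c_ss, css(s))
  expect_equal(sm$auc_0_168, weekly_auc(s)$mean)
  expect_equal(sm$t_half, log(2) / 0.0244)
  expect_lte(sm$time_in_range, 504)
  # units are checked before mixing
  expect_error(pk_summary(s, tbl1$EE), "unit")
})
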