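test_that("event and regimen validation enforce the wear-state rules", {
  expect_error(patch_event(-1, "apply_new"), "non-negative")
  expect_error(patch_event(0, "apply_new", area_fraction = 1.5), "\\[0, 1\\]")
  expect_error(patch_event(10, "remove", area_fraction = 0.5), "remove")
  expect_error(patch_event(10, "replace", area_fraction = 0), "positive")

  # first event must put a patch on
  expect_error(regimen(patch_event(0, "remove", 0), horizon = 10),
               "apply_new")
  # events beyond the horizon
  expect_error(
    regimen(rbind(patch_event(0, "apply_new"), patch_event(20, "remove")),
            horizon = 10),
    "within"
  )
  # overlapping patches: a second apply_new while one is attached
  expect_error(
    regimen(rbind(patch_event(0, "apply_new"),
                  patch_event(24, "apply_new")), horizon = 100),
    "overlapping"
  )
  # detach with nothing on the skin
  expect_error(
    regimen(rbind(patch_event(0, "apply_new"),
                  patch_event(24, "remove"),
                  patch_event(48, "detach", 0.5)), horizon = 100),
    "detach"
  )
  # replace after removal
  expect_error(
    regimen(rbind(patch_event(0, "apply_new"),
                  patch_event(24, "remove"),
                  patch_event(48, "replace")), horizon = 100),
    "replace"
  )
  # events are sorted on construction
  r <- regimen(rbind(patch_event(168, "replace"),
                     patch_event(0, "apply_new"),
                     patch_event(336, "remove")), horizon = 400)
  expect_equal(r$events$time, c(0, 168, 336))
})

test_that("wear state tracks area fraction and patch age across events", {
  reg <- regimen(
    rbind(
      patch_event(0, "apply_new"),
      patch_event(100, "replace"),
      patch_event(150, "detach", 0.5),
      patch_event(170, "reattach", 1),
      patch_event(250, "remove")
    ),
    horizon = 300
  )
  st <- patchpk:::wear_state(reg, c(50, 120, 160, 200, 260))
  expect_equal(st$fraction, c(1, 1, 0.5, 1, 0))
  # age resets at replace (t=100) but keeps running through detach/reattach
  expect_equal(st$age[1:4], c(50, 20, 60, 100))
})

test_that("standard cycle has the canonical four events and decay tail", {
  reg <- standard_cycle()
  expect_equal(nrow(reg$events), 4)
  expect_equal(reg$events$kind, c("apply_new", "replace", "replace", "remove"))
  expect_equal(reg$events$time, c(0, 168, 336, 504))
  expect_gte(reg$horizon, 504 + 96)
})

test_that("delayed replacement reduces to the standard cycle at zero delay", {
  expect_identical(delayed_replacement(0), standard_cycle())
  d3 <- delayed_replacement(3)
  expect_equal(d3$events$time, c(0, 168, 408, 576))
  expect_error(delayed_replacement(-1), "non-negative")
})

test_that("detachment inserts and reverts a wear interruption", {
  reg <- detachment(72, 0.5, 24)
  ev <- reg$events
  expect_equal(ev$kind[ev$time == 72], "detach")
  expect_equal(ev$area_fraction[ev$time == 72], 0.5)
  expect_equal(ev$kind[ev$time == 96], "reattach")

  # no-op cases return the standard cycle exactly
  expect_identical(detachment(72, 1, 24), standard_cycle())
  expect_identical(detachment(72, 0.5, 0), standard_cycle())

  # a fresh patch is only allowed after total detachment
  new_reg <- detachment(192, 0, 24, reattach_as_new = TRUE)
  expect_equal(new_reg$events$kind[new_reg$events$time == 216], "apply_new")
  expect_error(detachment(192, 0.5, 24, reattach_as_new = TRUE), "total")

  # detachment must not straddle a scheduled event
  expect_error(detachment(160, 0.5, 24), "inside one wear week")
  expect_error(detachment(600, 0.5, 24), "worn")
})
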