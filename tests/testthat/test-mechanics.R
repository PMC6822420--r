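test_that("anatomical dead space scales linearly with predicted body weight", {
  expect_equal(anatomical_dead_space(74), 162.8)
  expect_equal(anatomical_dead_space(100), 220)
  expect_error(anatomical_dead_space(0), "positive")
  expect_error(anatomical_dead_space(-5), "positive")
})

test_that("predicted body weight follows the ARDSNet formula", {
  expect_equal(predicted_body_weight(181, "male"), 50 + 0.905 * 28.6)
  expect_equal(predicted_body_weight(181, "male"), 75.9, tolerance = 1e-3)
  expect_equal(predicted_body_weight(152.4, "male"), 50)
  expect_equal(predicted_body_weight(152.4, "female"), 45.5)
  expect_error(predicted_body_weight(100, "male"), "120-220")
  expect_error(predicted_body_weight(250, "female"), "120-220")
})

test_that("patient mechanics enforce positivity and RCe consistency", {
  m <- patient_mechanics(crs = 55, r_insp = 11, rce = 0.82, pbw = 74)
  expect_equal(m$r_exp * m$crs / 1000, m$rce, tolerance = 1e-12)
  expect_equal(m$vda, 162.8)
  expect_true(trial_eligible(m))
  expect_false(trial_eligible(patient_mechanics(crs = 80, r_insp = 11,
                                                rce = 1.6, pbw = 74)))
  expect_error(patient_mechanics(crs = -1, r_insp = 11, rce = 0.8, pbw = 74),
               "positive")
  expect_error(patient_mechanics(crs = 55, r_insp = 11, pbw = 74),
               "r_exp.*rce|rce.*r_exp")
  expect_error(patient_mechanics(crs = 55, r_insp = 11, r_exp = 10,
                                 rce = 0.9, pbw = 74), "inconsistent")
})

test_that("Otis fixed point matches the cohort-typical example and limits", {
  inp <- typical_input()
  sel <- select_rr_otis(inp)
  expect_equal(sel$rr, 13.6, tolerance = 0.01)
  # residual of the fixed point in canonical breaths/s
  expect_lt(sel$residual, 1e-9)
  expect_false(sel$clamped)
  # RCe -> 0 limit is VE/(2 VDa)
  lim <- select_rr_otis(typical_input(rce = 1e-9))
  expect_equal(lim$rr, 8491 / (2 * 162.8), tolerance = 0.01)
  # doubling the dead space lowers the selected rate
  sel2 <- select_rr_otis(typical_input(vda = 325.6))
  expect_lt(sel2$rr, sel$rr)
})

test_that("min-power fixed point matches its oracle and analytic limits", {
  sel <- select_rr_minpower(typical_input())
  expect_equal(sel$rr, 18.05, tolerance = 0.05)
  expect_lt(sel$residual, 1e-9)
  # shared RCe -> 0 limit with the Otis selector
  lim <- select_rr_minpower(typical_input(rce = 1e-9))
  expect_equal(lim$rr, 26.078, tolerance = 0.01)
  # correction factor in (0,1): rate below VE/(2 VDa), VT above 2 VDa
  expect_lt(sel$rr, 8491 / (2 * 162.8))
  expect_gt(sel$vt, 2 * 162.8)
})

test_that("large-RCe behaviour follows the inverse-sqrt asymptote with its
           known first-order correction", {
  # the fixed point approaches sqrt(VE/(8 VDa RCe)) from below, with
  # relative deviation 1/(12 x), x = 2 RR RCe (verified against the
  # asymptotic expansion of the correction factor)
  for (rce in c(50, 200, 800)) {
    sel <- select_rr_minpower(typical_input(rce = rce, rr_min = 0.5))
    asym <- sqrt(8491 / 60 / (8 * 162.8 * rce)) * 60
    dev <- asym / sel$rr - 1
    x <- 2 * (sel$rr / 60) * rce
    expect_gt(dev, 0)
    expect_equal(dev, 1 / (12 * x), tolerance = 0.05)
  }
})

test_that("min-power rate always exceeds the Otis rate across the cohort grid", {
  g <- selector_grid()
  for (i in seq_len(nrow(g))) {
    inp <- rr_selection_input(g$ve[i], g$vda[i], g$rce[i])
    rr_a <- select_rr_otis(inp)$rr
    rr_2 <- select_rr_minpower(inp)$rr
    expect_gte(rr_2, rr_a - 1e-6)
    expect_gt(select_rr_minpower(inp)$vt, 2 * g$vda[i])
  }
})

test_that("selectors reject inadmissible targets", {
  # VE so small that no rate in bounds keeps alveolar ventilation positive
  expect_error(select_rr_otis(rr_selection_input(300, 160, 0.8)),
               "admissible|alveolar")
  expect_error(rr_selection_input(-1, 160, 0.8), "positive")
  expect_error(rr_selection_input(8000, 160, -0.1), "non-negative")
})

test_that("square-wave inspiratory power converts units exactly", {
  expect_equal(inspiratory_power_square_wave(10, 10, 500), 4.903,
               tolerance = 1e-3)
  expect_equal(inspiratory_power_square_wave(0, 10, 500), 0)
  # arithmetic on mode-level means (plausibility scale of measured power)
  expect_equal(inspiratory_power_square_wave(12.9, 23.9, 606.8), 18.35,
               tolerance = 1e-2)
  expect_error(inspiratory_power_square_wave(-1, 10, 500), "non-negative")
})

test_that("power curve argmin coincides with the fixed point", {
  pc <- power_curve(typical_input(), crs = 55)
  sel <- select_rr_minpower(typical_input())
  expect_equal(pc$argmin_rr, sel$rr, tolerance = 0.05)
  expect_false(pc$boundary)
  expect_true(all(pc$power >= 0))
  # local-minimum sanity: neighbours on the grid are no better
  i <- which.min(pc$power)
  expect_lte(pc$power[i], pc$power[max(i - 100, 1)])
  expect_lte(pc$power[i], pc$power[min(i + 100, length(pc$power))])
  # RCe -> 0: argmin at the shared analytic limit
  pc0 <- power_curve(typical_input(rce = 1e-9), crs = 55)
  expect_equal(pc0$argmin_rr, 26.08, tolerance = 0.05)
})
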