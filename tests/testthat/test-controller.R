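test_that("inspiratory-time rules match their design targets", {
  # AVM2 at the observed mode-level rate: exact half cycle
  expect_equal(ie_rule("AVM2", 15.8, 0.82), 0.5 * 60 / 15.8)
  expect_equal(ie_rule("AVM2", 15.8, 0.82), 1.899, tolerance = 1e-3)
  # expiratory-time protection shortens Ti at high RR * RCe
  ti_hi <- ie_rule("AVM2", 20, 1.0)
  expect_equal(60 / 20 - ti_hi, 2 * 1.0)
  # AVM grants at least min(3 RCe, 2/3 cycle) of expiration across a grid
  for (rr in c(10, 13, 16, 20)) for (rce in c(0.3, 0.8, 1.2, 1.5)) {
    te <- 60 / rr - ie_rule("AVM", rr, rce)
    expect_gte(te, min(3 * rce, 2 / 3 * 60 / rr) - 1e-9)
  }
  # vanishing RCe: AVM Ti capped at its maximum inspiratory fraction
  expect_equal(ie_rule("AVM", 15, 1e-9), (60 / 15) / 3, tolerance = 1e-6)
})

test_that("banded %MinVol rule follows the protocol", {
  expect_equal(minvol_adjustment(41, 40, 100), 100)
  expect_equal(minvol_adjustment(44, 40, 100), 110)
  expect_equal(minvol_adjustment(36, 40, 110), 99)
  expect_equal(minvol_adjustment(80, 40, 340), 350)   # upper bound
  expect_equal(minvol_adjustment(20, 40, 26), 25)     # lower bound
  expect_error(minvol_adjustment(-1, 40, 100), "positive")
})

test_that("controller step reproduces the mechanics-core oracle chain", {
  m <- typical_mech()
  cfg2 <- mode_config("AVM2", nominal_ve = 8491)
  s2 <- controller_step(cfg2, m, peep = 8)
  expect_equal(s2$settings$rr, 18.05, tolerance = 0.05)
  expect_equal(s2$vt_target, 8491 / s2$settings$rr, tolerance = 1e-9)
  expect_equal(s2$vt_target, 470, tolerance = 1)
  cfga <- mode_config("AVM", nominal_ve = 8491)
  sa <- controller_step(cfga, m, peep = 8)
  expect_equal(sa$settings$rr, 13.6, tolerance = 0.05)
  expect_equal(sa$vt_target, 624, tolerance = 1)
  # AVM2 tidal volume exceeds twice the anatomical dead space
  expect_gt(s2$vt_target, 2 * m$vda)
  # determinism
  expect_identical(controller_step(cfg2, m, peep = 8), s2)
})

test_that("the servo pressure actually delivers the target tidal volume", {
  m <- typical_mech(crs = 45, rce = 1.1, r_insp = 13)
  cfg <- mode_config("AVM2", nominal_ve = 7800)
  st <- controller_step(cfg, m, peep = 10)
  w <- simulate_breath(m, st$settings)
  expect_equal(breath_metrics(w)$vt_insp, st$vt_target,
               tolerance = 0.01 * st$vt_target)
})

test_that("closed loop reaches the etCO2 band for every cohort patient and
           equalizes alveolar ventilation across modes", {
  cohort <- generate_cohort(12, 6, seed = 21)
  for (pat in cohort) {
    loops <- lapply(c("AVM", "AVM2"), function(mode) {
      run_controller_loop(pat$mech,
                          mode_config(mode, nominal_ve = pat$baseline$ve),
                          peep = pat$baseline$peep,
                          baseline_etco2 = pat$baseline$etco2)
    })
    for (l in loops) {
      expect_true(l$converged)
      expect_true(l$in_band)
      expect_lte(l$steps, 20)
      # clamp-free on the cohort envelope
      expect_false(l$flags$rr_clamped)
      expect_false(l$flags$dp_clamped)
    }
    va <- vapply(loops, function(l) l$gas$va, numeric(1))
    expect_lt(abs(va[1] - va[2]) / min(va), 0.05)
  }
})

test_that("controller trace records every adjustment step", {
  pat <- sample_patient(99, ards = FALSE)
  loop <- run_controller_loop(pat$mech,
                              mode_config("AVM2",
                                          nominal_ve = pat$baseline$ve),
                              peep = pat$baseline$peep,
                              baseline_etco2 = pat$baseline$etco2)
  expect_named(loop$trace, c("step", "mode", "pct_minvol", "rr", "ti_s",
                             "delta_p", "etco2"))
  expect_equal(nrow(loop$trace), loop$steps + 1L)
  f <- tempfile(fileext = ".csv")
  write_controller_trace_csv(loop, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(loop$trace))
  unlink(f)
})
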