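test_that("static driving pressure needs a hold and recovers VT/Crs", {
  m <- typical_mech(crs = 50, r_insp = 10, rce = 0.8)
  set <- ventilator_settings(8, 10, rr = 10, ti = 1.5)   # te = 4.5 s, no trap
  ph <- simulate_phase(m, set, n_breaths = 3, terminal_hold = 2.5)
  dp <- driving_pressure_static(ph)
  vt <- breath_metrics(ph)$vt_exp[1]
  expect_equal(as.numeric(dp), vt / 50, tolerance = 0.02)
  expect_equal(attr(dp, "plateau"), 8 + as.numeric(dp))
  no_hold <- simulate_phase(m, set, n_breaths = 3)
  expect_error(driving_pressure_static(no_hold), "hold")
})

test_that("static compliance is expired volume over driving pressure", {
  expect_equal(static_compliance(500, 10), 50)
  expect_equal(static_compliance(606.8, 12.6), 48.2, tolerance = 0.05)
  expect_equal(static_compliance(0, 10), 0)
  expect_error(static_compliance(500, 0), "positive")
})

test_that("compliance recovery from simulated breaths is within 1%", {
  for (crs in c(35, 50, 70)) {
    m <- typical_mech(crs = crs, r_insp = 10, rce = 0.7)
    set <- ventilator_settings(8, 9, rr = 10, ti = 1.4)
    ph <- simulate_phase(m, set, n_breaths = 3, terminal_hold = 2.5)
    crs_m <- static_compliance(breath_metrics(ph)$vt_exp[1],
                               as.numeric(driving_pressure_static(ph)))
    expect_equal(crs_m, crs, tolerance = 0.01 * crs)
  }
})

test_that("mechanical power of an ideal square wave matches the closed form", {
  m <- typical_mech(crs = 50, r_insp = 8, rce = 0.7)
  set <- ventilator_settings(5, 10, rr = 10, ti = 2.5)
  ph <- simulate_phase(m, set, n_breaths = 10)
  vt <- breath_metrics(ph)$vt_exp[1]
  mp_expected <- 10 * (5 + 10) * vt * 9.80665e-5
  expect_equal(mechanical_power(ph), mp_expected,
               tolerance = 0.02 * mp_expected)
  # a linear pressurization ramp strictly reduces the inspiratory integral
  ramp <- simulate_phase(m, ventilator_settings(5, 10, rr = 10, ti = 2.5,
                                                rise_time = 0.4), 10)
  expect_lt(mechanical_power(ramp), mechanical_power(ph))
})

test_that("mean airway pressure is the duty-cycle weighted square-wave mean", {
  m <- typical_mech(crs = 50, r_insp = 0.5, rce = 0.3)  # fast lung: clean wave
  ie11 <- simulate_phase(m, ventilator_settings(8, 12, rr = 10, ti = 3), 5)
  expect_equal(mean_airway_pressure(ie11), 14.0, tolerance = 0.05)
  ie12 <- simulate_phase(m, ventilator_settings(8, 12, rr = 10, ti = 2), 5)
  expect_equal(mean_airway_pressure(ie12), 12.0, tolerance = 0.05)
})

test_that("expiratory time constant is recovered exactly, with noise within
           5%, and when truncated", {
  m <- typical_mech(crs = 50, r_insp = 10, rce = 0.8)
  w <- simulate_breath(m, ventilator_settings(8, 10, rr = 10, ti = 1.5))
  expect_equal(as.numeric(expiratory_time_constant(w)), 0.8,
               tolerance = 1e-3)
  expect_false(attr(expiratory_time_constant(w), "truncated"))

  # Gaussian flow noise, sigma = 5 ml/s: recovered within 5% (20 replicates)
  m12 <- typical_mech(crs = 60, r_insp = 10, rce = 1.2)
  w12 <- simulate_breath(m12, ventilator_settings(8, 10, rr = 8, ti = 1.5))
  set.seed(42)
  for (rep in 1:20) {
    wn <- w12
    wn$flow <- wn$flow + stats::rnorm(length(wn$flow), 0, 5)
    exp_idx <- which(w12$flow < 0)
    # volume re-integrated from the noisy flow over the expiratory limb
    wn$volume[exp_idx] <- wn$volume[exp_idx[1]] +
      cumsum(c(0, (wn$flow[exp_idx][-1] +
                     wn$flow[exp_idx][-length(exp_idx)]) / 2 * 0.01))
    expect_equal(as.numeric(expiratory_time_constant(wn)), 1.2,
                 tolerance = 0.05 * 1.2)
  }

  # truncated expiration (te = 1 tau): flagged, still accurate because the
  # fitted intercept absorbs the trapped volume
  mt <- typical_mech(crs = 50, r_insp = 10, rce = 0.8)
  wt <- simulate_breath(mt, ventilator_settings(8, 10,
                                                rr = 60 / 1.8, ti = 1.0))
  tau_t <- expiratory_time_constant(wt)
  expect_true(attr(tau_t, "truncated"))
  expect_equal(as.numeric(tau_t), 0.8, tolerance = 0.10 * 0.8)
})

test_that("Bohr dead space spans its algebraic range", {
  expect_equal(bohr_dead_space(40, 40, 500), 0)
  expect_equal(bohr_dead_space(40, 30, 500), 125)
  expect_equal(bohr_dead_space(40, 0, 500), 500)
  expect_error(bohr_dead_space(40, 45, 500), "within")
  expect_error(bohr_dead_space(0, 0, 500), "positive")
})

test_that("alveolar minute ventilation and the end-tidal Bohr identity", {
  expect_equal(alveolar_minute_ventilation(500, 125, 15), 5625)
  expect_equal(alveolar_minute_ventilation(500, 500, 15), 0)
  expect_equal(alveolar_minute_ventilation(532.8, 150, 15.8), 6048.24)
  expect_error(alveolar_minute_ventilation(500, 600, 15), "within")
  # VA = VE * eCO2/PaCO2 when VD comes from the Bohr relation
  vt <- 520; rr <- 14; pa <- 42; et <- 35
  vd <- bohr_dead_space(pa, et, vt)
  expect_equal(alveolar_minute_ventilation(vt, vd, rr),
               vt * rr * et / pa, tolerance = 1e-9)
})

test_that("window averaging uses only the final-window breaths", {
  mk <- function(t_end, vt) data.frame(breath = seq_along(t_end),
                                       t_start = t_end - 4, t_end = t_end,
                                       duration_s = 4, vt_exp = vt)
  # constant stream: mean equals any breath
  s1 <- mk(seq(4, 400, by = 4), 500)
  expect_equal(window_average(s1, 300)$vt_exp, 500)
  # step change 400 s before the end: window sees only post-change values
  t <- seq(4, 800, by = 4)
  s2 <- mk(t, ifelse(t <= max(t) - 400, 400, 520))
  expect_equal(window_average(s2, 300)$vt_exp, 520)
  # alternating breaths average to the midpoint (even count in window)
  s3 <- mk(seq(4, 400, by = 4), rep(c(480, 520), 50))
  expect_equal(window_average(s3, 200)$vt_exp, 500)
  expect_error(window_average(mk(seq(4, 40, 4), 500), 300), "shorter")
})
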