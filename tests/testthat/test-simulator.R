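test_that("settings validation rejects unphysical combinations", {
  expect_error(ventilator_settings(8, 12, rr = 20, ti = 3.2), "expiratory")
  expect_error(ventilator_settings(8, 12, rr = 15, ti = 1.5,
                                   hold_duration = 1), "2-3")
  expect_error(ventilator_settings(8, 0, rr = 15, ti = 1.5), "positive")
  expect_error(ventilator_settings(-1, 10, rr = 15, ti = 1.5),
               "non-negative")
})

test_that("delivered volume follows the exponential inflation law", {
  m <- typical_mech(crs = 50, r_insp = 10)   # tau_i = 0.5 s
  # full equilibration: VT -> delta_p * crs
  long <- simulate_breath(m, ventilator_settings(0, 10, rr = 6, ti = 5))
  bm <- breath_metrics(long)
  expect_equal(bm$vt_insp, 500, tolerance = 0.005 * 500)
  # ti = tau_i with negligible trapping: VT = 500 (1 - 1/e)
  one_tau <- simulate_breath(m, ventilator_settings(0, 10, rr = 5, ti = 0.5))
  expect_equal(breath_metrics(one_tau)$vt_insp, 500 * (1 - exp(-1)),
               tolerance = 1)
})

test_that("waveform respects the 100-Hz contract and per-segment
           flow-volume consistency", {
  m <- typical_mech()
  w <- simulate_breath(m, ventilator_settings(8, 12, rr = 14, ti = 1.4))
  expect_equal(unique(round(diff(w$time), 10)), 0.01)
  bm <- breath_metrics(w)
  # cyclic steady state: inspired equals expired within 0.1%
  expect_equal(bm$vt_insp, bm$vt_exp, tolerance = 1e-3 * bm$vt_exp)
  # within the inspiratory segment, the volume channel equals the running
  # trapezoidal integral of flow to better than 0.5 ml
  insp <- which(w$flow > 0)
  v_num <- cumsum(c(0, (w$flow[insp][-1] + w$flow[insp][-length(insp)]) / 2 *
                      0.01))
  expect_lt(max(abs((w$volume[insp] - w$volume[insp][1]) - v_num)), 0.5)
})

test_that("auto-PEEP at short expiratory times matches the iterated
           breath-map oracle", {
  m <- typical_mech(crs = 50, r_insp = 10, rce = 0.8)
  # expiratory time of one time constant
  set <- ventilator_settings(8, 10, rr = 60 / (1.0 + 0.8), ti = 1.0)
  w <- simulate_breath(m, set)
  oracle <- iterate_breath_map(10, 50, 0.5, 0.8, ti = 1.0, te = 0.8)
  expect_equal(attr(w, "auto_peep"), oracle$v0 / 50, tolerance = 1e-6)
  expect_gt(attr(w, "auto_peep"), 0.5)   # substantial trapping at te = tau
  # with ample expiratory time auto-PEEP is below 1% of delta_p
  slow <- simulate_breath(m, ventilator_settings(8, 10, rr = 10, ti = 1.5))
  expect_lt(attr(slow, "auto_peep"), 0.01 * 10)
})

test_that("phase simulation is steady, deterministic and consistent with a
           single breath", {
  m <- typical_mech()
  set <- ventilator_settings(8, 12, rr = 15, ti = 1.3)
  ph <- simulate_phase(m, set, n_breaths = 12)
  bm <- breath_metrics(ph)
  last10 <- utils::tail(bm$vt_insp, 10)
  expect_lt(diff(range(last10)) / mean(last10), 1e-3)
  one <- simulate_breath(m, set)
  expect_identical(ph$paw[1:length(one$paw)], one$paw)
  expect_identical(simulate_phase(m, set, 12), ph)   # bit-identical rerun
})

test_that("terminal hold produces a flat plateau at total PEEP + VT/Crs", {
  m <- typical_mech(crs = 50)
  set <- ventilator_settings(8, 10, rr = 12, ti = 1.5)
  ph <- simulate_phase(m, set, n_breaths = 3, terminal_hold = 2.5)
  bm <- breath_metrics(ph)
  expect_true(any(bm$has_hold))
  vt <- bm$vt_exp[1]
  plateau_expected <- attr(ph, "peep_total") + vt / 50
  expect_equal(bm$plateau[bm$has_hold], plateau_expected, tolerance = 0.05)
})

test_that("waveform CSV dialect round-trips", {
  m <- typical_mech()
  w <- simulate_phase(m, ventilator_settings(8, 12, rr = 15, ti = 1.3), 3)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_waveform_csv(w, f1, f2)
  r <- read_waveform_csv(f1, f2, peep_set = 8)
  expect_equal(r$paw, w$paw)
  expect_equal(r$flow, w$flow)
  expect_equal(r$volume, w$volume)
  expect_equal(r$breath_boundaries$start, w$breath_boundaries$start)
  unlink(c(f1, f2))
})

test_that("steady-state gas exchange follows the alveolar ventilation
           equation", {
  m0 <- typical_mech(vco2 = 200, etco2_gradient = 0)
  g <- gas_exchange_steady_state(m0, 4315)
  expect_equal(g$paco2, 0.863 * 200 / 4.315, tolerance = 1e-6)
  expect_equal(g$paco2, 40, tolerance = 0.01)
  expect_equal(g$etco2, g$paco2)
  # inverse proportionality
  expect_equal(gas_exchange_steady_state(m0, 2 * 4315)$paco2, g$paco2 / 2)
  m4 <- typical_mech(vco2 = 231, etco2_gradient = 4)
  g4 <- gas_exchange_steady_state(m4, 4500)
  expect_equal(g4$paco2, 44.3, tolerance = 0.01)
  expect_equal(g4$etco2, 40.3, tolerance = 0.01)
  expect_error(gas_exchange_steady_state(m0, 0), "positive")
})

test_that("mixed-expired CO2 encodes the physiological dead space", {
  m <- typical_mech(dead_space_fraction = 0.15)
  vt <- 550
  pe <- mixed_expired_co2(m, paco2 = 42, vt = vt)
  vd <- bohr_dead_space(42, pe, vt)
  expect_equal(vd, m$vda + 0.15 * (vt - m$vda), tolerance = 1e-9)
  expect_error(mixed_expired_co2(m, 42, vt = 100), "exceed")
})
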