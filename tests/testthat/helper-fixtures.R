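# Shared fixtures: a typical cohort-mean patient and convenience builders.

typical_mech <- function(crs = 55, r_insp = 11, rce = 0.82, pbw = 74,
                         vco2 = 250, etco2_gradient = 4,
                         dead_space_fraction = 0.15) {
  patient_mechanics(crs = crs, r_insp = r_insp, rce = rce, pbw = pbw,
                    vco2 = vco2, etco2_gradient = etco2_gradient,
                    dead_space_fraction = dead_space_fraction)
}

typical_input <- function(ve = 8491, vda = 162.8, rce = 0.82, ...) {
  rr_selection_input(ve = ve, vda = vda, rce = rce, ...)
}

# Small parameter grid shared by the selector property tests.
selector_grid <- function(n = 5) {
  expand.grid(ve = seq(5000, 15000, length.out = n),
              rce = seq(0.3, 1.5, length.out = n),
              vda = seq(110, 220, length.out = n))
}

# Independent oracle for the cyclic steady state: iterate the per-breath
# end-expiratory volume map until it stops moving.
iterate_breath_map <- function(delta_p, crs, tau_i, tau_e, ti, te,
                               n_iter = 400) {
  a <- exp(-ti / tau_i)
  b <- exp(-te / tau_e)
  v_zero <- delta_p * crs * (1 - a)
  v0 <- 0
  for (k in seq_len(n_iter)) v0 <- b * (v_zero + a * v0)
  list(v0 = v0, v_ei = v_zero + a * v0)
}
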