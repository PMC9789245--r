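# Lumped electrode-tissue interface: double-layer capacitance, scar
# resistance, contact impedance and the power-limitation rule.

test_that("double-layer capacitance scales with electrode area", {
  expect_equal(cdl_from_radius(15e-6, 150e-6), 4.241150082346221e-08,
               tolerance = 1e-12)
  expect_equal(cdl_from_radius(10e-6, 150e-6), 2.827433388230814e-08,
               tolerance = 1e-12)
  expect_equal(cdl_from_radius(15e-6, 300e-6) / cdl_from_radius(15e-6,
                                                                150e-6), 4)
  expect_error(cdl_from_radius(0, 1), "> 0")
})

test_that("contact impedance follows R_scar + 1/(j w C_dl)", {
  m <- interface_model(C_dl = cdl_from_radius(), R_scar = 0)
  z <- z_et(m, 1e3)
  expect_equal(Mod(z), 3752.6364311976963, tolerance = 1e-9)
  expect_equal(Re(z), 0)
  # high-frequency limit -> R_scar
  m2 <- interface_model(C_dl = cdl_from_radius(), R_scar = 123)
  expect_equal(Re(z_et(m2, 1e12)), 123, tolerance = 1e-9)
  expect_lt(Mod(z_et(m2, 1e12) - 123), 1e-3)
  # enormous capacitance with no scar -> short circuit
  m3 <- interface_model(C_dl = 1e6, R_scar = 0)
  expect_lt(Mod(z_et(m3, 1e3)), 1e-9)
  # DC handled as scar resistance only, with a warning
  expect_warning(zdc <- z_et(m2, c(0, 1e3)), "DC")
  expect_equal(zdc[1], 123 + 0i)
})

test_that("scar shell resistance matches the spherical-shell formula", {
  r1 <- 150e-6
  th <- 500e-6
  expect_equal(scar_resistance(th, r1, 0.1),
               (1 / (4 * pi * 0.1)) * (1 / r1 - 1 / (r1 + th)))
  expect_equal(scar_resistance(0), 0)
  # thicker shells are more resistive
  expect_gt(scar_resistance(500e-6), scar_resistance(300e-6))
})

test_that("power limitation rescales a 70 V / 1 mA drive to 0.27 mA", {
  stim <- stim_long()
  I <- stim$samples                       # 1 mA amplitude
  V_E <- 70e3 * I                         # Z_tot = 70 kOhm -> 70 V peak
  lim <- apply_power_limit(V_E, I, P_max = 5e-3)
  expect_equal(round(max(abs(lim$I)) * 1e3, 2), 0.27)
  expect_equal(max(lim$V_E * lim$I), 5e-3, tolerance = 1e-9)
  expect_equal(lim$scale, sqrt(5e-3 / 70e-3), tolerance = 1e-12)

  # exactly at the cap: untouched
  lim2 <- apply_power_limit(5 * I, I, P_max = 5e-3)
  expect_equal(lim2$scale, 1)
  expect_identical(lim2$I, I)

  # equivalence with the I_new = sqrt(P_max / Z_tot) form at the binding
  # time step
  worst <- which.max(V_E * I)
  Z_tot <- V_E[worst] / I[worst]
  expect_equal(max(abs(lim$I)), sqrt(5e-3 / Z_tot), tolerance = 1e-12)
  expect_error(apply_power_limit(c(1, NaN), c(1, 1)), "non-finite")
})

test_that("tissue-surface voltage is invariant under the interface", {
  mesh <- fx_mesh_tiny_mono()
  tis <- phantom_tissues(mesh)
  sp <- forward_dft(stim_long(), f_max = 10e3)
  iface <- interface_model(C_dl = cdl_from_radius(),
                           R_scar = scar_resistance(500e-6))
  sw0 <- run_fourier_sweep(mesh, tis, mesh$electrodes, sp)
  sw1 <- run_fourier_sweep(mesh, tis, mesh$electrodes, sp,
                           interface = iface)
  expect_equal(sw0$V_M, sw1$V_M, tolerance = 1e-10)
  expect_gt(max(Mod(sw1$V_E - sw0$V_E)), 0)     # V_E does feel Z_ET
  times <- stim_long()$time
  vE0 <- electrode_time_series(sw0, 1L, times)
  vE1 <- electrode_time_series(sw1, 1L, times)
  expect_gt(max(abs(vE1)), max(abs(vE0)))       # interface raises |V_E|
})

test_that("a meshed scar shell raises the electrode voltage with thickness", {
  el <- function(cfg) place_electrodes(cfg, "monopolar")
  peaks <- vapply(c(300e-6, 500e-6), function(th) {
    cfg <- cfg_tiny(scar_thickness = th)
    mesh <- build_phantom(cfg, el(cfg))
    qs <- solve_qs(mesh, phantom_tissues(mesh), mesh$electrodes)
    abs(qs$V_M_unit[1])
  }, numeric(1L))
  cfg0 <- cfg_tiny()
  mesh0 <- build_phantom(cfg0, el(cfg0))
  qs0 <- solve_qs(mesh0, phantom_tissues(mesh0), mesh0$electrodes)
  expect_gt(peaks[1], abs(qs0$V_M_unit[1]))
  expect_gt(peaks[2], peaks[1])
})
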