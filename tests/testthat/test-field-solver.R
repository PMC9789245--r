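# FEM assembly and solves: P1 exactness, conservation, anisotropy,
# electrode terminal bookkeeping, reciprocity and the frequency sweep.

# structured unit-cube mesh (Kuhn subdivision), faces x=0 -> electrode_1,
# x=1 -> outer_boundary; used as an exactly solvable geometry
cube_mesh <- function(n = 3L, region = "fluid", axis = NULL) {
  g <- seq(0, 1, length.out = n + 1L)
  idx <- function(i, j, k) (k - 1L) * (n + 1L)^2 + (j - 1L) * (n + 1L) + i
  verts <- as.matrix(expand.grid(x = g, y = g, z = g))[, 1:3]
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  tets <- matrix(0L, 0, 4)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    for (p in perms) {
      steps <- diag(3)[p, , drop = FALSE]
      corners <- apply(rbind(0, apply(steps, 2, cumsum)), 1, function(s)
        idx(i + s[1], j + s[2], k + s[3]))
      tets <- rbind(tets, corners)
    }
  }
  tets <- vestifem:::orient_tets(verts, tets)
  tf <- vestifem:::tet_faces(tets)
  bnd <- tf$key %in% names(which(table(tf$key) == 1L))
  fv <- tf$verts[bnd, , drop = FALSE]
  onx <- function(x0) {
    sel <- abs(verts[fv[, 1], 1] - x0) < 1e-12 &
      abs(verts[fv[, 2], 1] - x0) < 1e-12 &
      abs(verts[fv[, 3], 1] - x0) < 1e-12
    fv[sel, , drop = FALSE]
  }
  fa <- matrix(NA_real_, nrow(tets), 3)
  if (!is.null(axis)) fa <- matrix(axis, nrow(tets), 3, byrow = TRUE)
  structure(list(vertices = verts, tets = tets,
                 region = rep(region, nrow(tets)), fiber_axis = fa,
                 patches = list(electrode_1 = onx(0),
                                outer_boundary = onx(1)),
                 electrodes = NULL, cfg = NULL),
            class = "labeled_mesh")
}

cube_electrode <- list(electrode_spec(c(0, 0.5, 0.5), role = "source"))

test_that("a linear potential is reproduced to machine precision", {
  mesh <- cube_mesh(3L)
  sys <- assemble_system(mesh, list(fluid = 1 + 0i))
  # unconstrained stiffness rows sum to zero (partition of unity)
  expect_lt(max(abs(Matrix::rowSums(sys$Kr))), 1e-12)
  sys <- apply_electrode_bc(sys, cube_electrode, I = 2e-3 + 0i, Z_ET = 0)
  fld <- solve_frequency(sys, 0)
  # unit cube, sigma = 1: exact solution phi = I * (1 - x)
  expect_lt(max(abs(Re(fld$phi) - 2e-3 * (1 - mesh$vertices[, 1]))), 1e-10)
  expect_identical(max(abs(Im(fld$phi))), 0)
  expect_equal(Re(fld$V_M), 2e-3, tolerance = 1e-9)
})

test_that("anisotropic assembly with equal eigenvalues equals isotropic", {
  ax <- c(1, 2, 2) / 3
  mesh <- cube_mesh(2L, region = "nerve_t", axis = ax)
  g <- 0.5 + 0.3i
  s_iso <- assemble_system(mesh, list(nerve_t = g))
  s_ani <- assemble_system(mesh, list(nerve_t = list(long = g, trans = g)))
  expect_lt(max(abs(s_iso$Kr - s_ani$Kr)), 1e-14)
  expect_lt(max(abs(s_iso$Ki - s_ani$Ki)), 1e-14)
  # unmapped region rejected
  expect_error(assemble_system(mesh, list(fluid = g)), "nerve_t")
})

test_that("electrode terminal, contact impedance and flux are consistent", {
  mesh <- cube_mesh(3L)
  sys <- assemble_system(mesh, list(fluid = 0.7 + 0i))
  I <- 1e-3 + 0i
  s0 <- apply_electrode_bc(sys, cube_electrode, I = I, Z_ET = 0)
  f0 <- solve_frequency(s0, 0)
  expect_equal(f0$V_E, f0$V_M)                  # Z_ET = 0
  z <- 150 + 40i
  s1 <- apply_electrode_bc(sys, cube_electrode, I = I, Z_ET = z)
  f1 <- solve_frequency(s1, 1e3)
  expect_equal(f1$V_E, f1$V_M + z * I, tolerance = 1e-12)
  # consistent flux equals the injected current
  expect_equal(patch_flux(s1, f1, "electrode_1"), I, tolerance = 5e-3)
  expect_equal(patch_flux(s1, f1, "outer_boundary"), -I, tolerance = 5e-3)
})

test_that("bipolar currents are conserved and reciprocal", {
  mesh <- fx_mesh_tiny_bi()
  tis <- const_tissues(mesh)
  gam <- vestifem:::tissue_sigma_ref(tis, 100)
  sys <- assemble_system(mesh, gam)
  I <- 1e-3 + 0i
  el <- mesh$electrodes
  s <- apply_electrode_bc(sys, el, I = I, Z_ET = 0)
  f <- solve_frequency(s, 0)
  fx_src <- patch_flux(s, f, "electrode_1")
  fx_snk <- patch_flux(s, f, "electrode_2")
  expect_lt(Mod(fx_src + fx_snk), 1e-3 * Mod(I))
  expect_equal(Re(fx_src), 1e-3, tolerance = 5e-3)
  z12 <- (f$V_M[1] - f$V_M[2]) / I
  # swap source and sink roles: transfer impedance must be unchanged
  el2 <- el
  el2[[1]]$role <- "sink"
  el2[[2]]$role <- "source"
  s2 <- apply_electrode_bc(sys, el2, I = I, Z_ET = 0)
  f2 <- solve_frequency(s2, 0)
  z21 <- (f2$V_M[2] - f2$V_M[1]) / I
  expect_lt(Mod(z12 - z21) / Mod(z12), 5e-3)
  # a missing reference is refused
  mesh_norefs <- mesh
  mesh_norefs$patches$outer_boundary <- NULL
  sys_n <- assemble_system(mesh_norefs, gam)
  expect_error(apply_electrode_bc(sys_n, el, I = I), "singular")
})

test_that("purely resistive sweep is Ohmic and skips empty bins", {
  mesh <- fx_mesh_tiny_mono()
  tis <- const_tissues(mesh)
  stim <- stim_long()
  sp <- forward_dft(stim, f_max = 30e3)
  sw <- run_fourier_sweep(mesh, tis, mesh$electrodes, sp)
  expect_true(length(sw$skipped) >= 1L)         # at least the DC bin
  expect_true(all(sw$f > 0))
  times <- stim$time
  I_bl <- inverse_dft(sw$coef, sw$f, times)
  V_M <- electrode_time_series(sw, 1L, times, "V_M")
  # on the cathodic plateau the ratio V_M / I is a constant resistance
  plateau <- times > stim$onset + 2e-5 &
    times < stim$onset + stim$phase_duration - 2e-5
  ratio <- V_M[plateau] / I_bl[plateau]
  expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-6)
  # synthesis is real-valued by the one-sided cosine construction
  pr <- probe_time_series(sw, mesh, rbind(c(0, 0, 3e-3)), times)
  expect_true(all(is.finite(pr)) && is.numeric(pr))
  # with purely real admittivity each bin's field is the (complex) drive
  # coefficient times a real transfer function
  tf <- sweep(sw$phi, 2, sw$coef, "/")
  expect_lt(max(abs(Im(tf))), 1e-7 * max(abs(Re(tf))))
})

test_that("probe potentials converge under mesh refinement", {
  cfgA <- phantom_config(bundles = NULL, h_electrode = 150e-6, grade = 1.5,
                         h_cavity = 1.8e-3, level = 2L)
  cfgB <- phantom_config(bundles = NULL, h_electrode = 100e-6, grade = 1.0,
                         h_cavity = 1.2e-3, level = 3L)
  el <- list(electrode_spec(c(0, 0, 0), role = "source"))
  probe <- rbind(c(0, 0, 8e-3), c(0, 0, 17.5e-3))
  vals <- lapply(list(cfgA, cfgB), function(cf) {
    m <- build_phantom(cf, el)
    sys <- assemble_system(m, list(fluid = 1 + 0i, bone = 1 + 0i,
                                   saline = 1 + 0i))
    sys <- apply_electrode_bc(sys, el, I = 1e-3 + 0i, Z_ET = 0)
    fld <- solve_frequency(sys, 0)
    loc <- vestifem:::locate_points(m$vertices, m$tets, probe)
    vapply(1:2, function(q)
      Re(sum(loc$bary[q, ] * fld$phi[m$tets[loc$tet[q], ]])), numeric(1))
  })
  expect_lt(max(abs(vals[[1]] / vals[[2]] - 1)), 0.02)
})
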