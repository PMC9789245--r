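# SENN fiber model: resting stability, activating-function nullspace,
# threshold search properties, and a cross-check of the built-in
# integrator against an independent stiff ODE solver.

test_that("resting state is a fixed point and gating stays in [0,1]", {
  fib <- focal_fiber()
  r <- simulate_fiber(matrix(0, 21, 1000), fib, dt = 1e-6,
                      return_traces = TRUE)
  expect_false(r$activated)
  expect_lt(max(abs(r$V)), 0.5e-3)              # < 0.5 mV drift over 1 ms
  expect_lt(r$max_m_overall, 0.01)
  expect_true(all(r$m >= 0 & r$m <= 1))
})

test_that("spatially uniform extracellular potential never activates", {
  fib <- focal_fiber()
  for (amp in c(0.1, 5, 50)) {
    r <- simulate_fiber(matrix(amp, 21, 800), fib, dt = 1e-6)
    expect_false(r$activated)
    expect_lt(max(abs(r$max_m - r$max_m[1])), 1e-12)
  }
})

test_that("integration matches an independent stiff ODE solver", {
  # independently coded FH/SENN right-hand side, integrated with lsoda
  fib <- focal_fiber(n_nodes = 9L)
  stim <- stim_long()
  Ve <- focal_Ve(stim, n_nodes = 9L, depth = 0.15)
  p <- fh_params()
  nn <- 9L
  d_ax <- 0.7 * fib$diameter
  area <- pi * d_ax * p$node_length
  g_a <- pi * d_ax^2 / 4 / (p$rho_axial * fib$internode)
  lap <- function(x) c(x[2] - x[1], x[-c(1, 2)] + x[-c(nn - 1, nn)] -
                         2 * x[-c(1, nn)], x[nn - 1] - x[nn])
  qten <- function(q10) q10^((p$temperature - 293.15) / 10)
  sx <- function(x) ifelse(abs(x) < 1e-7, 1 - x / 2, x / (exp(x) - 1))
  deriv <- function(t, y, parms) {
    V <- y[1:nn]; m <- y[nn + 1:nn]; h <- y[2 * nn + 1:nn]
    ng <- y[3 * nn + 1:nn]; pg <- y[4 * nn + 1:nn]
    vm <- V * 1e3
    am <- 0.36 * 3e3 * sx((22 - vm) / 3) * qten(1.8)
    bm <- 0.4 * 2e4 * sx((vm - 13) / 20) * qten(1.7)
    ah <- 0.1 * 6e3 * sx((vm + 10) / 6) * qten(2.8)
    bh <- 4.5e3 / (1 + exp((45 - vm) / 10)) * qten(2.9)
    an <- 0.02 * 1e4 * sx((35 - vm) / 10) * qten(3.2)
    bn <- 0.05 * 1e4 * sx((vm - 10) / 10) * qten(2.8)
    ap <- 0.006 * 1e4 * sx((40 - vm) / 10) * qten(3.0)
    bp <- 0.09 * 2e4 * sx((vm + 25) / 20) * qten(3.0)
    E <- V + p$v_rest
    u <- E * 96485.332 / (8.314462 * p$temperature)
    eu <- exp(u)
    gk <- ifelse(abs(u) < 1e-9, -96485.332, 96485.332 * u / (1 - eu))
    iion <- p$p_na * m^2 * h * gk * (p$na_o - p$na_i * eu) +
      p$p_k * ng^2 * gk * (p$k_o - p$k_i * eu) +
      p$p_p * pg^2 * gk * (p$na_o - p$na_i * eu) +
      p$g_leak * (V - p$v_leak)
    ve_t <- vapply(1:nn, function(i)
      stats::approx(stim$time, Ve[i, ], xout = t, rule = 2)$y, numeric(1))
    dV <- (-area * iion + g_a * lap(V) + g_a * lap(ve_t)) / (p$c_m * area)
    list(c(dV, am * (1 - m) - bm * m, ah * (1 - h) - bh * h,
           an * (1 - ng) - bn * ng, ap * (1 - pg) - bp * pg))
  }
  g0 <- vestifem:::fh_rest_gates(p)
  y0 <- c(rep(0, nn), rep(g0$m, nn), rep(g0$h, nn), rep(g0$n, nn),
          rep(g0$p, nn))
  sol <- deSolve::ode(y0, seq(0, 1e-3, by = 1e-5), deriv, NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  m_ref <- max(sol[, 1 + nn + 1:nn])
  r <- simulate_fiber(Ve, fib, p, dt = 1e-6)
  expect_true(r$activated)
  expect_gt(m_ref, 0.7)                          # oracle agrees: activated
  expect_lt(abs(r$max_m_overall - m_ref), 0.05)
  # subthreshold drive: both routes stay quiet
  r2 <- simulate_fiber(Ve * 0.05, fib, p, dt = 1e-6)
  Ve_sub <- Ve * 0.05
  Ve <- Ve_sub
  sol2 <- deSolve::ode(y0, seq(0, 1e-3, by = 1e-5), deriv, NULL,
                       method = "lsoda", rtol = 1e-8, atol = 1e-10)
  expect_false(r2$activated)
  expect_lt(max(sol2[, 1 + nn + 1:nn]), 0.7)
})

test_that("threshold search brackets, scales and converges", {
  fib <- focal_fiber()
  stim <- stim_long()
  Ve <- focal_Ve(stim)
  th <- find_threshold(Ve, fib, I_ref = stim$amplitude, dt = 1e-6)
  expect_true(th$converged)

  # bracketing at +-1 %
  on <- simulate_fiber(Ve * (1.01 * th$threshold / stim$amplitude), fib,
                       dt = 1e-6)
  off <- simulate_fiber(Ve * (0.99 * th$threshold / stim$amplitude), fib,
                        dt = 1e-6)
  expect_true(on$activated)
  expect_false(off$activated)

  # doubling the field exactly halves the threshold
  th2 <- find_threshold(2 * Ve, fib, I_ref = stim$amplitude, dt = 1e-6)
  expect_equal(th2$threshold, th$threshold / 2, tolerance = 2e-3)

  # threshold invariant under halving dt
  Ve_half <- focal_Ve(stim)[, rep(seq_len(1000), each = 2)]
  th_h <- find_threshold(Ve_half, fib, I_ref = stim$amplitude, dt = 5e-7)
  expect_lt(abs(th_h$threshold - th$threshold) / th$threshold, 5e-3)

  # a drive that can never activate is flagged unconverged
  flat <- matrix(1e-9, 21, 1000)
  un <- find_threshold(flat, fib, I_ref = stim$amplitude, dt = 1e-6,
                       max_amp = 1e-2)
  expect_false(un$converged)
  expect_true(is.na(un$threshold))
})

test_that("node potentials interpolate the field exactly (P1)", {
  mesh <- fx_mesh_tiny_mono()
  stim <- stim_long()
  # linear-in-x synthetic unit field: interpolation must be exact
  qs <- structure(list(phi_unit = 2.5 + 3 * mesh$vertices[, 1],
                       V_M_unit = 0), class = "qs_solution")
  nodes <- rbind(c(2.5e-3, 0.1e-3, 0), c(3.2e-3, -0.2e-3, 0.1e-3))
  fib <- structure(list(nodes = nodes, internode = 0.7e-3, diameter = 2e-6,
                        type = "calyx", branch = "nerve_target", id = 9L),
                   class = "fiber_geometry")
  Ve <- extracellular_at_nodes(qs, mesh, fib, stim$time, stim)
  expect_equal(Ve, outer(2.5 + 3 * nodes[, 1], stim$samples),
               tolerance = 1e-9)
  # a node placed at a mesh vertex reproduces the vertex value
  vtx <- mesh$vertices[100, , drop = FALSE]
  fibv <- structure(list(nodes = rbind(vtx, vtx + c(1e-4, 0, 0)),
                         internode = 1e-4, diameter = 2e-6,
                         type = "calyx", branch = "nerve_target", id = 1L),
                    class = "fiber_geometry")
  Vev <- extracellular_at_nodes(qs, mesh, fibv, stim$time[1:3], stim)
  expect_equal(Vev[1, ], (2.5 + 3 * vtx[1]) * stim$samples[1:3],
               tolerance = 1e-12)
  # nodes outside the mesh are rejected with the fiber id
  fib_out <- structure(list(nodes = rbind(c(1, 1, 1)), internode = 1e-4,
                            diameter = 2e-6, type = "calyx",
                            branch = "nerve_target", id = 42L),
                       class = "fiber_geometry")
  expect_error(extracellular_at_nodes(qs, mesh, fib_out, stim$time, stim),
               "42")
})
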