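# Spatially extended nonlinear node (SENN) model of a myelinated fiber:
# every node of Ranvier carries nonlinear Na+ and K+ channels, a leak and
# a membrane capacitance (Frankenhaeuser-Huxley kinetics with GHK flux
# equations), consecutive nodes are coupled by the axoplasmic conductance,
# and the fiber is driven by the extracellular potential at the nodes.

FARADAY <- 96485.332
RGAS <- 8.314462

#' Frankenhaeuser-Huxley membrane parameters
#'
#' Classical amphibian-node constants: permeabilities for the GHK Na+,
#' K+ and nonspecific currents, leak conductance, nodal capacitance, ionic
#' concentrations and rate equations referenced to 293.15 K with Q10
#' scaling of the rate constants. The numeric values are the standard
#' published set for this membrane; the structural choices (two nonlinear
#' channels, leak, capacitance, axoplasmic coupling) are what the fiber
#' recruitment model requires.
#'
#' @param temperature simulation temperature in kelvin (default body
#'   temperature 310.15 K)
#' @param rho_axial axoplasmic resistivity in ohm m (default 1.1)
#' @param node_length nodal gap length in m (default 2.5 um)
#' @param v_rest resting potential in V (default -70 mV)
#' @return object of class \code{membrane_params}
#' @export
fh_params <- function(temperature = 310.15, rho_axial = 1.10,
                      node_length = 2.5e-6, v_rest = -70e-3) {
  structure(list(
    c_m = 0.02,          # F/m^2
    g_leak = 303,        # S/m^2
    v_leak = 0.026e-3,   # V relative to rest
    p_na = 8e-5,         # m/s
    p_k = 1.2e-5,
    p_p = 0.54e-5,
    na_o = 114.5, na_i = 13.74,   # mol/m^3
    k_o = 2.5, k_i = 120,
    temperature = temperature, t_base = 293.15,
    rho_axial = rho_axial, node_length = node_length, v_rest = v_rest),
    class = "membrane_params")
}

# Q10 temperature factors for the eight rate constants
fh_q10 <- function(p) {
  q <- function(q10) q10^((p$temperature - p$t_base) / 10)
  c(a_m = q(1.8), b_m = q(1.7), a_h = q(2.8), b_h = q(2.9),
    a_n = q(3.2), b_n = q(2.8), a_p = q(3.0), b_p = q(3.0))
}

# gating rate constants (1/s); v in volts relative to rest
fh_rates <- function(v, p, qf = fh_q10(p)) {
  vm <- v * 1e3                       # mV
  sx <- function(x) ifelse(abs(x) < 1e-7, 1 - x / 2, x / (exp(x) - 1))
  # each alpha/beta written via the numerically safe x/(exp(x)-1) form
  list(a_m = 0.36 * 3e3 * sx((22 - vm) / 3) * qf[[1L]],
       b_m = 0.4 * 2e4 * sx((vm - 13) / 20) * qf[[2L]],
       a_h = 0.1 * 6e3 * sx((vm + 10) / 6) * qf[[3L]],
       b_h = 4.5e3 / (1 + exp((45 - vm) / 10)) * qf[[4L]],
       a_n = 0.02 * 1e4 * sx((35 - vm) / 10) * qf[[5L]],
       b_n = 0.05 * 1e4 * sx((vm - 10) / 10) * qf[[6L]],
       a_p = 0.006 * 1e4 * sx((40 - vm) / 10) * qf[[7L]],
       b_p = 0.09 * 2e4 * sx((vm + 25) / 20) * qf[[8L]])
}

# GHK flux ionic current density (A/m^2); e_abs absolute potential (V)
fh_ionic <- function(e_abs, gates, p) {
  u <- e_abs * FARADAY / (RGAS * p$temperature)
  eu <- exp(u)
  gk <- ifelse(abs(u) < 1e-9, -FARADAY, FARADAY * u / (1 - eu))
  i_na <- p$p_na * gates$m^2 * gates$h * gk * (p$na_o - p$na_i * eu)
  i_k <- p$p_k * gates$n^2 * gk * (p$k_o - p$k_i * eu)
  i_p <- p$p_p * gates$p^2 * gk * (p$na_o - p$na_i * eu)
  i_na + i_k + i_p
}

# steady-state gating at rest
fh_rest_gates <- function(p) {
  r <- fh_rates(0, p)
  list(m = r$a_m / (r$a_m + r$b_m), h = r$a_h / (r$a_h + r$b_h),
       n = r$a_n / (r$a_n + r$b_n), p = r$a_p / (r$a_p + r$b_p))
}

#' Simulate a SENN fiber under an extracellular potential
#'
#' Integrates the nodal cable system
#' \deqn{c_m A \dot V_n = -A\,i_{ion}(V_n) + g_a (V_{n-1}-2V_n+V_{n+1})
#'   + g_a (V_{e,n-1}-2V_{e,n}+V_{e,n+1})}
#' with an implicit (backward Euler) treatment of the linear cable part,
#' exponential-Euler gating updates and explicit ionic currents. The fiber
#' is considered activated when the Na+ activation variable m exceeds 0.7
#' at any node.
#'
#' @param Ve nodes x time matrix of extracellular potentials (V)
#' @param fiber a \code{fiber_geometry} (diameter and internode length are
#'   used; the number of rows of \code{Ve} must match its node count)
#' @param params a [fh_params()] object
#' @param dt time step in seconds (must be <= 2 us)
#' @param return_traces also return voltage and m traces
#' @return list with \code{activated}, \code{max_m} (per node),
#'   \code{max_m_overall}, and optionally \code{V}, \code{m} traces
#' @export
simulate_fiber <- function(Ve, fiber, params = fh_params(), dt = 1e-6,
                           return_traces = FALSE) {
  stopifnot(is.matrix(Ve), dt > 0)
  if (dt > 2e-6) stop("dt must be <= 2 us for a stable, accurate update")
  nn <- nrow(Ve)
  nt <- ncol(Ve)
  D <- fiber$diameter
  d_ax <- 0.7 * D
  area <- pi * d_ax * params$node_length
  g_a <- pi * d_ax^2 / 4 / (params$rho_axial * fiber$internode)
  # second-difference cable operator with sealed ends
  L <- matrix(0, nn, nn)
  for (i in seq_len(nn)) {
    if (i > 1) { L[i, i - 1] <- 1; L[i, i] <- L[i, i] - 1 }
    if (i < nn) { L[i, i + 1] <- 1; L[i, i] <- L[i, i] - 1 }
  }
  A_lhs <- diag(params$c_m * area / dt, nn) - g_a * L
  A_inv <- solve(A_lhs)
  g <- fh_rest_gates(params)
  gates <- list(m = rep(g$m, nn), h = rep(g$h, nn), n = rep(g$n, nn),
                p = rep(g$p, nn))
  V <- numeric(nn)            # deviation from rest
  max_m <- rep(gates$m[1L], nn)
  if (return_traces) {
    Vtr <- matrix(0, nn, nt)
    mtr <- matrix(0, nn, nt)
  }
  qf <- fh_q10(params)
  cdt <- params$c_m * area / dt
  for (k in seq_len(nt)) {
    r <- fh_rates(V, params, qf)
    upd <- function(x, a, b) {
      inf <- a / (a + b)
      inf + (x - inf) * exp(-(a + b) * dt)
    }
    gates$m <- upd(gates$m, r$a_m, r$b_m)
    gates$h <- upd(gates$h, r$a_h, r$b_h)
    gates$n <- upd(gates$n, r$a_n, r$b_n)
    gates$p <- upd(gates$p, r$a_p, r$b_p)
    i_ion <- fh_ionic(V + params$v_rest, gates, params) +
      params$g_leak * (V - params$v_leak)
    rhs <- cdt * V - area * i_ion + g_a * drop(L %*% Ve[, k])
    V <- drop(A_inv %*% rhs)
    if (any(!is.finite(V)))
      stop("membrane integration diverged; reduce dt (", dt, " s)")
    max_m <- pmax(max_m, gates$m)
    if (return_traces) {
      Vtr[, k] <- V
      mtr[, k] <- gates$m
    }
  }
  out <- list(activated = any(max_m > 0.7), max_m = max_m,
              max_m_overall = max(max_m))
  if (return_traces) {
    out$V <- Vtr
    out$m <- mtr
  }
  out
}

#' Extracellular potential time series at the nodes of a fiber
#'
#' Interpolates the swept complex potentials at every node of Ranvier
#' (linear P1 interpolation in the containing tetrahedron) and synthesizes
#' the real time series by inverse DFT.
#'
#' @param sweep a [run_fourier_sweep()] result (or a \code{qs_solution};
#'   then \code{stimulus} must be given and the series is
#'   \eqn{\phi_1(x) I(t)})
#' @param mesh the mesh the solution was computed on
#' @param fiber a \code{fiber_geometry}
#' @param times synthesis times (s)
#' @param stimulus a \code{stimulus_waveform}, required for QS solutions
#' @return nodes x time matrix of potentials (V)
#' @export
extracellular_at_nodes <- function(sweep, mesh, fiber, times,
                                   stimulus = NULL) {
  nodes <- fiber$nodes
  if (inherits(sweep, "qs_solution")) {
    if (is.null(stimulus)) stop("QS synthesis needs the stimulus waveform")
    loc <- locate_points(mesh$vertices, mesh$tets, nodes)
    if (anyNA(loc$tet))
      stop("fiber ", fiber$id, " node(s) outside the mesh: ",
           paste(which(is.na(loc$tet)), collapse = ", "))
    cur <- stats::approx(stimulus$time, stimulus$samples, xout = times,
                         method = "constant", rule = 2)$y
    phi_n <- vapply(seq_len(nrow(nodes)), function(q)
      sum(loc$bary[q, ] * sweep$phi_unit[mesh$tets[loc$tet[q], ]]),
      numeric(1L))
    outer(phi_n, cur)
  } else {
    probe_time_series(sweep, mesh, nodes, times)
  }
}

#' Binary-search excitation threshold of one fiber
#'
#' The extracellular field scales linearly with the stimulus amplitude, so
#' the node potentials for amplitude \eqn{A} are \eqn{(A/I_{ref})} times a
#' reference solution. The threshold is bracketed (expanding the upper
#' bound by doubling if needed) and bisected until the relative bracket
#' width falls below \code{tol}; the upper bound is returned.
#'
#' @param Ve_ref nodes x time extracellular potentials at the reference
#'   amplitude \code{I_ref} (V)
#' @param fiber the \code{fiber_geometry}
#' @param I_ref reference amplitude in A
#' @param params [fh_params()]
#' @param dt integration step (s)
#' @param bounds initial amplitude bracket (A)
#' @param tol relative bracket width at termination (default 1e-3,
#'   i.e. 0.1 %)
#' @param max_amp give up (unconverged) above this amplitude (A)
#' @return object of class \code{threshold_result}: \code{threshold} (A),
#'   \code{converged}, \code{iterations}, \code{fiber_id}, \code{branch},
#'   \code{type}
#' @export
find_threshold <- function(Ve_ref, fiber, I_ref = 1e-3,
                           params = fh_params(), dt = 1e-6,
                           bounds = c(1e-5, 1e-2), tol = 1e-3,
                           max_amp = 1) {
  act <- function(amp)
    simulate_fiber(Ve_ref * (amp / I_ref), fiber, params, dt)$activated
  lo <- bounds[1L]
  hi <- bounds[2L]
  it <- 0L
  while (act(lo) && lo > 1e-9) {     # lower bound must not activate
    hi <- lo
    lo <- lo / 4
    it <- it + 1L
  }
  while (!act(hi)) {                 # upper bound must activate
    lo <- hi
    hi <- hi * 2
    it <- it + 1L
    if (hi > max_amp)
      return(structure(list(threshold = NA_real_, converged = FALSE,
                            iterations = it, fiber_id = fiber$id,
                            branch = fiber$branch, type = fiber$type),
                       class = "threshold_result"))
  }
  while ((hi - lo) / hi >= tol) {
    mid <- sqrt(lo * hi)
    if (act(mid)) hi <- mid else lo <- mid
    it <- it + 1L
  }
  structure(list(threshold = hi, converged = TRUE, iterations = it,
                 fiber_id = fiber$id, branch = fiber$branch,
                 type = fiber$type),
            class = "threshold_result")
}

#' Thresholds for a fiber population
#'
#' Convenience loop: node potentials for every fiber are interpolated
#' once from the field solution at the reference amplitude, then each
#' threshold is found by [find_threshold()].
#'
#' @param sweep field solution ([run_fourier_sweep()] or [solve_qs()])
#' @param mesh the mesh
#' @param fibers list of \code{fiber_geometry}
#' @param times simulation time grid (s); its spacing sets the SENN step
#' @param stimulus stimulus waveform (required for QS solutions, used for
#'   \code{I_ref} otherwise)
#' @param params [fh_params()]
#' @param ... passed to [find_threshold()]
#' @return list of \code{threshold_result}
#' @export
population_thresholds <- function(sweep, mesh, fibers, times, stimulus,
                                  params = fh_params(), ...) {
  dt <- times[2L] - times[1L]
  I_ref <- stimulus$amplitude
  lapply(fibers, function(fb) {
    Ve <- extracellular_at_nodes(sweep, mesh, fb, times, stimulus)
    find_threshold(Ve, fb, I_ref = I_ref, params = params, dt = dt, ...)
  })
}
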