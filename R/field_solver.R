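# First-order (P1) tetrahedral FEM for the source-free complex Laplace
# equation -div(gamma grad phi) = 0, one solve per stimulus frequency
# component. Driven electrodes are equipotential floating terminals
# injecting a prescribed total current through a lumped contact impedance;
# the outer boundary is the 0 V reference. Complex systems are solved as
# 2N x 2N real block systems (Matrix has no complex sparse storage).

# per-tet P1 basis gradients and volumes
tet_gradients <- function(verts, tets) {
  a <- verts[tets[, 1], , drop = FALSE]
  e1 <- verts[tets[, 2], , drop = FALSE] - a
  e2 <- verts[tets[, 3], , drop = FALSE] - a
  e3 <- verts[tets[, 4], , drop = FALSE] - a
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  det6 <- rowSums(e1 * cr(e2, e3))
  g2 <- cr(e2, e3) / det6
  g3 <- cr(e3, e1) / det6
  g4 <- cr(e1, e2) / det6
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = det6 / 6)
}

# stiffness matrix over a subset of tets for a unit tensor field:
# kind "iso" uses the identity, kind "axis" uses a a^T from `axis`
unit_stiffness <- function(verts, tets, sel, kind = "iso", axis = NULL) {
  tt <- tets[sel, , drop = FALSE]
  gr <- tet_gradients(verts, tt)
  n <- nrow(tt)
  ii <- jj <- integer(16L * n)
  xx <- numeric(16L * n)
  k <- 0L
  for (i in 1:4) {
    gi <- gr$g[[i]]
    git <- if (kind == "axis") rowSums(gi * axis) else NULL
    for (j in 1:4) {
      gj <- gr$g[[j]]
      v <- if (kind == "axis") {
        git * rowSums(gj * axis) * gr$vol
      } else {
        rowSums(gi * gj) * gr$vol
      }
      idx <- k * n + seq_len(n)
      ii[idx] <- tt[, i]
      jj[idx] <- tt[, j]
      xx[idx] <- v
      k <- k + 1L
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(verts), nrow(verts)))
}

# unit stiffness matrices per region (isotropic part and, for nerve
# regions with a fiber axis, the rank-one longitudinal part)
region_unit_matrices <- function(mesh) {
  out <- list()
  for (rg in sort(unique(mesh$region))) {
    sel <- mesh$region == rg
    ent <- list(iso = unit_stiffness(mesh$vertices, mesh$tets, sel))
    ax <- mesh$fiber_axis[sel, , drop = FALSE]
    if (!anyNA(ax[, 1])) {
      ent$axis <- unit_stiffness(mesh$vertices, mesh$tets, sel,
                                 kind = "axis", axis = ax)
    }
    out[[rg]] <- ent
  }
  out
}

#' Assemble the FEM system for one set of region admittivities
#'
#' Builds the P1 Galerkin stiffness matrix of
#' \eqn{-\nabla\cdot(\gamma\nabla\phi)=0} with a complex admittivity per
#' region. Isotropic regions take a complex scalar; nerve regions take
#' \code{list(long=, trans=)} complex values, applied as the tensor
#' \eqn{\gamma_t I + (\gamma_l-\gamma_t)\,aa^T} with \eqn{a} the local
#' fiber axis (the permittivity part is carried in both eigenvalues).
#'
#' @param mesh a \code{labeled_mesh}
#' @param gamma named list over regions: complex scalar or
#'   \code{list(long, trans)}
#' @param units optional precomputed region unit matrices (internal reuse)
#' @return object of class \code{solver_system} with real/imaginary
#'   stiffness parts; pass to [apply_electrode_bc()]
#' @export
assemble_system <- function(mesh, gamma, units = NULL) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  regs <- sort(unique(mesh$region))
  if (!all(regs %in% names(gamma)))
    stop("no admittivity for region(s): ",
         paste(setdiff(regs, names(gamma)), collapse = ", "))
  if (is.null(units)) units <- region_unit_matrices(mesh)
  n <- nrow(mesh$vertices)
  Kr <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                             dims = c(n, n))
  Ki <- Kr
  for (rg in regs) {
    g <- gamma[[rg]]
    if (is.list(g)) {
      if (is.null(units[[rg]]$axis))
        stop("anisotropic admittivity for region without fiber axis: ", rg)
      gt <- g$trans
      gl <- g$long
      Kr <- Kr + Re(gt) * units[[rg]]$iso + Re(gl - gt) * units[[rg]]$axis
      Ki <- Ki + Im(gt) * units[[rg]]$iso + Im(gl - gt) * units[[rg]]$axis
    } else {
      Kr <- Kr + Re(g) * units[[rg]]$iso
      Ki <- Ki + Im(g) * units[[rg]]$iso
    }
  }
  structure(list(Kr = Kr, Ki = Ki, n = n, mesh_patches = mesh$patches,
                 constrained = FALSE),
            class = "solver_system")
}

#' Apply electrode and reference boundary conditions
#'
#' Each driven electrode patch is collapsed to a single equipotential
#' terminal unknown that receives the prescribed total current (the sink
#' of a bipolar pair receives the inverted current); outer-boundary nodes
#' are clamped to the 0 V reference. The lumped contact impedance
#' \eqn{Z_{ET}} acts between the metal terminal and the tissue surface, so
#' it does not enter the field system: the electrode voltage is recovered
#' afterwards as \eqn{V_E = V_M + Z_{ET} I}.
#'
#' @param system a [assemble_system()] result
#' @param electrodes list of [electrode_spec()] matching the mesh patches
#'   \code{electrode_1}, \code{electrode_2}, ...
#' @param I complex stimulus current of the source electrode (A)
#' @param Z_ET complex contact impedance, recycled over driven electrodes
#' @return the system with constraint bookkeeping and load attached
#' @export
apply_electrode_bc <- function(system, electrodes, I, Z_ET = 0) {
  stopifnot(inherits(system, "solver_system"))
  roles <- vapply(electrodes, `[[`, character(1L), "role")
  if (sum(roles == "source") != 1L)
    stop("exactly one source electrode required")
  if (any(roles == "sink") && sum(roles == "sink") != 1L)
    stop("at most one sink electrode supported")
  if (is.null(system$mesh_patches$outer_boundary))
    stop("mesh has no outer_boundary patch; system would be singular")
  n <- system$n
  Z_ET <- rep_len(as.complex(Z_ET), length(electrodes))
  # node sets
  dir_nodes <- sort(unique(as.vector(system$mesh_patches$outer_boundary)))
  pnodes <- lapply(seq_along(electrodes), function(i)
    sort(unique(as.vector(system$mesh_patches[[paste0("electrode_", i)]]))))
  # map: 0 = eliminated (Dirichlet), k = reduced dof
  map <- integer(n)
  free <- setdiff(seq_len(n), c(dir_nodes, unlist(pnodes)))
  map[free] <- seq_along(free)
  nred <- length(free)
  term <- integer(length(electrodes))
  for (i in seq_along(electrodes)) {
    nred <- nred + 1L
    map[pnodes[[i]]] <- nred
    term[i] <- nred
  }
  keep <- map > 0L
  C <- Matrix::sparseMatrix(i = which(keep), j = map[keep], x = 1,
                            dims = c(n, nred))
  cur <- rep(0 + 0i, length(electrodes))
  cur[roles == "source"] <- I
  cur[roles == "sink"] <- -I
  b <- rep(0 + 0i, nred)
  b[term] <- cur
  system$C <- C
  system$Kr_c <- Matrix::t(C) %*% system$Kr %*% C
  system$Ki_c <- Matrix::t(C) %*% system$Ki %*% C
  system$b <- b
  system$term <- term
  system$I_el <- cur
  system$Z_ET <- Z_ET
  system$constrained <- TRUE
  system
}

#' Solve the constrained system at one frequency
#'
#' Direct sparse factorization; complex systems are solved in the
#' equivalent 2N x 2N real block form. The relative residual of the
#' constrained system is checked against 1e-8.
#'
#' @param system a constrained [apply_electrode_bc()] system
#' @param f frequency of this component (Hz), stored in the result
#' @return object of class \code{frequency_field}: \code{phi} (complex per
#'   mesh vertex, 0 on the reference boundary), \code{V_M} and \code{V_E}
#'   per electrode, \code{f}, \code{residual}
#' @export
solve_frequency <- function(system, f = NA_real_) {
  stopifnot(inherits(system, "solver_system"), isTRUE(system$constrained))
  Kr <- system$Kr_c
  Ki <- system$Ki_c
  b <- system$b
  # sparse Cholesky of the conductive part; the capacitive part is folded
  # in by preconditioned fixed-point iteration, whose contraction rate is
  # bounded by the largest tissue ratio omega*eps0*eps_r/sigma (< 1 for
  # all tissues handled here)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kr), LDL = FALSE)
  csolve <- function(v) as.vector(Matrix::solve(ch, v, system = "A"))
  complex_part <- length(Ki@x) > 0 && any(Ki@x != 0)
  if (!complex_part && all(Im(b) == 0)) {
    xr <- csolve(Re(b))
    xi <- numeric(length(xr))
  } else {
    br <- Re(b)
    bi <- Im(b)
    xr <- csolve(br)
    xi <- csolve(bi)
    bnorm <- sqrt(sum(br^2 + bi^2))
    ok <- FALSE
    for (it in seq_len(120L)) {
      rr <- br - as.vector(Kr %*% xr) + as.vector(Ki %*% xi)
      ri <- bi - as.vector(Kr %*% xi) - as.vector(Ki %*% xr)
      if (sqrt(sum(rr^2 + ri^2)) <= 1e-10 * bnorm) { ok <- TRUE; break }
      xr <- xr + csolve(rr)
      xi <- xi + csolve(ri)
    }
    if (!ok) {      # heavily capacitive corner case: direct block solve
      M <- rbind(cbind(Kr, -Ki), cbind(Ki, Kr))
      x2 <- as.vector(Matrix::solve(M, c(br, bi)))
      m <- length(b)
      xr <- x2[seq_len(m)]
      xi <- x2[m + seq_len(m)]
    }
  }
  xc <- complex(real = xr, imaginary = xi)
  res <- (Kr %*% xr - Ki %*% xi - Re(b))^2 +
    (Kr %*% xi + Ki %*% xr - Im(b))^2
  relres <- sqrt(sum(res)) / max(sqrt(sum(Mod(b)^2)), 1e-300)
  if (!is.finite(relres) || relres > 1e-8)
    stop(sprintf("solver residual %.3g at f = %g Hz", relres, f))
  phi <- complex(real = as.vector(system$C %*% xr),
                 imaginary = as.vector(system$C %*% xi))
  V_M <- xc[system$term]
  V_E <- V_M + system$Z_ET * system$I_el
  structure(list(f = f, phi = phi, V_M = V_M, V_E = V_E,
                 I_el = system$I_el, residual = relres),
            class = "frequency_field")
}

#' Consistent current flux into an electrode patch
#'
#' Evaluates the discrete (variationally consistent) flux
#' \eqn{\sum_{i\in\mathrm{patch}} (K\phi)_i}, the FEM analogue of the
#' surface integral of \eqn{\gamma\nabla\phi\cdot n} over the patch.
#'
#' @param system an (unconstrained or constrained) \code{solver_system}
#' @param field a [solve_frequency()] result on the same mesh
#' @param patch patch name, e.g. \code{"electrode_1"} or
#'   \code{"outer_boundary"}
#' @return complex current in amperes flowing out of the domain through
#'   the patch
#' @export
patch_flux <- function(system, field, patch) {
  nodes <- sort(unique(as.vector(system$mesh_patches[[patch]])))
  if (length(nodes) == 0L) stop("unknown or empty patch: ", patch)
  rr <- as.vector(system$Kr %*% Re(field$phi) -
                    system$Ki %*% Im(field$phi))
  ri <- as.vector(system$Kr %*% Im(field$phi) +
                    system$Ki %*% Re(field$phi))
  sum(complex(real = rr[nodes], imaginary = ri[nodes]))
}

# admittivity per region at a frequency from a tissue map entry
tissue_gamma <- function(tissues, f) {
  lapply(tissues, function(ts) {
    if (identical(ts$type, "aniso")) {
      vl <- interp_property(ts$long, f)
      vt <- interp_property(ts$trans, f)
      list(long = admittivity(vl$sigma, vl$eps_r, f),
           trans = admittivity(vt$sigma, vt$eps_r, f))
    } else {
      v <- interp_property(ts$prop, f)
      admittivity(v$sigma, v$eps_r, f)
    }
  })
}

# purely conductive admittivity map at a reference frequency (QS mode)
tissue_sigma_ref <- function(tissues, f_ref = 100) {
  lapply(tissues, function(ts) {
    if (identical(ts$type, "aniso")) {
      list(long = complex(real = interp_property(ts$long, f_ref,
                                                 what = "sigma")),
           trans = complex(real = interp_property(ts$trans, f_ref,
                                                  what = "sigma")))
    } else {
      complex(real = interp_property(ts$prop, f_ref, what = "sigma"))
    }
  })
}

#' Default tissue assignment for the phantom
#'
#' Maps every phantom region to its dielectric model: CSF for the fluid
#' cavity and the saline shell, cortical bone for the bone sphere, and
#' anisotropic nerve for the bundles, with the nerve conductivity rescaled
#' at 100 Hz to the longitudinal and transversal reference values. A
#' meshed scar shell, when present, is a fixed 0.1 S/m conductor.
#'
#' @param mesh a \code{labeled_mesh} (its region set drives the map)
#' @param sigma_long,sigma_trans nerve conductivity at 100 Hz along /
#'   across the fiber axis (S/m); defaults follow the roughly 10:1
#'   anisotropy reported for myelinated nerve trunks
#' @param bounds named list region -> \code{"default"}/\code{"upper"}/
#'   \code{"lower"} selecting the uncertainty bound per tissue
#' @param literature named list region -> [tissue_property()] on the
#'   canonical knot grid; when given, bone/fluid/saline bounds use the
#'   median-log-distance rule against it
#' @param bound_log_distance half-width in decades of the bone/CSF bounds
#'   when no literature table is supplied (nerve bounds are always the
#'   fractional +-50 % rule)
#' @return named list usable by [run_fourier_sweep()] and [solve_qs()]
#' @export
phantom_tissues <- function(mesh, sigma_long = 0.3, sigma_trans = 0.03,
                            bounds = list(), literature = list(),
                            bound_log_distance = 0.15) {
  lib <- tissue_library()
  pick <- function(base, region, mode) {
    tag <- bounds[[region]]
    if (is.null(tag) || tag == "default") return(base)
    if (mode == "fractional")
      return(property_bounds(base, "fractional")[[tag]])
    if (!is.null(literature[[region]]))
      return(property_bounds(base, "median_log_distance",
                             literature = literature[[region]])[[tag]])
    s <- if (tag == "upper") 10^bound_log_distance else
      10^(-bound_log_distance)
    tissue_property(base$name, base$freq, base$sigma * s, base$eps_r * s,
                    tag)
  }
  out <- list()
  for (rg in sort(unique(mesh$region))) {
    if (rg %in% c("fluid", "saline")) {
      out[[rg]] <- list(type = "iso",
                        prop = pick(lib$tables$csf, rg,
                                    "median_log_distance"))
    } else if (rg == "bone") {
      out[[rg]] <- list(type = "iso",
                        prop = pick(lib$tables$bone, rg,
                                    "median_log_distance"))
    } else if (rg == "scar") {
      grid <- lib$tables$csf$freq
      out[[rg]] <- list(type = "iso",
                        prop = tissue_property("scar", grid,
                                               rep(0.1, length(grid)),
                                               rep(1, length(grid))))
    } else if (startsWith(rg, "nerve_")) {
      base <- pick(lib$tables$nerve, rg, "fractional")
      out[[rg]] <- list(type = "aniso",
                        long = scale_nerve_conductivity(base, sigma_long),
                        trans = scale_nerve_conductivity(base, sigma_trans))
    } else stop("no tissue rule for region ", rg)
  }
  out
}

#' Quasi-static unit solve
#'
#' Solves the purely resistive problem once with a unit (1 A) stimulus
#' current; by linearity the time-dependent potential is the unit solution
#' scaled by the stimulus waveform, \eqn{\phi(x,t)=\phi_1(x)\,I(t)}.
#'
#' @param mesh a \code{labeled_mesh}
#' @param tissues a [phantom_tissues()]-style map
#' @param electrodes matching [electrode_spec()] list
#' @param f_ref frequency at which the conductivities are taken (Hz)
#' @return object of class \code{qs_solution}: \code{phi_unit} (V per
#'   vertex at 1 A), \code{V_M_unit}, \code{system}
#' @export
solve_qs <- function(mesh, tissues, electrodes, f_ref = 100) {
  gam <- tissue_sigma_ref(tissues, f_ref)
  sys <- assemble_system(mesh, gam)
  sys <- apply_electrode_bc(sys, electrodes, I = 1 + 0i, Z_ET = 0)
  fld <- solve_frequency(sys, f = 0)
  structure(list(phi_unit = Re(fld$phi), V_M_unit = Re(fld$V_M),
                 system = sys, f_ref = f_ref),
            class = "qs_solution")
}

#' Fourier FEM sweep over a stimulus spectrum
#'
#' Solves the complex-admittivity Laplace problem at every spectrum bin
#' whose magnitude exceeds \code{mag_floor} times the peak bin (skipped
#' bins contribute zero; the charge-balanced stimuli used here have
#' essentially no DC content, and a DC bin above the floor would use
#' \code{R_scar} alone as interface impedance). Tissue properties are
#' interpolated from their knot tables at each bin frequency.
#'
#' @param mesh a \code{labeled_mesh}
#' @param tissues [phantom_tissues()]-style map
#' @param electrodes matching [electrode_spec()] list
#' @param spectrum a [forward_dft()] spectrum of the stimulus current
#' @param interface optional [interface_model()] giving \eqn{Z_{ET}(f)}
#' @param mag_floor relative bin-magnitude floor (default 1e-6)
#' @param verbose print one line per solved bin
#' @return object of class \code{fourier_sweep}: \code{f} (solved bin
#'   frequencies), \code{phi} (vertices x bins complex), \code{V_E},
#'   \code{V_M} (electrodes x bins), \code{coef} (drive coefficients),
#'   \code{skipped} (bin frequencies below the floor)
#' @export
run_fourier_sweep <- function(mesh, tissues, electrodes, spectrum,
                              interface = NULL, mag_floor = 1e-6,
                              verbose = FALSE) {
  stopifnot(inherits(spectrum, "stimulus_spectrum"))
  coef <- spectrum_coefficients(spectrum)
  keep <- spectrum$magnitude > mag_floor * max(spectrum$magnitude)
  units <- region_unit_matrices(mesh)
  nel <- length(electrodes)
  fk <- spectrum$f[keep]
  phi <- matrix(0 + 0i, nrow(mesh$vertices), sum(keep))
  V_E <- V_M <- matrix(0 + 0i, nel, sum(keep))
  for (k in seq_along(fk)) {
    f <- fk[k]
    zet <- if (is.null(interface)) 0 + 0i else {
      if (f > 0) z_et(interface, f) else complex(real = interface$R_scar)
    }
    # properties are tabulated from 100 Hz up; sub-100 Hz bins (incl. a
    # DC bin above the floor) use the 100 Hz values
    gam <- tissue_gamma(tissues, max(f, 100))
    sys <- assemble_system(mesh, gam, units = units)
    sys <- apply_electrode_bc(sys, electrodes,
                              I = coef[keep][k], Z_ET = zet)
    fld <- solve_frequency(sys, f = f)
    phi[, k] <- fld$phi
    V_E[, k] <- fld$V_E
    V_M[, k] <- fld$V_M
    if (verbose)
      message(sprintf("f = %6.0f Hz solved (residual %.2e)", f,
                      fld$residual))
  }
  structure(list(f = fk, phi = phi, V_E = V_E, V_M = V_M,
                 coef = coef[keep], skipped = spectrum$f[!keep],
                 spectrum = spectrum, electrodes = electrodes),
            class = "fourier_sweep")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthesized time series at probe points
#'
#' Linearly interpolates the per-bin complex potentials at the probe
#' points (P1 barycentric interpolation inside the containing
#' tetrahedron) and converts them to the time domain.
#'
#' @param sweep a [run_fourier_sweep()] result
#' @param mesh the mesh the sweep was run on
#' @param points k x 3 matrix of probe coordinates (m)
#' @param times times at which to synthesize (s)
#' @return k x length(times) matrix of potentials (V)
#' @export
probe_time_series <- function(sweep, mesh, points, times) {
  stopifnot(inherits(sweep, "fourier_sweep"))
  points <- matrix(points, ncol = 3)
  loc <- locate_points(mesh$vertices, mesh$tets, points)
  if (anyNA(loc$tet)) stop("probe point(s) outside the mesh: ",
                           paste(which(is.na(loc$tet)), collapse = ", "))
  out <- matrix(0, nrow(points), length(times))
  for (q in seq_len(nrow(points))) {
    vi <- mesh$tets[loc$tet[q], ]
    vals <- drop(loc$bary[q, ] %*% sweep$phi[vi, , drop = FALSE])
    out[q, ] <- inverse_dft(vals, sweep$f, times)
  }
  out
}

#' Electrode terminal voltage time series
#'
#' @param sweep a [run_fourier_sweep()] result
#' @param electrode electrode index (1 = source)
#' @param times times at which to synthesize (s)
#' @param what \code{"V_E"} (terminal, behind the interface) or
#'   \code{"V_M"} (tissue surface)
#' @return numeric vector of voltages (V)
#' @export
electrode_time_series <- function(sweep, electrode = 1L, times,
                                  what = c("V_E", "V_M")) {
  what <- match.arg(what)
  inverse_dft(sweep[[what]][electrode, ], sweep$f, times)
}
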