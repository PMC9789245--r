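# Scenario orchestration: one declarative description of a simulation
# (phantom, tissues, electrode mode, stimulus, solver mode, interface and
# power limiting, fiber counts and seeds) is run end to end into a results
# bundle: probe waveforms, thresholds, recruitment, ROC/AUC and a
# provenance log.

# small FNV-1a hash for provenance logging (no external digest dependency)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Simulation scenario
#'
#' @param phantom a [phantom_config()]
#' @param mode electrode configuration, \code{"monopolar"} or
#'   \code{"bipolar"}
#' @param solver \code{"fourier"} (complex admittivity per frequency
#'   component) or \code{"qs"} (one purely resistive unit solve scaled by
#'   the stimulus)
#' @param stimulus a [build_biphasic()] waveform
#' @param f_max maximum retained spectrum frequency (Hz)
#' @param interface \code{NULL}, or an [interface_model()] to include the
#'   electrode-tissue contact impedance
#' @param power_limit apply the [apply_power_limit()] rule to the drive
#' @param bounds per-region bound tags (see [phantom_tissues()])
#' @param n_fibers fibers per branch (study default 400; reduce for
#'   desk-scale runs)
#' @param type_mix,seed fiber population controls ([generate_fibers()])
#' @param mag_floor spectrum magnitude floor for the sweep
#' @param qs_f_ref conductivity reference frequency for QS mode (Hz)
#' @return object of class \code{scenario}
#' @export
scenario <- function(phantom = phantom_config(),
                     mode = c("monopolar", "bipolar"),
                     solver = c("fourier", "qs"),
                     stimulus = build_biphasic(), f_max = 5e5,
                     interface = NULL, power_limit = FALSE,
                     bounds = list(), n_fibers = 400,
                     type_mix = c(calyx = 0.25, dimorphic = 0.5,
                                  bouton = 0.25),
                     seed = 1L, mag_floor = 1e-6, qs_f_ref = 100) {
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  if (power_limit && is.null(interface) && phantom$scar_thickness == 0)
    message("power limit without interface model: cap binds only via ",
            "tissue impedance")
  structure(list(phantom = phantom, mode = mode, solver = solver,
                 stimulus = stimulus, f_max = f_max, interface = interface,
                 power_limit = power_limit, bounds = bounds,
                 n_fibers = n_fibers, type_mix = type_mix, seed = seed,
                 mag_floor = mag_floor, qs_f_ref = qs_f_ref),
            class = "scenario")
}

#' Run a scenario into a results bundle
#'
#' Builds (or reuses) the phantom, solves the field problem in the
#' requested mode, synthesizes electrode and nerve-probe waveforms,
#' applies the power limitation, estimates fiber thresholds per branch and
#' derives recruitment curves and worst-case ROC/AUC.
#'
#' @param sc a [scenario()]
#' @param mesh optional pre-built \code{labeled_mesh} for this scenario
#'   (must match its phantom config and electrode mode)
#' @param with_fibers set \code{FALSE} to stop after the field stage
#' @return object of class \code{results_bundle}
#' @export
run_scenario <- function(sc, mesh = NULL, with_fibers = TRUE) {
  stopifnot(inherits(sc, "scenario"))
  electrodes <- place_electrodes(sc$phantom, sc$mode)
  if (is.null(mesh)) mesh <- build_phantom(sc$phantom, electrodes)
  tissues <- phantom_tissues(mesh, bounds = sc$bounds)
  times <- sc$stimulus$time
  spec <- forward_dft(sc$stimulus, df = 1 / sc$stimulus$window,
                      f_max = sc$f_max)
  zet_dc <- if (is.null(sc$interface)) 0 else sc$interface$R_scar
  if (sc$solver == "fourier") {
    sweep <- run_fourier_sweep(mesh, tissues, electrodes, spec,
                               interface = sc$interface,
                               mag_floor = sc$mag_floor)
    I_t <- inverse_dft(sweep$coef, sweep$f, times)
    V_E <- electrode_time_series(sweep, 1L, times, "V_E")
    V_M <- electrode_time_series(sweep, 1L, times, "V_M")
  } else {
    sweep <- solve_qs(mesh, tissues, electrodes, f_ref = sc$qs_f_ref)
    I_t <- sc$stimulus$samples
    V_M <- sweep$V_M_unit[1L] * I_t
    V_E <- V_M + zet_dc * I_t     # a purely resistive interface at QS
  }
  # probe points: one at each bundle entry, plus the source electrode
  probes <- list()
  if (!is.null(sc$phantom$bundles)) {
    for (nm in names(sc$phantom$bundles)) {
      probes[[paste0("nerve_", nm)]] <-
        sc$phantom$bundles[[nm]] * (sc$phantom$cavity_radius + 1e-3)
    }
  }
  probe_mat <- do.call(rbind, probes)
  probe_series <- if (length(probes) > 0) {
    if (sc$solver == "fourier") {
      probe_time_series(sweep, mesh, probe_mat, times)
    } else {
      loc <- locate_points(mesh$vertices, mesh$tets, probe_mat)
      phi <- vapply(seq_len(nrow(probe_mat)), function(q)
        sum(loc$bary[q, ] * sweep$phi_unit[mesh$tets[loc$tet[q], ]]),
        numeric(1L))
      outer(phi, I_t)
    }
  } else NULL
  if (!is.null(probe_series)) rownames(probe_series) <- names(probes)
  plim <- apply_power_limit(V_E, I_t, if (is.null(sc$interface)) 5e-3 else
    sc$interface$P_max)
  if (!sc$power_limit) plim$scale <- 1
  amp_max <- sc$stimulus$amplitude * plim$scale

  thresholds <- curves <- roc <- NULL
  if (with_fibers && !is.null(sc$phantom$bundles)) {
    thresholds <- list()
    for (nm in names(sc$phantom$bundles)) {
      fibers <- generate_fibers(mesh, nm, n = sc$n_fibers,
                                type_mix = sc$type_mix,
                                seed = sc$seed + match(nm, names(
                                  sc$phantom$bundles)))
      thresholds[[paste0("nerve_", nm)]] <-
        population_thresholds(sweep, mesh, fibers, times, sc$stimulus)
    }
    grid <- amplitude_grid(unlist(thresholds, recursive = FALSE))
    if (sc$power_limit) grid <- grid[grid <= amp_max * 1.0000001]
    if (length(grid) >= 2L) {
      curves <- lapply(names(thresholds), function(nm)
        recruitment(thresholds[[nm]], grid, branch = nm))
      names(curves) <- names(thresholds)
      tgt <- grep("target$", names(curves), value = TRUE)[1L]
      if (!is.na(tgt) && length(curves) > 1L)
        roc <- roc_points(curves[[tgt]], curves[setdiff(names(curves),
                                                        tgt)])
    }
  }
  structure(list(
    scenario = sc, mesh = mesh, times = times, I = plim$scale * I_t,
    V_E = plim$scale * V_E, V_M = plim$scale * V_M,
    probe_series = if (is.null(probe_series)) NULL else
      plim$scale * probe_series,
    power = list(scale = plim$scale, P_peak = plim$P_peak,
                 amp_max = amp_max),
    thresholds = thresholds, curves = curves, roc = roc,
    log = list(config_hash = config_hash(sc),
               seed = sc$seed, n_tets = nrow(mesh$tets),
               n_vertices = nrow(mesh$vertices),
               solver = sc$solver, mode = sc$mode,
               skipped_bins = if (sc$solver == "fourier")
                 length(sweep$skipped) else NA_integer_,
               power_scale = plim$scale)),
    class = "results_bundle")
}

#' @exportS3Method base::print
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle: %s %s, %d tets, power scale %.3f%s>\n",
              x$log$solver, x$log$mode, x$log$n_tets, x$power$scale,
              if (!is.null(x$roc)) sprintf(", AUC %.4f", x$roc$auc) else ""))
  invisible(x)
}

#' Compare two results bundles
#'
#' Per-probe windowed RMSE between the predicted voltage waveforms of two
#' runs (e.g. default versus bound tissue properties, or QS versus the
#' full frequency-dependent solution) plus AUC and threshold deltas.
#'
#' @param a,b \code{results_bundle}s with identical probe sets and grids
#' @return object of class \code{bundle_comparison}: \code{rmse} (named,
#'   V), \code{auc_delta}, \code{threshold_ratio} (median b/a per branch),
#'   \code{worst_case} branches
#' @export
compare_bundles <- function(a, b) {
  stopifnot(inherits(a, "results_bundle"), inherits(b, "results_bundle"))
  if (!identical(rownames(a$probe_series), rownames(b$probe_series)) ||
      length(a$times) != length(b$times))
    stop("bundles have different probe sets or time grids")
  on <- a$scenario$stimulus$onset
  en <- on + 2 * a$scenario$stimulus$phase_duration +
    a$scenario$stimulus$phase_gap
  probes <- c(list(V_E = c(a$V_E), V_M = c(a$V_M)),
              if (!is.null(a$probe_series))
                setNames(lapply(rownames(a$probe_series), function(r)
                  a$probe_series[r, ]), rownames(a$probe_series)))
  probes_b <- c(list(V_E = c(b$V_E), V_M = c(b$V_M)),
                if (!is.null(b$probe_series))
                  setNames(lapply(rownames(b$probe_series), function(r)
                    b$probe_series[r, ]), rownames(b$probe_series)))
  rmse <- vapply(names(probes), function(nm)
    rmse_window(probes[[nm]], probes_b[[nm]], a$times, on, en),
    numeric(1L))
  thr_ratio <- NULL
  if (!is.null(a$thresholds) && !is.null(b$thresholds)) {
    thr_ratio <- vapply(names(a$thresholds), function(nm) {
      ta <- vapply(a$thresholds[[nm]], `[[`, numeric(1L), "threshold")
      tb <- vapply(b$thresholds[[nm]], `[[`, numeric(1L), "threshold")
      stats::median(tb / ta, na.rm = TRUE)
    }, numeric(1L))
  }
  structure(list(
    rmse = rmse,
    auc_delta = if (!is.null(a$roc) && !is.null(b$roc))
      b$roc$auc - a$roc$auc else NA_real_,
    threshold_ratio = thr_ratio,
    worst_case = c(a = if (!is.null(a$roc)) a$roc$worst_case_branch else NA,
                   b = if (!is.null(b$roc)) b$roc$worst_case_branch else NA)),
    class = "bundle_comparison")
}

#' Write the numeric summary of a bundle as JSON
#'
#' @param bundle a \code{results_bundle}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_bundle_summary <- function(bundle, path) {
  s <- list(config_hash = bundle$log$config_hash,
            solver = bundle$log$solver, mode = bundle$log$mode,
            n_tets = bundle$log$n_tets,
            power_scale = bundle$power$scale,
            P_peak_W = bundle$power$P_peak,
            auc = if (!is.null(bundle$roc)) bundle$roc$auc else NULL,
            worst_case_branch = if (!is.null(bundle$roc))
              bundle$roc$worst_case_branch else NULL)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
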