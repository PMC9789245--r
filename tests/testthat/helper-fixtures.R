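# Shared fixtures, built lazily and cached for the whole test run. The
# geometry is the study phantom at two reduced resolutions ("small" for
# recruitment-level checks, "tiny" for solver plumbing); the vignette
# records the problem sizes used here.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(build)()
  .fx[[name]]
}

cfg_small <- function() {
  phantom_config(h_electrode = 100e-6, grade = 1.0, h_cavity = 1.2e-3,
                 h_nerve = 0.8e-3, level = 2L)
}

cfg_tiny <- function(...) {
  phantom_config(h_electrode = 150e-6, grade = 1.5, h_cavity = 1.8e-3,
                 h_nerve = 1.2e-3, level = 2L, ...)
}

stim_long <- function() build_biphasic()
stim_short <- function() build_biphasic(phase_duration = 50e-6,
                                        phase_gap = 2e-6)

fx_mesh_small_mono <- function() fx("mesh_small_mono", function()
  build_phantom(cfg_small(), place_electrodes(cfg_small(), "monopolar")))

fx_mesh_small_bi <- function() fx("mesh_small_bi", function()
  build_phantom(cfg_small(), place_electrodes(cfg_small(), "bipolar")))

fx_mesh_tiny_mono <- function() fx("mesh_tiny_mono", function()
  build_phantom(cfg_tiny(), place_electrodes(cfg_tiny(), "monopolar")))

fx_mesh_tiny_bi <- function() fx("mesh_tiny_bi", function()
  build_phantom(cfg_tiny(), place_electrodes(cfg_tiny(), "bipolar")))

fx_mesh_default_mono <- function() fx("mesh_default_mono", function()
  build_phantom(phantom_config(),
                place_electrodes(phantom_config(), "monopolar")))

# frequency sweeps on the small monopolar/bipolar phantoms, long stimulus
# truncated at 50 kHz (50 bins at the canonical 1 kHz resolution)
fx_spectrum_50k <- function() fx("spectrum_50k", function()
  forward_dft(stim_long(), f_max = 50e3))

fx_sweep_mono <- function() fx("sweep_mono", function() {
  mesh <- fx_mesh_small_mono()
  run_fourier_sweep(mesh, phantom_tissues(mesh), mesh$electrodes,
                    fx_spectrum_50k())
})

fx_sweep_bi <- function() fx("sweep_bi", function() {
  mesh <- fx_mesh_small_bi()
  run_fourier_sweep(mesh, phantom_tissues(mesh), mesh$electrodes,
                    fx_spectrum_50k())
})

fx_qs_mono <- function() fx("qs_mono", function() {
  mesh <- fx_mesh_small_mono()
  solve_qs(mesh, phantom_tissues(mesh), mesh$electrodes)
})

# fiber population shared between QS and Fourier threshold sets
fx_fibers <- function(mesh, branch) {
  fx(paste0("fibers_", branch), function()
    generate_fibers(mesh, branch, n = 6,
                    type_mix = c(calyx = 0.5, dimorphic = 0.5), seed = 7L))
}

fx_thresholds <- function(which = c("fourier", "qs", "bipolar")) {
  which <- match.arg(which)
  fx(paste0("th_", which), function() {
    mesh <- if (which == "bipolar") fx_mesh_small_bi() else
      fx_mesh_small_mono()
    sol <- switch(which, fourier = fx_sweep_mono(), qs = fx_qs_mono(),
                  bipolar = fx_sweep_bi())
    out <- list()
    for (br in c("target", "nontarget1", "nontarget2")) {
      fibers <- fx_fibers(fx_mesh_small_mono(), br)
      out[[paste0("nerve_", br)]] <-
        population_thresholds(sol, mesh, fibers, stim_long()$time,
                              stim_long())
    }
    out
  })
}

# constant-conductivity, permittivity-free tissue map (QS oracle runs)
const_tissues <- function(mesh) {
  knots <- c(100, 5e5)
  mk <- function(s) tissue_property("const", knots, rep(s, 2), rep(1e-12, 2))
  out <- list()
  for (rg in sort(unique(mesh$region))) {
    out[[rg]] <- if (startsWith(rg, "nerve_")) {
      list(type = "aniso", long = mk(0.3), trans = mk(0.03))
    } else {
      list(type = "iso", prop = mk(c(fluid = 2, saline = 2, bone = 0.02,
                                     scar = 0.1)[[rg]]))
    }
  }
  out
}

flat_thresholds <- function(th) {
  unlist(lapply(th, function(l) vapply(l, `[[`, numeric(1L), "threshold")))
}

# synthetic focal extracellular profile for fiber-level tests
focal_fiber <- function(n_nodes = 21L, diameter = 2e-6) {
  structure(list(nodes = cbind(seq_len(n_nodes) * 100 * diameter, 0, 0),
                 internode = 100 * diameter, diameter = diameter,
                 type = "dimorphic", branch = "nerve_target", id = 1L),
            class = "fiber_geometry")
}

focal_Ve <- function(stim, n_nodes = 21L, depth = 1) {
  prof <- -depth / (1 + (seq_len(n_nodes) - (n_nodes + 1) / 2)^2)
  outer(prof, stim$samples / stim$amplitude)
}
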