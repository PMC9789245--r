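# Phantom geometry: mesh measures, electrode placement, fiber generation
# and mesh exchange formats.

test_that("default phantom reproduces the analytic measures", {
  mesh <- fx_mesh_default_mono()
  mm <- mesh_measures(mesh)
  expect_lt(abs(mm$volume / (4 / 3 * pi * 0.035^3) - 1), 0.05)
  expect_lt(abs(mm$patch_area[["electrode_1"]] / (4 * pi * 150e-6^2) - 1),
            0.05)
  # every configured region is present and labeled
  expect_setequal(unique(mesh$region),
                  c("fluid", "bone", "saline", "nerve_target",
                    "nerve_nontarget1", "nerve_nontarget2"))
  expect_false(anyNA(mesh$region))
  # all elements positively oriented, none degenerate
  vol <- vestifem:::tet_volumes(mesh$vertices, mesh$tets)
  expect_true(all(vol > 0))
  # quality floor
  expect_gt(min(vestifem:::min_dihedral(mesh$vertices, mesh$tets)), 0.5)
  # outer boundary on the saline sphere and closed (every edge in 2 faces)
  ob <- mesh$patches$outer_boundary
  r <- sqrt(rowSums(mesh$vertices[unique(as.vector(ob)), ]^2))
  expect_lt(max(abs(r - 0.035)), 1e-6)
  ek <- c(pmin(ob[, 1], ob[, 2]) * 2^26 + pmax(ob[, 1], ob[, 2]),
          pmin(ob[, 2], ob[, 3]) * 2^26 + pmax(ob[, 2], ob[, 3]),
          pmin(ob[, 1], ob[, 3]) * 2^26 + pmax(ob[, 1], ob[, 3]))
  expect_true(all(table(ek) == 2L))
})

test_that("electrode placement follows the monopolar/bipolar offsets", {
  cfg <- cfg_small()
  el <- place_electrodes(cfg, "monopolar")
  expect_length(el, 1L)
  expect_equal(sqrt(sum(el[[1]]$center^2)), 750e-6)
  expect_identical(el[[1]]$role, "source")

  el2 <- place_electrodes(cfg, "bipolar")
  expect_equal(sapply(el2, function(e) sqrt(sum(e$center^2))),
               c(250e-6, 1250e-6))
  expect_identical(sapply(el2, `[[`, "role"), c("source", "sink"))

  expect_error(place_electrodes(cfg, "monopolar", axis = c(0, 0, 0)),
               "zero")
  # an electrode pushed outside the fluid cavity is rejected
  expect_error(place_electrodes(cfg, "monopolar",
                                epithelium_center = c(1.5e-3, 0, 0)),
               "cavity")
})

test_that("overlapping electrode spheres are rejected", {
  cfg <- cfg_tiny()
  el <- list(electrode_spec(c(2e-4, 0, 0), role = "source"),
             electrode_spec(c(4e-4, 0, 0), role = "sink"))
  expect_error(build_phantom(cfg, el), "overlap")
})

test_that("fiber populations are sized, seeded and contained", {
  mesh <- fx_mesh_small_mono()
  fib <- generate_fibers(mesh, "target", n = 400, seed = 3L)
  expect_length(fib, 400L)

  again <- generate_fibers(mesh, "target", n = 400, seed = 3L)
  expect_identical(lapply(fib, `[[`, "nodes"), lapply(again, `[[`, "nodes"))
  other <- generate_fibers(mesh, "target", n = 400, seed = 4L)
  expect_false(identical(fib[[1]]$nodes, other[[1]]$nodes))

  nodes <- do.call(rbind, lapply(fib[1:50], `[[`, "nodes"))
  lab <- vestifem:::classify_points(mesh$cfg, nodes)
  expect_true(all(lab == "nerve_target"))
  # node spacing equals the internode length
  sp <- diff(fib[[1]]$nodes[, 1])
  expect_lt(max(abs(sp / fib[[1]]$internode - 1)), 0.01)

  expect_error(generate_fibers(mesh, "target", n = 0), "n > 0")
  expect_error(generate_fibers(mesh, "sideways", n = 1), "branch")
})

test_that("mesh files round trip through VTK and MSH", {
  mesh <- fx_mesh_tiny_mono()
  for (ext in c(".vtk", ".msh")) {
    path <- tempfile(fileext = ext)
    write_mesh(mesh, path)
    back <- read_mesh(path)
    expect_identical(back$vertices, mesh$vertices)   # bitwise coordinates
    expect_identical(back$tets, mesh$tets)
    expect_identical(back$region, mesh$region)
    expect_equal(back$fiber_axis, mesh$fiber_axis)
    expect_identical(names(back$patches), names(mesh$patches))
    expect_identical(back$patches$outer_boundary, mesh$patches$outer_boundary)
  }
  expect_error(write_mesh(mesh, tempfile(fileext = ".stl")), "unknown")
})

test_that("mesh files without region labels are rejected", {
  mesh <- fx_mesh_tiny_mono()
  path <- tempfile(fileext = ".vtk")
  write_mesh(mesh, path)
  ln <- readLines(path)
  ln[2] <- "exported grid"                      # drop the name table
  writeLines(ln, path)
  expect_error(read_mesh(path), "label")

  path2 <- tempfile(fileext = ".msh")
  write_mesh(mesh, path2)
  ln <- readLines(path2)
  i0 <- which(ln == "$PhysicalNames")
  i1 <- which(ln == "$EndPhysicalNames")
  writeLines(ln[-(i0:i1)], path2)
  expect_error(read_mesh(path2), "PhysicalNames")
})
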