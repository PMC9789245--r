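# Parametric phantom: a conductive fluid cavity holding spherical
# electrodes, one target and two non-target anisotropic nerve bundles,
# a 25 mm bone sphere and a 10 mm saline shell. Stands in for segmented
# inner-ear anatomy; all coordinates in meters, cavity centered at the
# origin (the "sensory epithelium center").

#' Electrode specification
#'
#' @param center electrode center, length-3 numeric (m)
#' @param radius electrode radius (m), default 150 um
#' @param role one of \code{"source"}, \code{"sink"}, \code{"reference"}
#' @param areal_cdl double-layer areal capacitance (F/cm^2)
#' @param scar_thickness encapsulation shell thickness (m): 0 or one of
#'   300/400/500 um in the lumped interface model
#' @return object of class \code{electrode_spec}
#' @export
electrode_spec <- function(center, radius = 150e-6,
                           role = c("source", "sink", "reference"),
                           areal_cdl = 15e-6, scar_thickness = 0) {
  role <- match.arg(role)
  stopifnot(is.numeric(center), length(center) == 3L, radius > 0,
            areal_cdl > 0, scar_thickness >= 0)
  structure(list(center = as.numeric(center), radius = radius, role = role,
                 areal_cdl = areal_cdl, scar_thickness = scar_thickness),
            class = "electrode_spec")
}

#' Phantom configuration
#'
#' Geometry and resolution of the synthetic labeled mesh. Defaults give the
#' standard study geometry: a 2 mm fluid cavity at the origin inside a
#' 25 mm bone sphere and a 10 mm saline shell (outer reference boundary at
#' 35 mm); a target nerve bundle leaving the cavity along +x (the
#' transversal electrode axis) and two non-target bundles along +y and +z.
#'
#' @param cavity_radius fluid cavity radius (m)
#' @param bone_radius bone sphere radius (m)
#' @param saline_radius outer (reference boundary) radius (m)
#' @param bundle_radius nerve bundle radius (m)
#' @param bundle_length nerve bundle length from the cavity wall (m)
#' @param bundles named list of unit direction vectors for the bundles;
#'   names become region labels \code{nerve_<name>}; \code{NULL} for a
#'   nerve-free phantom
#' @param h_electrode target edge length at the electrode surface (m)
#' @param grade mesh-size growth rate with distance from each electrode
#' @param h_cavity target edge length inside the fluid cavity (m)
#' @param h_nerve target edge length inside nerve bundles (m)
#' @param level angular subdivision level of the base icosphere shells
#' @param scar_thickness meshed scar-shell thickness around electrodes (m);
#'   0 (default) uses the lumped resistance instead
#' @return object of class \code{phantom_config}
#' @export
phantom_config <- function(cavity_radius = 2e-3, bone_radius = 25e-3,
                           saline_radius = 35e-3, bundle_radius = 0.6e-3,
                           bundle_length = 6e-3,
                           bundles = list(target = c(1, 0, 0),
                                          nontarget1 = c(0, 1, 0),
                                          nontarget2 = c(0, 0, 1)),
                           h_electrode = 60e-6, grade = 0.72,
                           h_cavity = 0.8e-3, h_nerve = 0.55e-3,
                           level = 3L, scar_thickness = 0) {
  stopifnot(cavity_radius > 0, bone_radius > cavity_radius,
            saline_radius > bone_radius, h_electrode > 0, grade > 0,
            scar_thickness >= 0)
  if (!is.null(bundles)) {
    for (d in bundles) stopifnot(length(d) == 3L, sum(d^2) > 0)
    bundles <- lapply(bundles, function(d) d / sqrt(sum(d^2)))
  }
  structure(list(cavity_radius = cavity_radius, bone_radius = bone_radius,
                 saline_radius = saline_radius,
                 bundle_radius = bundle_radius,
                 bundle_length = bundle_length, bundles = bundles,
                 h_electrode = h_electrode, grade = grade,
                 h_cavity = h_cavity, h_nerve = h_nerve, level = level,
                 scar_thickness = scar_thickness),
            class = "phantom_config")
}

#' Electrode placement for monopolar / bipolar stimulation
#'
#' Monopolar: a single source electrode 750 um from the epithelium center
#' along the transversal axis. Bipolar: source at 250 um and sink at
#' 1250 um with inverted current. The reference is always the outer
#' boundary of the saline shell.
#'
#' @param cfg a [phantom_config()]
#' @param mode \code{"monopolar"} or \code{"bipolar"}
#' @param epithelium_center center of the sensory epithelium (m)
#' @param axis transversal axis unit vector (normalized internally)
#' @param radius electrode radius (m)
#' @return list of [electrode_spec()] (source first)
#' @export
place_electrodes <- function(cfg, mode = c("monopolar", "bipolar"),
                             epithelium_center = c(0, 0, 0),
                             axis = c(1, 0, 0), radius = 150e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "phantom_config"), length(axis) == 3L)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must have nonzero length")
  axis <- axis / nrm
  offs <- if (mode == "monopolar") 750e-6 else c(250e-6, 1250e-6)
  roles <- if (mode == "monopolar") "source" else c("source", "sink")
  el <- mapply(function(o, rl) {
    ctr <- epithelium_center + o * axis
    if (sqrt(sum(ctr^2)) + radius >= cfg$cavity_radius)
      stop("electrode leaves the fluid cavity")
    electrode_spec(ctr, radius, rl, scar_thickness = cfg$scar_thickness)
  }, offs, roles, SIMPLIFY = FALSE)
  lab <- classify_points(cfg, do.call(rbind, lapply(el, `[[`, "center")))
  if (any(!lab %in% "fluid"))
    stop("electrode center not inside the fluid cavity")
  unname(el)
}

# region label per point ("electrode" handled separately by the builder)
classify_points <- function(cfg, pts) {
  pts <- matrix(pts, ncol = 3)
  r <- sqrt(rowSums(pts^2))
  lab <- rep("saline", nrow(pts))
  lab[r <= cfg$bone_radius] <- "bone"
  if (!is.null(cfg$bundles)) {
    for (nm in names(cfg$bundles)) {
      d <- cfg$bundles[[nm]]
      ax <- pts %*% d
      rad2 <- rowSums(pts^2) - ax^2
      inb <- ax >= cfg$cavity_radius - 1e-9 &
        ax <= cfg$cavity_radius + cfg$bundle_length &
        rad2 <= cfg$bundle_radius^2
      lab[inb & r <= cfg$bone_radius] <- paste0("nerve_", nm)
    }
  }
  lab[r <= cfg$cavity_radius] <- "fluid"
  lab[r > cfg$saline_radius] <- "outside"
  lab
}

# mesh size target (m) per point for the given electrodes
phantom_sizefun <- function(cfg, electrodes) {
  centers <- do.call(rbind, lapply(electrodes, `[[`, "center"))
  function(p) {
    h <- rep(Inf, nrow(p))
    for (i in seq_len(nrow(centers))) {
      d <- sqrt(rowSums((p - matrix(centers[i, ], nrow(p), 3,
                                    byrow = TRUE))^2))
      h <- pmin(h, pmax(cfg$h_electrode, cfg$grade * d))
    }
    r <- sqrt(rowSums(p^2))
    h[r < cfg$cavity_radius + 0.5e-3] <-
      pmin(h[r < cfg$cavity_radius + 0.5e-3], cfg$h_cavity)
    if (!is.null(cfg$bundles)) {
      for (d in cfg$bundles) {
        ax <- p %*% d
        rad2 <- rowSums(p^2) - ax^2
        inb <- ax > 0 & ax <= cfg$cavity_radius + cfg$bundle_length +
          0.3e-3 & rad2 <= (cfg$bundle_radius + 0.25e-3)^2
        h[inb] <- pmin(h[inb], cfg$h_nerve)
      }
    }
    h
  }
}

#' Build the labeled tetrahedral phantom mesh
#'
#' Generates a graded conforming tetrahedral mesh of the phantom geometry:
#' a spherical-shell base mesh is bisection-refined towards the electrodes,
#' the fluid cavity and the nerve bundles; vertices near each electrode
#' sphere are snapped onto it, electrode interiors are removed and their
#' surface triangles recorded as electrode patches. Tetrahedra are labeled
#' by region; nerve tetrahedra carry the local fiber-axis unit vector.
#'
#' @param cfg a [phantom_config()]
#' @param electrodes list of [electrode_spec()] from [place_electrodes()]
#' @return object of class \code{labeled_mesh}: \code{vertices} (n x 3, m),
#'   \code{tets} (m x 4 indices), \code{region} (character per tet),
#'   \code{fiber_axis} (m x 3, NA outside nerve), \code{patches} (named
#'   list of triangle index matrices: \code{electrode_1}, ...,
#'   \code{outer_boundary}), \code{electrodes} (the input specs),
#'   \code{cfg}
#' @export
build_phantom <- function(cfg, electrodes) {
  stopifnot(inherits(cfg, "phantom_config"), length(electrodes) >= 1L)
  centers <- do.call(rbind, lapply(electrodes, `[[`, "center"))
  radii <- vapply(electrodes, `[[`, numeric(1L), "radius")
  # geometric sanity: electrodes pairwise disjoint and inside the cavity
  if (nrow(centers) > 1L) {
    for (i in 1:(nrow(centers) - 1L)) for (j in (i + 1L):nrow(centers)) {
      if (sqrt(sum((centers[i, ] - centers[j, ])^2)) <= radii[i] + radii[j])
        stop("electrode spheres overlap")
    }
  }
  core_r <- max(2.5 * cfg$cavity_radius / 2, cfg$cavity_radius * 1.4)
  base <- onion_ball_mesh(core_r, cfg$saline_radius, level = cfg$level)
  ref <- refine_mesh(base$vertices, base$tets, phantom_sizefun(cfg, electrodes))
  verts <- ref$vertices
  tets <- ref$tets

  # cut the mesh to each electrode sphere so the contact surface is an
  # inscribed triangulation with every vertex on the sphere
  for (i in seq_along(electrodes)) {
    res <- cut_sphere(verts, tets, centers[i, ], radii[i])
    verts <- res$vertices
    tets <- res$tets
  }
  vol <- tet_volumes(verts, tets)
  if (any(vol <= 0)) stop("surface cut produced ", sum(vol <= 0),
                          " degenerate tetrahedra")

  cent <- tet_centroids(verts, tets)
  region <- classify_points(cfg, cent)
  inside_el <- rep(FALSE, nrow(tets))
  which_el <- rep(NA_integer_, nrow(tets))
  for (i in seq_along(electrodes)) {
    d <- sqrt(rowSums((cent - matrix(centers[i, ], nrow(cent), 3,
                                     byrow = TRUE))^2))
    hit <- d < radii[i]
    inside_el <- inside_el | hit
    which_el[hit] <- i
  }
  if (cfg$scar_thickness > 0) {
    for (i in seq_along(electrodes)) {
      d <- sqrt(rowSums((cent - matrix(centers[i, ], nrow(cent), 3,
                                       byrow = TRUE))^2))
      sc <- !inside_el & d < radii[i] + cfg$scar_thickness
      region[sc] <- "scar"
    }
  }
  if (any(region == "outside")) stop("internal error: tets beyond the hull")

  # electrode patches: faces between kept tets and removed interiors
  keep <- !inside_el
  tf <- tet_faces(tets)
  patches <- list()
  for (i in seq_along(electrodes)) {
    own <- which_el[tf$tet] %in% i
    other <- tf$key[keep[tf$tet]]
    fkey <- intersect(tf$key[own], other)
    sel <- own & tf$key %in% fkey
    fv <- tf$verts[sel, , drop = FALSE]
    patches[[paste0("electrode_", i)]] <- fv[!duplicated(face_key(
      fv[, 1], fv[, 2], fv[, 3])), , drop = FALSE]
  }

  tets2 <- tets[keep, , drop = FALSE]
  region <- region[keep]
  # outer boundary: unmatched faces of the kept mesh minus electrode faces
  tf2 <- tet_faces(tets2)
  tab <- table(tf2$key)
  bkey <- as.numeric(names(tab)[tab == 1L])
  elkeys <- unlist(lapply(patches, function(p)
    face_key(p[, 1], p[, 2], p[, 3])))
  sel <- tf2$key %in% setdiff(bkey, elkeys)
  outer <- tf2$verts[sel, , drop = FALSE]
  rout <- sqrt(rowSums(verts[unique(as.vector(outer)), , drop = FALSE]^2))
  if (any(abs(rout - cfg$saline_radius) > 1e-6 * cfg$saline_radius))
    stop("outer boundary vertices off the saline sphere")
  patches$outer_boundary <- outer

  fiber_axis <- matrix(NA_real_, nrow(tets2), 3)
  if (!is.null(cfg$bundles)) {
    for (nm in names(cfg$bundles)) {
      hit <- region == paste0("nerve_", nm)
      fiber_axis[hit, ] <- matrix(cfg$bundles[[nm]], sum(hit), 3,
                                  byrow = TRUE)
    }
  }

  # drop unreferenced vertices (electrode interiors)
  used <- sort(unique(c(as.vector(tets2),
                        unlist(lapply(patches, as.vector)))))
  remap <- integer(nrow(verts))
  remap[used] <- seq_along(used)
  tets2[] <- remap[tets2]
  patches <- lapply(patches, function(p) {
    p[] <- remap[p]
    p
  })
  storage.mode(tets2) <- "integer"
  dimnames(tets2) <- NULL
  patches <- lapply(patches, function(p) {
    storage.mode(p) <- "integer"
    dimnames(p) <- NULL
    p
  })
  verts <- unname(verts)
  structure(list(vertices = verts[used, , drop = FALSE], tets = tets2,
                 region = region, fiber_axis = fiber_axis,
                 patches = patches, electrodes = electrodes, cfg = cfg),
            class = "labeled_mesh")
}

#' @exportS3Method base::print
print.labeled_mesh <- function(x, ...) {
  cat(sprintf("<labeled_mesh: %d vertices, %d tets, regions: %s>\n",
              nrow(x$vertices), nrow(x$tets),
              paste(names(table(x$region)), collapse = ", ")))
  cat(sprintf("  patches: %s\n", paste(names(x$patches), collapse = ", ")))
  invisible(x)
}

#' Total volume and patch areas of a labeled mesh
#'
#' @param mesh a \code{labeled_mesh}
#' @return list with \code{volume} (m^3), per-region volumes and named
#'   patch areas (m^2)
#' @export
mesh_measures <- function(mesh) {
  vol <- tet_volumes(mesh$vertices, mesh$tets)
  areas <- vapply(mesh$patches, function(p) {
    a <- mesh$vertices[p[, 1], , drop = FALSE]
    b <- mesh$vertices[p[, 2], , drop = FALSE]
    c_ <- mesh$vertices[p[, 3], , drop = FALSE]
    u <- b - a
    v <- c_ - a
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    sum(sqrt(rowSums(cr^2)) / 2)
  }, numeric(1L))
  list(volume = sum(vol), region_volume = tapply(vol, mesh$region, sum),
       patch_area = areas, min_dihedral = NULL)
}

#' Generate a population of myelinated nerve fibers in a bundle
#'
#' Places \code{n} fibers along the axis of the requested bundle. Each
#' fiber is a straight chain of nodes of Ranvier with internode spacing of
#' 100 fiber diameters; its transverse position is drawn uniformly from the
#' bundle cross-section and its axial start is jittered by up to one
#' internode. Afferent types (calyx / dimorphic / bouton) with their
#' diameters are drawn from \code{type_mix}. Deterministic for a fixed
#' \code{seed}.
#'
#' @param mesh a \code{labeled_mesh} with nerve regions
#' @param branch bundle name (e.g. \code{"target"}) or full region label
#' @param n number of fibers (> 0); study default 400 per branch
#' @param type_mix named occurrence fractions summing to 1; names must
#'   appear in \code{diameters}
#' @param diameters named fiber diameters in meters per afferent type;
#'   defaults (calyx 3 um, dimorphic 2 um, bouton 1 um) are implementation
#'   choices documented in the methods vignette
#' @param seed integer seed
#' @return list of \code{fiber_geometry}: \code{nodes} (k x 3 m),
#'   \code{internode} (m), \code{diameter} (m), \code{type}, \code{branch}
#' @export
generate_fibers <- function(mesh, branch, n = 400,
                            type_mix = c(calyx = 0.25, dimorphic = 0.5,
                                         bouton = 0.25),
                            diameters = c(calyx = 3e-6, dimorphic = 2e-6,
                                          bouton = 1e-6),
                            seed = 1L) {
  stopifnot(inherits(mesh, "labeled_mesh"), n > 0)
  lab <- if (startsWith(branch, "nerve_")) branch else paste0("nerve_", branch)
  cfg <- mesh$cfg
  nm <- sub("^nerve_", "", lab)
  if (is.null(cfg$bundles) || !nm %in% names(cfg$bundles))
    stop("no such nerve branch: ", branch)
  if (abs(sum(type_mix) - 1) > 1e-9) stop("type_mix must sum to 1")
  if (!all(names(type_mix) %in% names(diameters)))
    stop("type_mix names must have diameters")
  dirv <- cfg$bundles[[nm]]
  # orthonormal frame of the bundle cross-section
  ref <- if (abs(dirv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * dirv) * dirv
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dirv[2] * e1[3] - dirv[3] * e1[2],
          dirv[3] * e1[1] - dirv[1] * e1[3],
          dirv[1] * e1[2] - dirv[2] * e1[1])
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  types <- sample(names(type_mix), n, replace = TRUE, prob = type_mix)
  fibers <- vector("list", n)
  margin <- 0.1e-3
  a0 <- cfg$cavity_radius + margin
  a1 <- cfg$cavity_radius + cfg$bundle_length - margin
  for (i in seq_len(n)) {
    D <- diameters[[types[i]]]
    internode <- 100 * D
    rr <- (cfg$bundle_radius - margin) * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    off <- rr * (cos(th) * e1 + sin(th) * e2)
    start <- a0 + stats::runif(1) * min(internode, a1 - a0)
    ax <- seq(start, a1, by = internode)
    nodes <- matrix(off, length(ax), 3, byrow = TRUE) + outer(ax, dirv)
    fibers[[i]] <- structure(list(nodes = nodes, internode = internode,
                                  diameter = D, type = types[i],
                                  branch = lab, id = i),
                             class = "fiber_geometry")
  }
  fibers
}
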