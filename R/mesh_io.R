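# Mesh exchange in two standard text formats: legacy VTK unstructured grid
# and Gmsh MSH 2.2 ASCII. Region labels, surface patches and the nerve
# fiber-axis field survive a round trip; no installed package reads these
# formats, so the (small) parsers live here.

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a labeled mesh to VTK or Gmsh format
#'
#' The format is chosen from the file extension: \code{.vtk} writes a
#' legacy ASCII unstructured grid (tetrahedra plus patch triangles, with
#' \code{region_id} cell scalars and \code{fiber_axis} cell vectors;
#' region/patch names are kept in the title line), \code{.msh} writes Gmsh
#' MSH 2.2 with physical names and a \code{fiber_axis} element data block.
#'
#' @param mesh a \code{labeled_mesh}
#' @param path output path ending in \code{.vtk} or \code{.msh}
#' @return \code{path}, invisibly
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtk = write_mesh_vtk(mesh, path),
         msh = write_mesh_msh(mesh, path),
         stop("unknown mesh format: .", ext, " (use .vtk or .msh)"))
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         vtk = read_mesh_vtk(path),
         msh = read_mesh_msh(path),
         stop("unknown mesh format: .", ext, " (use .vtk or .msh)"))
}

# name table shared by both formats: regions first, then patches
mesh_name_table <- function(mesh) {
  rn <- sort(unique(mesh$region))
  pn <- names(mesh$patches)
  list(regions = rn, patches = pn,
       region_id = match(mesh$region, rn),
       patch_id = length(rn) + seq_along(pn))
}

write_mesh_vtk <- function(mesh, path) {
  nt <- mesh_name_table(mesh)
  title <- paste0("vestifem|regions=", paste(nt$regions, collapse = ","),
                  "|patches=", paste(nt$patches, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  tri <- do.call(rbind, mesh$patches)
  ntri <- nrow(tri)
  ntet <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", ntet + ntri, 5L * ntet + 4L * ntri), con)
  writeLines(paste(4L, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  if (ntri > 0)
    writeLines(paste(3L, tri[, 1] - 1L, tri[, 2] - 1L, tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ntet + ntri), con)
  writeLines(as.character(c(rep(10L, ntet), rep(5L, ntri))), con)
  patch_rep <- rep(nt$patch_id, vapply(mesh$patches, nrow, integer(1L)))
  writeLines(c(sprintf("CELL_DATA %d", ntet + ntri),
               "SCALARS region_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(c(nt$region_id, patch_rep)), con)
  writeLines("VECTORS fiber_axis double", con)
  fa <- mesh$fiber_axis
  fa[is.na(fa)] <- 0
  fa <- rbind(fa, matrix(0, ntri, 3))
  writeLines(apply(fa, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  invisible(path)
}

read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  title <- ln[2L]
  if (!startsWith(title, "vestifem|"))
    stop("VTK file lacks the region/patch name table; cannot label mesh")
  part <- strsplit(title, "|", fixed = TRUE)[[1L]]
  regions <- strsplit(sub("^regions=", "", part[2L]), ",")[[1L]]
  pnames <- strsplit(sub("^patches=", "", part[3L]), ",")[[1L]]
  ip <- grep("^POINTS", ln)[1L]
  nv <- as.integer(strsplit(ln[ip], " +")[[1L]][2L])
  verts <- matrix(scan(text = ln[(ip + 1L):(ip + nv)], quiet = TRUE),
                  nv, 3, byrow = TRUE)
  ic <- grep("^CELLS", ln)[1L]
  nc <- as.integer(strsplit(ln[ic], " +")[[1L]][2L])
  cells <- strsplit(trimws(ln[(ic + 1L):(ic + nc)]), " +")
  sizes <- vapply(cells, function(x) as.integer(x[1L]), integer(1L))
  id <- grep("^CELL_DATA", ln)[1L]
  isc <- grep("^SCALARS region_id", ln)[1L]
  rid <- as.integer(scan(text = ln[(isc + 2L):(isc + 1L + nc)], quiet = TRUE))
  ivc <- grep("^VECTORS fiber_axis", ln)[1L]
  fa_all <- matrix(scan(text = ln[(ivc + 1L):(ivc + nc)], quiet = TRUE),
                   nc, 3, byrow = TRUE)
  tet_sel <- sizes == 4L
  tets <- do.call(rbind, lapply(cells[tet_sel], function(x)
    as.integer(x[2:5]) + 1L))
  region <- regions[rid[tet_sel]]
  if (anyNA(region)) stop("tetrahedron with unknown region id")
  fiber_axis <- fa_all[tet_sel, , drop = FALSE]
  fiber_axis[rowSums(fiber_axis^2) == 0, ] <- NA_real_
  tri_sel <- sizes == 3L
  tri <- do.call(rbind, lapply(cells[tri_sel], function(x)
    as.integer(x[2:4]) + 1L))
  prid <- rid[tri_sel] - length(regions)
  patches <- lapply(seq_along(pnames), function(i)
    tri[prid == i, , drop = FALSE])
  names(patches) <- pnames
  structure(list(vertices = verts, tets = tets, region = region,
                 fiber_axis = fiber_axis, patches = patches,
                 electrodes = NULL, cfg = NULL),
            class = "labeled_mesh")
}

write_mesh_msh <- function(mesh, path) {
  nt <- mesh_name_table(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames",
               as.character(length(nt$regions) + length(nt$patches))), con)
  for (i in seq_along(nt$regions))
    writeLines(sprintf("3 %d \"%s\"", i, nt$regions[i]), con)
  for (i in seq_along(nt$patches))
    writeLines(sprintf("2 %d \"%s\"", nt$patch_id[i], nt$patches[i]), con)
  writeLines("$EndPhysicalNames", con)
  nv <- nrow(mesh$vertices)
  writeLines(c("$Nodes", as.character(nv)), con)
  writeLines(paste(seq_len(nv),
                   fmt_num(mesh$vertices[, 1]), fmt_num(mesh$vertices[, 2]),
                   fmt_num(mesh$vertices[, 3])), con)
  writeLines("$EndNodes", con)
  ntet <- nrow(mesh$tets)
  tri <- do.call(rbind, mesh$patches)
  patch_rep <- rep(nt$patch_id, vapply(mesh$patches, nrow, integer(1L)))
  writeLines(c("$Elements", as.character(ntet + nrow(tri))), con)
  writeLines(paste(seq_len(ntet), 4L, 2L, nt$region_id, nt$region_id,
                   mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                   mesh$tets[, 4]), con)
  if (nrow(tri) > 0)
    writeLines(paste(ntet + seq_len(nrow(tri)), 2L, 2L, patch_rep,
                     patch_rep, tri[, 1], tri[, 2], tri[, 3]), con)
  writeLines("$EndElements", con)
  fa <- mesh$fiber_axis
  fa[is.na(fa)] <- 0
  writeLines(c("$ElementData", "1", "\"fiber_axis\"", "1", "0.0", "3", "0",
               "3", as.character(ntet)), con)
  writeLines(paste(seq_len(ntet), fmt_num(fa[, 1]), fmt_num(fa[, 2]),
                   fmt_num(fa[, 3])), con)
  writeLines("$EndElementData", con)
  invisible(path)
}

read_mesh_msh <- function(path) {
  ln <- readLines(path)
  sec <- function(tag) {
    i0 <- which(ln == paste0("$", tag))[1L]
    i1 <- which(ln == paste0("$End", tag))[1L]
    if (is.na(i0) || is.na(i1)) stop("MSH file missing $", tag, " section")
    ln[(i0 + 1L):(i1 - 1L)]
  }
  pn <- sec("PhysicalNames")
  npn <- as.integer(pn[1L])
  pdim <- integer(npn); pid <- integer(npn); pname <- character(npn)
  for (i in seq_len(npn)) {
    tok <- strsplit(pn[i + 1L], " ")[[1L]]
    pdim[i] <- as.integer(tok[1L])
    pid[i] <- as.integer(tok[2L])
    pname[i] <- gsub("\"", "", paste(tok[-(1:2)], collapse = " "))
  }
  nd <- sec("Nodes")
  nv <- as.integer(nd[1L])
  nm <- matrix(scan(text = nd[1L + seq_len(nv)], quiet = TRUE), nv, 4,
               byrow = TRUE)
  verts <- nm[order(nm[, 1]), 2:4, drop = FALSE]
  el <- sec("Elements")
  ne <- as.integer(el[1L])
  toks <- strsplit(el[1L + seq_len(ne)], " +")
  etype <- vapply(toks, function(x) as.integer(x[2L]), integer(1L))
  ephys <- vapply(toks, function(x) as.integer(x[4L]), integer(1L))
  tsel <- etype == 4L
  if (!any(tsel)) stop("MSH file contains no tetrahedra")
  tets <- do.call(rbind, lapply(toks[tsel], function(x)
    as.integer(x[6:9])))
  region <- pname[match(ephys[tsel], pid)]
  if (anyNA(region)) stop("tetrahedron with unknown physical region")
  trisel <- etype == 2L
  tri <- do.call(rbind, lapply(toks[trisel], function(x) as.integer(x[6:8])))
  tphys <- ephys[trisel]
  patch_ids <- pid[pdim == 2L]
  patches <- lapply(patch_ids, function(i) tri[tphys == i, , drop = FALSE])
  names(patches) <- pname[match(patch_ids, pid)]
  fiber_axis <- matrix(NA_real_, nrow(tets), 3)
  if (any(ln == "$ElementData")) {
    ed <- sec("ElementData")
    hdr <- 1L + as.integer(ed[1L])       # string tags
    hdr <- hdr + 1L + as.integer(ed[hdr + 1L])   # real tags
    nint <- as.integer(ed[hdr + 1L])
    nrec <- as.integer(ed[hdr + 1L + nint])
    rec <- matrix(scan(text = ed[(hdr + 1L + nint) + seq_len(nrec)],
                       quiet = TRUE), nrec, 4, byrow = TRUE)
    fiber_axis[rec[, 1], ] <- rec[, 2:4]
    fiber_axis[rowSums(fiber_axis^2) == 0 &
                 !is.na(fiber_axis[, 1]), ] <- NA_real_
    fiber_axis[is.na(fiber_axis[, 1]), ] <- NA_real_
  }
  structure(list(vertices = verts, tets = tets, region = region,
                 fiber_axis = fiber_axis, patches = patches,
                 electrodes = NULL, cfg = NULL),
            class = "labeled_mesh")
}
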