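# Tetrahedral mesh primitives: icosphere-onion base meshes, conforming
# longest-edge bisection refinement, quality metrics and point location.
# Coordinates are in meters throughout.

# --- icosphere ------------------------------------------------------------

# unit icosahedron, subdivided `level` times with midpoint projection
icosphere <- function(level = 3L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(level)) {
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- pmin(edges[, 1], edges[, 2]) * 2^26 + pmax(edges[, 1], edges[, 2])
    uk <- unique(key)
    idx <- match(key, uk)
    pairs <- edges[match(uk, key), , drop = FALSE]
    mid <- (v[pairs[, 1], , drop = FALSE] + v[pairs[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    m <- nrow(v) + idx          # midpoint vertex index per face edge
    v <- rbind(v, mid)
    nf <- nrow(f)
    m12 <- m[seq_len(nf)]
    m23 <- m[nf + seq_len(nf)]
    m31 <- m[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  list(vertices = v, faces = unname(f))
}

# --- onion base mesh ------------------------------------------------------

# consistent split of the prism (p,q,r | p',q',r') into three tets; the
# quad diagonals are chosen from the smaller bottom index so that adjacent
# prisms triangulate shared quads identically
split_prisms <- function(bot, top) {
  o <- t(apply(bot, 1, order))
  pick <- function(m, ord) m[cbind(seq_len(nrow(m)), ord)]
  p <- pick(bot, o[, 1]); q <- pick(bot, o[, 2]); r <- pick(bot, o[, 3])
  p2 <- pick(top, o[, 1]); q2 <- pick(top, o[, 2]); r2 <- pick(top, o[, 3])
  rbind(cbind(p, q, r, r2), cbind(p, q, q2, r2), cbind(p, p2, q2, r2))
}

#' Graded spherical base mesh
#'
#' Builds a tetrahedral mesh of a ball of radius \code{r_out}: an inner
#' core (icosphere surface at \code{r_core} coned to the center) wrapped in
#' geometrically graded icosphere shells out to \code{r_out}. All shell
#' vertices lie exactly on spheres, so the outer boundary is an inscribed
#' icosphere triangulation of the target sphere. Used as the starting point
#' for bisection refinement; not exported surface.
#'
#' @noRd
onion_ball_mesh <- function(r_core, r_out, level = 3L, ratio = 1.22) {
  ico <- icosphere(level)
  nv <- nrow(ico$vertices)
  nshell <- max(1L, ceiling(log(r_out / r_core) / log(ratio)))
  radii <- r_core * (r_out / r_core)^(seq(0, 1, length.out = nshell + 1L))
  verts <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(radii, function(r) ico$vertices * r)))
  off <- function(k) 1L + (k - 1L) * nv   # first vertex index of layer k
  tets <- cbind(1L, ico$faces + off(1L))  # core cones, apex at center
  for (k in seq_len(nshell)) {
    bot <- ico$faces + off(k)
    top <- ico$faces + off(k + 1L)
    tets <- rbind(tets, split_prisms(bot, top))
  }
  tets <- orient_tets(verts, tets)
  list(vertices = verts, tets = tets)
}

# flip vertex order where the signed volume is negative
orient_tets <- function(verts, tets) {
  v6 <- tet_volumes(verts, tets)
  neg <- v6 < 0
  if (any(neg)) tets[neg, c(1, 2)] <- tets[neg, c(2, 1)]
  tets
}

tet_volumes <- function(verts, tets) {
  a <- verts[tets[, 1], , drop = FALSE]
  b <- verts[tets[, 2], , drop = FALSE] - a
  c_ <- verts[tets[, 3], , drop = FALSE] - a
  d <- verts[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) +
     b[, 2] * (c_[, 3] * d[, 1] - c_[, 1] * d[, 3]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

tet_centroids <- function(verts, tets) {
  (verts[tets[, 1], , drop = FALSE] + verts[tets[, 2], , drop = FALSE] +
     verts[tets[, 3], , drop = FALSE] + verts[tets[, 4], , drop = FALSE]) / 4
}

EDGE_PAIRS <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))

edge_keys <- function(tets) {
  # 6 canonical edge keys per tet, ntet x 6 (exact in double for < 2^26 verts)
  out <- vapply(seq_len(6), function(e) {
    i <- tets[, EDGE_PAIRS[e, 1]]
    j <- tets[, EDGE_PAIRS[e, 2]]
    pmin(i, j) * 2^26 + pmax(i, j)
  }, numeric(nrow(tets)))
  matrix(out, nrow = nrow(tets))
}

edge_lengths2 <- function(verts, tets) {
  out <- vapply(seq_len(6), function(e) {
    d <- verts[tets[, EDGE_PAIRS[e, 1]], , drop = FALSE] -
      verts[tets[, EDGE_PAIRS[e, 2]], , drop = FALSE]
    rowSums(d * d)
  }, numeric(nrow(tets)))
  matrix(out, nrow = nrow(tets))
}

# --- conforming edge splitting -------------------------------------------

# Split a set of edges conformally: every tetrahedron containing a marked
# edge is subdivided along all of its marked edges, processing them in a
# single global rank order so that shared faces are triangulated
# identically on both sides. `skey` are canonical edge keys, `newpts` the
# split-point coordinates (one per key), `rank` a global priority (lower
# splits first). Returns the updated vertex matrix and tet list.
split_edges <- function(verts, tets, skey, newpts, rank = seq_along(skey)) {
  mid_idx <- nrow(verts) + seq_along(skey)
  verts <- rbind(verts, newpts)
  done <- tets[0, , drop = FALSE]
  act <- tets
  guard <- 0L
  while (nrow(act) > 0L) {
    guard <- guard + 1L
    if (guard > 12L) stop("edge-split sub-round failed to converge")
    k <- edge_keys(act)
    pos <- match(k, skey)                       # ntet x 6, NA if unmarked
    rk <- matrix(rank[pos], nrow = nrow(act))
    rk[is.na(rk)] <- .Machine$integer.max
    best <- max.col(-rk, ties.method = "first")
    has <- rk[cbind(seq_len(nrow(act)), best)] != .Machine$integer.max
    done <- rbind(done, act[!has, , drop = FALSE])
    act <- act[has, , drop = FALSE]
    if (nrow(act) == 0L) break
    be <- best[has]
    m <- mid_idx[match(k[cbind(which(has), be)], skey)]
    ia <- EDGE_PAIRS[be, 1]
    ib <- EDGE_PAIRS[be, 2]
    c1 <- act
    c1[cbind(seq_len(nrow(act)), ib)] <- m
    c2 <- act
    c2[cbind(seq_len(nrow(act)), ia)] <- m
    act <- rbind(c1, c2)
  }
  list(vertices = verts, tets = done)
}

# --- conforming bisection refinement -------------------------------------

# Parallel longest-edge bisection with Rivara-style closure. `sizefun` maps
# an n x 3 centroid matrix to target edge lengths (m).
refine_mesh <- function(verts, tets, sizefun, max_rounds = 80L) {
  for (round in seq_len(max_rounds)) {
    el2 <- edge_lengths2(verts, tets)
    keys <- edge_keys(tets)
    longest <- max.col(el2, ties.method = "first")
    lmax2 <- el2[cbind(seq_len(nrow(tets)), longest)]
    h <- sizefun(tet_centroids(verts, tets))
    over <- lmax2 > h * h
    if (!any(over)) break
    lkey <- keys[cbind(seq_len(nrow(tets)), longest)]
    S <- unique(lkey[over])
    # closure: any tet touching a marked edge must also have its own
    # longest edge marked (keeps the longest-edge character of splits)
    repeat {
      touched <- rowSums(matrix(keys %in% S, nrow = nrow(keys))) > 0
      add <- setdiff(unique(lkey[touched]), S)
      if (length(add) == 0L) break
      S <- c(S, add)
    }
    skey <- sort(S)
    sa <- floor(skey / 2^26)
    sb <- skey - sa * 2^26
    slen2 <- rowSums((verts[sa, , drop = FALSE] - verts[sb, , drop = FALSE])^2)
    rank <- integer(length(skey))
    rank[order(-slen2, skey)] <- seq_along(skey)   # longer edges first
    mid <- (verts[sa, , drop = FALSE] + verts[sb, , drop = FALSE]) / 2
    res <- split_edges(verts, tets, skey, mid, rank)
    verts <- res$vertices
    tets <- res$tets
  }
  if (any(over)) warning("refinement stopped at max_rounds with oversized tets")
  list(vertices = verts, tets = tets)
}

# --- conforming spherical cut --------------------------------------------

# Make the mesh conform to the sphere |x - ctr| = re: edges crossing the
# surface are split at their (radially projected) intersection point;
# crossings very close to an endpoint instead project that endpoint onto
# the sphere (rolled back if an element would invert or collapse). After
# convergence no edge crosses the surface, so the sphere is represented by
# an inscribed triangulated surface with all vertices on it.
cut_sphere <- function(verts, tets, ctr, re, eps = NULL, max_rounds = 8L) {
  if (is.null(eps)) eps <- 1e-6 * re
  sphere_dist <- function(v) {
    sqrt(rowSums((v - matrix(ctr, nrow(v), 3, byrow = TRUE))^2)) - re
  }
  # move the given vertices radially onto the sphere, rolling back any
  # move that would collapse an element below 5 % of its current volume
  project_rollback <- function(idx) {
    if (length(idx) > 0L)    # a vertex at the center cannot be projected
      idx <- idx[sphere_dist(verts[idx, , drop = FALSE]) + re > 0.05 * re]
    if (length(idx) == 0L) return(invisible())
    vol_before <- tet_volumes(verts, tets)
    saved <- verts[idx, , drop = FALSE]
    dvp <- sphere_dist(saved) + re
    verts[idx, ] <<- matrix(ctr, length(idx), 3, byrow = TRUE) +
      (saved - matrix(ctr, length(idx), 3, byrow = TRUE)) * (re / dvp)
    live <- idx
    repeat {
      bad <- which(tet_volumes(verts, tets) < 0.05 * vol_before)
      if (length(bad) == 0L) break
      rv <- intersect(unique(as.vector(tets[bad, ])), live)
      if (length(rv) == 0L) break
      verts[rv, ] <<- saved[match(rv, idx), , drop = FALSE]
      live <- setdiff(live, rv)
    }
  }
  for (round in seq_len(max_rounds)) {
    s <- sphere_dist(verts)
    keys <- unique(as.vector(edge_keys(tets)))
    ka <- floor(keys / 2^26)
    kb <- keys - ka * 2^26
    cross <- (s[ka] < -eps & s[kb] > eps) | (s[kb] < -eps & s[ka] > eps)
    if (!any(cross)) break
    ka <- ka[cross]
    kb <- kb[cross]
    t <- s[ka] / (s[ka] - s[kb])                  # crossing parameter a->b
    near_a <- t < 0.2 & s[ka] + re > 0.05 * re    # never move the center
    near_b <- t > 0.8
    project_rollback(unique(c(ka[near_a], kb[near_b])))
    # re-evaluate after projections: some edges no longer cross
    s <- sphere_dist(verts)
    still <- !(near_a | near_b) & ((s[ka] < -eps & s[kb] > eps) |
                                     (s[kb] < -eps & s[ka] > eps))
    if (any(still)) {
      a <- ka[still]
      b <- kb[still]
      t <- s[a] / (s[a] - s[b])
      p <- verts[a, , drop = FALSE] +
        (verts[b, , drop = FALSE] - verts[a, , drop = FALSE]) * t
      skey <- pmin(a, b) * 2^26 + pmax(a, b)
      o <- order(skey)
      n0 <- nrow(verts)
      res <- split_edges(verts, tets, skey[o], p[o, , drop = FALSE])
      verts <- res$vertices
      tets <- res$tets
      # chord points sit slightly inside the sphere; lift them onto it
      project_rollback(n0 + seq_len(sum(still)))
    } else if (!any(near_a | near_b)) break
  }
  list(vertices = verts, tets = tets)
}

# --- quality --------------------------------------------------------------

# minimum dihedral angle per tet, degrees
min_dihedral <- function(verts, tets) {
  # outward face normals for faces opposite each vertex
  p <- lapply(1:4, function(i) verts[tets[, i], , drop = FALSE])
  cross3 <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
  normal <- function(a, b, c) {
    n <- cross3(b - a, c - a)
    n / sqrt(rowSums(n * n))
  }
  # face i = face not containing vertex i
  n1 <- normal(p[[2]], p[[3]], p[[4]])
  n2 <- normal(p[[1]], p[[3]], p[[4]])
  n3 <- normal(p[[1]], p[[2]], p[[4]])
  n4 <- normal(p[[1]], p[[2]], p[[3]])
  ns <- list(n1, n2, n3, n4)
  ang <- matrix(NA_real_, nrow(tets), 6)
  cnt <- 0L
  for (i in 1:3) for (j in (i + 1):4) {
    cnt <- cnt + 1L
    cosd <- -rowSums(ns[[i]] * ns[[j]])   # interior dihedral
    cosd <- pmin(1, pmax(-1, cosd))
    ang[, cnt] <- acos(cosd) * 180 / pi
  }
  apply(ang, 1, min)
}

# --- faces / boundary -----------------------------------------------------

FACE_TRIPLES <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))

face_key <- function(a, b, c) {
  lo <- pmin(a, b, c)
  hi <- pmax(a, b, c)
  md <- a + b + c - lo - hi
  (lo * 2^17 + md) * 2^17 + hi
}

# all 4 faces of every tet: list(tet = rep, verts = 3 cols, key)
tet_faces <- function(tets) {
  n <- nrow(tets)
  fv <- do.call(rbind, lapply(1:4, function(i) tets[, FACE_TRIPLES[i, ]]))
  list(tet = rep(seq_len(n), 4),
       verts = fv,
       key = face_key(fv[, 1], fv[, 2], fv[, 3]))
}

# --- point location -------------------------------------------------------

# barycentric point location: returns list(tet index, 4 barycentric weights)
# per query point, NA where outside the mesh
locate_points <- function(verts, tets, pts, tol = 1e-8) {
  pts <- matrix(pts, ncol = 3)
  lo <- pmin(verts[tets[, 1], 1], verts[tets[, 2], 1],
             verts[tets[, 3], 1], verts[tets[, 4], 1])
  hi <- pmax(verts[tets[, 1], 1], verts[tets[, 2], 1],
             verts[tets[, 3], 1], verts[tets[, 4], 1])
  lo2 <- pmin(verts[tets[, 1], 2], verts[tets[, 2], 2],
              verts[tets[, 3], 2], verts[tets[, 4], 2])
  hi2 <- pmax(verts[tets[, 1], 2], verts[tets[, 2], 2],
              verts[tets[, 3], 2], verts[tets[, 4], 2])
  lo3 <- pmin(verts[tets[, 1], 3], verts[tets[, 2], 3],
              verts[tets[, 3], 3], verts[tets[, 4], 3])
  hi3 <- pmax(verts[tets[, 1], 3], verts[tets[, 2], 3],
              verts[tets[, 3], 3], verts[tets[, 4], 3])
  out_tet <- integer(nrow(pts))
  out_bar <- matrix(NA_real_, nrow(pts), 4)
  for (q in seq_len(nrow(pts))) {
    p <- pts[q, ]
    pad <- tol + 1e-12
    cand <- which(p[1] >= lo - pad & p[1] <= hi + pad &
                    p[2] >= lo2 - pad & p[2] <= hi2 + pad &
                    p[3] >= lo3 - pad & p[3] <= hi3 + pad)
    found <- FALSE
    best_t <- NA_integer_; best_b <- rep(NA_real_, 4); best_min <- -Inf
    for (ti in cand) {
      a <- verts[tets[ti, 1], ]
      M <- cbind(verts[tets[ti, 2], ] - a, verts[tets[ti, 3], ] - a,
                 verts[tets[ti, 4], ] - a)
      lam <- tryCatch(solve(M, p - a), error = function(e) NULL)
      if (is.null(lam)) next
      b <- c(1 - sum(lam), lam)
      mn <- min(b)
      if (mn > best_min) { best_min <- mn; best_t <- ti; best_b <- b }
      if (mn >= -tol) { found <- TRUE; break }
    }
    if (found || best_min >= -1e-6) {
      out_tet[q] <- best_t
      out_bar[q, ] <- pmax(best_b, 0) / sum(pmax(best_b, 0))
    } else {
      out_tet[q] <- NA_integer_
    }
  }
  list(tet = out_tet, bary = out_bar)
}
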