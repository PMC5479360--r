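# Idealized LV geometry: truncated prolate ellipsoid wall meshes with tagged
# endocardial / epicardial / basal surfaces, quadratic interpolation nodes and
# the auxiliary structures the mechanics solver needs (cavity closure, edges).
#
# Conventions: long axis along +z, apex at -z, base = flat truncation plane at
# z = z_base; azimuth measured from +x; SI units (metres) throughout.

#' Closed-form volume of a truncated semi-ellipsoid cavity
#'
#' Volume of the solid bounded by the ellipsoid with short semi-axis `rs`
#' (x and y) and long semi-axis `rl` (z), from the apex at z = -rl up to the
#' truncation plane z = zb.
#'
#' @param rs short semi-axis (m).
#' @param rl long semi-axis (m).
#' @param zb truncation plane coordinate (m), -rl < zb < rl.
#' @return volume in m^3.
#' @export
truncated_ellipsoid_volume <- function(rs, rl, zb) {
  stopifnot(zb > -rl, zb < rl)
  pi * rs^2 * (zb - zb^3 / (3 * rl^2) + 2 * rl / 3)
}

# Dompierre-style split of a prism (bottom v1 v2 v3, top v4 v5 v6, vertical
# edges i -- i+3) into 3 tetrahedra, with every quadrilateral face diagonal
# passing through its globally smallest vertex so neighbouring cells conform.
split_prism <- function(v) {
  perms <- list(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4), c(3, 1, 2, 6, 4, 5),
                c(4, 6, 5, 1, 3, 2), c(6, 5, 4, 3, 2, 1), c(5, 4, 6, 2, 1, 3))
  pos <- which.min(v)
  for (p in perms) if (p[1] == pos) { w <- v[p]; break }
  # remaining quad face (w2, w3, w6, w5): diagonal through its smallest vertex
  if (min(w[2], w[6]) < min(w[3], w[5])) {
    rbind(c(w[1], w[2], w[3], w[6]),
          c(w[1], w[2], w[6], w[5]),
          c(w[1], w[5], w[6], w[4]))
  } else {
    rbind(c(w[1], w[2], w[3], w[5]),
          c(w[1], w[5], w[3], w[6]),
          c(w[1], w[5], w[6], w[4]))
  }
}

# 4 straight sub-triangles of a quadratic facet (v1,v2,v3,m12,m13,m23),
# preserving orientation.
subdivide_facet <- function(f) {
  rbind(c(f[1], f[4], f[5]),
        c(f[4], f[2], f[6]),
        c(f[5], f[6], f[3]),
        c(f[4], f[6], f[5]))
}

#' Assemble an LV mesh object from vertex / connectivity arrays
#'
#' Builds the full mesh structure (quadratic edge-midpoint nodes, tagged
#' quadratic boundary facets, basal endocardial ring and the cavity closure
#' used by [cavity_volume()]) from a linear tetrahedral mesh. This is the
#' single construction path used both by [make_idealized_lv_mesh()] and when
#' loading externally supplied meshes.
#'
#' @param vertices 3 x nv matrix of vertex positions (m).
#' @param tets 4 x ne integer matrix of tetrahedra (1-based vertex ids).
#' @param node_layer optional integer vector: transmural layer index of each
#'   vertex (0 = endocardium); used only to tag boundary facets when `tags`
#'   is absent.
#' @param base_z basal plane coordinate (m).
#' @param tags optional integer vector tagging each boundary facet directly
#'   (1 endocardium, 2 epicardium, 3 base) in the facet order produced by the
#'   internal boundary extraction; normally derived automatically.
#' @param ring optional ordered node ids of the basal endocardial ring
#'   (skips geometric detection; used when rebasing onto a deformed frame).
#' @param params list of generation parameters kept for provenance.
#' @return an object of class `lv_mesh`.
#' @export
lv_mesh_from_arrays <- function(vertices, tets, node_layer = NULL, base_z,
                                tags = NULL, ring = NULL, params = list()) {
  nv <- ncol(vertices)
  ne <- ncol(tets)
  storage.mode(tets) <- "integer"

  # enforce positive orientation
  v1 <- vertices[, tets[1, ]]; v2 <- vertices[, tets[2, ]]
  v3 <- vertices[, tets[3, ]]; v4 <- vertices[, tets[4, ]]
  a <- v2 - v1; b <- v3 - v1; cc <- v4 - v1
  det6 <- a[1, ] * (b[2, ] * cc[3, ] - b[3, ] * cc[2, ]) -
          a[2, ] * (b[1, ] * cc[3, ] - b[3, ] * cc[1, ]) +
          a[3, ] * (b[1, ] * cc[2, ] - b[2, ] * cc[1, ])
  flip <- det6 < 0
  if (any(flip)) tets[3:4, flip] <- tets[4:3, flip]
  if (any(abs(det6) < .Machine$double.eps)) stop("degenerate tetrahedron")

  # unique edges -> quadratic midpoint nodes
  ep <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  e_a <- as.vector(tets[ep[, 1], ]); e_b <- as.vector(tets[ep[, 2], ])
  lo <- pmin(e_a, e_b); hi <- pmax(e_a, e_b)
  key <- (lo - 1) * nv + hi
  ukey <- unique(key)
  eid <- match(key, ukey)
  n_edge <- length(ukey)
  elo <- (ukey - 1) %/% nv + 1; ehi <- (ukey - 1) %% nv + 1
  mid <- (vertices[, elo, drop = FALSE] + vertices[, ehi, drop = FALSE]) / 2
  X <- cbind(vertices, mid)
  nq <- nv + n_edge

  tet10 <- rbind(tets, matrix(nv + eid, nrow = 6, ncol = ne, byrow = FALSE))
  storage.mode(tet10) <- "integer"
  edge_of <- function(va, vb) {  # midpoint node id for vertex pair
    k <- (pmin(va, vb) - 1) * nv + pmax(va, vb)
    nv + match(k, ukey)
  }

  # boundary facets: faces occurring once, oriented outward from the solid
  faceidx <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  fv <- matrix(0L, nrow = 3, ncol = 4 * ne)
  for (ff in 1:4) fv[, seq.int(ff, by = 4, length.out = ne)] <- tets[faceidx[ff, ], ]
  sf <- apply(fv, 2, sort)
  fkey <- paste(sf[1, ], sf[2, ], sf[3, ])
  cnt <- table(fkey)
  bidx <- which(cnt[fkey] == 1L)
  btri <- fv[, bidx, drop = FALSE]

  btri6 <- rbind(btri,
                 edge_of(btri[1, ], btri[2, ]),
                 edge_of(btri[1, ], btri[3, ]),
                 edge_of(btri[2, ], btri[3, ]))
  storage.mode(btri6) <- "integer"

  scale <- max(apply(vertices, 1, function(r) diff(range(r))))
  ztol <- 1e-8 * scale
  if (is.null(tags)) {
    if (is.null(node_layer)) stop("need node_layer or tags to label boundary surfaces")
    zs <- matrix(vertices[3, btri], nrow = 3)
    on_base <- colSums(abs(zs - base_z) < ztol) == 3L
    lay <- matrix(node_layer[btri], nrow = 3)
    nlay <- max(node_layer)
    tags <- integer(ncol(btri))
    tags[on_base] <- 3L
    tags[!on_base & colSums(lay == 0L) == 3L] <- 1L
    tags[!on_base & colSums(lay == nlay) == 3L] <- 2L
    if (any(tags == 0L)) stop("untagged boundary facet: surface tags do not partition the boundary")
  }

  # basal endocardial ring, ordered by azimuth (counter-clockwise from +x)
  endo6 <- btri6[, tags == 1L, drop = FALSE]
  if (is.null(ring)) {
    endo_nodes <- unique(as.vector(endo6))
    ring <- endo_nodes[abs(X[3, endo_nodes] - base_z) < ztol]
    if (length(ring) < 6) stop("open or missing basal endocardial ring")
    ring <- ring[order(atan2(X[2, ring], X[1, ring]))]
  }

  # cavity boundary: reversed endocardial sub-triangles (outward from cavity)
  cav <- do.call(cbind, lapply(seq_len(ncol(endo6)), function(i) {
    t(subdivide_facet(endo6[c(1, 3, 2, 5, 4, 6), i]))
  }))
  storage.mode(cav) <- "integer"

  structure(list(
    X = X, nv = nv, nq = nq, ne = ne,
    tets = tets, tet10 = tet10,
    edges = rbind(elo, ehi),
    boundary_tris = btri6, boundary_tags = tags,
    cavity_tris = cav, ring = ring,
    base_z = base_z, long_axis = c(0, 0, 1),
    node_layer = node_layer,
    params = params), class = "lv_mesh")
}

#' Generate an idealized truncated-ellipsoid LV mesh
#'
#' The wall is bounded by two confocal-like ellipsoidal surfaces (semi-axes
#' interpolated linearly across the wall), truncated by a flat basal plane.
#' With truncation fraction tau the base sits at z = (2 tau - 1) * long
#' semi-axis, i.e. tau is the retained fraction of the full long-axis extent
#' measured from the apex. Elements are straight tetrahedra obtained by
#' splitting the prisms of an extruded surface triangulation; quadratic
#' interpolation nodes sit at edge midpoints (subparametric scheme).
#'
#' @param endo_long_semi_axis endocardial long semi-axis (m).
#' @param endo_short_semi_axis endocardial short semi-axis (m).
#' @param wall_thickness_equator wall thickness added to the short semi-axis (m).
#' @param wall_thickness_apex wall thickness added to the long semi-axis (m).
#' @param truncation_fraction retained fraction of the long-axis extent, in (0, 1).
#' @param target_h target element size (m).
#' @param nc,nl,ns optional explicit circumferential / longitudinal /
#'   transmural resolution overrides.
#' @return an [lv_mesh_from_arrays()] object.
#' @examples
#' m <- make_idealized_lv_mesh(0.045, 0.022, 0.008, 0.008, 0.75, 0.008)
#' cavity_volume(m)
#' @export
make_idealized_lv_mesh <- function(endo_long_semi_axis, endo_short_semi_axis,
                                   wall_thickness_equator, wall_thickness_apex,
                                   truncation_fraction, target_h,
                                   nc = NULL, nl = NULL, ns = NULL) {
  rl <- endo_long_semi_axis; rs <- endo_short_semi_axis
  we <- wall_thickness_equator; wa <- wall_thickness_apex
  tau <- truncation_fraction; h <- target_h
  if (!all(is.finite(c(rl, rs, we, wa, tau, h))))
    stop("invalid geometry: non-finite parameter")
  if (rl <= 0 || rs <= 0 || we <= 0 || wa <= 0 || h <= 0)
    stop("invalid geometry: all lengths must be positive")
  if (tau <= 0 || tau >= 1) stop("invalid geometry: truncation_fraction must be in (0, 1)")
  if (we >= rs) stop("invalid geometry: equatorial wall thickness must be below the short semi-axis")
  if (h > max(we, wa)) stop("target_h exceeds the wall thickness; refusing to build a mesh coarser than the wall")

  zb <- (2 * tau - 1) * rl

  # resolution from the mid-wall surface
  rs_mid <- rs + we / 2; rl_mid <- rl + wa / 2
  if (is.null(ns)) ns <- max(1L, round(we / h))
  if (is.null(nc)) nc <- max(8L, round(2 * pi * rs_mid / h))
  th_max_mid <- acos(-zb / rl_mid)
  th <- seq(0, th_max_mid, length.out = 200)
  arc <- sum(sqrt(diff(rs_mid * sin(th))^2 + diff(-rl_mid * cos(th))^2))
  if (is.null(nl)) nl <- max(3L, round(arc / h))
  nc <- as.integer(nc); nl <- as.integer(nl); ns <- as.integer(ns)

  per_layer <- 1L + nl * nc
  idx <- function(i, j, k) {  # layer i (0..ns), ring j (0 apex .. nl base), sector k (0-based)
    if (j == 0L) i * per_layer + 1L
    else i * per_layer + 1L + (j - 1L) * nc + (k %% nc) + 1L
  }

  nvert <- (ns + 1L) * per_layer
  V <- matrix(0, 3, nvert)
  layer_of <- integer(nvert)
  for (i in 0:ns) {
    s <- i / ns
    rsi <- rs + s * we; rli <- rl + s * wa
    th_max <- acos(-zb / rli)
    V[, idx(i, 0L, 0L)] <- c(0, 0, -rli)
    layer_of[i * per_layer + 1L] <- i
    for (j in 1:nl) {
      thj <- th_max * j / nl
      kk <- 0:(nc - 1L)
      phi <- 2 * pi * kk / nc
      ii <- idx(i, j, kk)
      V[1, ii] <- rsi * sin(thj) * cos(phi)
      V[2, ii] <- rsi * sin(thj) * sin(phi)
      V[3, ii] <- -rli * cos(thj)
      layer_of[ii] <- i
    }
  }
  # base ring exactly coplanar
  for (i in 0:ns) V[3, idx(i, nl, 0:(nc - 1L))] <- zb

  # surface template triangles (apex fan + ring quads split in two)
  kk <- 0:(nc - 1L)
  tri_list <- list()
  for (k in kk) tri_list[[length(tri_list) + 1L]] <- c(-1L, k, 0L)  # apex tri: (-1 flag, k)
  for (j in 1:(nl - 1L)) for (k in kk) {
    tri_list[[length(tri_list) + 1L]] <- c(j, k, 1L)
    tri_list[[length(tri_list) + 1L]] <- c(j, k, 2L)
  }

  tet_cols <- list()
  for (i in 0:(ns - 1L)) {
    for (tr in tri_list) {
      if (tr[1] == -1L) {
        k <- tr[2]
        A <- idx(i, 0L, 0L); B <- idx(i, 1L, k); C <- idx(i, 1L, k + 1L)
        A2 <- idx(i + 1L, 0L, 0L); B2 <- idx(i + 1L, 1L, k); C2 <- idx(i + 1L, 1L, k + 1L)
      } else {
        j <- tr[1]; k <- tr[2]
        if (tr[3] == 1L) {
          A <- idx(i, j, k); B <- idx(i, j, k + 1L); C <- idx(i, j + 1L, k)
          A2 <- idx(i + 1L, j, k); B2 <- idx(i + 1L, j, k + 1L); C2 <- idx(i + 1L, j + 1L, k)
        } else {
          A <- idx(i, j, k + 1L); B <- idx(i, j + 1L, k + 1L); C <- idx(i, j + 1L, k)
          A2 <- idx(i + 1L, j, k + 1L); B2 <- idx(i + 1L, j + 1L, k + 1L); C2 <- idx(i + 1L, j + 1L, k)
        }
      }
      tet_cols[[length(tet_cols) + 1L]] <- t(split_prism(c(A, B, C, A2, B2, C2)))
    }
  }
  tets <- do.call(cbind, tet_cols)

  lv_mesh_from_arrays(V, tets, node_layer = layer_of, base_z = zb,
                      params = list(endo_long_semi_axis = rl,
                                    endo_short_semi_axis = rs,
                                    wall_thickness_equator = we,
                                    wall_thickness_apex = wa,
                                    truncation_fraction = tau,
                                    target_h = h, nc = nc, nl = nl, ns = ns))
}

boundary_subtris <- function(mesh, tag) {
  f <- mesh$boundary_tris[, mesh$boundary_tags == tag, drop = FALSE]
  do.call(cbind, lapply(seq_len(ncol(f)), function(i) t(subdivide_facet(f[, i]))))
}

# 9 x nt matrix of stacked (possibly deformed) triangle vertex coordinates
tri_coords <- function(mesh, tris3, u = NULL) {
  x <- mesh$X
  if (!is.null(u)) x <- x + matrix(u, nrow = 3)
  rbind(x[, tris3[1, ], drop = FALSE],
        x[, tris3[2, ], drop = FALSE],
        x[, tris3[3, ], drop = FALSE])
}

#' Transmural coordinate field
#'
#' Normalized distance coordinate s = d_endo / (d_endo + d_epi), 0 on the
#' endocardium and 1 on the epicardium, evaluated at every interpolation
#' node. The local transmural direction is the volume-averaged finite-element
#' gradient of s (the distance field itself is exactly equivariant under
#' rigid motions, and so is its FE gradient, unlike closest-point directions
#' whose tie-breaking is unstable on symmetric faceted surfaces).
#'
#' @param mesh an `lv_mesh`.
#' @return object of class `lv_transmural` with elements `s` (length nq) and
#'   `tdir` (3 x nq unit vectors).
#' @export
transmural_coordinate <- function(mesh) {
  if (is.null(mesh$boundary_tags) || !all(c(1, 2) %in% mesh$boundary_tags))
    stop("mesh is missing endocardial/epicardial surface tags")
  endo <- tri_coords(mesh, boundary_subtris(mesh, 1L))
  epi <- tri_coords(mesh, boundary_subtris(mesh, 2L))
  de <- dist_to_surface(mesh$X, endo)
  dp <- dist_to_surface(mesh$X, epi)
  s <- de$dist / (de$dist + dp$dist)
  endo_nodes <- unique(as.vector(mesh$boundary_tris[, mesh$boundary_tags == 1L]))
  epi_nodes <- unique(as.vector(mesh$boundary_tris[, mesh$boundary_tags == 2L]))
  s[endo_nodes] <- 0; s[epi_nodes] <- 1

  # per-element P1 gradient of s, volume-averaged to vertices
  tets <- mesh$tets
  v <- lapply(1:4, function(k) mesh$X[, tets[k, ], drop = FALSE])
  sv <- lapply(1:4, function(k) s[tets[k, ]])
  Vol <- abs(tet_volumes(mesh))
  cross3 <- function(a, b) rbind(a[2, ] * b[3, ] - a[3, ] * b[2, ],
                                 a[3, ] * b[1, ] - a[1, ] * b[3, ],
                                 a[1, ] * b[2, ] - a[2, ] * b[1, ])
  grad_lambda <- function(p0, pa, pb, pc) {
    # gradient of the barycentric coordinate that is 1 at p0, 0 on (pa,pb,pc)
    n <- cross3(pb - pa, pc - pa)
    den <- colSums(n * (p0 - pa))
    sweep(n, 2, den, "/")
  }
  ge <- grad_lambda(v[[1]], v[[2]], v[[3]], v[[4]]) * rep(sv[[1]], each = 3) +
        grad_lambda(v[[2]], v[[1]], v[[3]], v[[4]]) * rep(sv[[2]], each = 3) +
        grad_lambda(v[[3]], v[[1]], v[[2]], v[[4]]) * rep(sv[[3]], each = 3) +
        grad_lambda(v[[4]], v[[1]], v[[2]], v[[3]]) * rep(sv[[4]], each = 3)
  acc <- matrix(0, 3, mesh$nq)
  gw <- ge * rep(Vol, each = 3)
  for (k in 1:4) {
    rs <- rowsum(t(gw), tets[k, ])
    ids <- as.integer(rownames(rs))
    acc[, ids] <- acc[, ids] + t(rs)
  }
  # quadratic midpoint nodes inherit the mean of their edge endpoints
  mid_ids <- (mesh$nv + 1L):mesh$nq
  acc[, mid_ids] <- acc[, mesh$edges[1, ]] + acc[, mesh$edges[2, ]]
  tdir <- acc
  nrm <- sqrt(colSums(tdir^2))
  bad <- nrm < 1e-12
  tdir[, !bad] <- sweep(tdir[, !bad, drop = FALSE], 2, nrm[!bad], "/")
  if (any(bad)) {  # degenerate: fall back to outward radial direction
    xy <- mesh$X[, bad, drop = FALSE]
    r <- sqrt(colSums(xy[1:2, , drop = FALSE]^2))
    tdir[, bad] <- rbind(ifelse(r > 0, xy[1, ] / r, 1),
                         ifelse(r > 0, xy[2, ] / r, 0), 0)
  }
  structure(list(s = s, tdir = tdir), class = "lv_transmural")
}

#' Rule-based transmural fibre field
#'
#' Fibre direction f0 = cos(alpha) e_c + sin(alpha) e_l with helix angle
#' alpha(s) = theta (1 - 2 s) varying linearly from +theta on the endocardium
#' to -theta on the epicardium. e_c and e_l are the local circumferential and
#' longitudinal unit directions orthogonal to the transmural direction. Near
#' the apex, where the circumferential direction degenerates, e_c falls back
#' to the azimuth of a fixed off-axis reference node (an arbitrary but
#' rotation-equivariant limit; the field stays unit-norm and finite).
#'
#' @param mesh an `lv_mesh`.
#' @param s an `lv_transmural` field from [transmural_coordinate()].
#' @param theta_deg maximal helix angle in degrees, in (0, 90).
#' @return object of class `lv_fibres`: list with `f0` (3 x nq unit vectors)
#'   and `theta_deg`.
#' @export
fibre_field <- function(mesh, s, theta_deg) {
  stopifnot(inherits(s, "lv_transmural"))
  if (theta_deg <= 0 || theta_deg >= 90) stop("theta_deg must be in (0, 90)")
  alpha <- theta_deg * (1 - 2 * s$s) * pi / 180
  td <- s$tdir
  zx <- rbind(-td[2, ], td[1, ], 0)           # z-hat cross t
  nrm <- sqrt(colSums(zx^2))
  bad <- nrm < 1e-8
  zx[, !bad] <- sweep(zx[, !bad, drop = FALSE], 2, nrm[!bad], "/")
  if (any(bad)) {
    # apex fallback: the circumferential direction degenerates where the
    # transmural direction aligns with the long axis. Use the azimuth of a
    # fixed off-axis reference node, which rotates with the mesh (keeping
    # the whole field equivariant under rigid rotations), normalized in the
    # plane orthogonal to the long axis.
    r_all <- sqrt(colSums(mesh$X[1:2, , drop = FALSE]^2))
    ref <- which(r_all > 0.5 * max(r_all))[1]
    for (bidx in which(bad)) {
      d <- mesh$X[, ref] - mesh$X[, bidx]
      v <- c(-d[2], d[1], 0)
      zx[, bidx] <- v / sqrt(sum(v^2))
    }
  }
  ec <- zx
  el <- rbind(td[2, ] * ec[3, ] - td[3, ] * ec[2, ],
              td[3, ] * ec[1, ] - td[1, ] * ec[3, ],
              td[1, ] * ec[2, ] - td[2, ] * ec[1, ])
  eln <- sqrt(colSums(el^2))
  el <- sweep(el, 2, pmax(eln, 1e-12), "/")
  f0 <- sweep(ec, 2, cos(alpha), "*") + sweep(el, 2, sin(alpha), "*")
  f0 <- sweep(f0, 2, sqrt(colSums(f0^2)), "/")
  structure(list(f0 = f0, theta_deg = theta_deg, alpha = alpha),
            class = "lv_fibres")
}

#' Epicardial RV-attachment weighting field
#'
#' Smooth scalar field H marking the region of the epicardium where the right
#' ventricle attaches: H = 1 inside an azimuthal band around `azimuth_center`,
#' 0 outside, with a cosine ramp of width `transition_width` between. Defined
#' on epicardial nodes (zero elsewhere).
#'
#' @param mesh an `lv_mesh`.
#' @param azimuth_center band centre azimuth in degrees from +x (default 180,
#'   the septal -x direction).
#' @param half_width half-width of the H = 1 band (degrees).
#' @param transition_width width of the smooth ramp (degrees).
#' @return numeric vector of length nq.
#' @export
rv_attachment_field <- function(mesh, azimuth_center = 180, half_width = 60,
                                transition_width = 15) {
  if (half_width + transition_width >= 180)
    stop("half_width + transition_width must be below 180 degrees")
  H <- numeric(mesh$nq)
  epi <- unique(as.vector(mesh$boundary_tris[, mesh$boundary_tags == 2L]))
  az <- atan2(mesh$X[2, epi], mesh$X[1, epi]) * 180 / pi
  d <- abs(((az - azimuth_center + 180) %% 360) - 180)
  val <- numeric(length(epi))
  val[d <= half_width] <- 1
  ramp <- d > half_width & d < half_width + transition_width
  val[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - half_width) / transition_width))
  H[epi] <- val
  H
}

tet_vertex_coords <- function(mesh) {
  list(v1 = mesh$X[, mesh$tets[1, ], drop = FALSE],
       v2 = mesh$X[, mesh$tets[2, ], drop = FALSE],
       v3 = mesh$X[, mesh$tets[3, ], drop = FALSE],
       v4 = mesh$X[, mesh$tets[4, ], drop = FALSE])
}

tet_volumes <- function(mesh) {
  vc <- tet_vertex_coords(mesh)
  a <- vc$v2 - vc$v1; b <- vc$v3 - vc$v1; cc <- vc$v4 - vc$v1
  (a[1, ] * (b[2, ] * cc[3, ] - b[3, ] * cc[2, ]) -
   a[2, ] * (b[1, ] * cc[3, ] - b[3, ] * cc[1, ]) +
   a[3, ] * (b[1, ] * cc[2, ] - b[2, ] * cc[1, ])) / 6
}

#' Per-element mesh quality
#'
#' Quality q = 3 r / R with r the inradius and R the circumradius of each
#' tetrahedron; q = 1 for the regular tetrahedron and q -> 0 for degenerate
#' elements (degenerate elements are assigned q = 0 and flagged).
#'
#' @param mesh an `lv_mesh`.
#' @return list with `q` per element, `mean`, `sd` and `degenerate` flags.
#' @export
mesh_quality <- function(mesh) {
  vc <- tet_vertex_coords(mesh)
  V <- abs(tet_volumes(mesh))   # quality is orientation-independent
  tri_area <- function(p, q2, r) {
    u <- q2 - p; w <- r - p
    cx <- rbind(u[2, ] * w[3, ] - u[3, ] * w[2, ],
                u[3, ] * w[1, ] - u[1, ] * w[3, ],
                u[1, ] * w[2, ] - u[2, ] * w[1, ])
    sqrt(colSums(cx^2)) / 2
  }
  Atot <- tri_area(vc$v2, vc$v3, vc$v4) + tri_area(vc$v1, vc$v3, vc$v4) +
          tri_area(vc$v1, vc$v2, vc$v4) + tri_area(vc$v1, vc$v2, vc$v3)
  rin <- 3 * V / Atot
  # circumradius via |p - c|^2 equal for all vertices
  ne <- ncol(mesh$tets)
  Rc <- numeric(ne)
  for (e in seq_len(ne)) {
    p1 <- vc$v1[, e]; A <- rbind(2 * (vc$v2[, e] - p1),
                                 2 * (vc$v3[, e] - p1),
                                 2 * (vc$v4[, e] - p1))
    rhs <- c(sum(vc$v2[, e]^2) - sum(p1^2),
             sum(vc$v3[, e]^2) - sum(p1^2),
             sum(vc$v4[, e]^2) - sum(p1^2))
    cen <- tryCatch(solve(A, rhs), error = function(e2) rep(NA_real_, 3))
    Rc[e] <- sqrt(sum((p1 - cen)^2))
  }
  q <- 3 * rin / Rc
  degen <- !is.finite(q) | V <= .Machine$double.eps
  q[degen] <- 0
  list(q = q, mean = mean(q), sd = sd(q), degenerate = degen)
}

#' Per-element mesh size
#'
#' h = det(S)^(1/3) with S the affine map from the unit right tetrahedron to
#' the element (det S = 6 V).
#'
#' @param mesh an `lv_mesh`.
#' @return list with `h` per element (m), `mean` and `sd`.
#' @export
mesh_size <- function(mesh) {
  V <- tet_volumes(mesh)
  if (any(V <= 0)) stop("inverted element(s): ", paste(which(V <= 0), collapse = ", "))
  h <- (6 * V)^(1 / 3)
  list(h = h, mean = mean(h), sd = sd(h))
}
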