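# Idealized LV geometry: mesh generation, surface tagging, transmural and
# fibre fields, RV attachment weighting, element quality and size metrics.

test_that("generated mesh reproduces the closed-form cavity volume and scales correctly", {
  mesh <- make_idealized_lv_mesh(0.045, 0.022, 0.008, 0.008, 0.75, 0.004)
  zb <- (2 * 0.75 - 1) * 0.045
  Va <- truncated_ellipsoid_volume(0.022, 0.045, zb)
  expect_lt(abs(cavity_volume(mesh) - Va) / Va, 0.05)

  # wall volume validates the prism-to-tet decomposition (no gaps/overlaps)
  Wa <- truncated_ellipsoid_volume(0.030, 0.053, zb) - Va
  expect_lt(abs(sum(lvstiff:::tet_volumes(mesh)) - Wa) / Wa, 0.02)

  # doubling all linear dimensions multiplies the cavity volume by 8
  mesh2 <- make_idealized_lv_mesh(0.090, 0.044, 0.016, 0.016, 0.75, 0.008,
                                  nc = mesh$params$nc, nl = mesh$params$nl,
                                  ns = mesh$params$ns)
  expect_equal(cavity_volume(mesh2) / cavity_volume(mesh), 8, tolerance = 1e-9)

  # uniform dilation of the displacement field scales volume by 1.1^3
  u <- as.vector(0.1 * mesh$X)
  expect_equal(cavity_volume(mesh, u) / cavity_volume(mesh), 1.1^3,
               tolerance = 1e-10)
})

test_that("degenerate geometry inputs are refused", {
  expect_error(make_idealized_lv_mesh(0.045, 0.022, 0, 0.008, 0.75, 0.004),
               "positive")
  expect_error(make_idealized_lv_mesh(0.045, 0.022, 0.025, 0.008, 0.75, 0.004),
               "short semi-axis")
  expect_error(make_idealized_lv_mesh(0.045, 0.022, 0.008, 0.008, 1.2, 0.004),
               "truncation")
  expect_error(make_idealized_lv_mesh(0.045, 0.022, 0.008, 0.008, 0.75, 0.02),
               "wall thickness")
})

test_that("boundary surfaces are tagged, closed and the base is coplanar", {
  mesh <- coarse_mesh()
  expect_setequal(unique(mesh$boundary_tags), c(1L, 2L, 3L))
  # watertight: every tet face is shared by exactly two tets or is boundary
  tets <- mesh$tets
  faceidx <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  keys <- unlist(lapply(1:4, function(f)
    apply(tets[faceidx[f, ], , drop = FALSE], 2,
          function(v) paste(sort(v), collapse = "-"))))
  cnt <- table(table(keys))
  expect_true(all(names(cnt) %in% c("1", "2")))
  expect_equal(sum(table(keys) == 1L), ncol(mesh$boundary_tris))
  base_nodes <- unique(as.vector(
    mesh$boundary_tris[, mesh$boundary_tags == 3L]))
  expect_lt(max(abs(mesh$X[3, base_nodes] - mesh$base_z)), 1e-9)
})

test_that("transmural coordinate is 0/1 on the surfaces and ~0.5 at midwall", {
  mesh <- shell_mesh(0.020, 0.030)
  s <- transmural_coordinate(mesh)
  expect_true(all(s$s >= 0 & s$s <= 1))
  endo <- unique(as.vector(mesh$boundary_tris[, mesh$boundary_tags == 1L]))
  epi <- unique(as.vector(mesh$boundary_tris[, mesh$boundary_tags == 2L]))
  expect_true(all(s$s[endo] == 0))
  expect_true(all(s$s[epi] == 1))
  # nodes near r = 25 mm in the concentric 20/30 mm shell
  r <- sqrt(colSums(mesh$X^2))
  mid <- which(abs(r - 0.025) < 5e-4 & mesh$X[3, ] < 0)
  expect_gt(length(mid), 0)
  expect_true(all(abs(s$s[mid] - 0.5) < 0.05))
})

test_that("fibre helix angle follows the linear transmural rule", {
  mesh <- coarse_mesh()
  s <- transmural_coordinate(mesh)
  fib <- fibre_field(mesh, s, 60)
  expect_equal(max(abs(sqrt(colSums(fib$f0^2)) - 1)), 0, tolerance = 1e-12)
  # endpoints and midpoint of the rule
  expect_equal(unname(fib$alpha[s$s == 0][1]), 60 * pi / 180, tolerance = 1e-12)
  expect_equal(unname(fib$alpha[s$s == 1][1]), -60 * pi / 180, tolerance = 1e-12)
  # at the equator away from the apex, check angle against the local
  # circumferential direction explicitly
  eq <- which(abs(mesh$X[3, ]) < 0.005 & s$s < 1e-9)
  n0 <- eq[1]
  xy <- mesh$X[, n0]
  ec <- c(-xy[2], xy[1], 0) / sqrt(sum(xy[1:2]^2))
  ang <- acos(pmin(1, abs(sum(fib$f0[, n0] * ec))))
  expect_lt(abs(ang - 60 * pi / 180), 0.15)
  expect_error(fibre_field(mesh, s, 95), "theta")
})

test_that("fibre field is equivariant under rotation about the long axis", {
  mesh <- coarse_mesh()
  s <- transmural_coordinate(mesh)
  fib <- fibre_field(mesh, s, 50)
  m2 <- rotate_mesh_z(mesh, 30)
  s2 <- transmural_coordinate(m2)
  fib2 <- fibre_field(m2, s2, 50)
  Q <- rotation_z(30)
  expect_lt(max(abs(fib2$f0 - Q %*% fib$f0)), 1e-6)
})

test_that("RV attachment field is 1 in the band, 0 opposite, smooth between", {
  mesh <- coarse_mesh()
  H <- rv_attachment_field(mesh, azimuth_center = 180, half_width = 60,
                           transition_width = 15)
  expect_true(all(H >= 0 & H <= 1))
  epi <- unique(as.vector(mesh$boundary_tris[, mesh$boundary_tags == 2L]))
  az <- atan2(mesh$X[2, epi], mesh$X[1, epi]) * 180 / pi
  d <- abs(((az - 180 + 180) %% 360) - 180)
  expect_true(all(H[epi][d < 59] == 1))
  expect_true(all(H[epi][d > 76] == 0))
  ramp <- H[epi][d > 61 & d < 74]
  if (length(ramp)) expect_true(all(ramp > 0 & ramp < 1))
  # monotone along azimuthal distance
  ord <- order(d)
  expect_true(all(diff(H[epi][ord]) < 1e-9 + 1e-12))
  expect_error(rv_attachment_field(mesh, half_width = 170, transition_width = 20),
               "180")
})

test_that("mesh quality is 1 for the regular tetrahedron and ~0 for slivers", {
  # regular tetrahedron
  V <- matrix(c(1, 1, 1, -1, -1, 1, -1, 1, -1, 1, -1, -1), nrow = 3)
  m <- list(tets = matrix(1:4, ncol = 1), X = V)
  q <- mesh_quality(m)
  expect_equal(q$q, 1, tolerance = 1e-12)
  # near-flat sliver
  Vs <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.5, 0.5, 1e-4), nrow = 3)
  qs <- mesh_quality(list(tets = matrix(1:4, ncol = 1), X = Vs))
  expect_lt(qs$q, 0.05)
  # healthy preset passes the generator quality gate
  mesh <- make_idealized_lv_mesh(0.045, 0.022, 0.008, 0.008, 0.75, 0.004)
  expect_gt(mesh_quality(mesh)$mean, 0.6)
})

test_that("mesh size h = det(S)^(1/3) with the expected scaling", {
  Vu <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), nrow = 3)
  m <- list(tets = matrix(1:4, ncol = 1), X = Vu)
  expect_equal(mesh_size(m)$h, 1, tolerance = 1e-12)
  expect_equal(mesh_size(list(tets = matrix(1:4, ncol = 1), X = 2 * Vu))$h, 2,
               tolerance = 1e-12)
  mesh <- make_idealized_lv_mesh(0.045, 0.022, 0.008, 0.008, 0.75, 0.004)
  h <- mesh_size(mesh)
  expect_true(h$mean > 0.003 && h$mean < 0.005)
  expect_gt(mean(h$h >= 0.5 * 0.004 & h$h <= 1.5 * 0.004), 0.9)
  # inverted element is reported
  bad <- list(tets = matrix(c(1, 3, 2, 4), ncol = 1), X = Vu)
  expect_error(mesh_size(bad), "inverted")
})

test_that("quality and size agree with brute-force recomputation on random elements", {
  mesh <- coarse_mesh()
  set.seed(42)
  idx <- sample(ncol(mesh$tets), 10)
  q <- mesh_quality(mesh); h <- mesh_size(mesh)
  for (e in idx) {
    P <- mesh$X[, mesh$tets[, e]]
    # independent: volume via determinant, areas via Heron, circumcentre via
    # explicit normal equations
    M <- cbind(P[, 2] - P[, 1], P[, 3] - P[, 1], P[, 4] - P[, 1])
    Vol <- det(M) / 6
    area <- function(a, b, cc) {
      la <- sqrt(sum((b - cc)^2)); lb <- sqrt(sum((a - cc)^2)); lc <- sqrt(sum((a - b)^2))
      sp <- (la + lb + lc) / 2
      sqrt(sp * (sp - la) * (sp - lb) * (sp - lc))
    }
    A <- area(P[, 2], P[, 3], P[, 4]) + area(P[, 1], P[, 3], P[, 4]) +
         area(P[, 1], P[, 2], P[, 4]) + area(P[, 1], P[, 2], P[, 3])
    rin <- 3 * Vol / A
    G <- rbind(2 * t(P[, 2] - P[, 1]), 2 * t(P[, 3] - P[, 1]), 2 * t(P[, 4] - P[, 1]))
    rhs <- c(sum(P[, 2]^2) - sum(P[, 1]^2), sum(P[, 3]^2) - sum(P[, 1]^2),
             sum(P[, 4]^2) - sum(P[, 1]^2))
    cen <- solve(G, rhs)
    Rc <- sqrt(sum((P[, 1] - cen)^2))
    expect_equal(q$q[e], 3 * rin / Rc, tolerance = 1e-12)
    expect_equal(h$h[e], (6 * Vol)^(1 / 3), tolerance = 1e-12)
  }
})
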