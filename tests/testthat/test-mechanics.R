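# Volume-driven incompressible solver: equilibrium, consistency of the
# assembled system, frame solves and basic physics of the inflation response.

test_that("unloaded state with matching data is an exact equilibrium", {
  su <- coarse_setup()
  params <- material_parameters(a = 500, a_f = 1000)
  st <- lvstiff:::new_state(su$model, params)
  sys <- assemble_system(su$model, params, st, cavity_volume(su$mesh))
  expect_lt(sqrt(sum(sys$R^2)), 1e-10)
})

test_that("assembled Jacobian matches directional finite differences", {
  su <- coarse_setup()
  params <- material_parameters(a = 500, a_f = 1000)
  set.seed(5)
  st <- lvstiff:::new_state(su$model, params)
  st$u <- st$u + rnorm(length(st$u), 0, 2e-4)
  st$p <- st$p + rnorm(length(st$p), 0, 50)
  st$ll <- 40
  V0 <- cavity_volume(su$mesh)
  sys <- assemble_system(su$model, params, st, V0 * 1.02)
  x <- lvstiff:::state_to_vec(st)
  nu <- 3 * su$mesh$nq
  for (rep in 1:3) {
    dx <- rnorm(length(x)); dx <- dx / sqrt(sum(dx^2))
    h <- 1e-6
    stp <- lvstiff:::vec_to_state(x + h * dx, su$model)
    Rp <- assemble_system(su$model, params, stp, V0 * 1.02,
                          want_matrix = FALSE)$R
    fd <- (Rp - sys$R) / h
    an <- lvstiff:::saddle_apply(sys, dx, nu)
    expect_lt(sqrt(sum((fd - an)^2)) / sqrt(sum(an^2)), 1e-3)
  }
})

test_that("solve_frame converges immediately at equilibrium and inflates with positive pressure", {
  su <- coarse_setup()
  params <- material_parameters(a = 500, a_f = 1000)
  st <- lvstiff:::new_state(su$model, params)
  V0 <- cavity_volume(su$mesh)
  res0 <- solve_frame(su$model, params, st, V0)
  expect_equal(res0$iters, 0)
  res <- solve_frame(su$model, params, st, V0 * 1.05)
  expect_gt(res$state$ll, 0)
  expect_lt(abs(res$V - V0 * 1.05) / (V0 * 1.05), 1e-3)
  expect_true(res$jmin > 0)
  # degenerate material is refused
  expect_error(solve_frame(su$model, list(a = 0, a_f = 0, b = 5, b_f = 5),
                           st, V0 * 1.05), "singular material")
})

test_that("solution is objective under rigid rotation about the long axis", {
  # non-axisymmetric data (septal band squeeze + basal lift) anchor the
  # azimuthal orientation; mesh, data and the attachment band all rotate
  params <- material_parameters(a = 500, a_f = 1000)
  Q <- rotation_z(30)
  solve_case <- function(mesh, h_center, rot) {
    s <- transmural_coordinate(mesh)
    fib <- fibre_field(mesh, s, 60)
    model <- lv_model(mesh, fib, boundary_spec("RV", H_azimuth_center = h_center))
    V0 <- cavity_volume(mesh)
    bn <- model$base_nodes; en <- model$epi_nodes
    ud_b <- rep(c(0, 0, 0.002), length(bn))
    xy <- mesh$X[1:2, en, drop = FALSE]
    r <- pmax(sqrt(colSums(xy^2)), 1e-9)
    ud_e <- as.vector(-rbind(xy[1, ] / r, xy[2, ] / r, 0)) * 0.001
    st <- lvstiff:::new_state(model, params)
    res <- solve_frame(model, params, st, V0 * 1.08, ud_b, ud_e)
    res$state
  }
  st1 <- solve_case(coarse_mesh(), 180, diag(3))
  st2 <- solve_case(rotate_mesh_z(coarse_mesh(), 30), 210, Q)
  u1 <- matrix(st1$u, nrow = 3)
  u2 <- matrix(st2$u, nrow = 3)
  expect_lt(max(abs(u2 - Q %*% u1)) / max(abs(u1)), 1e-6)
  expect_lt(abs(st2$ll - st1$ll) / abs(st1$ll), 1e-6)
})

test_that("NT mode removes the epicardial multiplier block", {
  su_nt <- coarse_setup(mode = "NT")
  expect_null(su_nt$model$Pen_e)
  expect_null(su_nt$model$H)
  params <- material_parameters(a = 500, a_f = 1000)
  st <- lvstiff:::new_state(su_nt$model, params)
  res <- solve_frame(su_nt$model, params, st, cavity_volume(su_nt$mesh) * 1.05)
  expect_length(res$state$le, 0)
  expect_gt(res$state$ll, 0)
})

test_that("filling pressure rises monotonically along a monotone volume trace", {
  subj <- tiny_subject()
  lam <- subj$trajectory$lambda_l
  expect_true(all(diff(lam) > 0))
  expect_equal(subj$trajectory$lambda_ED, lam[length(lam)])
  # per-frame volume constraint satisfied
  for (n in 2:subj$motion$n_frames) {
    Vn <- cavity_volume(subj$mesh, subj$trajectory$u[, n])
    expect_lt(abs(Vn - subj$motion$vol[n]) / subj$motion$vol[n], 1e-3)
  }
})

test_that("condensed boundary multipliers act as tractions proportional to mismatch", {
  su <- coarse_setup()
  params <- material_parameters(a = 500, a_f = 1000)
  st <- lvstiff:::new_state(su$model, params)
  V0 <- cavity_volume(su$mesh)
  res <- solve_frame(su$model, params, st, V0 * 1.05)
  eps <- lvstiff:::eps_effective(su$model$bcs, params)
  ub <- res$state$u[lvstiff:::u_dofs(su$model$base_nodes)]
  expect_equal(res$state$lb, ub / eps$b, tolerance = 1e-12)
})
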