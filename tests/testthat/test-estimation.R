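# Objective function, sweep bookkeeping, rescaling and identifiability
# diagnostics. Full recovery experiments live in the acceptance suite.

single_tet_model <- function() {
  V <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), nrow = 3)
  mesh <- list(X = NULL, nq = NULL)
  tets <- matrix(1:4, ncol = 1)
  # quadratic nodes via the shared construction path
  ep <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  mid <- (V[, ep[, 1]] + V[, ep[, 2]]) / 2
  X <- cbind(V, mid)
  tet10 <- matrix(c(1:4, 5:10), ncol = 1)
  mt <- lvstiff:::mass_p2(X, tet10 - 1L)
  Mu <- Matrix::sparseMatrix(i = mt$i + 1L, j = mt$j + 1L, x = mt$x,
                             dims = c(10, 10))
  list(mesh = list(nq = 10L, X = X), Mu = Mu)
}

test_that("objective L2 integrals match hand-worked values on a single tetrahedron", {
  m <- single_tet_model()
  # int over the unit right tet: volume 1/6; int x^2 dV = 1/60
  const <- rep(c(2, 0, 0), 10)
  expect_equal(lvstiff:::l2_norm2(m, const), 4 / 6, tolerance = 1e-12)
  lin <- as.vector(rbind(m$mesh$X[1, ], 0, 0))  # u = (x, 0, 0)
  expect_equal(lvstiff:::l2_norm2(m, lin), 1 / 60, tolerance = 1e-12)

  # two-frame toy objective: model = data/2 everywhere -> J = 1/2
  motion <- list(n_frames = 2, ud = cbind(0 * lin, lin))
  traj_half <- list(u = cbind(0 * lin, lin / 2))
  expect_equal(objective_function(traj_half, motion, m), 0.5, tolerance = 1e-12)
  # mixed frames with hand arithmetic:
  # frames (const, lin) data vs (0, 0) model -> sqrt((4/6 + 1/60)/(4/6 + 1/60)) = 1
  motion2 <- list(n_frames = 2, ud = cbind(const, lin))
  expect_equal(objective_function(list(u = cbind(0 * const, 0 * lin)),
                                  motion2, m), 1, tolerance = 1e-12)
  # identical fields -> 0
  expect_equal(objective_function(list(u = motion2$ud), motion2, m), 0)
  # zero-motion data is undefined
  expect_error(objective_function(list(u = motion2$ud * 0),
                                  list(n_frames = 2, ud = motion2$ud * 0), m),
               "identically zero")
})

test_that("objective is invariant under joint rigid rotation of model and data", {
  subj <- tiny_subject()
  model <- lvstiff:::build_case_model(subj)
  motion <- subj$motion
  traj <- subj$trajectory
  J0 <- objective_function(list(u = traj$u * 0.9), motion, model)
  Q <- rotation_z(47)
  rot <- function(M) as.vector(Q %*% matrix(M, nrow = 3))
  motion2 <- motion
  motion2$ud <- apply(motion$ud, 2, rot)
  traj2 <- list(u = apply(traj$u * 0.9, 2, rot))
  J1 <- objective_function(traj2, motion2, model)
  expect_equal(J1, J0, tolerance = 1e-12)
})

test_that("rescaling to absolute stiffness follows the EDP ratio and preserves gamma", {
  sc <- scale_parameters(0.5, 1000, lambda_ED = 1500, edp_est = 1500)
  expect_equal(unname(sc["a"]), 500)
  expect_equal(unname(sc["a_f"]), 1000)
  sc2 <- scale_parameters(0.5, 1000, lambda_ED = 2 * 1500, edp_est = 1500)
  expect_equal(unname(sc2["a_f"]), 500)
  # exact arithmetic identity: gamma unchanged by rescaling
  for (g in c(0.31, 0.77, 1.4)) {
    sc3 <- scale_parameters(g, 1000, 1234.5, 987.6)
    expect_equal(unname(sc3["a"] / sc3["a_f"]), g, tolerance = 1e-15)
  }
  expect_error(scale_parameters(0.5, 1000, -1, 1500), "positive")
  expect_error(scale_parameters(0.5, 1000, 1500, 0), "positive")
})

fake_sweep <- function(gamma, J) {
  structure(list(runs = data.frame(gamma = gamma, J = J,
                                   lambda_ED_Pa = 1000, converged = TRUE)),
            class = "lv_sweep")
}

test_that("identifiability diagnostics flag unique minima and flat curves", {
  g <- seq(0.3, 2, length.out = 9)
  conv <- fake_sweep(g, (g - 1)^2 + 0.1)
  rep1 <- identifiability_report(conv)
  expect_true(rep1$unique_minimum)
  expect_gt(rep1$curvature, 0)
  expect_equal(rep1$gamma_hat, g[which.min((g - 1)^2)])

  flat <- identifiability_report(fake_sweep(g, rep(0.4, 9)))
  expect_equal(flat$variation, 0)
  expect_false(flat$unique_minimum)

  bimodal <- identifiability_report(
    fake_sweep(g, 0.2 + 0.1 * sin(6 * g)))
  expect_false(bimodal$unique_minimum)
  expect_error(identifiability_report(fake_sweep(c(0.5, 1), c(1, 2))),
               "3 grid points")
})

test_that("degenerate single-value grid returns that value with zero variation", {
  subj <- tiny_subject()
  sw <- shared_truth_sweep()   # single-point grid at gamma* = 0.5
  expect_equal(sw$gamma_hat, 0.5)
  expect_equal(sw$variation, 0)
  expect_true(all(sw$runs$converged))
  # noiseless self-consistency: simulating at the truth reproduces the data
  expect_lt(sw$J_min, 1e-3)
  # rescaled parameters recover the ground truth at exact EDP
  expect_lt(abs(sw$a_f_Pa - subj$truth$a_f) / subj$truth$a_f, 0.05)
  expect_lt(abs(sw$a_Pa - subj$truth$a) / subj$truth$a, 0.05)
  expect_error(parameter_sweep(subj, gamma_grid = numeric(0)), "non-empty")
  expect_error(parameter_sweep(subj, gamma_grid = c(-1, 0.5)), "positive")
})

test_that("refine_sweep with no extra points is the identity and never worsens the minimum", {
  subj <- tiny_subject()
  sw <- parameter_sweep(subj, gamma_grid = c(0.4, 0.5, 0.65))
  expect_identical(refine_sweep(sw, 0), sw)
  sw2 <- refine_sweep(sw, 2)
  expect_lte(sw2$J_min, sw$J_min)
  expect_gte(nrow(sw2$runs), nrow(sw$runs))
})

test_that("rebasing onto a later frame shifts the reference geometry and data", {
  subj <- tiny_subject()
  expect_identical(rebase_subject(subj, 0), subj)
  rb <- rebase_subject(subj, 1)
  expect_equal(rb$motion$n_frames, subj$motion$n_frames - 1L)
  # new reference vertices are the frame-2 deformed positions
  ud2 <- matrix(subj$motion$ud[, 2], nrow = 3)
  expect_lt(max(abs(rb$mesh$X[, 1:rb$mesh$nv] -
                    (subj$mesh$X[, 1:subj$mesh$nv] + ud2[, 1:subj$mesh$nv]))),
            1e-12)
  # data relative to the new reference vanish at its first frame
  expect_true(all(rb$motion$ud[, 1] == 0))
  # reference volume tracks the data volume of the chosen frame
  expect_lt(abs(rb$motion$vol[1] - subj$motion$vol[2]) / subj$motion$vol[2],
            2e-2)
  expect_error(rebase_subject(subj, 10), "missing frames")
})
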