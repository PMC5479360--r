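# Synthetic subject generation: volume traces, ground-truth bookkeeping,
# displacement noise and the wall-volume conservation projection.

test_that("volume trace has exact endpoints and is strictly increasing", {
  tr <- make_volume_trace(55, 120, 10)
  expect_equal(tr[1], 55)
  expect_equal(tr[10], 120)
  expect_true(all(diff(tr) > 0))
  expect_equal(make_volume_trace(55, 120, 2), c(55, 120))
  expect_error(make_volume_trace(120, 55, 5), "EDV > ESV")
  expect_error(make_volume_trace(55, 120, 1), "frames")
})

test_that("presets produce the intended group contrast and EF composes correctly", {
  vp <- subject_preset("volunteer")
  dp <- subject_preset("dcm")
  expect_gt(dp$esv_ml, vp$esv_ml)
  expect_gt(dp$edv_ml, vp$edv_ml)
  expect_gt(dp$edp_mmhg, vp$edp_mmhg)
  expect_lt(dp$la_sa, vp$la_sa)
  ve_v <- volumes_and_ef(make_volume_trace(vp$esv_ml, vp$edv_ml, 10))
  ve_d <- volumes_and_ef(make_volume_trace(dp$esv_ml, dp$edv_ml, 10))
  expect_equal(ve_v$ef, 1 - vp$esv_ml / vp$edv_ml, tolerance = 1e-12)
  expect_gt(ve_v$ef, ve_d$ef)
  expect_lt(abs(ve_v$ef - 0.5), 0.05)
  expect_error(subject_preset("volunteer", nonsense = 1), "unknown")
})

test_that("preset geometry reproduces the target reference volume and shape", {
  for (g in c("volunteer", "dcm")) {
    p <- subject_preset(g)
    geo <- lvstiff:::preset_geometry(p)
    zb <- (2 * p$truncation - 1) * geo$rl
    V <- truncated_ellipsoid_volume(geo$rs, geo$rl, zb)
    expect_equal(V * 1e6, p$esv_ml, tolerance = 1e-6)
    la_sa <- (geo$rl + zb) / (2 * geo$rs)
    expect_equal(la_sa, p$la_sa, tolerance = 1e-9)
  }
})

test_that("generated subjects are reproducible and carry consistent ground truth", {
  s1 <- tiny_subject()
  s2 <- generate_subject(subject_preset("volunteer", gamma = 0.5,
                                        bc_mode = "RV", n_frames = 6),
                         seed = 7, nc = 10, nl = 5, ns = 1)
  expect_identical(s1$motion$ud, s2$motion$ud)
  expect_identical(s1$truth, s2$truth)
  # truth bookkeeping: a = gamma * a_f, EDP surrogate returns the model EDP
  expect_equal(s1$truth$a, s1$truth$gamma * s1$truth$a_f, tolerance = 1e-12)
  expect_equal(estimate_edp(s1$E, s1$Ea), s1$truth$edp_mmhg, tolerance = 1e-9)
  expect_equal(s1$truth$lambda_ED_Pa, mmhg_to_pa(s1$truth$edp_mmhg),
               tolerance = 1e-6)
  # data displacements reproduce the data volume trace
  N <- s1$motion$n_frames
  Vn <- cavity_volume(s1$mesh, s1$motion$ud[, N])
  expect_lt(abs(Vn - s1$motion$vol[N]) / s1$motion$vol[N], 1e-3)
})

test_that("displacement noise has the right scale and leaves the reference exact", {
  subj <- tiny_subject()
  noised <- add_displacement_noise(subj, 0.5, seed = 123)
  expect_identical(add_displacement_noise(subj, 0, seed = 1)$motion$ud,
                   subj$motion$ud)
  expect_identical(noised$motion$ud,
                   add_displacement_noise(subj, 0.5, seed = 123)$motion$ud)
  expect_true(all(noised$motion$ud[, 1] == subj$motion$ud[, 1]))
  d <- noised$motion$ud[, -1] - subj$motion$ud[, -1]
  # per-node 3-component perturbation norm ~ sigma * sqrt(3)
  rms <- sqrt(mean(colSums(matrix(d, nrow = 3)^2)))
  expect_lt(abs(rms - 0.5e-3 * sqrt(3)) / (0.5e-3 * sqrt(3)), 0.05)
  expect_equal(noised$truth$sigma_mm, 0.5)
})

test_that("wall-volume projection restores the reference wall volume", {
  subj <- tiny_subject()
  mesh <- subj$mesh
  tet0 <- mesh$tet10 - 1L
  W0 <- lvstiff:::wall_volume_p2(mesh$X, tet0, numeric(3 * mesh$nq))
  # the forward-simulated motion already conserves wall volume: fixed point
  fixed <- conserve_wall_volume(mesh, subj$motion, subj$s)
  expect_lt(max(abs(fixed$ud - subj$motion$ud)), 1e-10)
  # construct a violation: inflate epicardial side along the transmural dir
  bad <- subj$motion
  infl <- as.vector(sweep(subj$s$tdir, 2, subj$s$s, "*")) * 0.8e-3
  for (n in 2:bad$n_frames) bad$ud[, n] <- bad$ud[, n] + infl
  Wbad <- lvstiff:::wall_volume_p2(mesh$X, tet0, bad$ud[, bad$n_frames])
  expect_gt(abs(Wbad - W0) / W0, 2e-3)
  fix2 <- conserve_wall_volume(mesh, bad, subj$s)
  for (n in 2:bad$n_frames) {
    Wn <- lvstiff:::wall_volume_p2(mesh$X, tet0, fix2$ud[, n])
    expect_lt(abs(Wn - W0) / W0, 1e-3)
    # endocardial surface fixed: cavity volumes unchanged
    expect_lt(abs(cavity_volume(mesh, fix2$ud[, n]) -
                  cavity_volume(mesh, bad$ud[, n])) /
              cavity_volume(mesh, bad$ud[, n]), 1e-3)
  }
  # excessive corruption is refused
  worse <- subj$motion
  for (n in 2:worse$n_frames) worse$ud[, n] <- worse$ud[, n] + infl * 8
  expect_error(conserve_wall_volume(mesh, worse, subj$s), "corrupted")
})
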