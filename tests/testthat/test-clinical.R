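# Clinical LV metrics and group statistics, anchored on the reference cohort
# table worked examples.

test_that("SV and EF recomputed from printed EDV/ESV match every cohort row", {
  tab <- lv_reference_cohort()
  for (i in seq_len(nrow(tab))) {
    ve <- volumes_and_ef(c(tab$edv_ml[i], tab$esv_ml[i]))
    # the printed per-subject values are independently rounded, so the
    # recomputation can differ by one unit in the last printed digit
    expect_lte(abs(round(ve$sv, 1) - tab$sv_ml[i]), 0.1 + 1e-9)
    expect_equal(round(ve$ef, 2), tab$ef[i])
  }
  expect_equal(volumes_and_ef(c(100, 50))$ef, 0.5)
  ve <- volumes_and_ef(rep(80, 5))
  expect_equal(ve$sv, 0); expect_equal(ve$ef, 0)
  expect_error(volumes_and_ef(numeric(0)), "non-empty")
  expect_error(volumes_and_ef(c(0, 0)), "end-diastolic")
})

test_that("group means and SDs reproduce the cohort summary rows", {
  tab <- lv_reference_cohort()
  vol <- tab[tab$group == "volunteer", ]
  dcm <- tab[tab$group == "dcm", ]
  # volunteer EDP example and all Mean/SD cells at printed rounding
  expect_equal(round(mean(vol$edp_est_mmhg), 1), 11.4)
  expect_equal(round(sd(vol$edp_est_mmhg), 1), 2.8)
  vmeans <- c(edv_ml = 119.3, esv_ml = 55.8, sv_ml = 63.5, ef = 0.53,
              wt_ed_mm = 7.76, la_sa = 1.45, edp_est_mmhg = 11.4)
  vsds <- c(edv_ml = 23.6, esv_ml = 9.7, sv_ml = 14.6, ef = 0.03,
            wt_ed_mm = 0.90, wt_es_mm = 1.45, la_sa = 0.13,
            edp_est_mmhg = 2.8)
  pmeans <- c(edv_ml = 152.2, esv_ml = 85.7, sv_ml = 66.5, ef = 0.43,
              wt_ed_mm = 7.46, wt_es_mm = 9.56, la_sa = 1.22,
              edp_est_mmhg = 15.2)
  psds <- c(edv_ml = 23.6, esv_ml = 8.3, sv_ml = 15.3, ef = 0.03,
            wt_ed_mm = 0.80, wt_es_mm = 1.15, edp_est_mmhg = 3.2)
  ulp <- function(x) 10^(-nchar(sub(".*\\.", "", as.character(x))))
  # per-subject cells are independently rounded: allow one unit in the
  # summary's last printed digit
  for (m in names(vmeans))
    expect_lte(abs(mean(vol[[m]]) - vmeans[[m]]), ulp(vmeans[[m]]) * 1.0 + 1e-9)
  for (m in names(vsds))
    expect_lte(abs(sd(vol[[m]]) - vsds[[m]]), ulp(vsds[[m]]) * 1.0 + 1e-9)
  for (m in names(pmeans))
    expect_lte(abs(mean(dcm[[m]]) - pmeans[[m]]), ulp(pmeans[[m]]) * 1.0 + 1e-9)
  for (m in names(psds))
    expect_lte(abs(sd(dcm[[m]]) - psds[[m]]), ulp(psds[[m]]) * 1.0 + 1e-9)
  # two summary cells are internally inconsistent with the per-subject
  # values they summarize; assert our recomputation instead. The volunteer
  # WT_ES spread is consistent with the printed per-subject values (SD 1.45)
  # while the mean cell (10.34) is not (recomputation gives 10.38); the DCM
  # LA/SA per-subject values give an SD of 0.02, not the printed 0.18.
  expect_equal(round(mean(vol$wt_es_mm), 2), 10.38)
  expect_equal(round(sd(vol$wt_es_mm), 2), 1.45)
  expect_equal(round(sd(dcm$la_sa), 2), 0.02)
})

test_that("EDP surrogate is the printed affine formula and strictly increasing", {
  expect_equal(estimate_edp(1.0, 0.1), 14.3)
  expect_equal(estimate_edp(0.5, 0.1), 8.1)
  expect_equal(estimate_edp(0, 0.1), 1.9)
  ratios <- seq(0, 20, by = 0.5)
  vals <- estimate_edp(ratios * 0.1, 0.1)
  expect_true(all(diff(vals) > 0))
  # affine: second differences vanish
  expect_lt(max(abs(diff(diff(vals)))), 1e-12)
  expect_error(estimate_edp(1, 0), "positive")
})

test_that("pooled t-test separates the cohort EF groups and handles degenerate input", {
  tab <- lv_reference_cohort()
  gc <- group_compare(tab$ef, tab$group)
  expect_lte(gc$p, 0.005)
  expect_equal(unname(gc$df), 6)
  # identical groups: t = 0, p = 1
  same <- group_compare(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(unname(same$t), 0)
  expect_equal(same$p, 1)
  expect_error(group_compare(1:5, c("a", "a", "a", "a", "b")), "at least 2")
  expect_error(group_compare(1:6, rep("a", 6)), "two groups")
})

test_that("t-test ordering agrees with a permutation test on synthetic group pairs", {
  set.seed(99)
  perm_p <- function(x, g) {
    obs <- abs(mean(x[g == 1]) - mean(x[g == 2]))
    cnt <- 0; B <- 400
    for (b in seq_len(B)) {
      gp <- sample(g)
      if (abs(mean(x[gp == 1]) - mean(x[gp == 2])) >= obs - 1e-12) cnt <- cnt + 1
    }
    cnt / B
  }
  seps <- c(0.5, 2, 4, 8, 16)
  pt <- pp <- numeric(length(seps))
  g <- rep(1:2, each = 6)
  base <- rnorm(12)
  for (i in seq_along(seps)) {
    x <- base + ifelse(g == 2, seps[i], 0)
    pt[i] <- group_compare(x, g)$p
    pp[i] <- perm_p(x, g)
  }
  # larger separation -> smaller p in both tests (permutation p saturates at
  # its resolution 1/B, hence non-strict)
  expect_true(all(diff(pt) < 0))
  expect_true(all(diff(pp) <= 0))
})

test_that("wall thickness recovers the analytic shell thickness", {
  mesh <- shell_mesh(0.020, 0.028)
  wt <- wall_thickness(mesh)
  expect_lt(abs(wt$mean_mm - 8) / 8, 0.02)
  # identity deformation changes nothing
  wt0 <- wall_thickness(mesh, numeric(3 * mesh$nq))
  expect_equal(wt0$mean_mm, wt$mean_mm)
  expect_equal(wall_thickening_ratio(8, 8), 0)
  expect_equal(wall_thickening_ratio(8, 10), 0.2)
})

test_that("shape metrics: near-full sphere has LA/SA ~ 1, ellipsoid matches construction", {
  sph <- make_idealized_lv_mesh(0.025, 0.025, 0.005, 0.005, 0.97, 0.005,
                                nc = 20, nl = 14, ns = 1)
  sm <- shape_metrics(sph, numeric(3 * sph$nq))
  expect_lt(abs(sm$la_sa - 1), 0.05)
  expect_equal(sm$long_axis_shortening, 0)

  ell <- make_idealized_lv_mesh(0.045, 0.022, 0.008, 0.008, 0.75, 0.004,
                                nc = 20, nl = 12, ns = 1)
  sm2 <- shape_metrics(ell, numeric(3 * ell$nq))
  # analytic: LA = apex-to-base-centroid = rl + zb; SA = 2 rs
  la <- 0.045 + (2 * 0.75 - 1) * 0.045
  expect_lt(abs(sm2$la_sa - la / 0.044) / (la / 0.044), 0.05)
})
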