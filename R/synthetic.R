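# Synthetic subjects with known ground-truth stiffness. Motion "data" are
# produced by the package's own forward model at a prescribed parameter ratio
# gamma*, with prescribed basal / epicardial surface target trajectories
# standing in for tagged-MRI-derived boundary data; the full-field data
# displacements are the forward solution itself (optionally perturbed by
# Gaussian tracking noise).

mesh_surface_nodes <- function(mesh, tag) {
  sort(unique(as.vector(mesh$boundary_tris[, mesh$boundary_tags == tag,
                                           drop = FALSE])))
}

#' Diastolic cavity-volume trace
#'
#' Smooth, strictly increasing two-phase trace from ESV to EDV: a rapid
#' early-filling (E-wave) rise, a diastasis plateau and a late (A-wave)
#' contribution, with exact endpoints.
#'
#' @param esv_ml end-systolic (reference) volume, ml.
#' @param edv_ml end-diastolic volume, ml; must exceed `esv_ml`.
#' @param n_frames number of frames (>= 2), the first being the reference.
#' @return numeric vector of volumes in ml.
#' @export
make_volume_trace <- function(esv_ml, edv_ml, n_frames) {
  if (!(edv_ml > esv_ml) || esv_ml <= 0) stop("need EDV > ESV > 0")
  if (n_frames < 2) stop("need at least 2 frames")
  tau <- seq(0, 1, length.out = n_frames)
  smoothstep <- function(x) { x <- pmin(pmax(x, 0), 1); x^2 * (3 - 2 * x) }
  g <- 0.62 * smoothstep(tau / 0.45) + 0.30 * smoothstep((tau - 0.55) / 0.45) +
       0.08 * tau
  esv_ml + (edv_ml - esv_ml) * g
}

#' Synthetic subject presets
#'
#' Group-level generator targets for healthy volunteers and dilated-
#' cardiomyopathy (DCM) subjects: cavity volumes, estimated end-diastolic
#' pressure, long-axis/short-axis shape ratio, wall thickness at the
#' end-systolic reference, ground-truth parameter ratio and fibre angle, and
#' the tracking-noise scale. The DCM preset is dilated and sphericalized with
#' reduced deformation and elevated EDP.
#'
#' @param group `"volunteer"` or `"dcm"`.
#' @param ... named overrides of any preset field.
#' @return object of class `lv_preset`.
#' @export
subject_preset <- function(group = c("volunteer", "dcm"), ...) {
  group <- match.arg(group)
  p <- if (group == "volunteer") {
    list(group = "volunteer", esv_ml = 55, edv_ml = 119, edp_mmhg = 11.4,
         la_sa = 1.45, wall_eq = 0.010, wall_apex = 0.007,
         truncation = 0.75, theta_deg = 60, gamma = 0.5,
         a_f_true = NULL, b = 5, b_f = 5, bc_mode = "RV",
         base_lift = 0.004, epi_squeeze = 0.0015,
         sigma_mm = 0.5, n_frames = 10, target_h = 0.005)
  } else {
    list(group = "dcm", esv_ml = 86, edv_ml = 152, edp_mmhg = 15.2,
         la_sa = 1.22, wall_eq = 0.0095, wall_apex = 0.0065,
         truncation = 0.75, theta_deg = 60, gamma = 0.5,
         a_f_true = NULL, b = 5, b_f = 5, bc_mode = "RV",
         base_lift = 0.0025, epi_squeeze = 0.0010,
         sigma_mm = 0.5, n_frames = 10, target_h = 0.005)
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown preset fields: ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  structure(p, class = "lv_preset")
}

# endocardial semi-axes reproducing the preset's reference (ES) cavity volume
# and LA/SA ratio under the given truncation, from the closed-form volume
preset_geometry <- function(preset) {
  tau <- preset$truncation
  aspect <- preset$la_sa / tau            # rl / rs so that (2 tau rl)/(2 rs) = LA/SA
  zb1 <- 2 * tau - 1                      # base plane in units of rl
  gfac <- zb1 - zb1^3 / 3 + 2 / 3
  rs <- (preset$esv_ml * 1e-6 / (pi * aspect * gfac))^(1 / 3)
  list(rs = rs, rl = aspect * rs)
}

#' Generate a complete synthetic subject
#'
#' Builds the idealized mesh and fibre field of the preset, prescribes
#' synthetic basal and (in RV mode) epicardial surface target trajectories,
#' forward-simulates diastolic inflation along the preset's volume trace at
#' the ground-truth parameter ratio, and records the solution as the
#' full-field motion data. The absolute stiffness scale is calibrated through
#' the exact linear-scaling property so that the model's end-diastolic
#' filling pressure equals the preset EDP (unless `a_f_true` pins it
#' directly); E and Ea velocities are synthesized so the Nagueh surrogate
#' returns that EDP.
#'
#' @param preset an [subject_preset()].
#' @param seed integer seed (reproducibility of any stochastic stage).
#' @param target_h,nc,nl,ns mesh resolution controls (see
#'   [make_idealized_lv_mesh()]).
#' @param n_frames number of diastolic frames (default from preset).
#' @param kappa_rel quasi-incompressibility penalty scale passed to
#'   [material_parameters()].
#' @param control solver tolerances.
#' @return object of class `lv_subject` with fields `mesh`, `s`, `fibres`,
#'   `bcs`, `motion`, `truth`, `E`, `Ea`, `edp_est_mmhg`, `group`.
#' @export
generate_subject <- function(preset, seed = 1L, target_h = preset$target_h,
                             nc = NULL, nl = NULL, ns = NULL,
                             n_frames = preset$n_frames, kappa_rel = 3000,
                             control = default_control()) {
  stopifnot(inherits(preset, "lv_preset"))
  set.seed(seed)
  geo <- preset_geometry(preset)
  mesh <- make_idealized_lv_mesh(geo$rl, geo$rs, preset$wall_eq,
                                 preset$wall_apex, preset$truncation,
                                 target_h, nc = nc, nl = nl, ns = ns)
  s <- transmural_coordinate(mesh)
  fib <- fibre_field(mesh, s, preset$theta_deg)
  bcs <- boundary_spec(mode = preset$bc_mode)
  model <- lv_model(mesh, fib, bcs)

  V_ref <- cavity_volume(mesh)
  # keep the preset's inflation ratio on the discrete mesh
  V_ed <- V_ref * preset$edv_ml / preset$esv_ml
  vol <- make_volume_trace(V_ref * 1e6, V_ed * 1e6, n_frames) * 1e-6
  beta <- (vol - vol[1]) / (vol[n_frames] - vol[1])

  base_nodes <- mesh_surface_nodes(mesh, 3L)
  epi_nodes <- mesh_surface_nodes(mesh, 2L)
  nb <- length(base_nodes); nepi <- length(epi_nodes)
  ud_b <- matrix(0, 3 * nb, n_frames)
  lift <- rep(c(0, 0, preset$base_lift), nb)
  for (n in seq_len(n_frames)) ud_b[, n] <- beta[n] * lift

  ud_e <- matrix(0, 3 * nepi, n_frames)
  if (preset$bc_mode == "RV") {
    xy <- mesh$X[1:2, epi_nodes, drop = FALSE]
    r <- sqrt(colSums(xy^2)); r[r == 0] <- 1
    inward <- -rbind(xy[1, ] / r, xy[2, ] / r, 0)
    sq <- as.vector(inward) * preset$epi_squeeze
    for (n in seq_len(n_frames)) ud_e[, n] <- beta[n] * sq
  }

  motion <- structure(list(times = seq(0, 0.5, length.out = n_frames),
                           vol = vol, n_frames = n_frames,
                           ud = NULL, ud_b = ud_b, ud_e = ud_e,
                           base_nodes = base_nodes, epi_nodes = epi_nodes),
                      class = "lv_motion")

  a_f_sim <- 1000
  params <- material_parameters(a = preset$gamma * a_f_sim, a_f = a_f_sim,
                                b = preset$b, b_f = preset$b_f,
                                kappa_rel = kappa_rel)
  traj <- simulate_diastole(model, params, motion, control)

  # linear-scaling calibration of the absolute stiffness
  lam0 <- traj$lambda_ED
  if (!is.null(preset$a_f_true)) {
    kap <- preset$a_f_true / a_f_sim
    edp_mmhg <- pa_to_mmhg(lam0 * kap)
  } else {
    kap <- mmhg_to_pa(preset$edp_mmhg) / lam0
    edp_mmhg <- preset$edp_mmhg
  }
  a_f_true <- a_f_sim * kap
  a_true <- preset$gamma * a_f_true

  motion$ud <- traj$u
  Ea <- 0.1
  E <- Ea * (edp_mmhg - 1.9) / 1.24

  structure(list(
    mesh = mesh, s = s, fibres = fib, bcs = bcs, motion = motion,
    group = preset$group, preset = preset,
    E = E, Ea = Ea, edp_est_mmhg = edp_mmhg,
    truth = list(gamma = preset$gamma, a = a_true, a_f = a_f_true,
                 b = preset$b, b_f = preset$b_f,
                 theta_deg = preset$theta_deg, bc_mode = preset$bc_mode,
                 lambda_ED_Pa = lam0 * kap, edp_mmhg = edp_mmhg,
                 sigma_mm = 0, seed = seed),
    trajectory = structure(list(
      u = traj$u, p = traj$p * kap, lambda_l = traj$lambda_l * kap,
      lambda_ED = lam0 * kap, vol = traj$vol, times = traj$times,
      newton_iters = traj$newton_iters, residuals = traj$residuals,
      max_detF_dev = traj$max_detF_dev), class = "lv_trajectory")),
    class = "lv_subject")
}

#' Add Gaussian displacement noise to motion data
#'
#' Independent zero-mean Gaussian perturbations per node, component and frame
#' of the full-field data displacements, emulating tagged-MRI tracking error.
#' The reference frame (frame 1) is left exact.
#'
#' @param x an `lv_subject` or `lv_motion`.
#' @param sigma_mm noise standard deviation per component, mm (>= 0).
#' @param seed integer seed.
#' @return same class as `x`, with perturbed `ud` (and, for subjects, the
#'   ground-truth record updated with the noise level).
#' @export
add_displacement_noise <- function(x, sigma_mm, seed = 1L) {
  if (sigma_mm < 0) stop("sigma must be non-negative")
  if (inherits(x, "lv_subject")) {
    x$motion <- add_displacement_noise(x$motion, sigma_mm, seed)
    x$truth$sigma_mm <- sigma_mm
    return(x)
  }
  stopifnot(inherits(x, "lv_motion"))
  if (sigma_mm == 0) return(x)
  set.seed(seed)
  noise <- matrix(rnorm(length(x$ud), 0, sigma_mm * 1e-3), nrow(x$ud))
  noise[, 1] <- 0
  x$ud <- x$ud + noise
  x
}

#' Wall-volume conservation projection
#'
#' Projects per-frame data displacements so that the deformed myocardial wall
#' volume equals the reference wall volume (within 0.1%), by displacing nodes
#' along the local transmural direction with a single global correction
#' factor per frame, scaled by the transmural coordinate so the endocardial
#' surface (and hence the cavity-volume trace) is unchanged.
#'
#' @param mesh an `lv_mesh`.
#' @param motion an `lv_motion` with full-field `ud`.
#' @param s optional precomputed [transmural_coordinate()].
#' @return the corrected `lv_motion`.
#' @export
conserve_wall_volume <- function(mesh, motion, s = NULL) {
  stopifnot(inherits(motion, "lv_motion"))
  if (is.null(s)) s <- transmural_coordinate(mesh)
  dirvec <- as.vector(sweep(s$tdir, 2, s$s, "*"))
  tet0 <- mesh$tet10 - 1L
  W0 <- wall_volume_p2(mesh$X, tet0, numeric(3 * mesh$nq))
  wt <- mesh$params$wall_thickness_equator
  if (is.null(wt)) wt <- 0.1 * max(apply(mesh$X, 1, function(r) diff(range(r))))
  bound <- 0.2 * wt
  for (n in seq_len(motion$n_frames)) {
    un <- motion$ud[, n]
    f <- function(d) wall_volume_p2(mesh$X, tet0, un + d * dirvec) - W0
    if (abs(f(0)) / W0 <= 1e-3) next
    flo <- f(-bound); fhi <- f(bound)
    if (sign(flo) == sign(fhi))
      stop("frame ", n, ": required wall-volume correction exceeds 20% of the wall thickness; data too corrupted")
    root <- uniroot(f, c(-bound, bound), tol = 1e-4 * wt * 1e-3)
    motion$ud[, n] <- un + root$root * dirvec
  }
  motion
}
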