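# Shared fixtures, built once per test run and cached. Sizes are kept small:
# the mechanics checks use a coarse idealized ventricle (a few hundred
# elements) so the whole suite stays within a desktop-scale budget; the
# methods vignette documents the resolutions used.

.fixtures <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# coarse healthy-geometry mesh for solver tests
coarse_mesh <- function() with_cache("coarse_mesh", {
  make_idealized_lv_mesh(0.040, 0.020, 0.010, 0.007, 0.75, 0.008,
                         nc = 12, nl = 5, ns = 1)
})

coarse_setup <- function(theta = 60, mode = "RV") {
  key <- sprintf("setup_%g_%s", theta, mode)
  with_cache(key, {
    mesh <- coarse_mesh()
    s <- with_cache("coarse_s", transmural_coordinate(mesh))
    fib <- fibre_field(mesh, s, theta)
    list(mesh = mesh, s = s, fib = fib,
         model = lv_model(mesh, fib, boundary_spec(mode)))
  })
}

# spherical-shell test mesh (equal semi-axes): radii in metres
shell_mesh <- function(r_in = 0.020, r_out = 0.030, trunc = 0.5) {
  key <- sprintf("shell_%g_%g_%g", r_in, r_out, trunc)
  with_cache(key, {
    make_idealized_lv_mesh(r_in, r_in, r_out - r_in, r_out - r_in, trunc,
                           (r_out - r_in) / 2, nc = 20, nl = 10, ns = 2)
  })
}

# small synthetic volunteer subject with known ground truth
tiny_subject <- function(gamma = 0.5, mode = "RV", n_frames = 6, seed = 7) {
  key <- sprintf("subj_%g_%s_%d_%d", gamma, mode, n_frames, seed)
  with_cache(key, {
    preset <- subject_preset("volunteer", gamma = gamma, bc_mode = mode,
                             n_frames = n_frames)
    generate_subject(preset, seed = seed, nc = 10, nl = 5, ns = 1)
  })
}

# small DCM counterpart
tiny_dcm_subject <- function(n_frames = 5, seed = 11) {
  key <- sprintf("dcm_%d_%d", n_frames, seed)
  with_cache(key, {
    generate_subject(subject_preset("dcm", n_frames = n_frames), seed = seed,
                     nc = 10, nl = 5, ns = 1)
  })
}

# refined 8-point recovery sweep on the tiny volunteer subject, shared
# between the recovery and identifiability checks
shared_rv_sweep <- function() with_cache("shared_rv_sweep", {
  refine_sweep(parameter_sweep(tiny_subject(), lv_gamma_grid(8), warm_start = TRUE), 3)
})

# single forward evaluation at the exact ground-truth ratio (degenerate
# one-point sweep); forward/inverse consistency makes its objective ~ 0
shared_truth_sweep <- function() with_cache("shared_truth_sweep", {
  subj <- tiny_subject()
  parameter_sweep(subj, gamma_grid = subj$truth$gamma)
})

max_detF_deviation <- function(mesh, u) {
  dr <- lvstiff:::detF_range(mesh$X, mesh$tet10 - 1L, u)
  max(abs(dr - 1))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# rotate an lv_mesh rigidly about the long axis
rotate_mesh_z <- function(mesh, deg) {
  Q <- rotation_z(deg)
  m2 <- mesh
  m2$X <- Q %*% mesh$X
  m2
}
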