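# Incompressible hyperelastic finite-element solver for volume-driven
# diastolic inflation. Mixed saddle-point formulation: quadratic displacement,
# linear hydrostatic pressure, quadratic vector Lagrange-multiplier fields on
# the basal (and optionally epicardial) surfaces, and one scalar multiplier
# enforcing the cavity-volume constraint. The stationarity conditions of
#   Pi(u, p, lambda) = int Psi(F) + p (J - 1) dV
#                      - lambda_l (V_cav(u) - V_target)
#                      + int_base lambda_b . ((u - u_d) - eps_b/2 lambda_b) dA
#                      + int_epi  lambda_e . ((u - u_d) H - eps_e/2 lambda_e) dA
# are solved with Newton's method. The relaxed surface multipliers are
# condensed exactly (their stationarity ties them algebraically to the
# displacement mismatch), leaving a (u, p, lambda_l) saddle system that is
# factorized by a supernodal Cholesky of the displacement block plus a dense
# Schur complement over the constraints, with a sparse-LU fallback when the
# displacement block loses definiteness. The volume increment is bisected on
# divergence.

#' Boundary-condition specification
#'
#' Relaxed (multiplier + relaxation) data-tracking conditions on the basal
#' surface, plus either a traction-free epicardium (`"NT"`) or relaxed
#' tracking of data over the RV attachment region weighted by the field H
#' (`"RV"`). The relaxation parameters have units m / Pa: the multiplier
#' (a traction) equals the displacement mismatch divided by eps.
#'
#' @param mode `"NT"` or `"RV"`.
#' @param eps_e epicardial relaxation (m / Pa); default the moderate 5e-6.
#' @param eps_b basal relaxation (m / Pa); default 5e-6.
#' @param ref_stiffness reference fibre stiffness (Pa) at which the
#'   relaxation values are specified; the effective relaxation scales
#'   inversely with the material scale so that joint scaling of (a, a_f)
#'   leaves displacements exactly unchanged (the linear-dependence property
#'   the end-diastolic-pressure rescaling relies on).
#' @param H_azimuth_center,H_half_width,H_transition parameters of
#'   [rv_attachment_field()] (degrees).
#' @return object of class `lv_bcs`.
#' @export
boundary_spec <- function(mode = c("RV", "NT"), eps_e = 5e-6, eps_b = 5e-6,
                          ref_stiffness = 1000,
                          H_azimuth_center = 180, H_half_width = 60,
                          H_transition = 15) {
  mode <- match.arg(mode)
  if (eps_e <= 0 || eps_b <= 0) stop("relaxation parameters must be positive")
  structure(list(mode = mode, eps_e = eps_e, eps_b = eps_b,
                 ref_stiffness = ref_stiffness,
                 H_azimuth_center = H_azimuth_center,
                 H_half_width = H_half_width, H_transition = H_transition),
            class = "lv_bcs")
}

# effective relaxation parameters at the current material scale
eps_effective <- function(bcs, params) {
  sm <- if (params$a_f > 0) params$a_f else params$a
  ref <- bcs$ref_stiffness %||% 1000
  list(b = bcs$eps_b * ref / sm, e = bcs$eps_e * ref / sm)
}

sparse_from_triplets <- function(i, j, x, nrow, ncol) {
  Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = x, dims = c(nrow, ncol))
}

# scalar node-indexed triplets restricted to `nodes`, expanded to one block
# per displacement component in the full 3 nq dof numbering
expand_vector_mass <- function(trip, nq) {
  i <- trip$i + 1L; j <- trip$j + 1L; x <- trip$x
  Matrix::sparseMatrix(i = c(3 * i - 2, 3 * i - 1, 3 * i),
                       j = c(3 * j - 2, 3 * j - 1, 3 * j),
                       x = c(x, x, x), dims = c(3 * nq, 3 * nq))
}

#' Assemble the discrete model for one subject configuration
#'
#' Precomputes the constant structures of the solver: surface multiplier
#' mass matrices (and the sparse condensed forms of the relaxed boundary
#' terms), the cavity-closure topology, the displacement mass matrix used by
#' the estimation objective, and the degree-of-freedom layout.
#'
#' @param mesh an `lv_mesh`.
#' @param fibres an `lv_fibres` field.
#' @param bcs an [boundary_spec()] object.
#' @return object of class `lv_model`.
#' @export
lv_model <- function(mesh, fibres, bcs = boundary_spec()) {
  nq <- mesh$nq; nv <- mesh$nv
  tet10_0 <- mesh$tet10 - 1L
  base_nodes <- sort(unique(as.vector(
    mesh$boundary_tris[, mesh$boundary_tags == 3L, drop = FALSE])))
  epi_nodes <- sort(unique(as.vector(
    mesh$boundary_tris[, mesh$boundary_tags == 2L, drop = FALSE])))

  base6 <- mesh$boundary_tris[, mesh$boundary_tags == 3L, drop = FALSE] - 1L
  epi6 <- mesh$boundary_tris[, mesh$boundary_tags == 2L, drop = FALSE] - 1L
  ones <- rep(1, nq)
  # basal surface mass in the full u-dof space (nonzero on base nodes only)
  Mbb <- expand_vector_mass(surf_mass(mesh$X, base6, ones), nq)

  H <- NULL; MeH <- NULL; dMee <- NULL
  if (bcs$mode == "RV") {
    H <- rv_attachment_field(mesh, bcs$H_azimuth_center, bcs$H_half_width,
                             bcs$H_transition)
    MeH <- expand_vector_mass(surf_mass(mesh$X, epi6, H), nq)
    # diagonally-scaled (HRZ) lumping of the epicardial mass for the
    # relaxation term, so the condensed multiplier stays local; row-sum
    # lumping is unusable for quadratic elements (vertex rows integrate to
    # zero). Pseudo-inverse outside the surface.
    Ms <- expand_vector_mass(surf_mass(mesh$X, epi6, ones), nq)
    dv <- Matrix::diag(Ms)
    me <- dv * sum(Ms@x) / sum(dv)
    dMee_inv <- ifelse(me > 0, 1 / me, 0)
    dMee <- list(lumped = me, inv = dMee_inv)
  }

  mt <- mass_p2(mesh$X, tet10_0)
  Mu <- sparse_from_triplets(mt$i, mt$j, mt$x, nq, nq)

  # condensed penalty structures (scaled by 1/eps at assembly time)
  Pen_b <- Mbb
  Pen_e <- if (bcs$mode == "RV") {
    Matrix::t(MeH) %*% (Matrix::Diagonal(x = dMee$inv) %*% MeH)
  } else NULL

  off <- list(u = 0L, p = 3L * nq)
  ndof <- 3L * nq + nv + 1L

  structure(list(mesh = mesh, fibres = fibres, bcs = bcs,
                 base_nodes = base_nodes, epi_nodes = epi_nodes,
                 Mbb = Mbb, MeH = MeH, dMee = dMee,
                 Pen_b = Pen_b, Pen_e = Pen_e, H = H, Mu = Mu,
                 tet10_0 = tet10_0,
                 cav_tris0 = mesh$cavity_tris - 1L, ring0 = mesh$ring - 1L,
                 off = off, ndof = ndof,
                 n_b = 3L * length(base_nodes), n_e = 3L * length(epi_nodes)),
            class = "lv_model")
}

# dof indices (1-based) of the 3 displacement components of given nodes
u_dofs <- function(nodes) as.vector(rbind(3 * nodes - 2, 3 * nodes - 1, 3 * nodes))

new_state <- function(model, params) {
  list(u = numeric(3 * model$mesh$nq),
       p = rep(-params$a, model$mesh$nv),     # P(I, -a) = 0: stress-free rest
       ll = 0)
}

# surface data vectors in the full 3 nq dof space
spread_surface <- function(model, nodes, vals) {
  out <- numeric(3 * model$mesh$nq)
  if (length(vals)) out[u_dofs(nodes)] <- vals
  out
}

# condensed multiplier fields (tractions, Pa) at the current displacement
boundary_multipliers <- function(model, params, state, ud_b, ud_e) {
  eps <- eps_effective(model$bcs, params)
  db <- spread_surface(model, model$base_nodes, ud_b)
  lb_full <- (state$u - db) / eps$b
  lb <- lb_full[u_dofs(model$base_nodes)]
  le <- numeric(0)
  if (model$bcs$mode == "RV") {
    de <- spread_surface(model, model$epi_nodes, ud_e)
    le_full <- model$dMee$inv * as.numeric(model$MeH %*% (state$u - de)) / eps$e
    le <- le_full[u_dofs(model$epi_nodes)]
  }
  list(lb = lb, le = le)
}

#' Cavity volume of a (possibly deformed) LV mesh
#'
#' Lumen volume computed by the divergence theorem over the deformed
#' endocardial surface, closed by a fan of triangles to the centroid of the
#' deformed basal endocardial ring. Exact for the piecewise-straight surface
#' representation and differentiable in u.
#'
#' @param mesh an `lv_mesh`.
#' @param u displacement vector (3 nq), default zero.
#' @return volume in m^3.
#' @export
cavity_volume <- function(mesh, u = NULL) {
  if (is.null(u)) u <- numeric(3 * mesh$nq)
  ct <- cavity_terms(mesh$X, u, mesh$cavity_tris - 1L, mesh$ring - 1L,
                     want_hessian = FALSE)
  ct$V
}

#' Assemble residual and Jacobian of the saddle-point system
#'
#' Returns the discrete gradient of the total potential energy (with the
#' relaxed surface multipliers condensed out) and its symmetric Jacobian
#' blocks at the given state.
#'
#' @param model an [lv_model()].
#' @param params an [material_parameters()] object.
#' @param state solver state (list u, p, ll).
#' @param V_target target cavity volume (m^3).
#' @param ud_b data displacements at basal surface dofs (length 3 n_base).
#' @param ud_e data displacements at epicardial surface dofs (RV mode).
#' @param want_matrix assemble the Jacobian as well.
#' @return list with `R` (residual over u, p, lambda_l), `Kuu`, `Kup`,
#'   `gV` (volume-constraint gradient), `ok` (FALSE if det F <= 0), `V`,
#'   `jmin`, `jmax` (range of det F over quadrature points).
#' @export
assemble_system <- function(model, params, state, V_target,
                            ud_b = NULL, ud_e = NULL, want_matrix = TRUE) {
  mesh <- model$mesh
  nq <- mesh$nq; nv <- mesh$nv
  if (is.null(ud_b)) ud_b <- numeric(model$n_b)
  if (is.null(ud_e)) ud_e <- numeric(model$n_e)
  if (length(state$u) != 3 * nq || length(state$p) != nv ||
      length(ud_b) != model$n_b)
    stop("inconsistent field sizes")
  eps <- eps_effective(model$bcs, params)

  am <- asm_mech(mesh$X, model$tet10_0, state$u, state$p, model$fibres$f0,
                 params$a, params$b, params$a_f, params$b_f,
                 params$kappa %||% 0, want_matrix)
  if (!am$ok)
    return(list(ok = FALSE, R = NULL, jmin = am$jmin, jmax = am$jmax))

  ct <- cavity_terms(mesh$X, state$u, model$cav_tris0, model$ring0,
                     want_hessian = want_matrix)

  db <- spread_surface(model, model$base_nodes, ud_b)
  fu <- am$fu - state$ll * ct$grad +
    as.numeric(model$Pen_b %*% (state$u - db)) / eps$b
  if (model$bcs$mode == "RV") {
    de <- spread_surface(model, model$epi_nodes, ud_e)
    fu <- fu + as.numeric(model$Pen_e %*% (state$u - de)) / eps$e
  }
  R <- c(fu, am$fp, -(ct$V - V_target))

  out <- list(ok = TRUE, R = R, V = ct$V, jmin = am$jmin, jmax = am$jmax,
              energy = am$energy)
  if (want_matrix) {
    gnz <- which(ct$grad != 0)
    Kuu <- sparse_from_triplets(c(am$kuu_i, ct$hi),
                                c(am$kuu_j, ct$hj),
                                c(am$kuu_x, -state$ll * ct$hx),
                                3L * nq, 3L * nq)
    Kuu <- Kuu + model$Pen_b / eps$b
    if (model$bcs$mode == "RV") Kuu <- Kuu + model$Pen_e / eps$e
    out$Kuu <- Kuu
    out$Kup <- sparse_from_triplets(am$kup_i, am$kup_j, am$kup_x, 3L * nq, nv)
    out$gV <- ct$grad
  }
  out
}

state_to_vec <- function(s) c(s$u, s$p, s$ll)
vec_to_state <- function(x, model) {
  nq <- model$mesh$nq; nv <- model$mesh$nv
  list(u = x[seq_len(3 * nq)], p = x[3 * nq + seq_len(nv)],
       ll = x[3 * nq + nv + 1L])
}

# Solve the reduced saddle system
#   [Kuu  B'] [du]   [-Ru]      B = [Kup' ; -gV']
#   [B    0 ] [dc] = [-Rc]
# via supernodal Cholesky of Kuu and a dense Schur complement over the
# nv + 1 constraints; falls back to sparse LU of the full matrix if Kuu is
# not positive definite at the current state.
solve_saddle <- function(sys, model) {
  nq <- model$mesh$nq; nv <- model$mesh$nv
  nu <- 3L * nq
  Ru <- sys$R[seq_len(nu)]; Rc <- sys$R[nu + seq_len(nv + 1L)]
  Bt <- cbind(sys$Kup, -sys$gV)                     # nu x (nv+1)
  for (ldl in c(FALSE, TRUE)) {
    ch <- tryCatch(suppressWarnings(
      Matrix::Cholesky(Matrix::forceSymmetric(sys$Kuu, "U"),
                       LDL = ldl, super = !ldl)),
      error = function(e) NULL)
    if (is.null(ch)) next
    sol <- tryCatch(suppressWarnings({
      Y <- Matrix::solve(ch, Bt)                    # nu x (nv+1)
      du0 <- as.numeric(Matrix::solve(ch, -Ru))
      S <- -as.matrix(Matrix::t(Bt) %*% Y)
      # equilibrate the dense Schur complement: its pressure and volume
      # rows live on very different scales
      ds <- 1 / sqrt(pmax(abs(diag(S)), .Machine$double.xmin))
      Ssc <- S * (ds %o% ds)
      schur_solve <- function(rhs) ds * solve(Ssc, ds * rhs)
      dc <- schur_solve(as.numeric(-Rc - Matrix::t(Bt) %*% du0))
      du <- du0 - as.numeric(Y %*% dc)
      c(du, dc)
    }), error = function(e) NULL)
    if (!is.null(sol) && all(is.finite(sol))) {
      # one step of iterative refinement, then guard against breakdown
      for (ref in 1:2) {
        lin_res <- saddle_apply(sys, sol, nu) + sys$R
        err <- sqrt(sum(lin_res^2)) / max(sqrt(sum(sys$R^2)), 1e-300)
        if (err < 1e-10) break
        corr <- tryCatch(suppressWarnings({
          rv <- -lin_res[seq_len(nu)]; rc <- -lin_res[nu + seq_len(nv + 1L)]
          cu0 <- as.numeric(Matrix::solve(ch, rv))
          cc <- schur_solve(as.numeric(rc - Matrix::t(Bt) %*% cu0))
          c(cu0 - as.numeric(Y %*% cc), cc)
        }), error = function(e) NULL)
        if (is.null(corr) || !all(is.finite(corr))) break
        sol <- sol + corr
      }
      err <- sqrt(sum((saddle_apply(sys, sol, nu) + sys$R)^2)) /
             max(sqrt(sum(sys$R^2)), 1e-300)
      # an inexact direction at this accuracy still gives fast Newton
      # convergence; the guard only needs to catch broken factorizations
      if (err < 1e-5) return(sol)
    }
  }
  # fallback: sparse LU of the full indefinite system, triplet-assembled
  Kt <- methods::as(sys$Kuu, "TsparseMatrix")
  Bt2 <- methods::as(Bt, "TsparseMatrix")
  K <- Matrix::sparseMatrix(
    i = c(Kt@i + 1L, Bt2@i + 1L, nu + Bt2@j + 1L),
    j = c(Kt@j + 1L, nu + Bt2@j + 1L, Bt2@i + 1L),
    x = c(Kt@x, Bt2@x, Bt2@x),
    dims = c(nu + nv + 1L, nu + nv + 1L))
  tryCatch(as.numeric(Matrix::solve(K, -sys$R)), error = function(e) NULL)
}

# matrix-vector product of the reduced saddle system without forming it
saddle_apply <- function(sys, x, nu) {
  du <- x[seq_len(nu)]; dc <- x[-seq_len(nu)]
  Bt <- cbind(sys$Kup, -sys$gV)
  c(as.numeric(sys$Kuu %*% du) + as.numeric(Bt %*% dc),
    as.numeric(Matrix::t(Bt) %*% du))
}

# dimensionless per-block weights for the residual norm: forces scaled by the
# material stiffness times a wall-area scale, volumetric residuals by the
# wall volume, the constraint by the reference cavity volume
residual_weights <- function(model, params) {
  nq <- model$mesh$nq; nv <- model$mesh$nv
  Vw <- abs(sum(tet_volumes(model$mesh)))
  fscale <- (params$a + params$a_f) * Vw^(2 / 3)
  c(rep(1 / fscale, 3 * nq), rep(1 / Vw, nv), 1 / cavity_volume(model$mesh))
}

newton_solve <- function(model, params, state, V_target, ud_b, ud_e, control) {
  x <- state_to_vec(state)
  w <- residual_weights(model, params)
  rnorm_s <- function(R) sqrt(sum((R * w)^2))
  res0 <- NA_real_
  for (it in seq_len(control$max_iter)) {
    st <- vec_to_state(x, model)
    sys <- assemble_system(model, params, st, V_target, ud_b, ud_e, TRUE)
    if (!sys$ok) return(list(converged = FALSE, reason = "detF<=0", iters = it))
    rn <- rnorm_s(sys$R)
    if (it == 1) res0 <- rn
    if (rn <= control$tol_abs || (res0 > 0 && rn / res0 <= control$tol_rel))
      return(list(converged = TRUE, state = st, iters = it - 1L, residual = rn,
                  jmin = sys$jmin, jmax = sys$jmax, V = sys$V))
    dx <- solve_saddle(sys, model)
    if (is.null(dx) || !all(is.finite(dx)))
      return(list(converged = FALSE, reason = "singular system", iters = it))
    # backtracking line search on the scaled residual norm, guarding det F > 0
    alpha <- 1; accepted <- FALSE
    for (ls in 1:10) {
      xn <- x + alpha * dx
      sn <- assemble_system(model, params, vec_to_state(xn, model), V_target,
                            ud_b, ud_e, FALSE)
      if (sn$ok && is.finite(rnn <- rnorm_s(sn$R)) && rnn < rn) {
        x <- xn; accepted <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!accepted)
      return(list(converged = FALSE, reason = "line search failed", iters = it))
  }
  list(converged = FALSE, reason = "max iterations", iters = control$max_iter)
}

default_control <- function() list(tol_rel = 1e-8, tol_abs = 1e-9,
                                   max_iter = 25, max_bisect = 8)

#' Solve one quasi-static frame
#'
#' Newton iteration on the saddle-point system for a single target cavity
#' volume; on divergence the increment from the previous state (volume and
#' boundary data) is bisected, up to `max_bisect` sub-steps.
#'
#' @param model an [lv_model()].
#' @param params material parameters; a == a_f == 0 is refused.
#' @param state converged previous state (list u, p, ll).
#' @param V_target target cavity volume (m^3).
#' @param ud_b,ud_e boundary data displacements at this frame.
#' @param prev list with the previous frame's `V`, `ud_b`, `ud_e` (used for
#'   continuation); defaults to the state's own volume and data.
#' @param control solver tolerances.
#' @return list: converged `state` (with condensed multiplier fields `lb`,
#'   `le` attached), `iters`, `residual`, `jmin`, `jmax`, `V`.
#' @export
solve_frame <- function(model, params, state, V_target, ud_b = NULL,
                        ud_e = NULL, prev = NULL, control = default_control()) {
  if (params$a <= 0 && params$a_f <= 0)
    stop("singular material: a and a_f cannot both vanish")
  if (is.null(ud_b)) ud_b <- numeric(model$n_b)
  if (is.null(ud_e)) ud_e <- numeric(model$n_e)
  if (is.null(prev)) {
    sys0 <- assemble_system(model, params, state, V_target, ud_b, ud_e, FALSE)
    prev <- list(V = sys0$V, ud_b = state$u[u_dofs(model$base_nodes)],
                 ud_e = if (model$bcs$mode == "RV")
                   state$u[u_dofs(model$epi_nodes)] else numeric(0))
  }
  total_iters <- 0L
  solve_span <- function(state, t0, t1, depth) {
    Vt <- prev$V + t1 * (V_target - prev$V)
    db <- prev$ud_b + t1 * (ud_b - prev$ud_b)
    de <- if (model$bcs$mode == "RV") prev$ud_e + t1 * (ud_e - prev$ud_e)
          else numeric(0)
    res <- newton_solve(model, params, state, Vt, db, de, control)
    total_iters <<- total_iters + res$iters
    if (res$converged) return(res)
    if (depth >= control$max_bisect)
      stop("frame did not converge (", res$reason, ") after ", depth,
           " bisections")
    tm <- (t0 + t1) / 2
    mid <- solve_span(state, t0, tm, depth + 1L)
    solve_span(mid$state, tm, t1, depth + 1L)
  }
  # proactive sub-stepping: large volume increments rarely converge in one
  # Newton pass, so split them up front instead of discovering by failure
  dv_rel <- if (prev$V > 0) abs(V_target - prev$V) / prev$V else 0
  n_sub <- min(16L, max(1L, ceiling(dv_rel / 0.12)))
  out <- list(state = state)
  for (i in seq_len(n_sub))
    out <- solve_span(out$state, (i - 1) / n_sub, i / n_sub, 0L)
  out$iters <- total_iters
  mult <- boundary_multipliers(model, params, out$state, ud_b, ud_e)
  out$state$lb <- mult$lb; out$state$le <- mult$le
  out
}

#' Simulate diastolic filling along a cavity-volume trace
#'
#' Sequential quasi-static solves over the diastolic frames of a motion
#' record: each frame enforces the data-derived cavity volume through the
#' scalar endocardial multiplier, with relaxed basal (and, in RV mode,
#' epicardial) data tracking.
#'
#' @param model an [lv_model()].
#' @param params material parameters.
#' @param motion an `lv_motion` object; frame 1 is the reference state.
#' @param control solver tolerances.
#' @return object of class `lv_trajectory`: displacement / pressure fields
#'   per frame, multiplier traces (lambda_l in Pa), Newton diagnostics and
#'   `lambda_ED` (end-diastolic value).
#' @export
simulate_diastole <- function(model, params, motion, control = default_control(),
                              guess = NULL) {
  N <- motion$n_frames
  if (N < 2) stop("need at least 2 diastolic frames")
  if (any(diff(motion$vol) < -1e-12))
    stop("cavity-volume trace must be non-decreasing over diastole")
  nq <- model$mesh$nq
  st <- new_state(model, params)
  U <- matrix(0, 3 * nq, N)
  P <- matrix(0, model$mesh$nv, N); P[, 1] <- st$p
  lam <- numeric(N)
  iters <- integer(N); resid <- numeric(N); jdev <- numeric(N)
  prev <- list(V = motion$vol[1], ud_b = numeric(model$n_b),
               ud_e = if (model$bcs$mode == "RV") numeric(model$n_e)
                      else numeric(0))
  st_prev <- NULL
  for (n in 2:N) {
    ud_b <- motion$ud_b[, n]
    ud_e <- if (model$bcs$mode == "RV") motion$ud_e[, n] else numeric(0)
    res <- NULL
    # warm start from a previous run's converged frame, if provided
    if (!is.null(guess) && is.matrix(guess$u) && ncol(guess$u) >= n) {
      g <- list(u = guess$u[, n], p = guess$p[, n], ll = guess$lambda_l[n])
      ctrlw <- control; ctrlw$max_iter <- 12L
      trial <- newton_solve(model, params, g, motion$vol[n], ud_b, ud_e, ctrlw)
      if (trial$converged) res <- trial
    }
    # secant predictor: extrapolate the state along the volume trace
    if (is.null(res) && n > 2 && !is.null(st_prev)) {
      dV_prev <- motion$vol[n - 1] - motion$vol[n - 2]
      fac <- if (dV_prev > 0) (motion$vol[n] - motion$vol[n - 1]) / dV_prev else 0
      if (is.finite(fac) && fac > 0 && fac < 3) {
        pred <- list(u = st$u + fac * (st$u - st_prev$u),
                     p = st$p + fac * (st$p - st_prev$p),
                     ll = st$ll + fac * (st$ll - st_prev$ll))
        ctrl2 <- control; ctrl2$max_iter <- 12L
        trial <- newton_solve(model, params, pred, motion$vol[n], ud_b, ud_e,
                              ctrl2)
        if (trial$converged) res <- trial
      }
    }
    if (is.null(res))
      res <- tryCatch(
        solve_frame(model, params, st, motion$vol[n], ud_b, ud_e, prev, control),
        error = function(e) e)
    st_prev <- st
    if (inherits(res, "error")) {
      stop(errorCondition(
        paste0("frame ", n, " failed: ", conditionMessage(res)),
        class = c("lv_frame_error", "error"),
        partial = list(u = U[, 1:(n - 1), drop = FALSE], frames_done = n - 1L)))
    }
    st <- res$state
    U[, n] <- st$u; P[, n] <- st$p; lam[n] <- st$ll
    iters[n] <- res$iters; resid[n] <- res$residual
    jdev[n] <- max(abs(res$jmin - 1), abs(res$jmax - 1))
    prev <- list(V = motion$vol[n], ud_b = ud_b, ud_e = ud_e)
  }
  structure(list(u = U, p = P, lambda_l = lam, lambda_ED = lam[N],
                 vol = motion$vol, times = motion$times,
                 newton_iters = iters, residuals = resid,
                 max_detF_dev = jdev), class = "lv_trajectory")
}
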