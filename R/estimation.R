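# Parameter estimation by gamma = a / a_f sweeps. In volume-driven,
# displacement-only observation the two stiffness scales are not separately
# identifiable (joint scaling leaves displacements unchanged and scales the
# cavity pressure), so the fibre scale is held at an arbitrary a_f_sim during
# sweeps and the absolute parameters are recovered afterwards by rescaling
# with the ratio of estimated to simulated end-diastolic pressure.

#' Default gamma sweep grid
#'
#' 23 linearly spaced ratio values between 0.3 and 2.
#'
#' @param n number of grid points.
#' @param lo,hi grid range.
#' @return numeric vector.
#' @export
lv_gamma_grid <- function(n = 23, lo = 0.3, hi = 2) seq(lo, hi, length.out = n)

l2_norm2 <- function(model, v) {
  nq <- model$mesh$nq
  tot <- 0
  for (c in 1:3) {
    vc <- v[seq(c, 3 * nq, by = 3)]
    tot <- tot + as.numeric(vc %*% (model$Mu %*% vc))
  }
  tot
}

#' Relative displacement-error objective
#'
#' J = sqrt( sum_n ||u^n - u_d^n||^2_L2 / sum_n ||u_d^n||^2_L2 ), with the
#' L2(Omega_0) norms computed through the displacement mass matrix over the
#' reference domain and the sum running over all diastolic frames.
#'
#' @param traj an `lv_trajectory` from [simulate_diastole()].
#' @param motion an `lv_motion` holding the data displacements `ud`.
#' @param model the [lv_model()] the trajectory was computed on.
#' @return non-negative scalar.
#' @export
objective_function <- function(traj, motion, model) {
  N <- motion$n_frames
  if (ncol(traj$u) != N) stop("model and data must share frames")
  num <- den <- 0
  for (n in seq_len(N)) {
    num <- num + l2_norm2(model, traj$u[, n] - motion$ud[, n])
    den <- den + l2_norm2(model, motion$ud[, n])
  }
  if (den <= 0) stop("undefined objective: data displacements are identically zero")
  sqrt(num / den)
}

build_case_model <- function(subject, theta = NULL, bc_mode = NULL) {
  theta <- theta %||% subject$fibres$theta_deg
  bc_mode <- bc_mode %||% subject$bcs$mode
  fib <- if (theta == subject$fibres$theta_deg) subject$fibres
         else fibre_field(subject$mesh, subject$s, theta)
  bcs <- subject$bcs
  bcs$mode <- bc_mode
  lv_model(subject$mesh, fib, bcs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameter-ratio sweep
#'
#' Runs one forward diastolic simulation per grid value of gamma = a / a_f
#' (a = gamma * a_f_sim, a_f = a_f_sim fixed), records the objective and the
#' simulated end-diastolic pressure, and selects the grid minimiser (ties
#' broken towards smaller gamma). Non-converged runs are scored +Inf and
#' excluded from the argmin. If the subject carries an EDP estimate the
#' absolute parameters are recovered via [scale_parameters()].
#'
#' @param subject an `lv_subject` (or compatible list with mesh, s, fibres,
#'   bcs, motion, and optionally `edp_est_mmhg`).
#' @param gamma_grid positive ratio values (default [lv_gamma_grid()]).
#' @param a_f_sim fibre stiffness held fixed during sweeps (Pa).
#' @param theta,bc_mode optional overrides of the subject's fibre angle /
#'   epicardial boundary mode for sensitivity studies.
#' @param b,b_f fixed exponents.
#' @param warm_start initialize each run from the previous grid value's
#'   converged trajectory (accelerates sweeps; runs are independent by
#'   default).
#' @param control solver tolerances.
#' @return object of class `lv_sweep`: per-run table `runs`, `gamma_hat`,
#'   `J_min`, `variation`, `lambda_ED_Pa` at the minimiser, rescaled `a_Pa`
#'   and `a_f_Pa` (if an EDP estimate is available), and bookkeeping needed
#'   by [refine_sweep()].
#' @export
parameter_sweep <- function(subject, gamma_grid = lv_gamma_grid(),
                            a_f_sim = 1000, theta = NULL, bc_mode = NULL,
                            b = 5, b_f = 5, warm_start = FALSE,
                            control = default_control()) {
  if (length(gamma_grid) < 1 || any(gamma_grid <= 0))
    stop("gamma grid must be non-empty and positive")
  model <- build_case_model(subject, theta, bc_mode)
  runs <- sweep_runs(model, subject$motion, gamma_grid, a_f_sim, b, b_f,
                     control, warm_start)
  finalize_sweep(runs, subject, model, a_f_sim,
                 settings = list(theta = theta, bc_mode = bc_mode,
                                 b = b, b_f = b_f, control = control,
                                 warm_start = warm_start))
}

sweep_runs <- function(model, motion, gamma_grid, a_f_sim, b, b_f, control,
                       warm_start = FALSE) {
  prev_traj <- NULL
  out <- lapply(sort(gamma_grid), function(g) {
    params <- material_parameters(a = g * a_f_sim, a_f = a_f_sim, b = b, b_f = b_f)
    traj <- tryCatch(simulate_diastole(model, params, motion, control,
                                       guess = if (warm_start) prev_traj),
                     error = function(e) e)
    if (inherits(traj, "error"))
      return(data.frame(gamma = g, J = Inf, lambda_ED_Pa = NA_real_,
                        converged = FALSE, newton_iters = NA_integer_,
                        max_detF_dev = NA_real_))
    if (warm_start) prev_traj <<- traj
    data.frame(gamma = g,
               J = objective_function(traj, motion, model),
               lambda_ED_Pa = traj$lambda_ED, converged = TRUE,
               newton_iters = sum(traj$newton_iters),
               max_detF_dev = max(traj$max_detF_dev))
  })
  do.call(rbind, out)
}

finalize_sweep <- function(runs, subject, model, a_f_sim, settings) {
  runs <- runs[order(runs$gamma), , drop = FALSE]
  rownames(runs) <- NULL
  if (!any(is.finite(runs$J))) stop("all sweep runs failed to converge")
  fin <- which(is.finite(runs$J))
  ibest <- fin[which.min(runs$J[fin])]   # which.min takes the first = smallest gamma
  gamma_hat <- runs$gamma[ibest]
  lam <- runs$lambda_ED_Pa[ibest]
  res <- list(runs = runs, gamma_hat = gamma_hat, J_min = runs$J[ibest],
              variation = max(runs$J[fin]) - min(runs$J[fin]),
              lambda_ED_Pa = lam, a_f_sim = a_f_sim,
              a_sim_hat = gamma_hat * a_f_sim,
              a_Pa = NA_real_, a_f_Pa = NA_real_,
              subject = subject, settings = settings)
  if (!is.null(subject$edp_est_mmhg) && is.finite(lam) && lam > 0) {
    sc <- scale_parameters(gamma_hat, a_f_sim, lam,
                           mmhg_to_pa(subject$edp_est_mmhg))
    res$a_Pa <- sc[["a"]]; res$a_f_Pa <- sc[["a_f"]]
  }
  res$unique_minimum <- if (nrow(runs) >= 3)
    identifiability_report(res)$unique_minimum else NA
  structure(res, class = "lv_sweep")
}

#' Refine a sweep around its minimiser
#'
#' Adds `n_extra` gamma values spanning one coarse grid step either side of
#' the current estimate and re-selects the minimum; the refined minimum can
#' only improve (superset of evaluations).
#'
#' @param result an `lv_sweep`.
#' @param n_extra number of additional values (0 returns the input unchanged).
#' @return an updated `lv_sweep`.
#' @export
refine_sweep <- function(result, n_extra = 8) {
  stopifnot(inherits(result, "lv_sweep"))
  if (n_extra == 0) return(result)
  g <- result$runs$gamma
  step <- if (length(g) > 1) stats::median(diff(sort(g))) else 0.1 * result$gamma_hat
  lo <- max(result$gamma_hat - step, 1e-6)
  newg <- setdiff(round(seq(lo, result$gamma_hat + step,
                            length.out = n_extra + 2), 12),
                  round(g, 12))
  if (!length(newg)) return(result)
  s <- result$settings
  model <- build_case_model(result$subject, s$theta, s$bc_mode)
  extra <- sweep_runs(model, result$subject$motion, newg, result$a_f_sim,
                      s$b, s$b_f, s$control, s$warm_start %||% FALSE)
  finalize_sweep(rbind(result$runs, extra), result$subject, model,
                 result$a_f_sim, s)
}

#' Rescale sweep estimates to absolute stiffness
#'
#' a_f = a_f_sim * EDP_est / lambda_ED and a = gamma_hat * a_f: because joint
#' scaling of (a, a_f) scales the simulated filling pressure proportionally
#' without changing displacements, matching the simulated end-diastolic
#' multiplier to the estimated end-diastolic pressure fixes the absolute
#' scale. The ratio a / a_f = gamma_hat is left exactly unchanged.
#'
#' @param gamma_hat estimated ratio.
#' @param a_f_sim fibre stiffness used in the sweep (Pa).
#' @param lambda_ED simulated end-diastolic pressure at the minimiser (Pa).
#' @param edp_est estimated end-diastolic pressure (Pa).
#' @return named vector c(a = , a_f = ) in Pa.
#' @export
scale_parameters <- function(gamma_hat, a_f_sim, lambda_ED, edp_est) {
  if (!(lambda_ED > 0) || !(edp_est > 0))
    stop("end-diastolic pressures must be positive")
  a_f <- a_f_sim * edp_est / lambda_ED
  c(a = gamma_hat * a_f, a_f = a_f)
}

#' Identifiability diagnostics of a sweep
#'
#' Characterizes the objective curve over the gamma grid: minimum value and
#' position, min-max variation, a local second-difference curvature estimate
#' at the minimiser, and whether the grid carries exactly one strict local
#' minimum.
#'
#' @param result an `lv_sweep` (or list with a `runs` data frame).
#' @return list with `J_min`, `gamma_hat`, `variation`, `curvature`,
#'   `unique_minimum`.
#' @export
identifiability_report <- function(result) {
  runs <- result$runs
  if (nrow(runs) < 3) stop("need at least 3 grid points")
  J <- runs$J; g <- runs$gamma
  fin <- is.finite(J)
  Jf <- J[fin]; gf <- g[fin]
  ibest <- which.min(Jf)
  # strict local minima on the grid (boundary points count if strictly
  # below their single neighbour)
  nloc <- 0L
  nn <- length(Jf)
  for (i in seq_len(nn)) {
    below_left <- i == 1 || Jf[i] < Jf[i - 1]
    below_right <- i == nn || Jf[i] < Jf[i + 1]
    if (nn > 1 && below_left && below_right) nloc <- nloc + 1L
  }
  curv <- NA_real_
  if (ibest > 1 && ibest < length(Jf)) {
    h1 <- gf[ibest] - gf[ibest - 1]; h2 <- gf[ibest + 1] - gf[ibest]
    curv <- 2 * (h1 * Jf[ibest + 1] + h2 * Jf[ibest - 1] -
                 (h1 + h2) * Jf[ibest]) / (h1 * h2 * (h1 + h2))
  }
  variation <- max(Jf) - min(Jf)
  list(J_min = min(Jf), gamma_hat = gf[ibest], variation = variation,
       curvature = curv, unique_minimum = nloc == 1L && variation > 0)
}

#' Rebase a subject onto a later data frame
#'
#' Treats the deformed geometry of the chosen data frame as a new stress-free
#' reference configuration: vertices are displaced by the data, the
#' transmural coordinate and fibre field are rebuilt, and the remaining data
#' frames are expressed relative to the new reference. No unloading is
#' attempted.
#'
#' @param subject an `lv_subject`.
#' @param frame_offset number of frames after the end-systolic reference
#'   (0 returns the subject unchanged).
#' @return a rebased `lv_subject`.
#' @export
rebase_subject <- function(subject, frame_offset) {
  if (frame_offset == 0) return(subject)
  f <- 1L + frame_offset
  N <- subject$motion$n_frames
  if (f >= N) stop("missing frames for rebasing: need frames ",
                   paste(seq(f, N), collapse = ", "), " beyond the reference")
  mesh <- subject$mesh
  udf <- subject$motion$ud[, f]
  Vnew <- mesh$X[, 1:mesh$nv] + matrix(udf, nrow = 3)[, 1:mesh$nv]
  newmesh <- lv_mesh_from_arrays(Vnew, mesh$tets, node_layer = mesh$node_layer,
                                 base_z = mean(Vnew[3, mesh$ring[mesh$ring <= mesh$nv]]),
                                 tags = mesh$boundary_tags, ring = mesh$ring,
                                 params = mesh$params)
  s <- transmural_coordinate(newmesh)
  fib <- fibre_field(newmesh, s, subject$fibres$theta_deg)

  keep <- f:N
  m <- subject$motion
  ud <- m$ud[, keep, drop = FALSE] - m$ud[, f]
  ud_b <- m$ud_b[, keep, drop = FALSE] - m$ud_b[, f]
  ud_e <- m$ud_e[, keep, drop = FALSE] - m$ud_e[, f]
  vol <- m$vol[keep]
  vol[1] <- cavity_volume(newmesh)
  motion <- structure(list(times = m$times[keep], vol = vol,
                           n_frames = length(keep), ud = ud,
                           ud_b = ud_b, ud_e = ud_e,
                           base_nodes = m$base_nodes, epi_nodes = m$epi_nodes),
                      class = "lv_motion")
  out <- subject
  out$mesh <- newmesh; out$s <- s; out$fibres <- fib; out$motion <- motion
  out$reference_frame_offset <- frame_offset
  out
}

#' Fibre-angle / boundary-condition / reference-frame sensitivity study
#'
#' Full factorial table of sweeps over the requested fibre angles, epicardial
#' boundary modes and reference frames, with min-max normalized objective and
#' ratio estimates across the fibre angles of each (mode, frame) case.
#'
#' @param subject an `lv_subject`.
#' @param thetas fibre angles in degrees.
#' @param bc_modes epicardial modes, subset of c("NT", "RV").
#' @param ref_frames reference frame offsets after end-systole.
#' @param gamma_grid,a_f_sim,warm_start,control passed to [parameter_sweep()].
#' @return object of class `lv_sensitivity`: `table` (one row per case) and
#'   the underlying `sweeps`.
#' @export
sensitivity_study <- function(subject, thetas = c(50, 60, 70),
                              bc_modes = c("NT", "RV"), ref_frames = 0,
                              gamma_grid = lv_gamma_grid(), a_f_sim = 1000,
                              warm_start = FALSE,
                              control = default_control()) {
  rows <- list(); sweeps <- list()
  for (rf in ref_frames) {
    sub_rf <- rebase_subject(subject, rf)
    for (bc in bc_modes) for (th in thetas) {
      sw <- parameter_sweep(sub_rf, gamma_grid, a_f_sim, theta = th,
                            bc_mode = bc, warm_start = warm_start,
                            control = control)
      key <- sprintf("theta%g_%s_f%d", th, bc, rf)
      sweeps[[key]] <- sw
      rows[[key]] <- data.frame(theta_deg = th, bc_mode = bc, ref_frame = rf,
                                gamma_hat = sw$gamma_hat, J_min = sw$J_min,
                                variation = sw$variation,
                                lambda_ED_Pa = sw$lambda_ED_Pa,
                                a_Pa = sw$a_Pa, a_f_Pa = sw$a_f_Pa)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(NA_real_, length(x)) else (x - r[1]) / diff(r)
  }
  tab$J_min_norm <- NA_real_; tab$gamma_hat_norm <- NA_real_
  for (bc in unique(tab$bc_mode)) for (rf in unique(tab$ref_frame)) {
    i <- tab$bc_mode == bc & tab$ref_frame == rf
    if (sum(i) > 1) {
      tab$J_min_norm[i] <- norm01(tab$J_min[i])
      tab$gamma_hat_norm[i] <- norm01(tab$gamma_hat[i])
    }
  }
  structure(list(table = tab, sweeps = sweeps), class = "lv_sensitivity")
}
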