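# Image-derived clinical LV metrics (volumes, ejection fraction, wall
# thickness, shape indices, the E/Ea pressure surrogate) and group
# comparison by unpaired t-tests.

#' Reference cohort table of global LV indices
#'
#' Per-subject global indices for a published cohort of 5 healthy volunteers
#' and 3 non-ischemic dilated-cardiomyopathy patients: end-diastolic /
#' end-systolic volume, stroke volume, ejection fraction, wall thickness at
#' end diastole and end systole, long-axis to short-axis ratio, and the
#' E/Ea-derived end-diastolic pressure estimate. Used as worked examples for
#' the metric computations and group statistics.
#'
#' @return a data.frame with one row per subject.
#' @export
lv_reference_cohort <- function() {
  data.frame(
    case = c("V1", "V2", "V3", "V4", "V5", "P1", "P2", "P3"),
    group = rep(c("volunteer", "dcm"), c(5, 3)),
    age = c(28, 29, 48, 35, 41, 28, 55, 43),
    sex = c("M", "F", "M", "F", "M", "F", "M", "F"),
    edv_ml = c(129.5, 100.9, 152.6, 93.2, 120.4, 141.1, 179.3, 136.2),
    esv_ml = c(64.6, 47.7, 67.4, 46.0, 53.5, 81.9, 95.2, 79.9),
    sv_ml = c(64.9, 53.2, 85.1, 47.2, 66.9, 59.2, 84.1, 56.3),
    ef = c(0.50, 0.53, 0.56, 0.51, 0.56, 0.42, 0.47, 0.41),
    wt_ed_mm = c(8.03, 7.09, 8.73, 6.58, 8.38, 7.92, 7.94, 6.54),
    wt_es_mm = c(10.61, 9.07, 12.1, 8.74, 11.38, 10.11, 10.33, 8.24),
    la_sa = c(1.35, 1.59, 1.40, 1.59, 1.33, 1.23, 1.21, 1.24),
    edp_est_mmhg = c(10.5, 16.1, 10.2, 8.8, 11.4, 16.3, 17.6, 11.6))
}

#' Cavity volumes and ejection fraction from a volume trace
#'
#' @param volume_trace cavity volumes over a full cycle (ml), positive.
#' @return list with `edv`, `esv`, `sv` (ml) and `ef`.
#' @export
volumes_and_ef <- function(volume_trace) {
  if (!length(volume_trace) || any(volume_trace < 0))
    stop("volume trace must be non-empty and non-negative")
  edv <- max(volume_trace); esv <- min(volume_trace)
  if (edv <= 0) stop("zero end-diastolic volume")
  list(edv = edv, esv = esv, sv = edv - esv, ef = (edv - esv) / edv)
}

#' Mean wall thickness from transmural rays
#'
#' Mean endocardium-to-epicardium distance along rays cast from endocardial
#' facet centroids in the equatorial band (mid 50% of the deformed long-axis
#' extent), along the local endocardial surface normal. Rays that miss the
#' epicardium are skipped (with a warning above 10% misses).
#'
#' @param mesh an `lv_mesh`.
#' @param u displacement vector at the frame of interest (default reference).
#' @return list with `mean_mm`, per-ray `samples_mm` and `n_skipped`.
#' @export
wall_thickness <- function(mesh, u = NULL) {
  endo <- boundary_subtris(mesh, 1L)   # oriented outward from the solid
  epi <- boundary_subtris(mesh, 2L)
  te <- tri_coords(mesh, endo, u)
  tp <- tri_coords(mesh, epi, u)
  cen <- (te[1:3, ] + te[4:6, ] + te[7:9, ]) / 3
  # band: mid 50% of the long-axis extent of the deformed endocardium
  zr <- range(te[c(3, 6, 9), ])
  band <- cen[3, ] >= zr[1] + 0.25 * diff(zr) & cen[3, ] <= zr[1] + 0.75 * diff(zr)
  e1 <- te[4:6, band, drop = FALSE] - te[1:3, band, drop = FALSE]
  e2 <- te[7:9, band, drop = FALSE] - te[1:3, band, drop = FALSE]
  nrml <- rbind(e1[2, ] * e2[3, ] - e1[3, ] * e2[2, ],
                e1[3, ] * e2[1, ] - e1[1, ] * e2[3, ],
                e1[1, ] * e2[2, ] - e1[2, ] * e2[1, ])
  # endocardial facets are oriented outward from the wall (into the cavity);
  # flip to walk from endo- towards epicardium
  nrml <- -sweep(nrml, 2, sqrt(colSums(nrml^2)), "/")
  t_hit <- ray_surface_hits(cen[, band, drop = FALSE], nrml, tp)
  ok <- is.finite(t_hit)
  if (mean(!ok) > 0.10)
    warning(sprintf("%.0f%% of thickness rays missed the epicardium", 100 * mean(!ok)))
  list(mean_mm = mean(t_hit[ok]) * 1e3, samples_mm = t_hit[ok] * 1e3,
       n_skipped = sum(!ok))
}

#' Wall thickening ratio
#'
#' (t_ES - t_ED) / t_ES from end-diastolic and end-systolic thicknesses.
#'
#' @param t_ed,t_es thicknesses in consistent units.
#' @return dimensionless ratio.
#' @export
wall_thickening_ratio <- function(t_ed, t_es) (t_es - t_ed) / t_es

endo_nodes_of <- function(mesh) {
  unique(as.vector(mesh$boundary_tris[, mesh$boundary_tags == 1L, drop = FALSE]))
}

la_sa_of <- function(mesh, u) {
  x <- mesh$X + matrix(u, nrow = 3)
  en <- endo_nodes_of(mesh)
  apex <- en[which.min(mesh$X[3, en])]
  bc <- rowMeans(x[, mesh$ring, drop = FALSE])
  la <- sqrt(sum((x[, apex] - bc)^2))
  axis <- (x[, apex] - bc); axis <- axis / sqrt(sum(axis^2))
  rel <- x[, en, drop = FALSE] - bc
  proj <- colSums(rel * axis)
  perp <- sqrt(pmax(colSums(rel^2) - proj^2, 0))
  list(la = la, sa = 2 * max(perp))
}

#' LV shape metrics
#'
#' Long-axis length (apex to basal endocardial centroid), maximum endocardial
#' short-axis diameter perpendicular to the long axis, their ratio at end
#' diastole, and the normalized long-axis shortening
#' (LA_ED - LA_ES) / LA_ED.
#'
#' @param mesh an `lv_mesh`.
#' @param u_ed displacement at end diastole.
#' @param u_es displacement at end systole (default zero = reference frame).
#' @return list with `la_ed_mm`, `sa_ed_mm`, `la_sa`, `long_axis_shortening`.
#' @export
shape_metrics <- function(mesh, u_ed, u_es = NULL) {
  if (is.null(u_es)) u_es <- numeric(3 * mesh$nq)
  ed <- la_sa_of(mesh, u_ed)
  es <- la_sa_of(mesh, u_es)
  list(la_ed_mm = ed$la * 1e3, sa_ed_mm = ed$sa * 1e3,
       la_sa = ed$la / ed$sa,
       long_axis_shortening = (ed$la - es$la) / ed$la)
}

#' Non-invasive end-diastolic pressure estimate
#'
#' Nagueh-type surrogate from the mitral inflow / annular velocity ratio:
#' EDP_est = 1.24 (E / Ea) + 1.9 mmHg.
#'
#' @param E peak early diastolic transmitral flow velocity (m/s).
#' @param Ea early diastolic mitral annulus velocity (m/s), > 0.
#' @return estimated end-diastolic pressure in mmHg.
#' @export
estimate_edp <- function(E, Ea) {
  if (any(Ea <= 0)) stop("annular velocity Ea must be positive")
  1.24 * (E / Ea) + 1.9
}

#' Two-group comparison of a clinical metric
#'
#' Per-group mean and sample standard deviation (n - 1 denominator) and a
#' classical pooled-variance two-sided unpaired t-test.
#'
#' @param values numeric metric values, one per subject.
#' @param groups group labels (exactly two distinct values, each with >= 2
#'   subjects).
#' @return list with per-group `mean`, `sd`, `n`, and `t`, `df`, `p`.
#' @export
group_compare <- function(values, groups) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) != 2) stop("need exactly two groups")
  v1 <- values[groups == gl[1]]; v2 <- values[groups == gl[2]]
  if (length(v1) < 2 || length(v2) < 2)
    stop("each group needs at least 2 subjects")
  df <- length(v1) + length(v2) - 2
  sp2 <- ((length(v1) - 1) * stats::var(v1) + (length(v2) - 1) * stats::var(v2)) / df
  if (sp2 == 0) {
    # degenerate zero-variance case: identical groups are indistinguishable
    tt <- list(statistic = c(t = if (mean(v1) == mean(v2)) 0 else Inf),
               parameter = c(df = df),
               p.value = if (mean(v1) == mean(v2)) 1 else 0)
  } else {
    tt <- t.test(v1, v2, var.equal = TRUE)
  }
  out <- list(groups = gl,
              mean = c(mean(v1), mean(v2)), sd = c(sd(v1), sd(v2)),
              n = c(length(v1), length(v2)),
              t = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value)
  names(out$mean) <- names(out$sd) <- names(out$n) <- gl
  out
}
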