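# File I/O and configuration: ascii VTU meshes with tagged boundary
# surfaces and nodal fields, CSV traces and sweep tables, JSON sidecars and
# summaries, and a YAML run configuration with validated defaults. These
# functions back the numbered analysis scripts, which are the package's
# command-line surface.

vtu_data_array <- function(name, values, ncomp, type = "Float64") {
  sprintf('<DataArray type="%s" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
          type, name, ncomp,
          paste(formatC(values, format = if (type == "Float64") "g" else "d",
                        digits = 17), collapse = " "))
}

#' Write an unstructured-grid VTU file
#'
#' Writes points, cells and optional point-data arrays as ascii XML VTU.
#'
#' @param points 3 x n matrix.
#' @param cells integer matrix, one cell per column (1-based node ids).
#' @param cell_type VTK cell type id (10 linear tet, 24 quadratic tet,
#'   5 triangle, 22 quadratic triangle).
#' @param file output path.
#' @param point_data named list of nodal arrays (vectors or 3 x n matrices).
#' @param cell_data named list of integer per-cell arrays.
#' @return the file path, invisibly.
#' @export
write_vtu <- function(points, cells, cell_type, file,
                      point_data = list(), cell_data = list()) {
  np <- ncol(points); ncell <- ncol(cells); npc <- nrow(cells)
  pd <- paste(vapply(names(point_data), function(nm) {
    v <- point_data[[nm]]
    if (is.matrix(v)) vtu_data_array(nm, as.vector(v), nrow(v))
    else vtu_data_array(nm, v, 1L)
  }, ""), collapse = "\n")
  cd <- paste(vapply(names(cell_data), function(nm) {
    vtu_data_array(nm, as.integer(cell_data[[nm]]), 1L, type = "Int32")
  }, ""), collapse = "\n")
  xml <- sprintf(
'<?xml version="1.0"?>
<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">
<UnstructuredGrid>
<Piece NumberOfPoints="%d" NumberOfCells="%d">
<Points>
%s
</Points>
<Cells>
%s
%s
%s
</Cells>
<PointData>
%s
</PointData>
<CellData>
%s
</CellData>
</Piece>
</UnstructuredGrid>
</VTKFile>', np, ncell,
    vtu_data_array("Points", as.vector(points), 3L),
    vtu_data_array("connectivity", as.integer(cells) - 1L, 1L, "Int32"),
    vtu_data_array("offsets", as.integer(seq_len(ncell) * npc), 1L, "Int32"),
    vtu_data_array("types", rep(as.integer(cell_type), ncell), 1L, "UInt8"),
    pd, cd)
  writeLines(xml, file)
  invisible(file)
}

#' Read an ascii VTU file written by [write_vtu()]
#'
#' @param file path.
#' @return list with `points` (3 x n), `cells` (matrix, 1-based),
#'   `cell_type`, `point_data`, `cell_data`.
#' @export
read_vtu <- function(file) {
  doc <- xml2::read_xml(file)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  get <- function(name, parent) {
    nd <- xml2::xml_find_first(doc, sprintf(".//%s/DataArray[@name]", parent))
    for (a in arrays) {
      if (xml2::xml_attr(a, "Name") == name) {
        anc <- xml2::xml_name(xml2::xml_parent(a))
        if (anc == parent || name %in% c("connectivity", "offsets", "types", "Points"))
          return(list(vals = scan(text = xml2::xml_text(a), quiet = TRUE),
                      ncomp = as.integer(xml2::xml_attr(a, "NumberOfComponents"))))
      }
    }
    NULL
  }
  pts <- get("Points", "Points")
  conn <- get("connectivity", "Cells")$vals + 1
  off <- get("offsets", "Cells")$vals
  types <- get("types", "Cells")$vals
  npc <- off[1]
  cells <- matrix(as.integer(conn), nrow = npc)
  pd <- list(); cd <- list()
  for (a in arrays) {
    nm <- xml2::xml_attr(a, "Name")
    parent <- xml2::xml_name(xml2::xml_parent(a))
    if (parent == "PointData") {
      nc <- as.integer(xml2::xml_attr(a, "NumberOfComponents"))
      v <- scan(text = xml2::xml_text(a), quiet = TRUE)
      pd[[nm]] <- if (nc > 1) matrix(v, nrow = nc) else v
    } else if (parent == "CellData") {
      cd[[nm]] <- as.integer(scan(text = xml2::xml_text(a), quiet = TRUE))
    }
  }
  list(points = matrix(pts$vals, nrow = 3), cells = cells,
       cell_type = types[1], point_data = pd, cell_data = cd)
}

#' Write an LV mesh (volume + tagged surface) to VTU
#'
#' Writes the quadratic tetrahedral mesh with optional nodal fields, plus a
#' companion `<stem>_surface.vtu` holding the quadratic boundary triangles
#' with the integer cell field `surface_tag` (1 endocardium, 2 epicardium,
#' 3 base).
#'
#' @param mesh an `lv_mesh`.
#' @param stem output path stem (without extension).
#' @param point_data named list of nodal arrays (e.g. fibre, transmural_s, H).
#' @return paths of the written files, invisibly.
#' @export
write_lv_mesh <- function(mesh, stem, point_data = list()) {
  f1 <- paste0(stem, ".vtu")
  f2 <- paste0(stem, "_surface.vtu")
  write_vtu(mesh$X, mesh$tet10, 24L, f1, point_data = point_data)
  write_vtu(mesh$X, mesh$boundary_tris, 22L, f2,
            cell_data = list(surface_tag = mesh$boundary_tags))
  invisible(c(f1, f2))
}

#' Read an LV mesh written by [write_lv_mesh()]
#'
#' Rebuilds the full mesh structure from the volume and surface files.
#'
#' @param stem path stem used when writing.
#' @return an `lv_mesh`.
#' @export
read_lv_mesh <- function(stem) {
  vol <- read_vtu(paste0(stem, ".vtu"))
  surf <- read_vtu(paste0(stem, "_surface.vtu"))
  nv <- max(vol$cells[1:4, ])
  tags <- surf$cell_data$surface_tag
  base_nodes <- unique(as.vector(surf$cells[, tags == 3L]))
  lv_mesh_from_arrays(vol$points[, 1:nv, drop = FALSE],
                      vol$cells[1:4, , drop = FALSE],
                      node_layer = NULL,
                      base_z = stats::median(vol$points[3, base_nodes]),
                      tags = tags)
}

#' Write a synthetic subject to a directory
#'
#' Reference mesh (VTU), per-frame displacement data (VTU point data `u_d`),
#' the cavity-volume trace (CSV) and a JSON sidecar with ground truth, EDP
#' surrogate velocities, preset and seed.
#'
#' @param subject an `lv_subject`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lv_mesh(subject$mesh, file.path(dir, "reference"),
                point_data = list(fibre = subject$fibres$f0,
                                  transmural_s = subject$s$s))
  m <- subject$motion
  for (n in seq_len(m$n_frames)) {
    write_vtu(subject$mesh$X, subject$mesh$tet10, 24L,
              file.path(dir, sprintf("frame_%03d.vtu", n)),
              point_data = list(u_d = matrix(m$ud[, n], nrow = 3)))
  }
  write.csv(data.frame(frame = seq_len(m$n_frames), time_s = m$times,
                       volume_ml = m$vol * 1e6),
            file.path(dir, "volume_trace.csv"), row.names = FALSE)
  side <- list(group = subject$group, E_m_per_s = subject$E,
               Ea_m_per_s = subject$Ea, edp_est_mmhg = subject$edp_est_mmhg,
               truth = subject$truth,
               preset = unclass(subject$preset),
               base_nodes = m$base_nodes, epi_nodes = m$epi_nodes,
               ud_b = as.vector(m$ud_b), ud_e = as.vector(m$ud_e),
               n_frames = m$n_frames)
  jsonlite::write_json(side, file.path(dir, "subject.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a subject directory written by [write_subject()]
#'
#' @param dir subject directory.
#' @return an `lv_subject`.
#' @export
read_subject <- function(dir) {
  mesh <- read_lv_mesh(file.path(dir, "reference"))
  side <- jsonlite::read_json(file.path(dir, "subject.json"), simplifyVector = TRUE)
  trace <- read.csv(file.path(dir, "volume_trace.csv"))
  N <- side$n_frames
  ud <- matrix(0, 3 * mesh$nq, N)
  for (n in seq_len(N)) {
    fr <- read_vtu(file.path(dir, sprintf("frame_%03d.vtu", n)))
    ud[, n] <- as.vector(fr$point_data$u_d)
  }
  motion <- structure(list(times = trace$time_s, vol = trace$volume_ml * 1e-6,
                           n_frames = N, ud = ud,
                           ud_b = matrix(side$ud_b, ncol = N),
                           ud_e = matrix(side$ud_e, ncol = N),
                           base_nodes = side$base_nodes,
                           epi_nodes = side$epi_nodes), class = "lv_motion")
  s <- transmural_coordinate(mesh)
  fib <- fibre_field(mesh, s, side$truth$theta_deg)
  structure(list(mesh = mesh, s = s, fibres = fib,
                 bcs = boundary_spec(mode = side$truth$bc_mode),
                 motion = motion, group = side$group,
                 preset = do.call(subject_preset,
                                  c(list(group = side$group))),
                 E = side$E_m_per_s, Ea = side$Ea_m_per_s,
                 edp_est_mmhg = side$edp_est_mmhg, truth = side$truth),
            class = "lv_subject")
}

#' Write a sweep result as CSV + JSON summary
#'
#' @param sweep an `lv_sweep`.
#' @param stem output path stem.
#' @param theta_deg,bc_mode,ref_frame annotations for the CSV rows.
#' @return written paths, invisibly.
#' @export
write_sweep <- function(sweep, stem, theta_deg = NA, bc_mode = NA, ref_frame = 0) {
  runs <- sweep$runs
  tab <- data.frame(theta_deg = theta_deg, bc_mode = bc_mode,
                    ref_frame = ref_frame, gamma = runs$gamma,
                    J_obj = runs$J, lambda_ED_Pa = runs$lambda_ED_Pa,
                    lambda_ED_mmHg = pa_to_mmhg(runs$lambda_ED_Pa),
                    converged = runs$converged)
  f1 <- paste0(stem, ".csv"); f2 <- paste0(stem, ".json")
  write.csv(tab, f1, row.names = FALSE)
  jsonlite::write_json(list(gamma_hat = sweep$gamma_hat, J_min = sweep$J_min,
                            variation = sweep$variation,
                            lambda_ED_Pa = sweep$lambda_ED_Pa,
                            a_Pa = sweep$a_Pa, a_f_Pa = sweep$a_f_Pa,
                            unique_minimum = sweep$unique_minimum),
                       f2, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2))
}

lv_default_config <- function() {
  list(
    geometry = list(target_h = 0.005, truncation_fraction = 0.75),
    material = list(a_f_sim = 1000, b = 5, b_f = 5,
                    gamma_grid = list(n = 23, lo = 0.3, hi = 2)),
    bcs = list(mode = "RV", eps_e = 5e-6, eps_b = 5e-6,
               H_azimuth_center = 180, H_half_width = 60, H_transition = 15),
    estimation = list(n_refine = 8, thetas = c(50, 60, 70),
                      ref_frames = c(0, 2, 4)),
    synthetic = list(preset = "volunteer", seed = 1, sigma_mm = 0.5,
                     n_frames = 10),
    output_dir = "results")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration and merges it over the package defaults, which
#' reproduce the reference analysis choices (b = b_f = 5, eps_e = 5e-6,
#' 23-point gamma grid between 0.3 and 2, theta in {50, 60, 70} degrees,
#' a_f_sim = 1000 Pa). Unknown keys and out-of-range values are rejected.
#'
#' @param file YAML path, or NULL for pure defaults.
#' @return validated configuration list.
#' @export
lv_config <- function(file = NULL) {
  cfg <- lv_default_config()
  if (!is.null(file)) {
    user <- yaml::read_yaml(file)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown config blocks: ", paste(bad, collapse = ", "))
    for (blk in names(user)) {
      if (is.list(cfg[[blk]])) {
        badk <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
        if (length(badk))
          stop("unknown keys in '", blk, "': ", paste(badk, collapse = ", "))
        cfg[[blk]][names(user[[blk]])] <- user[[blk]]
      } else cfg[[blk]] <- user[[blk]]
    }
  }
  with(cfg, {
    stopifnot(geometry$target_h > 0,
              material$a_f_sim > 0, material$b > 0, material$b_f > 0,
              material$gamma_grid$lo > 0,
              material$gamma_grid$hi > material$gamma_grid$lo,
              bcs$mode %in% c("NT", "RV"), bcs$eps_e > 0, bcs$eps_b > 0,
              synthetic$preset %in% c("volunteer", "dcm"),
              synthetic$sigma_mm >= 0, synthetic$n_frames >= 2)
    if (any(estimation$thetas <= 0 | estimation$thetas >= 90))
      stop("config: fibre angles must lie in (0, 90) degrees")
  })
  cfg
}

#' Generate a subject from a configuration and write it to disk
#'
#' @param cfg an [lv_config()] list.
#' @param dir output directory (default under the config's output_dir).
#' @param ... resolution overrides passed to [generate_subject()].
#' @return the subject, invisibly.
#' @export
run_generate <- function(cfg, dir = file.path(cfg$output_dir, "subject"), ...) {
  preset <- subject_preset(cfg$synthetic$preset,
                           bc_mode = cfg$bcs$mode,
                           n_frames = cfg$synthetic$n_frames,
                           target_h = cfg$geometry$target_h,
                           truncation = cfg$geometry$truncation_fraction)
  subj <- generate_subject(preset, seed = cfg$synthetic$seed, ...)
  if (cfg$synthetic$sigma_mm > 0)
    subj <- add_displacement_noise(subj, cfg$synthetic$sigma_mm,
                                   seed = cfg$synthetic$seed + 1000L)
  write_subject(subj, dir)
  message(sprintf("subject '%s' (seed %d): %d frames, gamma* = %.3g, EDP %.1f mmHg -> %s",
                  subj$group, cfg$synthetic$seed, subj$motion$n_frames,
                  subj$truth$gamma, subj$edp_est_mmhg, dir))
  invisible(subj)
}

#' Run a sweep (with refinement) for a subject per configuration
#'
#' @param cfg an [lv_config()] list.
#' @param subject an `lv_subject` (or directory to read).
#' @param stem output stem for CSV/JSON (NULL to skip writing).
#' @return the refined `lv_sweep`, invisibly.
#' @export
run_sweep <- function(cfg, subject, stem = file.path(cfg$output_dir, "sweep")) {
  if (is.character(subject)) subject <- read_subject(subject)
  gg <- with(cfg$material$gamma_grid, lv_gamma_grid(n, lo, hi))
  sw <- parameter_sweep(subject, gg, a_f_sim = cfg$material$a_f_sim,
                        b = cfg$material$b, b_f = cfg$material$b_f)
  if (cfg$estimation$n_refine > 0) sw <- refine_sweep(sw, cfg$estimation$n_refine)
  if (!is.null(stem)) write_sweep(sw, stem)
  message(sprintf("sweep: gamma_hat = %.4g, J_min = %.4g, a = %.1f Pa, a_f = %.1f Pa",
                  sw$gamma_hat, sw$J_min, sw$a_Pa, sw$a_f_Pa))
  invisible(sw)
}

#' Tabulate clinical metrics for subjects and compare groups
#'
#' @param subjects list of `lv_subject`s.
#' @param file optional CSV output path.
#' @return list with the per-subject `table` and, when two groups are
#'   present, `comparisons` of each metric.
#' @export
run_metrics <- function(subjects, file = NULL) {
  rows <- lapply(subjects, function(s) {
    ve <- volumes_and_ef(s$motion$vol * 1e6)
    N <- s$motion$n_frames
    wt_es <- wall_thickness(s$mesh)                       # reference = ES
    wt_ed <- wall_thickness(s$mesh, s$motion$ud[, N])
    sh <- shape_metrics(s$mesh, s$motion$ud[, N])
    data.frame(group = s$group, edv_ml = ve$edv, esv_ml = ve$esv,
               sv_ml = ve$sv, ef = ve$ef,
               wt_ed_mm = wt_ed$mean_mm, wt_es_mm = wt_es$mean_mm,
               thickening_ratio = wall_thickening_ratio(wt_ed$mean_mm, wt_es$mean_mm),
               la_sa = sh$la_sa,
               long_axis_shortening = sh$long_axis_shortening,
               edp_est_mmhg = estimate_eddp_safe(s))
  })
  tab <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(tab, file, row.names = FALSE)
  comparisons <- NULL
  if (length(unique(tab$group)) == 2 && all(table(tab$group) >= 2)) {
    metrics <- setdiff(names(tab), "group")
    comparisons <- lapply(setNames(metrics, metrics),
                          function(m2) group_compare(tab[[m2]], tab$group))
  }
  list(table = tab, comparisons = comparisons)
}

estimate_eddp_safe <- function(s) {
  if (!is.null(s$E) && !is.null(s$Ea)) estimate_edp(s$E, s$Ea)
  else s$edp_est_mmhg %||% NA_real_
}
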