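# Measured properties of a phantom: the construction targets of the disc
# complex are verified on actual cross-sections of the generated meshes,
# not read back from the input parameters.

#' Measure disc-complex area fractions on the L4/5 mid-height section
#'
#' Slices the annulus, nucleus and L5 vertebral body meshes and reports
#' - `nucleus_over_disc`: nucleus / (annulus + nucleus) cross-section area;
#' - `disc_over_vertebra`: disc-complex cross-section over the L5 body
#'   cross-section at its superior surface;
#' - `ap_offset_ratio`: (anterior annulus edge to nucleus centroid) /
#'   (posterior annulus edge to nucleus centroid) along the mid-sagittal
#'   line of the section plane.
#'
#' @param model an `anatomy_model`
#' @param level disc level, `"L4L5"` (default) or `"L3L4"`
#' @return named list with the three measures
#' @export
measure_area_fractions <- function(model, level = "L4L5") {
  fd <- model$frames[[paste0("disc_", level)]]
  if (is.null(fd)) stop("unknown disc level: ", level)
  axes <- rbind(fd$R[, 1], fd$R[, 2])
  plane <- list(point = fd$origin, normal = fd$R[, 3])

  ann <- region_mesh(model, paste0("disc_", level, "_annulus"))
  nuc <- region_mesh(model, paste0("disc_", level, "_nucleus"))
  loops_ann <- tryCatch(mesh_section(ann, plane, axes),
                        error = function(e) stop("section plane misses region 'annulus'"))
  loops_nuc <- tryCatch(mesh_section(nuc, plane, axes),
                        error = function(e) stop("section plane misses region 'nucleus'"))
  if (length(loops_ann) < 2)
    stop("annulus section did not produce an outer and an inner loop")
  A_disc <- loops_ann[[1]]$area
  A_nuc <- loops_nuc[[1]]$area

  # vertebral body cross-section just below the superior surface of the
  # caudal vertebra of this level
  vlev <- if (level == "L4L5") "L5" else "L4"
  cort <- region_mesh(model, paste0(vlev, "_cortical"))
  fv <- model$frames[[vlev]]
  vplane <- list(
    point = as.numeric(frame_to_world(fv, c(0, 0, model$params$body_height - 1.5))),
    normal = fv$R[, 3])
  loops_v <- mesh_section(cort, vplane, rbind(fv$R[, 1], fv$R[, 2]))
  A_vert <- loops_v[[1]]$area

  # mid-sagittal anterior/posterior edges of the disc outer boundary
  ys <- polygon_line_crossings(loops_ann[[1]]$xy, 0)
  y_ant <- max(ys); y_post <- min(ys)
  ctr <- polygon_centroid(loops_nuc[[1]]$xy)
  list(nucleus_over_disc = A_nuc / A_disc,
       disc_over_vertebra = A_disc / A_vert,
       ap_offset_ratio = (y_ant - ctr[2]) / (ctr[2] - y_post))
}

#' Median cortical shell thickness by ray casting
#'
#' Casts rays outward from the vertebral body axis at mid-height and
#' measures the distance between the cortical outer and inner (cancellous)
#' crossings.
#' @param model an `anatomy_model`
#' @param level vertebra, default "L4"
#' @param n_rays number of rays
#' @return median thickness (mm)
#' @export
measure_shell_thickness <- function(model, level = "L4", n_rays = 72) {
  p <- model$params
  f <- model$frames[[level]]
  sol_out <- model$regions[[paste0(level, "_cancellous")]]
  # outer boundary: cortical = outer minus cancellous; recover the outer
  # field by union of the two region solids
  sol_full <- solid_union(model$regions[[paste0(level, "_cortical")]], sol_out)
  th <- numeric(n_rays)
  zmid <- p$body_height / 2
  for (i in seq_len(n_rays)) {
    ang <- 2 * pi * (i - 1) / n_rays
    d <- c(cos(ang), sin(ang), 0)
    ray_r <- function(sol) {
      lo <- 0; hi <- p$body_width
      for (k in 1:50) {
        mid <- (lo + hi) / 2
        Pw <- frame_to_world(f, c(mid * d[1], mid * d[2], zmid))
        if (solid_field(sol, Pw) < 0) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    th[i] <- ray_r(sol_full) - ray_r(sol_out)
  }
  stats::median(th)
}

#' Export a phantom to disk
#'
#' Writes one STL (or PLY) per region named `<subject>_<region>.stl`,
#' landmarks as JSON, and the subject parameters as YAML.
#' @param model an `anatomy_model`
#' @param dir output directory (created if missing)
#' @param subject subject tag used in file names
#' @param format "stl" or "ply"
#' @param regions subset of region names (default: all)
#' @return invisibly, the vector of files written
#' @export
export_phantom <- function(model, dir, subject = "subject", format = c("stl", "ply"),
                           regions = names(model$regions)) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in regions) {
    m <- region_mesh(model, nm)
    path <- file.path(dir, sprintf("%s_%s.%s", subject, nm, format))
    if (format == "stl") write_stl(m, path, name = nm) else write_ply(m, path)
    files <- c(files, path)
  }
  lmpath <- file.path(dir, sprintf("%s_landmarks.json", subject))
  lm <- apply(model$landmarks, 1, identity, simplify = FALSE)
  jsonlite::write_json(lm, lmpath, auto_unbox = FALSE, digits = NA)
  ppath <- file.path(dir, sprintf("%s_params.yaml", subject))
  yaml::write_yaml(unclass(model$params), ppath)
  invisible(c(files, lmpath, ppath))
}

#' Load a user-supplied anatomy from surface meshes
#'
#' Accepts watertight STL/PLY meshes in place of the generated phantom.
#' Region solids are backed by ray-cast containment; operations that need
#' parametric structure (the finite-element mesher) require a generated
#' phantom instead.
#' @param paths named character vector: region name -> mesh file (ASCII STL)
#' @param landmarks optional named list/matrix of landmark points
#' @return an `anatomy_model` with mesh-backed regions
#' @export
anatomy_from_meshes <- function(paths, landmarks = NULL) {
  meshes <- lapply(paths, read_stl)
  for (nm in names(meshes))
    if (!mesh_is_watertight(meshes[[nm]]))
      stop("mesh for region '", nm, "' is not watertight")
  regions <- lapply(names(meshes), function(nm)
    solid_from_mesh(meshes[[nm]], label = nm))
  names(regions) <- names(meshes)
  cache <- new.env(parent = emptyenv())
  for (nm in names(meshes)) cache[[nm]] <- meshes[[nm]]
  lm <- NULL
  if (!is.null(landmarks)) {
    lm <- if (is.matrix(landmarks)) landmarks else do.call(rbind, landmarks)
  }
  structure(list(params = NULL, frames = NULL, regions = regions,
                 joints = NULL, volume_groups = NULL, landmarks = lm,
                 ligaments = NULL, planes = NULL, mesh_cache = cache),
            class = "anatomy_model")
}
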