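# Targeted-puncture planning at the L4/5 interspace.
#
# The construction mirrors the clinical planning workflow: least-squares
# planes through the L4 inferior and L5 superior endplates, the interspace
# centre C as the midpoint of the two posterior-edge midpoints, a reference
# plane through C parallel to the L5 superior endplate, and a fan of
# trephine axes in that plane at 20-70 degrees from the posterior
# mid-sagittal axis, opening laterally towards the approach side.  The
# second attempt is the same axis rotated a further 5 degrees outward about
# C (pivot at the target keeps both attempts aimed at the lesion).

#' Construct a plane
#' @param point a point on the plane (mm)
#' @param normal plane normal (normalised internally)
#' @return list of class `ls_plane`
#' @export
plane_new <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = unit(normal)),
            class = "ls_plane")
}

#' Least-squares plane through an endplate region
#'
#' Fits the plane minimising squared vertex distance (principal component
#' analysis of the region's mesh vertices); the normal is oriented
#' cranially using the model's frame convention.
#'
#' @param model an `anatomy_model`
#' @param endplate_name one of `endplate_L4_inferior`, `endplate_L5_superior`,
#'   `endplate_L4_superior`, `endplate_L3_inferior`
#' @return an `ls_plane`
#' @export
fit_endplate_plane <- function(model, endplate_name) {
  if (!endplate_name %in% names(model$regions))
    stop("no such endplate region: ", endplate_name)
  V <- region_mesh(model, endplate_name)$V
  fit_plane_points(V, orient = cranial_hint(model))
}

# PCA plane fit; `orient` is a direction the normal should roughly follow
fit_plane_points <- function(V, orient = c(0, 0, 1)) {
  V <- as_points(V)
  if (nrow(V) < 3) stop("need at least 3 points to fit a plane")
  ctr <- colMeans(V)
  X <- sweep(V, 2, ctr)
  s <- svd(X, nu = 0, nv = 3)
  if (s$d[2] < 1e-9) stop("points are collinear; plane fit is degenerate")
  n <- s$v[, 3]
  if (sum(n * orient) < 0) n <- -n
  plane_new(ctr, n)
}

cranial_hint <- function(model) {
  if (!is.null(model$frames)) model$frames$disc_L4L5$R[, 3] else c(0, 0, 1)
}

#' RMS distance of points to a plane
#' @param plane an `ls_plane`
#' @param P points
#' @export
plane_rms <- function(plane, P) {
  d <- as.numeric(sweep(as_points(P), 2, plane$point) %*% plane$normal)
  sqrt(mean(d^2))
}

#' Build the L4/5 interspace frame
#'
#' C is the midpoint between the posterior-edge midpoints of the L4
#' inferior and L5 superior endplates; the reference plane passes through C
#' with the L5 superior endplate normal; the central axis is the posterior
#' mid-sagittal direction projected into the plane, and the lateral axis
#' points to the subject's right.
#'
#' @param model an `anatomy_model` (supplies the posterior-edge landmarks)
#' @param l4_inf_plane,l5_sup_plane endplate planes from
#'   [fit_endplate_plane()]
#' @return list of class `interspace_frame` with `center`,
#'   `reference_plane`, `central_axis`, `lateral_axis`
#' @export
build_interspace_frame <- function(model, l4_inf_plane, l5_sup_plane) {
  need <- c("endplate_L4_inferior_posterior_midpoint",
            "endplate_L5_superior_posterior_midpoint")
  if (is.null(model$landmarks) || !all(need %in% rownames(model$landmarks)))
    stop("missing posterior-edge midpoint landmarks: ",
         paste(setdiff(need, rownames(model$landmarks)), collapse = ", "))
  C <- colMeans(model$landmarks[need, , drop = FALSE])
  n <- unit(l5_sup_plane$normal)
  post <- posterior_hint(model)
  central <- unit(post - sum(post * n) * n)  # project into the plane
  lateral <- unit(cross3(n, central))
  structure(list(center = as.numeric(C),
                 reference_plane = plane_new(C, n),
                 central_axis = central, lateral_axis = lateral),
            class = "interspace_frame")
}

posterior_hint <- function(model) {
  if (!is.null(model$frames)) -model$frames$disc_L4L5$R[, 2] else c(0, -1, 0)
}

#' Trephine plan
#'
#' @param angle_deg entry angle from the central axis: 20/30/40 (PEID
#'   group) or 50/60/70 (PTED group)
#' @param diameter_mm trephine diameter: 7, 8 or 9 (other values need
#'   `allow_nonstandard = TRUE`)
#' @param attempts 1 or 2; the second attempt is offset 5 degrees outward
#' @param side approach side (the modelled procedure uses the right side)
#' @param cylinder_length total tool length (mm)
#' @param tip_overshoot distance the tool tip advances past C (mm)
#' @param second_attempt_offset_deg fixed outward offset of attempt 2
#' @param allow_nonstandard allow diameters outside {7, 8, 9}
#' @return list of class `trephine_plan`
#' @export
trephine_plan <- function(angle_deg, diameter_mm = 8, attempts = 1,
                          side = "right", cylinder_length = 120,
                          tip_overshoot = 5, second_attempt_offset_deg = 5,
                          allow_nonstandard = FALSE) {
  if (!angle_deg %in% c(20, 30, 40, 50, 60, 70))
    stop("angle_deg must be one of 20/30/40/50/60/70")
  if (!diameter_mm %in% c(7, 8, 9) && !allow_nonstandard)
    stop("diameter_mm must be 7, 8 or 9 (set allow_nonstandard to override)")
  if (!attempts %in% c(1, 2)) stop("attempts must be 1 or 2")
  side <- match.arg(side, c("right", "left"))
  structure(list(angle_deg = angle_deg, diameter_mm = diameter_mm,
                 attempts = attempts, side = side,
                 cylinder_length = cylinder_length,
                 tip_overshoot = tip_overshoot,
                 second_attempt_offset_deg = second_attempt_offset_deg,
                 group = if (angle_deg <= 40) "PEID" else "PTED"),
            class = "trephine_plan")
}

#' Trephine axis for a planned angle and attempt
#'
#' The returned direction lies in the reference plane, points from the
#' postero-lateral entry side towards C, and makes the requested in-plane
#' angle with the central axis (plus 5 degrees for the second attempt).
#'
#' @param frame an `interspace_frame`
#' @param angle_deg entry angle (degrees)
#' @param attempt 1 or 2
#' @param side "right" or "left"
#' @param second_attempt_offset_deg outward offset of attempt 2
#' @return list with `point` (C) and `direction` (unit, towards C)
#' @export
trephine_axis <- function(frame, angle_deg, attempt = 1, side = "right",
                          second_attempt_offset_deg = 5) {
  if (!attempt %in% c(1, 2)) stop("attempt must be 1 or 2")
  total <- angle_deg + (attempt - 1) * second_attempt_offset_deg
  lat <- if (side == "right") frame$lateral_axis else -frame$lateral_axis
  entry_dir <- cos(deg2rad(total)) * frame$central_axis +
    sin(deg2rad(total)) * lat
  list(point = frame$center, direction = -unit(entry_dir))
}

#' Cylinder mesh and solid for a trephine
#'
#' A right circular cylinder centred on the axis, with its tip
#' `tip_overshoot` past C and its shaft extending back through the
#' posterior elements.  The mesh is an analytic loft (96 facets), accurate
#' to well under 0.5% in volume.
#'
#' @param axis list with `point` (C) and `direction` (unit, towards C) as
#'   returned by [trephine_axis()]
#' @param diameter_mm cylinder diameter
#' @param length total cylinder length (mm)
#' @param tip_overshoot distance past C (mm)
#' @param nseg facet count of the loft
#' @return list of class `trephine_tool` with `solid`, `mesh`, `axis`
#' @export
trephine_cylinder <- function(axis, diameter_mm, length = 120,
                              tip_overshoot = 5, nseg = 96) {
  r <- diameter_mm / 2
  dir <- unit(axis$direction)
  tip <- axis$point + tip_overshoot * dir
  base <- tip - length * dir
  sol <- solid_cylinder(base, dir, r, length,
                        label = sprintf("trephine_d%g", diameter_mm))
  # analytic loft
  e1 <- unit(if (abs(dir[1]) < 0.9) cross3(dir, c(1, 0, 0)) else cross3(dir, c(0, 1, 0)))
  e2 <- cross3(dir, e1)
  th <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
  ring <- cbind(r * cos(th), r * sin(th)) %*% rbind(e1, e2)
  Vb <- sweep(ring, 2, base, `+`)
  Vt <- sweep(ring, 2, tip, `+`)
  V <- rbind(Vb, Vt, base, tip)
  i <- seq_len(nseg); j <- c(2:nseg, 1)
  F <- rbind(cbind(i, j, nseg + j), cbind(i, nseg + j, nseg + i),
             cbind(2 * nseg + 1, j, i), cbind(2 * nseg + 2, nseg + i, nseg + j))
  mesh <- mesh_new(V, F)
  if (mesh_volume(mesh) < 0) mesh$F <- mesh$F[, c(1, 3, 2)]
  structure(list(solid = sol, mesh = mesh, axis = list(point = axis$point,
                                                       direction = dir),
                 diameter_mm = diameter_mm, length = length,
                 tip_overshoot = tip_overshoot),
            class = "trephine_tool")
}

#' Tool solid for a full plan (one or two attempts)
#'
#' For two attempts the tool is the union of the attempt-1 and attempt-2
#' cylinders (overlap counted once).
#' @param frame an `interspace_frame`
#' @param plan a `trephine_plan`
#' @return list with `solid` (union), `tools` (per-attempt `trephine_tool`)
#' @export
plan_tool <- function(frame, plan) {
  tools <- lapply(seq_len(plan$attempts), function(att) {
    ax <- trephine_axis(frame, plan$angle_deg, att, plan$side,
                        plan$second_attempt_offset_deg)
    trephine_cylinder(ax, plan$diameter_mm, plan$cylinder_length,
                      plan$tip_overshoot)
  })
  sol <- if (length(tools) == 1) tools[[1]]$solid
  else solid_union(tools[[1]]$solid, tools[[2]]$solid,
                   label = sprintf("trephine_d%g_x2", plan$diameter_mm))
  list(solid = sol, tools = tools)
}

#' In-plane angle between a trephine axis and the central axis
#' @param frame an `interspace_frame`
#' @param axis axis as returned by [trephine_axis()]
#' @return signed angle in degrees (positive towards the lateral axis)
#' @export
axis_inplane_angle <- function(frame, axis) {
  d <- -axis$direction  # entry direction from C
  rad2deg(atan2(sum(d * frame$lateral_axis), sum(d * frame$central_axis)))
}

#' Serialise trephine plans to YAML
#' @param plans list of `trephine_plan`
#' @param path output file
#' @export
write_plans <- function(plans, path) {
  yaml::write_yaml(lapply(plans, unclass), path)
  invisible(path)
}

#' Read trephine plans from YAML
#' @param path YAML file written by [write_plans()]
#' @export
read_plans <- function(path) {
  lapply(yaml::read_yaml(path), function(p) do.call(trephine_plan, p[
    setdiff(names(p), "group")]))
}
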