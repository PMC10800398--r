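# Parametric L3-L5 phantom.
#
# The phantom stands in for a patient CT reconstruction.  Vertebral bodies
# are extruded superellipses with a 1 mm cortical shell; discs (annulus +
# offset nucleus + cartilage endplates) are wedge slabs between the
# adjacent endplate planes, sized to the stated cross-section fractions;
# posterior elements (pedicles, posterior arch with an arched interlaminar
# margin, spinous process, articular processes with cartilage-capped facet
# joints) are implicit-CSG blocks.  Every region exists both as an implicit
# solid (used by the Boolean/volume machinery) and as a watertight
# triangulated surface mesh (lofted analytically where the region is an
# extrusion, extracted by marching tetrahedra otherwise).

superellipse_xy <- function(a, b, n, nseg = 128, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
  e <- 2 / n
  cbind(center[1] + a * sign(cos(t)) * abs(cos(t))^e,
        center[2] + b * sign(sin(t)) * abs(sin(t))^e)
}

# parameter t along the frame's z-direction where the line through local
# (x, y) meets a plane
plane_line_t <- function(frame, xy, plane) {
  n <- unit(plane$normal)
  zdir <- frame$R[, 3]
  base <- frame_to_world(frame, cbind(xy[, 1], xy[, 2], 0))
  as.numeric((sum(plane$point * n) - base %*% n) / sum(zdir * n))
}

slab_point <- function(frame, xy, plane_a, plane_b, frac = 0.5) {
  xy <- matrix(xy, ncol = 2)
  ta <- plane_line_t(frame, xy, plane_a)
  tb <- plane_line_t(frame, xy, plane_b)
  as.numeric(frame_to_world(frame, cbind(xy, ta + (tb - ta) * frac)))
}

# watertight loft of a closed CCW cross-section curve between two planes
loft_slab_mesh <- function(frame, xy, plane_lo, plane_hi) {
  nseg <- nrow(xy)
  tlo <- plane_line_t(frame, xy, plane_lo)
  thi <- plane_line_t(frame, xy, plane_hi)
  Vb <- frame_to_world(frame, cbind(xy, tlo))
  Vt <- frame_to_world(frame, cbind(xy, thi))
  ctr <- colMeans(xy)
  cb <- slab_point(frame, ctr, plane_lo, plane_lo, 0)
  ct <- slab_point(frame, ctr, plane_hi, plane_hi, 0)
  V <- rbind(Vb, Vt, cb, ct)
  i <- seq_len(nseg); j <- c(2:nseg, 1)
  side <- rbind(cbind(i, j, nseg + j), cbind(i, nseg + j, nseg + i))
  capb <- cbind(2 * nseg + 1, j, i)
  capt <- cbind(2 * nseg + 2, nseg + i, nseg + j)
  m <- mesh_new(V, rbind(side, capb, capt))
  if (mesh_volume(m) < 0) m$F <- m$F[, c(1, 3, 2)]
  m
}

# watertight loft of a ring (outer minus inner curve, equal segment counts)
loft_ring_mesh <- function(frame, xy_outer, xy_inner, plane_lo, plane_hi) {
  nseg <- nrow(xy_outer)
  stopifnot(nrow(xy_inner) == nseg)
  pts <- function(xy, plane) frame_to_world(frame, cbind(xy, plane_line_t(frame, xy, plane)))
  Ob <- pts(xy_outer, plane_lo); Ot <- pts(xy_outer, plane_hi)
  Ib <- pts(xy_inner, plane_lo); It <- pts(xy_inner, plane_hi)
  V <- rbind(Ob, Ot, Ib, It)
  i <- seq_len(nseg); j <- c(2:nseg, 1)
  o_b <- i; o_t <- nseg + i; i_b <- 2 * nseg + i; i_t <- 3 * nseg + i
  o_bj <- j; o_tj <- nseg + j; i_bj <- 2 * nseg + j; i_tj <- 3 * nseg + j
  F <- rbind(
    cbind(o_b, o_bj, o_tj), cbind(o_b, o_tj, o_t),      # outer wall
    cbind(i_b, i_tj, i_bj), cbind(i_b, i_t, i_tj),      # inner wall (reversed)
    cbind(o_b, i_bj, o_bj), cbind(o_b, i_b, i_bj),      # bottom cap
    cbind(o_t, o_tj, i_tj), cbind(o_t, i_tj, i_t))      # top cap
  m <- mesh_new(V, F)
  if (mesh_volume(m) < 0) m$F <- m$F[, c(1, 3, 2)]
  m
}

plane_new_pair <- function(point, normal) list(point = as.numeric(point),
                                               normal = unit(normal))

## ---- phantom assembly ---------------------------------------------------

#' Generate a synthetic L3-L5 anatomy model
#'
#' Builds the full phantom for one subject: implicit solids, landmark
#' points, ligament attachment pairs and facet joint frames.  Regional
#' surface meshes are built lazily through [region_mesh()].  The
#' construction is deterministic: identical parameters give bit-identical
#' output.
#'
#' @param params a [subject_params()]
#' @return object of class `anatomy_model` with elements `params`, `frames`
#'   (level and disc mid-frames), `regions` (named `ls_solid` list),
#'   `landmarks` (named 3-column matrix), `ligaments` (attachment table),
#'   `joints` (facet frames) and `volume_groups` (CSG groups used for
#'   resected-volume attribution).
#' @export
generate_phantom <- function(params = subject_params()) {
  if (!inherits(params, "subject_params")) params <- do.call(subject_params, params)
  p <- params
  a <- p$body_width / 2; b <- p$body_depth / 2; nse <- p$se_exponent
  H <- p$body_height; hd <- p$disc_height; hep <- p$endplate_thickness
  tcort <- p$cortical_thickness
  s_d <- sqrt(p$disc_to_vertebra_area_fraction)
  s_n <- sqrt(p$nucleus_area_fraction)
  y_nc <- -b * s_d * (p$ap_offset_ratio - 1) / (p$ap_offset_ratio + 1)

  ## frames: stack upward from L5, wedge rotations at each disc
  f5 <- frame_new(c(0, 0, 0), diag(3))
  o5t <- as.numeric(frame_to_world(f5, c(0, 0, H)))
  Rm45 <- f5$R %*% rot_x(p$lordosis_l4l5 / 2)
  Q45 <- o5t + as.numeric(Rm45 %*% c(0, 0, hd / 2))
  o4b <- o5t + as.numeric(Rm45 %*% c(0, 0, hd))
  R4 <- f5$R %*% rot_x(p$lordosis_l4l5)
  f4 <- frame_new(o4b, R4)
  o4t <- as.numeric(frame_to_world(f4, c(0, 0, H)))
  Rm34 <- R4 %*% rot_x(p$lordosis_l3l4 / 2)
  Q34 <- o4t + as.numeric(Rm34 %*% c(0, 0, hd / 2))
  o3b <- o4t + as.numeric(Rm34 %*% c(0, 0, hd))
  R3 <- R4 %*% rot_x(p$lordosis_l3l4)
  f3 <- frame_new(o3b, R3)
  # recentre: L4/5 disc centre at the origin
  shift <- -Q45
  f5$origin <- f5$origin + shift; f4$origin <- f4$origin + shift
  f3$origin <- f3$origin + shift
  o5t <- o5t + shift; o4b <- o4b + shift; o4t <- o4t + shift
  o3b <- o3b + shift; Q34 <- Q34 + shift; Q45 <- Q45 + shift
  fd45 <- frame_new(Q45, Rm45)
  fd34 <- frame_new(Q34, Rm34)
  frames <- list(L5 = f5, L4 = f4, L3 = f3,
                 disc_L4L5 = fd45, disc_L3L4 = fd34)

  ## cross-section fields
  bb2 <- rbind(c(-a, -b), c(a, b))
  f_outer <- se_field(a, b, nse)
  f_inner <- se_field(a - tcort, b - tcort, nse)
  f_disc <- se_field(a * s_d, b * s_d, nse)
  f_nuc <- se_field(a * s_d * s_n, b * s_d * s_n, nse, center = c(0, y_nc))
  f_ann <- ring_field(f_disc, f_nuc)

  zax <- function(f) f$R[, 3]
  vert_solids <- function(f, name) {
    obot <- f$origin; otop <- as.numeric(frame_to_world(f, c(0, 0, H)))
    z <- zax(f)
    outer <- solid_slab(f, f_outer, bb2,
                        plane_new_pair(obot, -z), plane_new_pair(otop, z),
                        label = paste0(name, "_outer"))
    canc <- solid_slab(f, f_inner, bb2,
                       plane_new_pair(obot + tcort * z, -z),
                       plane_new_pair(otop - tcort * z, z),
                       label = paste0(name, "_cancellous"))
    cort <- solid_difference(outer, canc, label = paste0(name, "_cortical"))
    list(outer = outer, cancellous = canc, cortical = cort,
         obot = obot, otop = otop)
  }
  v5 <- vert_solids(f5, "L5"); v4 <- vert_solids(f4, "L4"); v3 <- vert_solids(f3, "L3")

  disc_solids <- function(fmid, olo, zlo, ohi, zhi, lv) {
    # olo: point on the lower vertebra's top plane (normal zlo, cranial)
    ep_lo <- solid_slab(fmid, f_disc, bb2,
                        plane_new_pair(olo, -zlo),
                        plane_new_pair(olo + hep * zlo, zlo),
                        label = paste0(lv, "_ep_lo"))
    ep_hi <- solid_slab(fmid, f_disc, bb2,
                        plane_new_pair(ohi - hep * zhi, -zhi),
                        plane_new_pair(ohi, zhi),
                        label = paste0(lv, "_ep_hi"))
    pl_lo <- plane_new_pair(olo + hep * zlo, -zlo)
    pl_hi <- plane_new_pair(ohi - hep * zhi, zhi)
    ann <- solid_slab(fmid, f_ann, bb2, pl_lo, pl_hi, label = paste0(lv, "_annulus"))
    nuc <- solid_slab(fmid, f_nuc, bb2, pl_lo, pl_hi, label = paste0(lv, "_nucleus"))
    list(ep_lo = ep_lo, ep_hi = ep_hi, annulus = ann, nucleus = nuc,
         pl_lo = pl_lo, pl_hi = pl_hi,
         plane_lower_vertebra = plane_new_pair(olo, zlo),
         plane_upper_vertebra = plane_new_pair(ohi, zhi))
  }
  d45 <- disc_solids(fd45, o5t, zax(f5), o4b, zax(f4), "L4L5")
  d34 <- disc_solids(fd34, o4t, zax(f4), o3b, zax(f3), "L3L4")

  ## posterior elements
  xm <- p$canal_width / 2; pw <- p$pedicle_width; ph <- p$pedicle_height
  pl <- p$pedicle_length; lt <- p$lamina_thickness
  z_lam_lo <- -3; z_lam_hi <- z_lam_lo + p$lamina_height
  B_i <- b + p$canal_depth
  A_i <- (xm + pw) / sqrt(1 - ((b + 2) / B_i)^2)
  A_o <- A_i + lt; B_o <- B_i + lt
  arch_rise <- p$interlaminar_arch

  local_box <- function(f, lo, hi, label = NULL) {
    ctr <- as.numeric(frame_to_world(f, (lo + hi) / 2))
    solid_box(ctr, (hi - lo) / 2, R = f$R, label = label)
  }
  arch_solid <- function(f, name) {
    el_o <- se_field(A_o, B_o, 2); el_i <- se_field(A_i, B_i, 2)
    field <- function(P) {
      L <- frame_to_local(f, P)
      x <- L[, 1]; y <- L[, 2]; z <- L[, 3]
      f_band <- pmax(el_o(L[, 1:2, drop = FALSE]), -el_i(L[, 1:2, drop = FALSE]))
      z_inf <- z_lam_lo + arch_rise * pmax(0, 1 - abs(x) / A_i)
      pmax(f_band, y + (b + 2), z_inf - z, z - z_lam_hi)
    }
    crn <- as.matrix(expand.grid(c(-A_o, A_o), c(-B_o, -(b + 2)),
                                 c(z_lam_lo, z_lam_hi)))
    solid_new(field, bbox_of(frame_to_world(f, crn)), label = name)
  }
  y_sp0 <- -(b + p$canal_depth + 2)
  post_blocks <- function(f, name) {
    list(
      pedicle_right = local_box(f, c(xm, -b - pl, H - 2 - ph), c(xm + pw, -b + 3, H - 2),
                                paste0(name, "_pedicle_right")),
      pedicle_left = local_box(f, c(-xm - pw, -b - pl, H - 2 - ph), c(-xm, -b + 3, H - 2),
                               paste0(name, "_pedicle_left")),
      arch = arch_solid(f, paste0(name, "_arch")),
      spinous = local_box(f, c(-p$spinous_thickness / 2, y_sp0 - p$spinous_process_length,
                               z_lam_lo + 1),
                          c(p$spinous_thickness / 2, y_sp0,
                            z_lam_lo + 1 + p$spinous_height),
                          paste0(name, "_spinous")))
  }
  pb5 <- post_blocks(f5, "L5"); pb4 <- post_blocks(f4, "L4"); pb3 <- post_blocks(f3, "L3")

  ## facet joints: frames, articular processes and cartilage pads
  phi <- deg2rad(p$facet_angle)
  gap <- p$facet_gap; cart <- p$cartilage_thickness
  pt <- p$process_thickness
  fw <- p$facet_width; fh <- p$facet_height
  joint_frame <- function(fd, side) {
    s <- if (side == "right") 1 else -1
    Fc <- as.numeric(frame_to_world(fd, c(s * p$facet_lateral_offset,
                                          -(b + p$facet_posterior_offset), 0)))
    u <- as.numeric(fd$R %*% c(s * sin(phi), -cos(phi), 0))
    n <- as.numeric(fd$R %*% c(-s * cos(phi), -sin(phi), 0))  # toward the IAP
    list(center = Fc, u = u, n = n, z = fd$R[, 3], side = side)
  }
  joints <- list(
    L4L5 = list(right = joint_frame(fd45, "right"), left = joint_frame(fd45, "left")),
    L3L4 = list(right = joint_frame(fd34, "right"), left = joint_frame(fd34, "left")))

  facet_blocks <- function(jf, name) {
    Rj <- cbind(jf$u, jf$n, jf$z)
    # articular processes are rounded blocks (superelliptic cross-section in
    # the joint plane) trimmed flat at the joint space, so the bone never
    # enters the cartilage/gap band
    jslab <- solid_box(jf$center, c(fw / 2 + 6, gap / 2 + cart, fh / 2 + 8), Rj)
    iap <- solid_difference(
      solid_oval_prism(jf$center + jf$n * (gap / 2 + cart + pt / 2) + jf$z * 2,
                       c(fw / 2 + 0.8, pt / 2 + 0.8, fh / 2 + 2), Rj,
                       exponent = 2.5), jslab, label = paste0(name, "_iap"))
    # the superior process bone merges anteromedially into the pedicle and
    # tapers towards its tip: its mass sits medial of the joint centre.
    # Lumbar joints are curved in axial section: the SAP carries a
    # posterolateral lip that cups the IAP beyond the articular margin.
    # the lip clearance prism is grown slightly so its cut surface never
    # coincides with the IAP boundary (coincident zero-thickness surfaces
    # pinch the extracted meshes)
    iap_grown <- solid_oval_prism(jf$center + jf$n * (gap / 2 + cart + pt / 2) +
                                    jf$z * 2,
                                  c(fw / 2 + 1.1, pt / 2 + 1.1, fh / 2 + 2.3), Rj,
                                  exponent = 2.5)
    lip <- solid_difference(
      solid_box(jf$center + jf$u * (fw / 2 + 2.5) + jf$n * 0.5,
                c(2.0, 5.0, fh / 2), Rj), iap_grown)
    sap <- solid_union(solid_difference(
      solid_oval_prism(jf$center - jf$n * (gap / 2 + cart + pt / 2) -
                         jf$z * 2 - jf$u * 1.5,
                       c(fw / 2, pt / 2 + 0.8, fh / 2 + 2), Rj,
                       exponent = 2.5), jslab), lip,
      label = paste0(name, "_sap"))
    pad_i <- solid_box(jf$center + jf$n * (gap / 2 + cart / 2),
                       c(fw / 2 - 0.5, cart / 2, fh / 2 - 0.5), Rj,
                       paste0(name, "_pad_iap"))
    pad_s <- solid_box(jf$center - jf$n * (gap / 2 + cart / 2),
                       c(fw / 2 - 0.5, cart / 2, fh / 2 - 0.5), Rj,
                       paste0(name, "_pad_sap"))
    list(iap = iap, sap = sap, pad_iap = pad_i, pad_sap = pad_s, jslab = jslab)
  }
  fb45r <- facet_blocks(joints$L4L5$right, "L4L5_right")
  fb45l <- facet_blocks(joints$L4L5$left, "L4L5_left")
  fb34r <- facet_blocks(joints$L3L4$right, "L3L4_right")
  fb34l <- facet_blocks(joints$L3L4$left, "L3L4_left")

  jslabs <- solid_union(fb45r$jslab, fb45l$jslab, fb34r$jslab, fb34l$jslab,
                        label = "joint_spaces")
  post_region <- function(blocks, iaps, saps, outer, name) {
    solid_difference(solid_difference(
      solid_union(c(unname(blocks), iaps, saps), label = name), outer),
      jslabs, label = name)
  }
  post5 <- post_region(pb5, list(), list(fb45r$sap, fb45l$sap), v5$outer,
                       "L5_posterior_elements")
  post4 <- post_region(pb4, list(fb45r$iap, fb45l$iap), list(fb34r$sap, fb34l$sap),
                       v4$outer, "L4_posterior_elements")
  post3 <- post_region(pb3, list(fb34r$iap, fb34l$iap), list(), v3$outer,
                       "L3_posterior_elements")

  regions <- list(
    L5_cortical = v5$cortical, L5_cancellous = v5$cancellous,
    L5_posterior_elements = post5,
    L4_cortical = v4$cortical, L4_cancellous = v4$cancellous,
    L4_posterior_elements = post4,
    L3_cortical = v3$cortical, L3_cancellous = v3$cancellous,
    L3_posterior_elements = post3,
    disc_L4L5_annulus = d45$annulus, disc_L4L5_nucleus = d45$nucleus,
    disc_L3L4_annulus = d34$annulus, disc_L3L4_nucleus = d34$nucleus,
    endplate_L5_superior = d45$ep_lo, endplate_L4_inferior = d45$ep_hi,
    endplate_L4_superior = d34$ep_lo, endplate_L3_inferior = d34$ep_hi,
    facet_cartilage_L4L5_right = solid_union(fb45r$pad_iap, fb45r$pad_sap,
                                             label = "facet_cartilage_L4L5_right"),
    facet_cartilage_L4L5_left = solid_union(fb45l$pad_iap, fb45l$pad_sap,
                                            label = "facet_cartilage_L4L5_left"),
    facet_cartilage_L3L4_right = solid_union(fb34r$pad_iap, fb34r$pad_sap,
                                             label = "facet_cartilage_L3L4_right"),
    facet_cartilage_L3L4_left = solid_union(fb34l$pad_iap, fb34l$pad_sap,
                                            label = "facet_cartilage_L3L4_left"))

  ## resected-volume attribution groups
  iap45 <- solid_union(fb45r$iap, fb45l$iap, label = "facet_L4_inferior")
  sap45 <- solid_union(fb45r$sap, fb45l$sap, label = "facet_L5_superior")
  arch_all <- solid_union(c(unname(pb5), unname(pb4), unname(pb3),
                            list(fb34r$iap, fb34l$iap, fb34r$sap, fb34l$sap)))
  lamina_grp <- solid_difference(
    solid_difference(solid_difference(solid_difference(arch_all, iap45), sap45),
                     v4$outer), v5$outer)
  lamina_grp <- solid_difference(solid_difference(lamina_grp, v3$outer), jslabs,
                                 label = "lamina")
  volume_groups <- list(
    lamina = lamina_grp,
    facet_L4_inferior = iap45,
    facet_L5_superior = sap45,
    other = solid_union(v3$outer, v4$outer, v5$outer, label = "other"),
    cartilage = solid_union(regions$facet_cartilage_L4L5_right,
                            regions$facet_cartilage_L4L5_left,
                            regions$facet_cartilage_L3L4_right,
                            regions$facet_cartilage_L3L4_left,
                            label = "cartilage"))

  ## landmarks
  lm <- list()
  post_mid <- function(fmid, xy, pa, pb) slab_point(fmid, xy, pa, pb, 0.5)
  yedge <- -b * s_d
  lm$endplate_L5_superior_posterior_midpoint <-
    slab_point(fd45, c(0, yedge), plane_new_pair(o5t, zax(f5)), d45$pl_lo, 0.5)
  lm$endplate_L4_inferior_posterior_midpoint <-
    slab_point(fd45, c(0, yedge), d45$pl_hi, plane_new_pair(o4b, zax(f4)), 0.5)
  lm$endplate_L4_superior_posterior_midpoint <-
    slab_point(fd34, c(0, yedge), plane_new_pair(o4t, zax(f4)), d34$pl_lo, 0.5)
  lm$endplate_L3_inferior_posterior_midpoint <-
    slab_point(fd34, c(0, yedge), d34$pl_hi, plane_new_pair(o3b, zax(f3)), 0.5)
  for (lv in names(joints)) for (sd in c("right", "left"))
    lm[[paste0("facet_center_", lv, "_", sd)]] <- joints[[lv]][[sd]]$center
  landmarks <- do.call(rbind, lm)

  ## ligament attachment table
  lig <- ligament_table(p, frames, joints, z_lam_lo, z_lam_hi, y_sp0,
                        arch_rise, A_i, xm, pw, pl, ph, b, H)

  model <- structure(list(
    params = p, frames = frames, regions = regions, joints = joints,
    volume_groups = volume_groups, landmarks = landmarks, ligaments = lig,
    planes = list(L5_superior = plane_new_pair(o5t, zax(f5)),
                  L4_inferior = plane_new_pair(o4b, zax(f4)),
                  L4_superior = plane_new_pair(o4t, zax(f4)),
                  L3_inferior = plane_new_pair(o3b, zax(f3))),
    mesh_cache = new.env(parent = emptyenv())),
    class = "anatomy_model")
  model
}

# attachment pairs for the seven ligament groups; coordinates built in the
# relevant level frames and returned in world coordinates.
ligament_table <- function(p, frames, joints, z_lam_lo, z_lam_hi, y_sp0,
                           arch_rise, A_i, xm, pw, pl, ph, b, H) {
  rows <- list()
  add <- function(group, level, side, pa, pb, share) {
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, level = level, side = side,
      ax = pa[1], ay = pa[2], az = pa[3],
      bx = pb[1], by = pb[2], bz = pb[3], share = share)
  }
  w <- function(f, v) as.numeric(frame_to_world(f, v))
  gap <- p$facet_gap; cart <- p$cartilage_thickness
  fw <- p$facet_width; fh <- p$facet_height
  levels <- list(L4L5 = list(lo = frames$L5, hi = frames$L4),
                 L3L4 = list(lo = frames$L4, hi = frames$L3))
  for (lv in names(levels)) {
    flo <- levels[[lv]]$lo; fhi <- levels[[lv]]$hi
    for (x in c(-6, 0, 6))
      add("ALL", lv, "mid", w(flo, c(x, b - 0.5, H - 1.5)),
          w(fhi, c(x, b - 0.5, 1.5)), 1 / 3)
    for (x in c(-4, 0, 4))
      add("PLL", lv, "mid", w(flo, c(x, -b + 0.8, H - 1.5)),
          w(fhi, c(x, -b + 0.8, 1.5)), 1 / 3)
    for (s in c(-1, 1)) {
      xlf <- s * 8
      ylf <- -(b + p$canal_depth + 1)
      z_inf <- z_lam_lo + arch_rise * max(0, 1 - abs(xlf) / A_i)
      add("LF", lv, if (s > 0) "right" else "left",
          w(flo, c(xlf, ylf, z_lam_hi - 1)), w(fhi, c(xlf, ylf, z_inf + 1)), 1 / 2)
      add("ITL", lv, if (s > 0) "right" else "left",
          w(flo, c(s * (xm + pw - 1), -b - pl / 2, H - 3)),
          w(fhi, c(s * (xm + pw - 1), -b - pl / 2, H - 1 - ph + 1)), 1 / 2)
    }
    for (k in c(0.3, 0.6))
      add("ISL", lv, "mid", w(flo, c(0, y_sp0 - k * p$spinous_process_length,
                                     z_lam_lo + p$spinous_height - 1)),
          w(fhi, c(0, y_sp0 - k * p$spinous_process_length, z_lam_lo + 2)), 1 / 2)
    ytip <- y_sp0 - p$spinous_process_length + 1
    add("SSL", lv, "mid", w(flo, c(0, ytip, z_lam_lo + p$spinous_height - 2)),
        w(fhi, c(0, ytip, z_lam_lo + 2)), 1)
    for (sd in c("right", "left")) {
      # capsule fibres cross the joint line obliquely: each strand anchors
      # higher on the inferior articular process (which descends from the
      # cranial vertebra) and lower on the superior process, so the capsule
      # resists both facet distraction and cranio-caudal gliding
      jf <- joints[[lv]][[sd]]
      for (du in c(-fw / 4, fw / 4)) for (dz in c(-fh / 6, fh / 6)) {
        pa <- jf$center + du * jf$u + (dz + fh / 6) * jf$z +
          jf$n * (gap / 2 + cart + 1.5)
        pb <- jf$center + 0.5 * du * jf$u + (0.5 * dz - 1.0) * jf$z -
          jf$n * (gap / 2 + cart + 0.6)
        # four capsular truss elements per joint, each carrying the full
        # capsular section area (truss sections are per element)
        add("CL", lv, sd, pa, pb, 1)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.anatomy_model <- function(x, ...) {
  cat(sprintf("<anatomy_model: %d regions, %d landmarks, %d ligament strands>\n",
              length(x$regions), nrow(x$landmarks), nrow(x$ligaments)))
  invisible(x)
}

#' Regional surface mesh of a phantom
#'
#' Extrusion-type regions (bodies, discs, endplates) are lofted
#' analytically; CSG regions (posterior elements, facet cartilage) are
#' extracted by marching tetrahedra.  Results are cached on the model.
#'
#' @param model an `anatomy_model`
#' @param name region name (see `names(model$regions)`)
#' @param pitch lattice pitch for extracted regions (mm)
#' @return an `ls_mesh`
#' @export
region_mesh <- function(model, name, pitch = NULL) {
  if (!name %in% names(model$regions)) stop("unknown region: ", name)
  key <- name
  cache <- model$mesh_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  p <- model$params
  a <- p$body_width / 2; b <- p$body_depth / 2; nse <- p$se_exponent
  H <- p$body_height; hep <- p$endplate_thickness; tcort <- p$cortical_thickness
  s_d <- sqrt(p$disc_to_vertebra_area_fraction)
  s_n <- sqrt(p$nucleus_area_fraction)
  y_nc <- -b * s_d * (p$ap_offset_ratio - 1) / (p$ap_offset_ratio + 1)
  nseg <- 160
  xy_outer <- superellipse_xy(a, b, nse, nseg)
  xy_inner <- superellipse_xy(a - tcort, b - tcort, nse, nseg)
  xy_disc <- superellipse_xy(a * s_d, b * s_d, nse, nseg)
  xy_nuc <- superellipse_xy(a * s_d * s_n, b * s_d * s_n, nse, nseg, c(0, y_nc))
  fr <- model$frames
  pln <- model$planes
  body_planes <- list(
    L5 = list(lo = list(point = fr$L5$origin, normal = -fr$L5$R[, 3]),
              hi = list(point = pln$L5_superior$point, normal = fr$L5$R[, 3])),
    L4 = list(lo = list(point = fr$L4$origin, normal = -fr$L4$R[, 3]),
              hi = list(point = pln$L4_superior$point, normal = fr$L4$R[, 3])),
    L3 = list(lo = list(point = fr$L3$origin, normal = -fr$L3$R[, 3]),
              hi = list(point = as.numeric(frame_to_world(fr$L3, c(0, 0, H))),
                        normal = fr$L3$R[, 3])))
  disc_frames <- list(L4L5 = fr$disc_L4L5, L3L4 = fr$disc_L3L4)
  disc_planes <- function(lv) {
    if (lv == "L4L5")
      list(lo_v = pln$L5_superior, hi_v = pln$L4_inferior)
    else list(lo_v = pln$L4_superior, hi_v = pln$L3_inferior)
  }
  inset <- function(pl, d) list(point = pl$point + d * pl$normal, normal = pl$normal)

  m <- NULL
  lvb <- sub("_.*", "", name)
  if (grepl("_cancellous$", name)) {
    bp <- body_planes[[lvb]]
    m <- loft_slab_mesh(fr[[lvb]], xy_inner,
                        list(point = bp$lo$point - tcort * bp$lo$normal,
                             normal = bp$lo$normal),
                        list(point = bp$hi$point - tcort * bp$hi$normal,
                             normal = bp$hi$normal))
  } else if (grepl("_cortical$", name)) {
    bp <- body_planes[[lvb]]
    outer <- loft_slab_mesh(fr[[lvb]], xy_outer, bp$lo, bp$hi)
    inner <- loft_slab_mesh(fr[[lvb]], xy_inner,
                            list(point = bp$lo$point - tcort * bp$lo$normal,
                                 normal = bp$lo$normal),
                            list(point = bp$hi$point - tcort * bp$hi$normal,
                                 normal = bp$hi$normal))
    inner$F <- inner$F[, c(1, 3, 2)]  # cavity: reversed orientation
    m <- mesh_merge(outer, inner)
  } else if (grepl("^disc_.*_annulus$", name)) {
    lv <- sub("disc_(.*)_annulus", "\\1", name)
    dp <- disc_planes(lv)
    m <- loft_ring_mesh(disc_frames[[lv]], xy_disc, xy_nuc,
                        inset(list(point = dp$lo_v$point, normal = -dp$lo_v$normal), -hep),
                        inset(list(point = dp$hi_v$point, normal = dp$hi_v$normal), -hep))
  } else if (grepl("^disc_.*_nucleus$", name)) {
    lv <- sub("disc_(.*)_nucleus", "\\1", name)
    dp <- disc_planes(lv)
    m <- loft_slab_mesh(disc_frames[[lv]], xy_nuc,
                        inset(list(point = dp$lo_v$point, normal = -dp$lo_v$normal), -hep),
                        inset(list(point = dp$hi_v$point, normal = dp$hi_v$normal), -hep))
  } else if (grepl("^endplate_", name)) {
    lv <- if (grepl("L5_superior|L4_inferior", name)) "L4L5" else "L3L4"
    dp <- disc_planes(lv)
    if (grepl("L5_superior|L4_superior", name)) {
      m <- loft_slab_mesh(disc_frames[[lv]], xy_disc,
                          list(point = dp$lo_v$point, normal = -dp$lo_v$normal),
                          inset(dp$lo_v, hep))
    } else {
      m <- loft_slab_mesh(disc_frames[[lv]], xy_disc,
                          list(point = dp$hi_v$point - hep * dp$hi_v$normal,
                               normal = -dp$hi_v$normal),
                          dp$hi_v)
    }
  } else {
    pt <- pitch %||% if (grepl("cartilage", name)) 0.3 else 0.7
    m <- solid_surface(model$regions[[name]], pitch = pt)
  }
  cache[[key]] <- m
  m
}

#' Mirror a phantom about the mid-sagittal plane
#'
#' Used for left/right symmetry checks: solids, meshes, landmarks, joint
#' frames and ligament attachments are reflected in x, with side labels
#' swapped.
#' @param model an `anatomy_model`
#' @return the mirrored `anatomy_model`
#' @export
mirror_anatomy <- function(model) {
  M <- diag(c(-1, 1, 1))
  mir_solid <- function(s) {
    if (s$empty) return(s)
    f <- s$field
    solid_new(function(P) f(P %*% M), s$bbox %*% M[, c(1, 2, 3)] |>
                (\(bb) rbind(pmin(bb[1, ], bb[2, ]), pmax(bb[1, ], bb[2, ])))(),
              s$label)
  }
  swap_side <- function(nm) {
    nm2 <- gsub("_right$", "_RIGHTTMP", nm)
    nm2 <- gsub("_left$", "_right", nm2)
    gsub("_RIGHTTMP$", "_left", nm2)
  }
  out <- model
  out$regions <- lapply(model$regions, mir_solid)
  names(out$regions) <- swap_side(names(model$regions))
  out$volume_groups <- lapply(model$volume_groups, mir_solid)
  out$landmarks <- model$landmarks %*% M
  rownames(out$landmarks) <- swap_side(rownames(model$landmarks))
  out$frames <- lapply(model$frames, function(f)
    frame_new(as.numeric(M %*% f$origin), M %*% f$R %*% diag(c(-1, 1, 1))))
  out$joints <- lapply(model$joints, function(jj) {
    mj <- function(j, side) list(center = as.numeric(M %*% j$center),
                                 u = as.numeric(M %*% j$u),
                                 n = as.numeric(M %*% j$n),
                                 z = as.numeric(M %*% j$z), side = side)
    list(right = mj(jj$left, "right"), left = mj(jj$right, "left"))
  })
  lig <- model$ligaments
  lig$ax <- -lig$ax; lig$bx <- -lig$bx
  lig$side <- c(right = "left", left = "right", mid = "mid")[lig$side]
  out$ligaments <- lig
  out$planes <- lapply(model$planes, function(pl)
    list(point = as.numeric(M %*% pl$point), normal = as.numeric(M %*% pl$normal)))
  out$mesh_cache <- new.env(parent = emptyenv())
  out
}
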