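# Structured finite-element mesher for the phantom.
#
# The spine column (bodies, endplates, annulus, nucleus) is meshed as a
# boundary-fitted ray grid: radial rings fitted per angular sector to the
# nucleus, cortical-inner, disc-outer and body-outer boundaries, extruded
# through axial stations that follow the lordotic level frames.  Posterior
# elements are swept/lofted blocks (pedicle-to-pedicle arch band, spinous
# process, articular processes with one-element cartilage layers) whose
# root columns reuse column-surface nodes, so region interfaces share
# nodes by construction.  Hexahedral cells are split into six tetrahedra
# (Freudenthal), degenerate core cells collapse gracefully.

#' Tetrahedral FE mesh of a phantom
#'
#' @param model an `anatomy_model` from [generate_phantom()] (parametric
#'   phantoms only)
#' @param target_edge nominal element edge length (mm)
#' @return list of class `fe_model`: `nodes` (n x 3), `tets` (m x 4),
#'   `region` (length m), plus node sets (`fixed_nodes` on the L5 inferior
#'   surface, `load_nodes` on the L3 superior surface) and bookkeeping used
#'   by [attach_ligaments()] and the solver.
#' @export
tetrahedralize <- function(model, target_edge = 3) {
  if (is.null(model$params))
    stop("tetrahedralize needs a parametric phantom (mesh-backed anatomies ",
         "are not supported)")
  p <- model$params
  a <- p$body_width / 2; b <- p$body_depth / 2; nse <- p$se_exponent
  H <- p$body_height; hd <- p$disc_height; hep <- p$endplate_thickness
  tc <- p$cortical_thickness
  s_d <- sqrt(p$disc_to_vertebra_area_fraction)
  s_n <- sqrt(p$nucleus_area_fraction)
  y_nc <- -b * s_d * (p$ap_offset_ratio - 1) / (p$ap_offset_ratio + 1)
  edge <- target_edge
  az <- 1.45 * edge   # axial spacing slightly coarser than in-plane

  ## ---- cross-section ray grid ------------------------------------------
  NS <- max(16L, 2L * round(45 / edge))    # even sector count
  th <- 2 * pi * (seq_len(NS) - 1) / NS    # 0 = anterior midline
  ux <- sin(th); uy <- cos(th)
  c0 <- c(0, y_nc)
  r_nuc <- se_ray_radius(a * s_d * s_n, b * s_d * s_n, nse, center = c(0, y_nc),
                         from = c0, ux = ux, uy = uy)
  r_ci <- se_ray_radius(a - tc, b - tc, nse, from = c0, ux = ux, uy = uy)
  r_do <- se_ray_radius(a * s_d, b * s_d, nse, from = c0, ux = ux, uy = uy)
  r_o <- se_ray_radius(a, b, nse, from = c0, ux = ux, uy = uy)
  n1 <- max(2L, round(mean(r_nuc) / edge))        # rings inside the nucleus
  n2 <- max(2L, round(mean(r_ci - r_nuc) / edge)) # nucleus -> cortical inner
  NR <- n1 + n2 + 2L                              # + cort-inner->disc, disc->outer
  ring_radii <- function(j) {
    c(seq_len(n1) / n1 * r_nuc[j],
      r_nuc[j] + seq_len(n2) / n2 * (r_ci[j] - r_nuc[j]),
      r_do[j], r_o[j])
  }
  radii <- t(vapply(seq_len(NS), ring_radii, numeric(NR)))  # NS x NR

  ## ---- axial stations ---------------------------------------------------
  body_knots <- c(0, tc, seq(tc, H - tc, length.out = max(2, round((H - 2 * tc) / az) + 1))[-1])
  body_knots <- unique(c(body_knots, H - tc, H))
  nann <- max(2, round((hd - 2 * hep) / az))
  disc_knots <- c(0, hep, hep + seq_len(nann - 1) / nann * (hd - 2 * hep),
                  hd - hep, hd)
  # station table: z-knot positions with level bookkeeping and frames
  fr <- model$frames
  stations <- list()
  add_station <- function(origin, R, level, kind) {
    stations[[length(stations) + 1]] <<- list(origin = origin, R = R,
                                              level = level, kind = kind)
  }
  seg <- function(f, lv) {
    for (k in seq_along(body_knots)) {
      kind <- if (k == 1) "body_bot" else if (k == length(body_knots)) "body_top"
      else "body"
      add_station(as.numeric(frame_to_world(f, c(0, 0, body_knots[k]))), f$R, lv, kind)
    }
  }
  dseg <- function(o_lo, R_lo, w, lv) {
    # interior disc stations (both interfaces already emitted by bodies)
    for (k in 2:(length(disc_knots) - 1)) {
      frac <- disc_knots[k] / hd
      Rk <- R_lo %*% rot_x(w * frac)
      ok <- o_lo + as.numeric((R_lo %*% rot_x(w * frac / 2)) %*% c(0, 0, disc_knots[k]))
      add_station(ok, Rk, lv, if (k == 2 || k == length(disc_knots) - 1)
        "disc_ep" else "disc")
    }
  }
  o5t <- as.numeric(frame_to_world(fr$L5, c(0, 0, H)))
  o4t <- as.numeric(frame_to_world(fr$L4, c(0, 0, H)))
  seg(fr$L5, "L5")
  dseg(o5t, fr$L5$R, p$lordosis_l4l5, "L4L5")
  seg(fr$L4, "L4")
  dseg(o4t, fr$L4$R, p$lordosis_l3l4, "L3L4")
  seg(fr$L3, "L3")
  nst <- length(stations)

  per_st <- 1L + NS * NR
  nid <- function(s, j, r) {
    # r = 0 -> centre node; j wraps
    j <- ((j - 1L) %% NS) + 1L
    n <- max(length(s), length(j), length(r))
    s <- rep_len(s, n); j <- rep_len(j, n); r <- rep_len(r, n)
    out <- (s - 1L) * per_st + 1L + (j - 1L) * NR + r
    ctr <- r == 0L
    out[ctr] <- (s[ctr] - 1L) * per_st + 1L
    as.integer(out)
  }
  nodes <- matrix(0, nst * per_st, 3)
  for (s in seq_len(nst)) {
    st <- stations[[s]]
    loc <- rbind(c(c0, 0),
                 cbind(c0[1] + as.vector(t(radii * ux)),   # careful: order (j, r)
                       c0[2] + as.vector(t(radii * uy)), 0))
    # as.vector(t(radii * ux)) enumerates r fastest within each j
    nodes[(s - 1) * per_st + seq_len(per_st), ] <-
      sweep(loc %*% t(st$R), 2, st$origin, `+`)
  }

  ## ---- column cells ----------------------------------------------------
  hexes <- list(); hreg <- list()
  fiber_pairs <- list(); fiber_level <- list()
  add_hex <- function(h, region) {
    hexes[[length(hexes) + 1]] <<- h
    hreg[[length(hreg) + 1]] <<- rep(region, nrow(h))
  }
  # station intervals with their (level, kind) classification
  for (s in seq_len(nst - 1)) {
    lo <- stations[[s]]; hi <- stations[[s + 1]]
    lv <- lo$level
    in_disc <- lo$kind %in% c("disc", "disc_ep") || hi$kind %in% c("disc", "disc_ep")
    if (lo$kind == "body_top" && hi$kind == "disc_ep") in_disc <- TRUE
    # classify the interval
    if (!in_disc && lv %in% c("L5", "L4", "L3")) {
      maxr <- NR
      region_of <- function(rband) {
        lay_cort <- lo$kind == "body_bot" || hi$kind == "body_top"
        if (lay_cort || rband > n1 + n2) paste0(lv, "_cortical")
        else paste0(lv, "_cancellous")
      }
    } else {
      # disc interval: level name of the disc
      dlv <- if (lv %in% c("L5", "L4L5")) "L4L5" else "L3L4"
      maxr <- n1 + n2 + 1L
      # endplate layers: first and last interval of the disc stack
      is_ep_lo <- lo$kind == "body_top"
      is_ep_hi <- hi$kind == "body_top" || hi$kind == "body_bot"
      # (upper interface station has kind "body_bot" of the next body)
      region_of <- function(rband) {
        if (is_ep_lo) {
          if (dlv == "L4L5") "endplate_L5_superior" else "endplate_L4_superior"
        } else if (is_ep_hi) {
          if (dlv == "L4L5") "endplate_L4_inferior" else "endplate_L3_inferior"
        } else if (rband <= n1) paste0("disc_", dlv, "_nucleus")
        else paste0("disc_", dlv, "_annulus")
      }
    }
    for (rb in seq_len(maxr)) {
      reg <- region_of(rb)
      j <- seq_len(NS); jp <- c(2:NS, 1)
      h <- cbind(nid(s, j, rb - 1L), nid(s, j, rb),
                 nid(s, jp, rb - 1L), nid(s, jp, rb),
                 nid(s + 1L, j, rb - 1L), nid(s + 1L, j, rb),
                 nid(s + 1L, jp, rb - 1L), nid(s + 1L, jp, rb))
      add_hex(h, reg)
    }
    # annulus fibre families: criss-crossing diagonals on the outer disc wall
    if (grepl("_annulus$", region_of(maxr))) {
      j <- seq_len(NS); jp <- c(2:NS, 1)
      lvf <- sub("disc_(.*)_annulus", "\\1", region_of(maxr))
      fiber_pairs[[length(fiber_pairs) + 1]] <- cbind(
        rbind(cbind(nid(s, j, maxr), nid(s + 1L, jp, maxr)),
              cbind(nid(s, jp, maxr), nid(s + 1L, j, maxr))))
      fiber_level[[length(fiber_level) + 1]] <- rep(lvf, 2L * NS)
    }
  }

  ## ---- posterior arch blocks -------------------------------------------
  # bookkeeping of station indices per level
  st_level <- vapply(stations, `[[`, "", "level")
  st_kind <- vapply(stations, `[[`, "", "kind")
  body_sts <- function(lv) which(st_level == lv & st_kind %in%
                                   c("body_bot", "body", "body_top"))
  body_z <- body_knots  # local z of those stations

  # ray indices nearest the pedicle axis, per side
  ped_dir_ang <- atan2(p$canal_width / 2 + p$pedicle_width / 2, -b)
  jR <- round((ped_dir_ang %% (2 * pi)) / (2 * pi / NS)) + 1L
  jL <- ((NS - (jR - 1L)) %% NS) + 1L

  extra <- list(nodes = list(), hex = list(), reg = list())
  new_nodes_off <- nrow(nodes)
  push_nodes <- function(V) {
    k <- length(extra$nodes)
    extra$nodes[[k + 1]] <<- V
    off <- new_nodes_off + if (k == 0) 0 else sum(vapply(extra$nodes[seq_len(k)], nrow, 0L))
    off  # ids are off + 1..nrow(V)
  }
  push_hex <- function(h, region) {
    extra$hex[[length(extra$hex) + 1]] <<- h
    extra$reg[[length(extra$reg) + 1]] <<- rep(region, nrow(h))
  }

  arch_info <- list()
  build_arch <- function(lv) {
    f <- fr[[lv]]
    sts <- body_sts(lv)
    # pedicle root stations: body stations inside the pedicle z-range
    ped_lo <- H - 2 - p$pedicle_height; ped_hi <- H - 2
    root_k <- which(body_z >= ped_lo - 1 & body_z <= ped_hi + 0.1)
    # arch z rows: lamina rows (local) + pedicle root station rows; the
    # lamina top row is snapped onto a pedicle root row so the lamina and
    # pedicle always share a node row
    z_lam_lo <- -3
    rootz <- round(body_z[root_k], 6)
    z_lam_hi <- rootz[which.min(abs(rootz - (z_lam_lo + p$lamina_height)))]
    lam_rows <- seq(z_lam_lo, z_lam_hi,
                    length.out = max(3, round((z_lam_hi - z_lam_lo) / az) + 1))
    zrows <- sort(unique(round(c(lam_rows, rootz), 6)))
    nzr <- length(zrows)
    is_root_row <- zrows %in% round(body_z[root_k], 6)

    # 2-D band columns (right half, then mirrored):
    B_i <- b + p$canal_depth
    A_i <- (p$canal_width / 2 + p$pedicle_width) / sqrt(1 - ((b + 2) / B_i)^2)
    # root: boundary points at rays jR-1, jR, jR+1
    rootxy <- cbind(c0[1] + radii[c(jR - 1L, jR, jR + 1L), NR] * ux[c(jR - 1L, jR, jR + 1L)],
                    c0[2] + radii[c(jR - 1L, jR, jR + 1L), NR] * uy[c(jR - 1L, jR, jR + 1L)])
    A0 <- rootxy[2, ]
    u0 <- unit(c(A0[1] - c0[1], A0[2] - c0[2]))[1:2]
    Mpt <- c(0, -(B_i + p$lamina_thickness / 2))
    P1 <- A0 + u0 * (p$pedicle_length + 4)
    P2 <- Mpt + c(0.45 * A_i, 0)
    bez <- function(s) outer((1 - s)^3, A0) + outer(3 * (1 - s)^2 * s, P1) +
      outer(3 * (1 - s) * s^2, P2) + outer(s^3, Mpt)
    n_arc <- max(7L, round(45 / edge))
    sc <- seq(0, 1, length.out = n_arc + 1L)
    Pc <- bez(sc)
    # band normals and half widths
    dP <- bez(pmin(sc + 1e-4, 1)) - bez(pmax(sc - 1e-4, 0))
    tan2 <- dP / sqrt(rowSums(dP^2))
    nrm2 <- cbind(-tan2[, 2], tan2[, 1])
    w0 <- vnorm(rootxy[3, ] - rootxy[1, ]) / 2
    ws <- p$lamina_thickness / 2 +
      (w0 - p$lamina_thickness / 2) * pmax(0, (0.3 - sc) / 0.3)
    colxy <- lapply(seq_along(sc), function(i) {
      if (i == 1) rootxy
      else rbind(Pc[i, ] - ws[i] * nrm2[i, ], Pc[i, ], Pc[i, ] + ws[i] * nrm2[i, ])
    })
    # mirrored left half (shares the midline column)
    colxy_L <- lapply(colxy, function(m) cbind(-m[, 1], m[, 2]))
    cols <- c(colxy, rev(colxy_L)[-1])
    ncol_tot <- length(cols)
    mid_col <- n_arc + 1L
    scol <- c(sc, rev(sc)[-1])  # arc parameter per column (1 at midline)

    # nodes: ncol x 3(eta) x nzr in the LOCAL frame, then to world
    Vloc <- array(0, c(ncol_tot, 3, nzr, 3))
    for (ci in seq_len(ncol_tot)) for (ei in 1:3) for (zi in seq_len(nzr))
      Vloc[ci, ei, zi, ] <- c(cols[[ci]][ei, ], zrows[zi])
    Vflat <- matrix(Vloc, ncol = 3)
    Vw <- frame_to_world(f, Vflat)
    off <- push_nodes(Vw)
    aid <- function(ci, ei, zi)
      off + 1L + (ci - 1L) + (ei - 1L) * ncol_tot + (zi - 1L) * ncol_tot * 3L
    # but root columns must reuse column surface nodes
    root_ids <- function(side_j, zi)  # 3 ids along the boundary rays
      vapply(1:3, function(e) {
        jj <- switch(e, side_j - 1L, side_j, side_j + 1L)
        st <- sts[which(round(body_z, 6) == zrows[zi])]
        as.integer(nid(st, jj, NR))
      }, 0L)
    node_of <- function(ci, ei, zi) {
      if (ci == 1L && is_root_row[zi]) root_ids(jR, zi)[ei]
      else if (ci == ncol_tot && is_root_row[zi]) root_ids(jL, zi)[4L - ei]
      else aid(ci, ei, zi)
    }
    # cell inclusion
    ped_zone <- function(ci) scol[ci] < 0.28
    z_inf_of <- function(ci) {
      xmid <- cols[[ci]][2, 1]
      z_lam_lo + p$interlaminar_arch * max(0, 1 - abs(xmid) / A_i)
    }
    included <- matrix(FALSE, ncol_tot - 1L, nzr - 1L)
    for (ci in seq_len(ncol_tot - 1L)) for (zi in seq_len(nzr - 1L)) {
      zmid <- (zrows[zi] + zrows[zi + 1]) / 2
      ped_cell <- (ped_zone(ci) || ped_zone(ci + 1L)) &&
        zmid > ped_lo - 0.1 && zmid < ped_hi + 0.1 &&
        is_root_row[zi] && is_root_row[zi + 1]
      lam_cell <- zmid >= min(z_inf_of(ci), z_inf_of(ci + 1L)) &&
        zmid <= z_lam_hi && !ped_zone(ci) && !ped_zone(ci + 1L)
      # transition cells: pedicle zone columns within lamina z-range stay,
      # so the pars connects arch to pedicle
      pars_cell <- (ped_zone(ci) || ped_zone(ci + 1L)) && !ped_cell &&
        zmid >= z_lam_hi - p$pedicle_height / 2 && zmid <= z_lam_hi &&
        scol[pmin(ci + 1L, ncol_tot)] > 0.12 && scol[ci] > 0.12
      if (!(ped_cell || lam_cell || pars_cell)) next
      included[ci, zi] <- TRUE
      hh <- matrix(0L, 2, 8)
      for (ei in 1:2) {
        hh[ei, ] <- c(node_of(ci, ei, zi), node_of(ci, ei + 1L, zi),
                      node_of(ci + 1L, ei, zi), node_of(ci + 1L, ei + 1L, zi),
                      node_of(ci, ei, zi + 1L), node_of(ci, ei + 1L, zi + 1L),
                      node_of(ci + 1L, ei, zi + 1L), node_of(ci + 1L, ei + 1L, zi + 1L))
      }
      push_hex(hh, paste0(lv, "_posterior_elements"))
    }

    list(node_of = node_of, ncol = ncol_tot, nzr = nzr,
         zrows = zrows, cols = cols, mid = mid_col,
         scol = scol, f = f, included = included)
  }
  for (lv in c("L5", "L4", "L3")) arch_info[[lv]] <- build_arch(lv)

  ## ---- spinous processes ------------------------------------------------
  for (lv in c("L5", "L4", "L3")) {
    ai <- arch_info[[lv]]
    f <- ai$f
    spin_rows <- which(ai$zrows >= -2.5 & ai$zrows <= -3 + 1 + p$spinous_height)
    if (length(spin_rows) < 2) next
    ci0 <- ai$mid - 1L
    root_grid <- array(0L, c(3, length(spin_rows)))
    for (ii in 1:3) for (kk in seq_along(spin_rows))
      root_grid[ii, kk] <- ai$node_of(ci0 + ii - 1L, 3L, spin_rows[kk])
    getV <- function(id) {
      if (id <= new_nodes_off) nodes[id, ]
      else {
        # find in extra nodes
        idx <- id - new_nodes_off
        do.call(rbind, extra$nodes)[idx, ]
      }
    }
    rootV <- t(apply(matrix(root_grid, ncol = 1), 1, getV))
    dim(rootV) <- c(3 * length(spin_rows), 3)
    # tip face: translate posteriorly in the level frame, mild caudal slope
    tipV_loc <- frame_to_local(f, rootV)
    tipV_loc[, 2] <- tipV_loc[, 2] - p$spinous_process_length
    ctrz <- mean(tipV_loc[, 3])
    tipV_loc[, 3] <- ctrz + 0.8 * (tipV_loc[, 3] - ctrz)
    tipV <- frame_to_world(f, tipV_loc)
    nlay <- max(2L, round(p$spinous_process_length / az))
    layV <- list()
    for (l in seq_len(nlay)) {
      fracl <- l / nlay
      layV[[l]] <- rootV + fracl * (tipV - rootV)
    }
    off <- push_nodes(do.call(rbind, layV))
    sid <- function(l, ii, kk) {
      if (l == 0L) root_grid[ii, kk]
      else off + (l - 1L) * 3L * length(spin_rows) + (kk - 1L) * 3L + ii
    }
    for (l in 0:(nlay - 1L)) for (kk in seq_len(length(spin_rows) - 1L)) for (ii in 1:2) {
      hh <- matrix(c(sid(l, ii, kk), sid(l + 1L, ii, kk),
                     sid(l, ii + 1L, kk), sid(l + 1L, ii + 1L, kk),
                     sid(l, ii, kk + 1L), sid(l + 1L, ii, kk + 1L),
                     sid(l, ii + 1L, kk + 1L), sid(l + 1L, ii + 1L, kk + 1L)),
                   1, 8)
      push_hex(hh, paste0(lv, "_posterior_elements"))
    }
  }

  ## ---- articular processes + facet cartilage ---------------------------
  pt <- p$process_thickness; fw <- p$facet_width; fh <- p$facet_height
  gap <- p$facet_gap; cart <- p$cartilage_thickness
  springs_spec <- list()
  for (jl in names(model$joints)) {
    upper <- if (jl == "L4L5") "L4" else "L3"
    lower <- if (jl == "L4L5") "L5" else "L4"
    for (sd in c("right", "left")) {
      jf <- model$joints[[jl]][[sd]]
      for (role in c("iap", "sap")) {
        lv <- if (role == "iap") upper else lower
        ai <- arch_info[[lv]]
        # arch columns closest (in world x) to the joint centre
        colx <- vapply(seq_len(ai$ncol), function(ci) ai$cols[[ci]][2, 1], 0)
        target_x <- jf$center[1]
        # the SAP rises from the pedicle (root on the arch top row exists only
        # for pedicle-zone columns); the IAP hangs from the lamina margin
        # find a root row and five consecutive arch columns whose cells
        # exist on that row, nearest the joint centre: the IAP roots on the
        # lowest such lamina row, the SAP on the highest pedicle row
        pick_root <- function(zi_order) {
          for (zc in zi_order) {
            cols_ok <- which(ai$included[, zc])
            if (length(cols_ok) < 5) next
            runs <- cols_ok[vapply(cols_ok, function(c0)
              all((c0 + 0:4) %in% cols_ok), TRUE)]
            if (!length(runs)) next
            ctrx <- vapply(runs, function(c0) ai$cols[[c0 + 2L]][2, 1], 0)
            c0 <- runs[which.min(abs(ctrx - target_x))]
            if (abs(ctrx[which.min(abs(ctrx - target_x))] - target_x) > 12) next
            return(list(zi_cell = zc, cis = c0 + 0:4))
          }
          NULL
        }
        if (role == "iap") {
          pr <- pick_root(seq_len(ai$nzr - 1L))
          if (is.null(pr)) next
          zi <- pr$zi_cell
          cis <- pr$cis
          sgn <- +1
          tip_ctr <- jf$center + jf$n * (gap / 2 + cart + pt / 2) - jf$z * (fh / 2)
        } else {
          pr <- pick_root(rev(seq_len(ai$nzr - 1L)))
          if (is.null(pr)) next
          zi <- pr$zi_cell + 1L
          cis <- pr$cis
          sgn <- -1
          tip_ctr <- jf$center - jf$n * (gap / 2 + cart + pt / 2) + jf$z * (fh / 2)
        }
        nuc <- 5L
        root_ids <- matrix(0L, nuc, 3)
        for (ii in seq_along(cis)) for (ei in 1:3)
          root_ids[ii, ei] <- ai$node_of(cis[ii], ei, zi)
        allextra <- if (length(extra$nodes)) do.call(rbind, extra$nodes) else NULL
        getV <- function(id) if (id <= new_nodes_off) nodes[id, ]
        else allextra[id - new_nodes_off, ]
        rootV <- t(vapply(as.vector(root_ids), getV, numeric(3)))
        # tip face grid: (u x n), five columns across the articular width so
        # a trephine corridor can leave an annular bone remnant
        du <- seq(-fw / 2, fw / 2, length.out = nuc) * 0.9
        dn <- c(-pt / 2, 0, pt / 2) * sgn
        tipV <- matrix(0, nuc * 3, 3)
        kk <- 1
        for (ei in 1:3) for (ii in seq_len(nuc)) {
          tipV[kk, ] <- tip_ctr + du[ii] * jf$u + dn[ei] * jf$n
          kk <- kk + 1
        }
        tip_arr <- array(t(tipV), c(3, nuc, 3))  # xyz, ii, ei
        dist0 <- vnorm(colMeans(rootV) - tip_ctr)
        # finer layering than the global axial spacing: the articular faces
        # need enough rows for a resolved contact patch
        nlay <- max(3L, round(dist0 / (0.55 * az)))
        layV <- list()
        for (l in seq_len(nlay)) {
          fracl <- l / nlay
          cur <- matrix(0, nuc * 3, 3)
          kk <- 1
          for (ei in 1:3) for (ii in seq_len(nuc)) {
            rv <- rootV[(ei - 1) * nuc + ii, ]
            cur[kk, ] <- rv + fracl * (tip_arr[, ii, ei] - rv)
            kk <- kk + 1
          }
          layV[[l]] <- cur
        }
        off <- push_nodes(do.call(rbind, layV))
        pid <- function(l, ii, ei) {
          if (l == 0L) root_ids[ii, ei]
          else off + (l - 1L) * (nuc * 3L) + (ei - 1L) * nuc + ii
        }
        for (l in 0:(nlay - 1L)) for (ei in 1:2) for (ii in seq_len(nuc - 1L)) {
          hh <- matrix(c(pid(l, ii, ei), pid(l + 1L, ii, ei),
                         pid(l, ii + 1L, ei), pid(l + 1L, ii + 1L, ei),
                         pid(l, ii, ei + 1L), pid(l + 1L, ii, ei + 1L),
                         pid(l, ii + 1L, ei + 1L), pid(l + 1L, ii + 1L, ei + 1L)),
                       1, 8)
          push_hex(hh, paste0(lv, "_posterior_elements"))
        }
        # cartilage: one-element layer extruded from the articular face,
        # the tip-face side nearest the joint plane
        dface <- vapply(c(1, 3), function(ei)
          abs(sum((tip_arr[, 2, ei] - jf$center) * jf$n)), 0)
        face_e <- c(1, 3)[which.min(dface)]
        nface <- min(nlay, max(2L, round(fh / (0.55 * az))))
        lay_face <- (nlay - nface + 1L):nlay
        cart_dir <- -sgn * jf$n * cart
        faceV <- list()
        for (l in lay_face) for (ii in seq_len(nuc)) {
          idx <- length(faceV) + 1
          base <- layV[[l]][(face_e - 1) * nuc + ii, ]
          faceV[[idx]] <- base + cart_dir
        }
        offc <- push_nodes(do.call(rbind, faceV))
        cid <- function(li, ii) offc + (li - 1L) * nuc + ii
        creg <- paste0("facet_cartilage_", jl, "_", sd)
        for (li in seq_len(length(lay_face) - 1L)) for (ii in seq_len(nuc - 1L)) {
          l <- lay_face[li]; l2 <- lay_face[li + 1L]
          hh <- matrix(c(pid(l, ii, face_e), cid(li, ii),
                         pid(l, ii + 1L, face_e), cid(li, ii + 1L),
                         pid(l2, ii, face_e), cid(li + 1L, ii),
                         pid(l2, ii + 1L, face_e), cid(li + 1L, ii + 1L)),
                       1, 8)
          push_hex(hh, creg)
        }
        springs_spec[[length(springs_spec) + 1]] <- list(
          joint = jl, side = sd, role = role, n = jf$n,
          ids = vapply(seq_along(lay_face), function(li)
            vapply(seq_len(nuc), function(ii) cid(li, ii), 0L), integer(nuc)))
      }
    }
  }

  ## ---- merge, split to tets, prune -------------------------------------
  allN <- rbind(nodes, if (length(extra$nodes)) do.call(rbind, extra$nodes))
  allH <- do.call(rbind, c(hexes, extra$hex))
  allR <- unlist(c(hreg, extra$reg))
  # weld coincident nodes (root columns were copied by id, but arch left/right
  # midline columns coincide by symmetry)
  key <- paste(round(allN[, 1], 5), round(allN[, 2], 5), round(allN[, 3], 5))
  first <- match(key, key)
  keep <- which(first == seq_along(first))
  remap <- match(first, keep)
  allN <- allN[keep, , drop = FALSE]
  allH <- matrix(remap[allH], ncol = 8)

  tets <- matrix(0L, nrow(allH) * 6L, 4L)
  treg <- character(nrow(allH) * 6L)
  for (r in seq_len(6)) {
    idx <- (r - 1L) * nrow(allH) + seq_len(nrow(allH))
    tets[idx, ] <- allH[, .freudenthal[r, ]]
    treg[idx] <- allR
  }
  # drop degenerate, fix inversions
  vol <- tet_volumes(allN, tets)
  ok <- abs(vol) > 1e-7
  tets <- tets[ok, , drop = FALSE]; treg <- treg[ok]; vol <- vol[ok]
  neg <- vol < 0
  tets[neg, 3:4] <- tets[neg, c(4, 3)]
  # drop duplicated tets (overlapping blocks resolve to same welded nodes)
  tkey <- apply(t(apply(tets, 1, sort)), 1, paste, collapse = "_")
  dup <- duplicated(tkey)
  tets <- tets[!dup, , drop = FALSE]; treg <- treg[!dup]
  # prune unused nodes
  used <- sort(unique(as.vector(tets)))
  remap2 <- integer(nrow(allN)); remap2[used] <- seq_along(used)
  springs_spec <- lapply(springs_spec, function(sp) {
    ids <- matrix(remap[as.vector(sp$ids)], nrow = nrow(sp$ids))
    ids <- matrix(remap2[ids], nrow = nrow(ids))
    sp$ids <- ids
    sp
  })
  fibers <- NULL
  if (length(fiber_pairs)) {
    fp <- do.call(rbind, fiber_pairs)
    fp <- matrix(remap2[remap[fp]], ncol = 2)
    fibers <- data.frame(n1 = fp[, 1], n2 = fp[, 2],
                         level = unlist(fiber_level))
    fibers <- fibers[fibers$n1 > 0 & fibers$n2 > 0, ]
  }
  nodesF <- allN[used, , drop = FALSE]
  tetsF <- matrix(remap2[tets], ncol = 4)

  # node sets
  st1 <- seq_len(per_st)
  fixed_raw <- remap2[remap[st1]]
  top0 <- (nst - 1L) * per_st + seq_len(per_st)
  load_raw <- remap2[remap[top0]]
  fixed_nodes <- sort(unique(fixed_raw[fixed_raw > 0]))
  load_nodes <- sort(unique(load_raw[load_raw > 0]))

  fem <- structure(list(
    nodes = nodesF, tets = tetsF, region = treg,
    fixed_nodes = fixed_nodes, load_nodes = load_nodes,
    trusses = NULL, fibers = fibers, springs_spec = springs_spec, springs = NULL,
    frames = model$frames, params = p, target_edge = target_edge,
    meta = list(NS = NS, NR = NR, n1 = n1, n2 = n2)),
    class = "fe_model")
  fem
}

tet_volumes <- function(N, T4) {
  a <- N[T4[, 1], , drop = FALSE]
  b <- N[T4[, 2], , drop = FALSE]
  c <- N[T4[, 3], , drop = FALSE]
  d <- N[T4[, 4], , drop = FALSE]
  u <- b - a; v <- c - a; w <- d - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
     u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
     u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model: %d nodes, %d tets, %d truss elements, %d regions>\n",
              nrow(x$nodes), nrow(x$tets),
              if (is.null(x$trusses)) 0L else nrow(x$trusses),
              length(unique(x$region))))
  invisible(x)
}
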