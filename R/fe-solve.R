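# Linear tetrahedral elasticity with truss ligaments and compression-only
# facet springs.  Assembly is fully vectorised over elements; the system is
# solved by sparse Cholesky factorisation (Matrix).  Loads follow the study
# protocol: a follower load distributed over the L3 superior surface along
# the segment's local axis, plus a pure moment applied as the minimum-norm
# nodal force system on the same surface.

#' Attach ligament trusses to an FE model
#'
#' Each ligament attachment point is tied to the nearest mesh node; an
#' attachment farther than `max_dist` from every node is an error.  Four
#' capsular trusses are created per facet joint and side; annulus fibre
#' trusses (two criss-crossing families on the outer annulus wall) are
#' taken from the mesher's records.
#'
#' @param fem an `fe_model` from [tetrahedralize()]
#' @param model the `anatomy_model` the mesh was built from
#' @param materials material table (for truss areas)
#' @param max_dist maximum landmark-to-node distance (mm)
#' @return the `fe_model` with a populated `trusses` table
#' @export
attach_ligaments <- function(fem, model, materials = material_table(),
                             max_dist = 5) {
  lig <- model$ligaments
  near <- function(P, subset = NULL) {
    cand <- if (is.null(subset)) seq_len(nrow(fem$nodes)) else subset
    NN <- fem$nodes[cand, , drop = FALSE]
    d2 <- outer(rep(1, nrow(NN)), rowSums(P^2)) +
      rowSums(NN^2) - 2 * NN %*% t(P)
    idx <- apply(d2, 2, which.min)
    dst <- sqrt(pmax(0, d2[cbind(idx, seq_len(ncol(d2)))]))
    if (any(dst > max_dist))
      stop("ligament attachment farther than ", max_dist, " mm from any node (",
           paste(unique(lig$group[dst > max_dist]), collapse = ", "), ")")
    cand[idx]
  }
  # capsular attachments must land on the correct side of their joint plane
  # (IAP side vs SAP side), otherwise both ends can snap to one node
  n1 <- integer(nrow(lig)); n2 <- integer(nrow(lig))
  iscl <- lig$group == "CL"
  if (any(!iscl)) {
    n1[!iscl] <- near(as.matrix(lig[!iscl, c("ax", "ay", "az")]))
    n2[!iscl] <- near(as.matrix(lig[!iscl, c("bx", "by", "bz")]))
  }
  bone_node <- rep(FALSE, nrow(fem$nodes))
  bone_node[unique(as.vector(fem$tets[!grepl("facet_cartilage", fem$region), ]))] <- TRUE
  for (r in which(iscl)) {
    jf <- model$joints[[lig$level[r]]][[lig$side[r]]]
    sgn <- as.numeric(sweep(fem$nodes, 2, jf$center) %*% jf$n)
    n1[r] <- near(matrix(as.numeric(lig[r, c("ax", "ay", "az")]), 1),
                  subset = which(sgn > 0.05 & bone_node))
    n2[r] <- near(matrix(as.numeric(lig[r, c("bx", "by", "bz")]), 1),
                  subset = which(sgn < -0.05 & bone_node))
  }
  area <- materials$area[match(lig$group, materials$name)] * lig$share
  tr <- data.frame(n1 = n1, n2 = n2, group = lig$group, level = lig$level,
                   side = lig$side, area = area)
  tr <- tr[tr$n1 != tr$n2, ]
  if (!is.null(fem$fibers) && nrow(fem$fibers)) {
    fa <- materials$area[materials$name == "annulus_fiber"]
    fib <- data.frame(n1 = fem$fibers$n1, n2 = fem$fibers$n2,
                      group = "annulus_fiber", level = fem$fibers$level,
                      side = "mid", area = fa)
    tr <- rbind(tr, fib)
  }
  fem$trusses <- tr
  fem
}

# Facet contact springs: pair cartilage outer-face nodes across each joint.
# The spring direction is the joint normal tilted caudally by
# `contact_tilt` degrees - a linearisation of the curved articular surface,
# which lets the joint pick up load in extension (caudal sliding of the
# inferior process) as well as in rotation/bending.  Spring stiffness is a
# contact penalty, large against the cartilage layer stiffness, so joint
# compliance stays governed by the cartilage solid elements.
build_facet_springs <- function(fem, materials = material_table(),
                                max_pair_dist = 3, contact_k = 2500,
                                contact_tilt = 25) {
  if (!length(fem$springs_spec)) { fem$springs <- NULL; return(fem) }
  E_c <- materials$E[materials$name == "cartilage"]
  p <- fem$params
  sp_all <- list()
  byjoint <- split(fem$springs_spec,
                   vapply(fem$springs_spec, function(s) paste(s$joint, s$side), ""))
  for (js in byjoint) {
    roles <- vapply(js, `[[`, "", "role")
    if (!("iap" %in% roles) || !("sap" %in% roles)) next
    iap <- js[[which(roles == "iap")[1]]]
    sap <- js[[which(roles == "sap")[1]]]
    ia <- as.vector(iap$ids); sa <- as.vector(sap$ids)
    ia <- ia[ia > 0]; sa <- sa[sa > 0]
    if (!length(ia) || !length(sa)) next
    tau <- deg2rad(contact_tilt)
    zax <- fem$frames$disc_L4L5$R[, 3]
    n_hat <- unit(cos(tau) * iap$n + sin(tau) * zax)  # SAP side -> IAP side
    # pair opposing face nodes by perpendicular offset to the contact
    # direction, so every spring has a small non-negative rest gap
    Pa <- fem$nodes[ia, , drop = FALSE]; Pb <- fem$nodes[sa, , drop = FALSE]
    aa <- integer(0); bb <- integer(0); g0 <- numeric(0)
    for (qi in seq_along(ia)) {
      q <- -sweep(Pb, 2, Pa[qi, ], `-`)  # Pa[qi,] - Pb
      along <- as.numeric(q %*% n_hat)
      perp2 <- rowSums(q^2) - along^2
      cand <- which(along > -0.3 & along < max_pair_dist & perp2 <= 4.5^2)
      if (!length(cand)) next
      jb <- cand[which.min(perp2[cand])]
      aa <- c(aa, ia[qi]); bb <- c(bb, sa[jb])
      g0 <- c(g0, max(0, along[jb]))
    }
    if (!length(aa)) next
    sp_all[[length(sp_all) + 1]] <- data.frame(
      joint = iap$joint, side = iap$side, a = aa, b = bb,
      nx = n_hat[1], ny = n_hat[2], nz = n_hat[3],
      g0 = g0, k = contact_k)
  }
  fem$springs <- if (length(sp_all)) do.call(rbind, sp_all) else NULL
  fem
}

#' Convenience builder: mesh + ligaments + facet springs
#' @inheritParams tetrahedralize
#' @param materials material table
#' @return a solver-ready `fe_model`
#' @export
build_fe_model <- function(model, target_edge = 3, materials = material_table()) {
  validate_materials(materials)
  fem <- tetrahedralize(model, target_edge)
  fem <- attach_ligaments(fem, model, materials)
  fem <- build_facet_springs(fem, materials)
  fem$materials <- materials
  fem
}

## ---- assembly -----------------------------------------------------------

# shape-function gradients per element: list(g = m x 4 x 3 array, V = volumes)
tet_gradients <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  u <- nodes[tets[, 2], , drop = FALSE] - a
  v <- nodes[tets[, 3], , drop = FALSE] - a
  w <- nodes[tets[, 4], , drop = FALSE] - a
  cx <- function(p, q) cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
                             p[, 3] * q[, 1] - p[, 1] * q[, 3],
                             p[, 1] * q[, 2] - p[, 2] * q[, 1])
  vw <- cx(v, w); wu <- cx(w, u); uv <- cx(u, v)
  det <- rowSums(u * vw)
  g <- array(0, c(nrow(tets), 4, 3))
  g[, 2, ] <- vw / det
  g[, 3, ] <- wu / det
  g[, 4, ] <- uv / det
  g[, 1, ] <- -(g[, 2, ] + g[, 3, ] + g[, 4, ])
  list(g = g, V = det / 6)
}

#' Assemble the global stiffness matrix
#'
#' @param fem a solver-ready `fe_model`
#' @param materials material table
#' @return sparse symmetric stiffness matrix (3n x 3n)
#' @export
assemble_stiffness <- function(fem, materials = fem$materials %||% material_table()) {
  mt <- materials
  mat <- if (!is.null(fem$region_map)) unname(fem$region_map[fem$region])
  else region_material(fem$region)
  E <- mt$E[match(mat, mt$name)]
  nu <- mt$nu[match(mat, mt$name)]
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  gr <- tet_gradients(fem$nodes, fem$tets)
  g <- gr$g; V <- gr$V
  m <- nrow(fem$tets)
  nI <- integer(0); nJ <- integer(0); nX <- numeric(0)
  Ilist <- vector("list", 144); Jlist <- vector("list", 144); Xlist <- vector("list", 144)
  idx <- 0
  for (i in 1:4) for (j in 1:4) {
    gij <- g[, i, 1] * g[, j, 1] + g[, i, 2] * g[, j, 2] + g[, i, 3] * g[, j, 3]
    for (a in 1:3) for (b in 1:3) {
      val <- V * (lam * g[, i, a] * g[, j, b] + mu * g[, j, a] * g[, i, b] +
                    (a == b) * mu * gij)
      idx <- idx + 1
      Ilist[[idx]] <- 3L * (fem$tets[, i] - 1L) + a
      Jlist[[idx]] <- 3L * (fem$tets[, j] - 1L) + b
      Xlist[[idx]] <- val
    }
  }
  ndof <- 3L * nrow(fem$nodes)
  K <- Matrix::sparseMatrix(i = unlist(Ilist), j = unlist(Jlist),
                            x = unlist(Xlist), dims = c(ndof, ndof))
  # trusses
  if (!is.null(fem$trusses) && nrow(fem$trusses)) {
    tr <- fem$trusses
    Etr <- mt$E[match(tr$group, mt$name)]
    d <- fem$nodes[tr$n2, , drop = FALSE] - fem$nodes[tr$n1, , drop = FALSE]
    L <- sqrt(rowSums(d^2))
    dn <- d / L
    kt <- Etr * tr$area / L
    ti <- list(); tj <- list(); tx <- list()
    for (a in 1:3) for (b in 1:3) {
      kab <- kt * dn[, a] * dn[, b]
      dofs1a <- 3L * (tr$n1 - 1L) + a; dofs2a <- 3L * (tr$n2 - 1L) + a
      dofs1b <- 3L * (tr$n1 - 1L) + b; dofs2b <- 3L * (tr$n2 - 1L) + b
      ti <- c(ti, list(dofs1a, dofs2a, dofs1a, dofs2a))
      tj <- c(tj, list(dofs1b, dofs2b, dofs2b, dofs1b))
      tx <- c(tx, list(kab, kab, -kab, -kab))
    }
    K <- K + Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                                  dims = c(ndof, ndof))
  }
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# gap Jacobian of the contact springs: g = g0 + B u (sparse ns x ndof)
contact_jacobian <- function(fem) {
  sp <- fem$springs
  ndof <- 3L * nrow(fem$nodes)
  n <- as.matrix(sp[, c("nx", "ny", "nz")])
  i <- rep(seq_len(nrow(sp)), 6)
  j <- c(3L * (sp$a - 1L) + 1L, 3L * (sp$a - 1L) + 2L, 3L * (sp$a - 1L) + 3L,
         3L * (sp$b - 1L) + 1L, 3L * (sp$b - 1L) + 2L, 3L * (sp$b - 1L) + 3L)
  x <- c(n[, 1], n[, 2], n[, 3], -n[, 1], -n[, 2], -n[, 3])
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nrow(sp), ndof))
}

# projected Gauss-Seidel for the contact LCP:
# lambda >= 0, g = ghat + A lambda >= 0, lambda' g = 0
solve_contact_lcp <- function(A, ghat, iters = 400, tol = 1e-12) {
  ns <- length(ghat)
  lam <- numeric(ns)
  Ad <- diag(A)
  for (it in seq_len(iters)) {
    delta <- 0
    for (r in seq_len(ns)) {
      gr <- ghat[r] + sum(A[r, ] * lam)
      new <- max(0, lam[r] - gr / Ad[r])
      delta <- max(delta, abs(new - lam[r]))
      lam[r] <- new
    }
    if (delta < tol) break
  }
  lam
}

#' Load case definition
#' @param direction one of flexion, extension, left_bending, right_bending,
#'   left_rotation, right_rotation
#' @param follower_load compressive preload (N), default 400
#' @param moment applied pure moment (N m), default 10
#' @export
load_case <- function(direction = c("flexion", "extension", "left_bending",
                                    "right_bending", "left_rotation",
                                    "right_rotation"),
                      follower_load = 400, moment = 10) {
  direction <- match.arg(direction)
  if (follower_load < 0 || moment < 0) stop("load magnitudes must be >= 0")
  structure(list(direction = direction, follower_load = follower_load,
                 moment = moment), class = "load_case")
}

# moment axis in world coordinates, following the frame convention
# (+x right, +y anterior, +z cranial): flexion is forward rotation about -x
moment_axis <- function(fem, direction) {
  R <- fem$frames$L3$R
  switch(direction,
         flexion = -R[, 1], extension = R[, 1],
         left_bending = -R[, 2], right_bending = R[, 2],
         left_rotation = R[, 3], right_rotation = -R[, 3])
}

# nodal force vector for a load case
load_vector <- function(fem, load) {
  ndof <- 3L * nrow(fem$nodes)
  f <- numeric(ndof)
  ln <- fem$load_nodes
  axis_z <- fem$frames$L3$R[, 3]
  if (load$follower_load > 0) {
    per <- load$follower_load / length(ln)
    for (a in 1:3) f[3L * (ln - 1L) + a] <- f[3L * (ln - 1L) + a] - per * axis_z[a]
  }
  if (load$moment > 0) {
    Mvec <- moment_axis(fem, load$direction) * load$moment * 1000  # N mm
    P <- fem$nodes[ln, , drop = FALSE]
    ctr <- colMeans(P)
    r <- sweep(P, 2, ctr)
    nl <- length(ln)
    # minimum-norm force system: A q = (0, M), q = A' (A A')^-1 b
    A <- matrix(0, 6, 3 * nl)
    for (a in 1:3) A[a, seq(a, 3 * nl, by = 3)] <- 1
    # moment rows: r x f
    A[4, seq(2, 3 * nl, 3)] <- -r[, 3]; A[4, seq(3, 3 * nl, 3)] <- r[, 2]
    A[5, seq(1, 3 * nl, 3)] <- r[, 3]; A[5, seq(3, 3 * nl, 3)] <- -r[, 1]
    A[6, seq(1, 3 * nl, 3)] <- -r[, 2]; A[6, seq(2, 3 * nl, 3)] <- r[, 1]
    b <- c(0, 0, 0, Mvec)
    q <- t(A) %*% solve(A %*% t(A), b)
    dofs <- as.vector(t(outer(3L * (ln - 1L), 1:3, `+`)))
    f[dofs] <- f[dofs] + as.numeric(q)
  }
  f
}

#' Solve a load case on an FE model
#'
#' Linear static solution of K u = f with the L5 inferior surface fixed.
#' Facet contact is resolved exactly within the linear kinematics: the
#' compression-only pairs define a small linear complementarity problem on
#' the contact Schur complement (gap >= 0, contact force >= 0,
#' complementary), solved by projected Gauss-Seidel; cartilage surface
#' compliance enters through the pairs' finite stiffness.
#'
#' @param fem solver-ready `fe_model` (see [build_fe_model()])
#' @param load a [load_case()]
#' @param K optional pre-assembled base stiffness (from
#'   [assemble_stiffness()]) to reuse across load cases
#' @param contact use the compression-only facet springs (default TRUE)
#' @return list with `u` (n x 3 displacements, mm), `residual` (relative),
#'   `reactions` (sum of reaction forces at fixed nodes), `engaged`
#'   (spring count)
#' @export
assemble_and_solve <- function(fem, load, K = NULL, contact = TRUE) {
  if (length(fem$fixed_nodes) == 0) stop("no fixed nodes: system is singular")
  if (is.null(K)) K <- assemble_stiffness(fem)
  f <- load_vector(fem, load)
  ndof <- 3L * nrow(fem$nodes)
  fixed_dofs <- as.vector(t(outer(3L * (fem$fixed_nodes - 1L), 1:3, `+`)))
  # nodes no longer referenced by any element (after resection) carry no
  # stiffness; exclude their dofs
  used <- unique(c(as.vector(fem$tets),
                   if (!is.null(fem$trusses)) c(fem$trusses$n1, fem$trusses$n2)))
  orphan <- setdiff(seq_len(nrow(fem$nodes)), used)
  if (length(orphan))
    fixed_dofs <- union(fixed_dofs, as.vector(t(outer(3L * (orphan - 1L), 1:3, `+`))))
  free <- setdiff(seq_len(ndof), fixed_dofs)
  Kff <- Matrix::forceSymmetric(K[free, free])
  ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE),
                 error = function(e)
                   stop("singular stiffness matrix (insufficient constraints ",
                        "or floating fragment): ", conditionMessage(e)))
  solve_free <- function(rhs_free) as.numeric(Matrix::solve(ch, rhs_free))
  u <- numeric(ndof)
  u[free] <- solve_free(f[free])
  engaged <- 0L
  ftot <- f
  if (contact && !is.null(fem$springs) && nrow(fem$springs)) {
    sp <- fem$springs
    B <- contact_jacobian(fem)
    Bf <- B[, free, drop = FALSE]
    ghat <- sp$g0 + as.numeric(Bf %*% u[free])
    # Schur complement of the stiffness onto the contact gaps, plus the
    # pairs' own compliance (cartilage surface stiffness)
    W <- matrix(0, length(free), nrow(sp))
    Bt <- Matrix::t(Bf)
    for (r in seq_len(nrow(sp))) W[, r] <- solve_free(Bt[, r])
    A <- as.matrix(Bf %*% W) + diag(1 / sp$k, nrow(sp))
    lam <- solve_contact_lcp(A, ghat)
    engaged <- sum(lam > 1e-9)
    if (engaged > 0) {
      u[free] <- u[free] + as.numeric(W %*% lam)
      ftot <- f + as.numeric(Matrix::t(B) %*% lam)
    }
  }
  res <- K %*% u - ftot
  rel_res <- sqrt(sum(res[free]^2)) / max(sqrt(sum(ftot[free]^2)), 1e-30)
  if (rel_res > 1e-8)
    stop(sprintf("solver did not reach the residual tolerance (%.2e)", rel_res))
  reactions <- as.numeric(res[fixed_dofs])
  list(u = matrix(u, ncol = 3, byrow = TRUE), residual = rel_res,
       reactions = matrix(reactions, ncol = 3, byrow = TRUE),
       engaged = engaged, f = ftot)
}

#' Element von Mises stresses and per-region maxima
#'
#' Constant strain/stress per tetrahedron;
#' `sigma_vm = sqrt(((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2) / 2)` evaluated
#' from the deviatoric stress invariant.
#'
#' @param fem `fe_model`
#' @param u displacement matrix from [assemble_and_solve()]
#' @param regions regions to report maxima for (default: L4/5 annulus and
#'   the adjacent endplates)
#' @return list with `vm` (per element) and `max_by_region`
#' @export
compute_von_mises <- function(fem, u,
                              regions = c("disc_L4L5_annulus",
                                          "endplate_L5_superior",
                                          "endplate_L4_inferior")) {
  mt <- fem$materials %||% material_table()
  mat <- if (!is.null(fem$region_map)) unname(fem$region_map[fem$region])
  else region_material(fem$region)
  E <- mt$E[match(mat, mt$name)]
  nu <- mt$nu[match(mat, mt$name)]
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  gr <- tet_gradients(fem$nodes, fem$tets)
  g <- gr$g
  ue <- array(0, c(nrow(fem$tets), 4, 3))
  for (i in 1:4) ue[, i, ] <- u[fem$tets[, i], ]
  eps <- array(0, c(nrow(fem$tets), 3, 3))
  for (a in 1:3) for (b in 1:3) {
    s <- 0
    for (i in 1:4) s <- s + 0.5 * (g[, i, a] * ue[, i, b] + g[, i, b] * ue[, i, a])
    eps[, a, b] <- s
  }
  tre <- eps[, 1, 1] + eps[, 2, 2] + eps[, 3, 3]
  sig <- array(0, c(nrow(fem$tets), 3, 3))
  for (a in 1:3) for (b in 1:3)
    sig[, a, b] <- 2 * mu * eps[, a, b] + (a == b) * lam * tre
  sm <- (sig[, 1, 1] + sig[, 2, 2] + sig[, 3, 3]) / 3
  dev11 <- sig[, 1, 1] - sm; dev22 <- sig[, 2, 2] - sm; dev33 <- sig[, 3, 3] - sm
  J2 <- 0.5 * (dev11^2 + dev22^2 + dev33^2) +
    sig[, 1, 2]^2 + sig[, 1, 3]^2 + sig[, 2, 3]^2
  vm <- sqrt(3 * J2)
  mx <- vapply(regions, function(rg) {
    sel <- fem$region == rg
    if (!any(sel)) NA_real_ else max(vm[sel])
  }, 0)
  list(vm = vm, max_by_region = mx)
}

#' Intervertebral range of motion from a displacement field
#'
#' Fits least-squares rigid transforms (Kabsch) to the cortical nodes of
#' the cranial and caudal vertebrae of a level and reports the total
#' relative rotation angle in degrees.
#'
#' @param fem `fe_model`
#' @param u displacement matrix
#' @param level "L4L5" or "L3L4"
#' @return rotation angle (degrees)
#' @export
compute_rom <- function(fem, u, level = c("L4L5", "L3L4")) {
  level <- match.arg(level)
  pair <- if (level == "L4L5") c("L4", "L5") else c("L3", "L4")
  rot_of <- function(lv) {
    sel <- unique(as.vector(fem$tets[fem$region == paste0(lv, "_cortical"), ]))
    if (length(sel) < 4) stop("too few cortical nodes for level ", lv)
    P <- fem$nodes[sel, , drop = FALSE]
    if (svd(sweep(P, 2, colMeans(P)))$d[3] < 1e-6)
      stop("degenerate (coplanar) cortical node set for ", lv)
    kabsch(P, P + u[sel, , drop = FALSE])$R
  }
  Rrel <- rot_of(pair[1]) %*% t(rot_of(pair[2]))
  rotation_angle_deg(Rrel)
}
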