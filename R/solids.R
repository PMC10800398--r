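# Implicit solids and constructive solid geometry.
#
# A solid is a continuous scalar field over R^3 that is negative inside,
# positive outside and zero on the boundary (signed-distance-like, not an
# exact distance), together with a finite axis-aligned bounding box.
# Booleans are field compositions (max/min); watertight boundary surfaces
# are recovered by marching tetrahedra on a lattice with per-edge bisection
# root finding, and volumes follow from the divergence theorem on that
# surface.  Monte Carlo point classification over the same predicates is
# the independent volume oracle.

#' Construct a solid from a field function
#'
#' @param field function taking an n x 3 point matrix, returning n signed
#'   values (negative inside).
#' @param bbox 2 x 3 bounding box (min row, max row) guaranteed to contain
#'   the solid.
#' @param label optional name.
#' @return an object of class `ls_solid`
#' @export
solid_new <- function(field, bbox, label = NULL) {
  structure(list(field = field, bbox = bbox, label = label, empty = is.null(bbox)),
            class = "ls_solid")
}

#' @export
print.ls_solid <- function(x, ...) {
  if (x$empty) cat("<ls_solid: empty>\n")
  else cat(sprintf("<ls_solid%s: bbox [%.1f..%.1f, %.1f..%.1f, %.1f..%.1f]>\n",
                   if (is.null(x$label)) "" else paste0(" ", x$label),
                   x$bbox[1, 1], x$bbox[2, 1], x$bbox[1, 2], x$bbox[2, 2],
                   x$bbox[1, 3], x$bbox[2, 3]))
  invisible(x)
}

#' Evaluate a solid's field
#' @param solid an `ls_solid`
#' @param P n x 3 point matrix
#' @return signed values, negative inside
#' @export
solid_field <- function(solid, P) {
  P <- as_points(P)
  if (solid$empty) return(rep(1, nrow(P)))
  solid$field(P)
}

#' Point containment in a solid
#' @inheritParams solid_field
#' @return logical vector
#' @export
solid_contains <- function(solid, P) solid_field(solid, P) < 0

## ---- primitives ---------------------------------------------------------

#' Oriented box solid
#' @param center box centre (mm)
#' @param hdims half side lengths along the local axes
#' @param R 3x3 rotation, columns = local axes in world coordinates
#' @export
solid_box <- function(center, hdims, R = diag(3), label = NULL) {
  center <- as.numeric(center); hdims <- as.numeric(hdims)
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  corners <- sweep(corners %*% diag(hdims) %*% t(R), 2, center, `+`)
  field <- function(P) {
    Q <- sweep(P, 2, center) %*% R
    pmax(abs(Q[, 1]) - hdims[1], abs(Q[, 2]) - hdims[2], abs(Q[, 3]) - hdims[3])
  }
  solid_new(field, bbox_of(corners), label)
}

#' Finite right circular cylinder solid
#' @param base centre of the base disc
#' @param dir unit axis direction (base -> tip)
#' @param radius radius (mm)
#' @param length axial length (mm)
#' @export
solid_cylinder <- function(base, dir, radius, length, label = NULL) {
  base <- as.numeric(base); dir <- unit(dir)
  tip <- base + length * dir
  field <- function(P) {
    Q <- sweep(P, 2, base)
    t <- as.numeric(Q %*% dir)
    rho2 <- rowSums(Q^2) - t^2
    pmax(sqrt(pmax(rho2, 0)) - radius, -t, t - length)
  }
  bb <- bbox_pad(bbox_of(rbind(base, tip)), radius)
  solid_new(field, bb, label)
}

#' Oriented superelliptic prism
#'
#' A prism along the local third axis whose cross-section in the first two
#' local axes is a superellipse — a box with rounded corners for exponents
#' between 2 and ~4.  Used for rounded anatomical blocks such as articular
#' processes.
#' @param center prism centre
#' @param hdims half dimensions (cross-section half-axes, half length)
#' @param R 3x3 orientation, columns = local axes
#' @param exponent superellipse exponent of the cross-section
#' @export
solid_oval_prism <- function(center, hdims, R = diag(3), exponent = 2.5,
                             label = NULL) {
  center <- as.numeric(center); hdims <- as.numeric(hdims)
  xf <- se_field(hdims[1], hdims[2], exponent)
  corners <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  corners <- sweep(corners %*% diag(hdims) %*% t(R), 2, center, `+`)
  field <- function(P) {
    Q <- sweep(P, 2, center) %*% R
    pmax(xf(Q[, 1:2, drop = FALSE]), abs(Q[, 3]) - hdims[3])
  }
  solid_new(field, bbox_of(corners), label)
}

#' Solid backed by a watertight mesh
#'
#' The field is a binary indicator (+/-1) from ray-cast containment; the
#' marching-tetrahedra extractor recovers the boundary by bisection, so the
#' binary field still yields surface points accurate to the bisection
#' tolerance.
#' @param mesh a watertight `ls_mesh`
#' @export
solid_from_mesh <- function(mesh, label = NULL) {
  field <- function(P) ifelse(point_in_mesh(mesh, P), -1, 1)
  solid_new(field, bbox_of(mesh$V), label)
}

# Extruded slab between two bounding planes, with a 2-D cross-section field
# evaluated in the x-y of `frame`.  Planes are given as (point, outward
# normal) pairs in world coordinates.
solid_slab <- function(frame, xsec_field, xsec_bbox2d, plane_lo, plane_hi,
                       label = NULL) {
  nlo <- unit(plane_lo$normal); nhi <- unit(plane_hi$normal)
  plo <- plane_lo$point; phi <- plane_hi$point
  field <- function(P) {
    L <- frame_to_local(frame, P)
    fxy <- xsec_field(L[, 1:2, drop = FALSE])
    flo <- as.numeric(sweep(P, 2, plo) %*% nlo)
    fhi <- as.numeric(sweep(P, 2, phi) %*% nhi)
    pmax(fxy, flo, fhi)
  }
  # bbox from the cross-section rectangle swept between the two planes
  g <- as.matrix(expand.grid(xsec_bbox2d[, 1], xsec_bbox2d[, 2]))
  span <- sum((phi - plo) * nhi)
  pts <- rbind(cbind(g, -abs(span) * 0.6 - 2), cbind(g, abs(span) * 0.6 + 2))
  # place relative to the slab's mid point
  mid <- (plo + phi) / 2
  fr2 <- frame_new(mid, frame$R)
  solid_new(field, bbox_pad(bbox_of(frame_to_world(fr2, pts)), 0.5), label)
}

# Superellipse cross-section field factory: |x/a|^n + |y/b|^n = 1 boundary,
# scaled so the value approximates a distance near the boundary.
se_field <- function(a, b, n, center = c(0, 0)) {
  s <- min(a, b)
  function(XY) {
    x <- abs(XY[, 1] - center[1]) / a
    y <- abs(XY[, 2] - center[2]) / b
    ((x^n + y^n)^(1 / n) - 1) * s
  }
}

# Ring between two cross-section fields (outer minus inner).
ring_field <- function(outer, inner) function(XY) pmax(outer(XY), -inner(XY))

# Radius of a superellipse boundary along direction (ux, uy) from `from`.
se_ray_radius <- function(a, b, n, center = c(0, 0), from = center, ux, uy) {
  f <- se_field(a, b, n, center)
  lo <- rep(0, length(ux)); hi <- rep(2 * (a + b), length(ux))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    v <- f(cbind(from[1] + mid * ux, from[2] + mid * uy))
    out <- v > 0
    hi[out] <- mid[out]
    lo[!out] <- mid[!out]
  }
  (lo + hi) / 2
}

## ---- CSG ----------------------------------------------------------------

# Children are evaluated lazily: once the first field decides the sign with
# a 1.5 mm margin, later (usually costlier) children are only evaluated on
# the undecided points.  Returned values are sign-correct everywhere and
# exact within the margin band, which is all the surface extractor needs.
.csg_margin <- 1.5

#' Boolean intersection of solids
#' @param ... `ls_solid` objects (cheapest field first for speed)
#' @export
solid_intersection <- function(..., label = NULL) {
  ss <- list(...)
  if (length(ss) == 1 && is.list(ss[[1]]) && !inherits(ss[[1]], "ls_solid"))
    ss <- ss[[1]]
  if (any(vapply(ss, `[[`, TRUE, "empty"))) return(solid_new(NULL, NULL, label))
  bb <- Reduce(bbox_intersect, lapply(ss, `[[`, "bbox"))
  if (is.null(bb)) return(solid_new(NULL, NULL, label))
  field <- function(P) {
    f <- ss[[1]]$field(P)
    if (length(ss) > 1) {
      act <- which(f < .csg_margin)
      if (length(act)) {
        sub <- P[act, , drop = FALSE]
        for (k in 2:length(ss)) f[act] <- pmax(f[act], ss[[k]]$field(sub))
      }
    }
    f
  }
  solid_new(field, bb, label)
}

#' Boolean union of solids
#' @param ... `ls_solid` objects or a single list of them
#' @export
solid_union <- function(..., label = NULL) {
  ss <- list(...)
  if (length(ss) == 1 && is.list(ss[[1]]) && !inherits(ss[[1]], "ls_solid"))
    ss <- ss[[1]]
  ss <- ss[!vapply(ss, `[[`, TRUE, "empty")]
  if (length(ss) == 0) return(solid_new(NULL, NULL, label))
  bb <- Reduce(bbox_union, lapply(ss, `[[`, "bbox"))
  field <- function(P) {
    f <- ss[[1]]$field(P)
    if (length(ss) > 1) {
      act <- which(f > -.csg_margin)
      if (length(act)) {
        sub <- P[act, , drop = FALSE]
        for (k in 2:length(ss)) f[act] <- pmin(f[act], ss[[k]]$field(sub))
      }
    }
    f
  }
  solid_new(field, bb, label)
}

#' Boolean difference a minus b
#' @param a,b `ls_solid` objects
#' @export
solid_difference <- function(a, b, label = NULL) {
  if (a$empty) return(solid_new(NULL, NULL, label))
  if (b$empty || is.null(bbox_intersect(a$bbox, b$bbox)))
    return(solid_new(a$field, a$bbox, label %||% a$label))
  field <- function(P) {
    f <- a$field(P)
    act <- which(f < .csg_margin)
    if (length(act)) f[act] <- pmax(f[act], -b$field(P[act, , drop = FALSE]))
    f
  }
  solid_new(field, a$bbox, label)
}

## ---- surface extraction (marching tetrahedra) ---------------------------

# evaluate a field over a lattice in z-slab chunks to bound memory
eval_field_grid <- function(solid, xs, ys, zs, chunk_pts = 6e5) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  out <- numeric(nx * ny * nz)
  per_slab <- nx * ny
  zstep <- max(1L, as.integer(floor(chunk_pts / per_slab)))
  xy <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  k <- 1L
  while (k <= nz) {
    kk <- seq.int(k, min(nz, k + zstep - 1L))
    P <- cbind(xy[rep(seq_len(per_slab), length(kk)), , drop = FALSE],
               rep(zs[kk], each = per_slab))
    out[(kk[1] - 1L) * per_slab + seq_len(per_slab * length(kk))] <- solid$field(P)
    k <- kk[length(kk)] + 1L
  }
  out
}

# Freudenthal decomposition of a cube into 6 tetrahedra, corners numbered by
# bit triplets (bx, by, bz) -> index = 1 + bx + 2 by + 4 bz.
.freudenthal <- rbind(
  c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
  c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))

#' Extract the boundary surface of a solid
#'
#' Marching tetrahedra on a uniform lattice.  Each lattice cell is split into
#' six tetrahedra; sign changes along tetrahedron edges are located by
#' bisection of the solid's field, so the surface is accurate to a small
#' fraction of the lattice pitch and watertight by construction.
#'
#' @param solid an `ls_solid`
#' @param pitch lattice spacing (mm)
#' @param bbox optional region of interest (2 x 3); defaults to the solid's
#'   bounding box
#' @param refine number of bisection iterations per crossing edge
#' @return an `ls_mesh` (possibly with zero faces when the solid is empty)
#' @export
solid_surface <- function(solid, pitch = 0.4, bbox = NULL, refine = 10) {
  empty <- mesh_new(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  if (solid$empty) return(empty)
  bb <- bbox %||% solid$bbox
  bb <- bbox_pad(bb, 1.01 * pitch)
  xs <- seq(bb[1, 1], bb[2, 1] + pitch, by = pitch)
  ys <- seq(bb[1, 2], bb[2, 2] + pitch, by = pitch)
  zs <- seq(bb[1, 3], bb[2, 3] + pitch, by = pitch)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  f <- eval_field_grid(solid, xs, ys, zs)
  f[f == 0] <- pitch * 1e-9
  inside <- f < 0
  if (!any(inside)) return(empty)

  # active cells: sign change among the 8 corners
  dim(inside) <- c(nx, ny, nz)
  ii <- 1:(nx - 1); jj <- 1:(ny - 1); kk <- 1:(nz - 1)
  cnt <- inside[ii, jj, kk] + inside[ii + 1, jj, kk] +
    inside[ii, jj + 1, kk] + inside[ii + 1, jj + 1, kk] +
    inside[ii, jj, kk + 1] + inside[ii + 1, jj, kk + 1] +
    inside[ii, jj + 1, kk + 1] + inside[ii + 1, jj + 1, kk + 1]
  act <- which(cnt > 0 & cnt < 8)
  if (length(act) == 0) return(empty)
  ai <- (act - 1) %% (nx - 1) + 1
  aj <- ((act - 1) %/% (nx - 1)) %% (ny - 1) + 1
  ak <- (act - 1) %/% ((nx - 1) * (ny - 1)) + 1
  base <- ai + (aj - 1) * nx + (ak - 1) * nx * ny
  off <- c(0, 1, nx, nx + 1, nx * ny, nx * ny + 1, nx * ny + nx, nx * ny + nx + 1)
  corners <- outer(base, off, `+`)  # ncell x 8 lattice ids

  # all tets of active cells: ntet x 4 lattice ids
  tets <- do.call(rbind, lapply(seq_len(6), function(r)
    corners[, .freudenthal[r, ], drop = FALSE]))
  tin <- matrix(inside[tets], ncol = 4)
  m <- rowSums(tin)
  keep <- m > 0 & m < 4
  tets <- tets[keep, , drop = FALSE]
  tin <- tin[keep, , drop = FALSE]
  m <- m[keep]
  if (nrow(tets) == 0) return(empty)

  # order each tet's corners as (inside..., outside...), vectorised
  ntet <- nrow(tets)
  W <- (!tin) * 8L + col(tin)
  og <- order(rep(seq_len(ntet), 4), as.vector(W))
  ord <- matrix(((og - 1L) %/% ntet) + 1L, ncol = 4, byrow = TRUE)
  tets_o <- matrix(tets[cbind(rep(seq_len(ntet), 4), as.vector(ord))],
                   ncol = 4)

  ekey <- function(i, j) pmin(i, j) * (nx * ny * nz + 1) + pmax(i, j)
  tris <- list(); tref <- list()
  emit <- function(e1, e2, e3, ref_in, ref_out) {
    tris[[length(tris) + 1]] <<- cbind(e1, e2, e3)
    tref[[length(tref) + 1]] <<- cbind(ref_in, ref_out)
  }
  # m == 1: inside corner v = col1; edges to cols 2..4
  s1 <- m == 1
  if (any(s1)) {
    t1 <- tets_o[s1, , drop = FALSE]
    emit(ekey(t1[, 1], t1[, 2]), ekey(t1[, 1], t1[, 3]), ekey(t1[, 1], t1[, 4]),
         t1[, 1], t1[, 2])
  }
  # m == 3: outside corner w = col4; edges from cols 1..3
  s3 <- m == 3
  if (any(s3)) {
    t3 <- tets_o[s3, , drop = FALSE]
    emit(ekey(t3[, 4], t3[, 1]), ekey(t3[, 4], t3[, 2]), ekey(t3[, 4], t3[, 3]),
         t3[, 1], t3[, 4])
  }
  # m == 2: inside cols 1-2, outside cols 3-4 -> quad
  s2 <- m == 2
  if (any(s2)) {
    t2 <- tets_o[s2, , drop = FALSE]
    e13 <- ekey(t2[, 1], t2[, 3]); e14 <- ekey(t2[, 1], t2[, 4])
    e23 <- ekey(t2[, 2], t2[, 3]); e24 <- ekey(t2[, 2], t2[, 4])
    emit(e13, e14, e24, t2[, 1], t2[, 3])
    emit(e13, e24, e23, t2[, 1], t2[, 3])
  }
  tris <- do.call(rbind, tris)
  tref <- do.call(rbind, tref)

  # unique crossing edges -> surface vertices by bisection
  allk <- unique(as.vector(tris))
  Nbig <- nx * ny * nz + 1
  idA <- floor(allk / Nbig); idB <- allk - idA * Nbig
  latpt <- function(id) {
    id0 <- id - 1
    cbind(xs[id0 %% nx + 1], ys[(id0 %/% nx) %% ny + 1], zs[id0 %/% (nx * ny) + 1])
  }
  P0 <- latpt(idA); P1 <- latpt(idB)
  f0 <- f[idA]; f1 <- f[idB]
  # ensure f0 < 0 (inside end first)
  sw <- f0 > 0
  if (any(sw)) {
    tmp <- P0[sw, , drop = FALSE]; P0[sw, ] <- P1[sw, , drop = FALSE]; P1[sw, ] <- tmp
    tf <- f0[sw]; f0[sw] <- f1[sw]; f1[sw] <- tf
  }
  for (it in seq_len(refine)) {
    Pm <- (P0 + P1) / 2
    fm <- solid$field(Pm)
    neg <- fm < 0
    P0[neg, ] <- Pm[neg, , drop = FALSE]; f0[neg] <- fm[neg]
    P1[!neg, ] <- Pm[!neg, , drop = FALSE]; f1[!neg] <- fm[!neg]
  }
  tt <- f0 / (f0 - f1)
  X <- P0 + (P1 - P0) * tt

  Fidx <- matrix(match(tris, allk), ncol = 3)
  # orient: normal should point from inside lattice corner toward outside one
  vin <- latpt(tref[, 1])
  vout <- latpt(tref[, 2])
  a <- X[Fidx[, 1], , drop = FALSE]
  b <- X[Fidx[, 2], , drop = FALSE]
  cc <- X[Fidx[, 3], , drop = FALSE]
  nrm <- cbind((b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
  flip <- rowSums(nrm * (vout - vin)) < 0
  Fidx[flip, ] <- Fidx[flip, c(1, 3, 2)]
  m <- mesh_new(X, Fidx)
  # weld coincident crossing points (CSG creases can pinch two lattice
  # edges onto one point) and drop the resulting degenerate faces
  m <- mesh_weld(m, tol = 1e-7)
  tr <- mesh_triangles(m)
  e1 <- tr$B - tr$A; e2 <- tr$C - tr$A
  nn2 <- (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])^2 +
    (e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3])^2 +
    (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2
  mesh_new(m$V, m$F[nn2 > (1e-9 * pitch^2)^2, , drop = FALSE])
}

#' Volume of a solid by surface extraction
#' @inheritParams solid_surface
#' @return volume in mm^3
#' @export
solid_volume <- function(solid, pitch = 0.4, bbox = NULL) {
  m <- solid_surface(solid, pitch = pitch, bbox = bbox)
  if (nrow(m$F) == 0) return(0)
  mesh_volume(m)
}
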