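# Triangulated surface meshes.  A mesh is a list with V (n x 3 vertex matrix)
# and F (m x 3 integer face matrix, 1-based, consistently oriented with
# outward normals).  A mesh may contain several closed components (for
# example a cortical shell stores its outer and inner boundary surfaces).

#' Construct a triangle mesh
#'
#' @param V n x 3 numeric matrix of vertex coordinates (mm).
#' @param F m x 3 integer matrix of vertex indices per triangle (1-based),
#'   oriented counter-clockwise when seen from outside.
#' @return an object of class `ls_mesh`.
#' @export
mesh_new <- function(V, F) {
  V <- as_points(V)
  F <- matrix(as.integer(F), ncol = 3)
  if (nrow(F) > 0 && (min(F) < 1 || max(F) > nrow(V)))
    stop("face indices out of range")
  structure(list(V = V, F = F), class = "ls_mesh")
}

#' @export
print.ls_mesh <- function(x, ...) {
  cat(sprintf("<ls_mesh: %d vertices, %d faces, volume %.2f mm^3>\n",
              nrow(x$V), nrow(x$F), mesh_volume(x)))
  invisible(x)
}

mesh_triangles <- function(mesh) {
  list(A = mesh$V[mesh$F[, 1], , drop = FALSE],
       B = mesh$V[mesh$F[, 2], , drop = FALSE],
       C = mesh$V[mesh$F[, 3], , drop = FALSE])
}

#' Enclosed volume of a closed oriented mesh (divergence theorem)
#' @param mesh an `ls_mesh`
#' @return volume in mm^3 (positive for outward orientation)
#' @export
mesh_volume <- function(mesh) {
  if (nrow(mesh$F) == 0) return(0)
  tr <- mesh_triangles(mesh)
  a <- tr$A; b <- tr$B; c <- tr$C
  det6 <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  sum(det6) / 6
}

#' Total surface area of a mesh
#' @param mesh an `ls_mesh`
#' @return area in mm^2
#' @export
mesh_area <- function(mesh) {
  tr <- mesh_triangles(mesh)
  e1 <- tr$B - tr$A
  e2 <- tr$C - tr$A
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(nx^2 + ny^2 + nz^2)) / 2
}

mesh_centroid <- function(mesh) {
  # volume centroid of the enclosed solid
  tr <- mesh_triangles(mesh)
  a <- tr$A; b <- tr$B; c <- tr$C
  det6 <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
  w <- det6 / 6
  ctr <- (a + b + c) / 4  # centroid of tet (origin, a, b, c)
  colSums(ctr * w) / sum(w)
}

#' Check watertightness of a mesh
#'
#' A mesh is watertight when every directed edge is matched by exactly one
#' oppositely directed edge (each undirected edge borders exactly two faces
#' with consistent orientation).
#' @param mesh an `ls_mesh`
#' @return TRUE/FALSE
#' @export
mesh_is_watertight <- function(mesh) {
  F <- mesh$F
  if (nrow(F) == 0) return(FALSE)
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key_fwd <- paste(he[, 1], he[, 2])
  key_rev <- paste(he[, 2], he[, 1])
  if (anyDuplicated(key_fwd)) return(FALSE)
  all(key_fwd %in% key_rev)
}

mesh_transform <- function(mesh, R = diag(3), t = c(0, 0, 0)) {
  m <- mesh_new(sweep(mesh$V %*% t(R), 2, t, `+`), mesh$F)
  if (det(R) < 0) m$F <- m$F[, c(1, 3, 2), drop = FALSE]  # keep orientation
  m
}

mesh_merge <- function(...) {
  ms <- list(...)
  V <- do.call(rbind, lapply(ms, `[[`, "V"))
  off <- cumsum(c(0, vapply(ms, function(m) nrow(m$V), 0L)))
  F <- do.call(rbind, Map(function(m, o) m$F + o, ms, off[-length(off)]))
  mesh_new(V, F)
}

# Weld vertices closer than `tol` and drop degenerate faces.
mesh_weld <- function(mesh, tol = 1e-6) {
  key <- paste(round(mesh$V[, 1] / tol), round(mesh$V[, 2] / tol),
               round(mesh$V[, 3] / tol))
  idx <- match(key, key)
  keep <- which(idx == seq_along(idx))
  remap <- match(idx, keep)
  F <- matrix(remap[mesh$F], ncol = 3)
  degen <- F[, 1] == F[, 2] | F[, 2] == F[, 3] | F[, 1] == F[, 3]
  mesh_new(mesh$V[keep, , drop = FALSE], F[!degen, , drop = FALSE])
}

## ---- planar cross sections ---------------------------------------------

#' Cross-section of a mesh by a plane
#'
#' Intersects a closed mesh with a plane and chains the crossing segments
#' into closed loops.  Loops are returned in 2-D in-plane coordinates.
#'
#' @param mesh an `ls_mesh`
#' @param plane a list with `point` and `normal` (see [plane_new()])
#' @param axes optional 2 x 3 matrix of in-plane basis vectors; defaults to
#'   an arbitrary orthonormal pair.
#' @return list of loops; each loop is a list with `xy` (k x 2 matrix of
#'   in-plane coordinates) and `area` (absolute polygon area, mm^2).
#' @export
mesh_section <- function(mesh, plane, axes = NULL) {
  n <- unit(plane$normal)
  d <- as.numeric(mesh$V %*% n) - sum(plane$point * n)
  F <- mesh$F
  sa <- d[F[, 1]]; sb <- d[F[, 2]]; sc <- d[F[, 3]]
  crosses <- (pmax(sa, sb, sc) > 0) & (pmin(sa, sb, sc) < 0)
  if (!any(crosses)) stop("plane does not intersect the mesh")
  F <- F[crosses, , drop = FALSE]

  # For each crossing triangle, find its two crossed edges (undirected keys).
  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  e12 <- (d[F[, 1]] > 0) != (d[F[, 2]] > 0)
  e23 <- (d[F[, 2]] > 0) != (d[F[, 3]] > 0)
  e31 <- (d[F[, 3]] > 0) != (d[F[, 1]] > 0)
  keys <- cbind(ifelse(e12, edge_key(F[, 1], F[, 2]), NA),
                ifelse(e23, edge_key(F[, 2], F[, 3]), NA),
                ifelse(e31, edge_key(F[, 3], F[, 1]), NA))
  pair <- t(apply(keys, 1, function(r) r[!is.na(r)][1:2]))

  # crossing point per unique edge key
  ukeys <- unique(as.vector(pair))
  usplit <- strsplit(ukeys, " ")
  ui <- as.integer(vapply(usplit, `[`, "", 1))
  uj <- as.integer(vapply(usplit, `[`, "", 2))
  ti <- d[ui] / (d[ui] - d[uj])
  upts <- mesh$V[ui, , drop = FALSE] +
    (mesh$V[uj, , drop = FALSE] - mesh$V[ui, , drop = FALSE]) * ti
  rownames(upts) <- ukeys

  # chain segments into loops (each key appears in exactly 2 segments for a
  # watertight mesh)
  adj <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(pair))) {
    for (s in 1:2) {
      k <- pair[r, s]
      assign(k, c(get0(k, envir = adj, ifnotfound = integer(0)), r), envir = adj)
    }
  }
  if (is.null(axes)) {
    ex <- unit(if (abs(n[1]) < 0.9) cross3(n, c(1, 0, 0)) else cross3(n, c(0, 1, 0)))
    ey <- cross3(n, ex)
    axes <- rbind(ex, ey)
  }
  used <- rep(FALSE, nrow(pair))
  loops <- list()
  for (start in seq_len(nrow(pair))) {
    if (used[start]) next
    used[start] <- TRUE
    loop_keys <- pair[start, 1]
    cur_key <- pair[start, 2]
    cur_seg <- start
    repeat {
      loop_keys <- c(loop_keys, cur_key)
      nxt <- setdiff(get0(cur_key, envir = adj, ifnotfound = integer(0)), cur_seg)
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      cur_seg <- nxt[1]
      used[cur_seg] <- TRUE
      ks <- pair[cur_seg, ]
      cur_key <- if (ks[1] == cur_key) ks[2] else ks[1]
      if (cur_key == loop_keys[1]) break
    }
    P3 <- upts[loop_keys, , drop = FALSE]
    o <- plane$point
    xy <- sweep(P3, 2, o) %*% t(axes)
    k <- nrow(xy)
    if (k >= 3) {
      x <- xy[, 1]; y <- xy[, 2]
      area <- abs(sum(x * y[c(2:k, 1)] - x[c(2:k, 1)] * y)) / 2
      loops[[length(loops) + 1]] <- list(xy = xy, area = area)
    }
  }
  loops[order(-vapply(loops, `[[`, 0, "area"))]
}

polygon_centroid <- function(xy) {
  k <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- x[c(2:k, 1)]; y2 <- y[c(2:k, 1)]
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * A)
}

# y-values where the polygon boundary crosses the vertical line x = x0
polygon_line_crossings <- function(xy, x0 = 0) {
  k <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- x[c(2:k, 1)]; y2 <- y[c(2:k, 1)]
  hit <- (x > x0) != (x2 > x0)
  t <- (x0 - x[hit]) / (x2[hit] - x[hit])
  y[hit] + t * (y2[hit] - y[hit])
}

## ---- point-in-mesh ------------------------------------------------------

#' Point containment test by ray casting
#'
#' Casts a ray along +z from every query point and counts triangle
#' crossings (even-odd rule).  Triangles are binned on an (x, y) grid so the
#' test stays fast for large meshes and many points.  Query points are
#' perturbed by a fixed sub-micron offset to avoid grazing hits on vertices
#' or edges of exactly axis-aligned fixtures.
#'
#' @param mesh a watertight `ls_mesh`
#' @param P n x 3 matrix of query points
#' @return logical vector, TRUE when the point lies inside
#' @export
point_in_mesh <- function(mesh, P) {
  P <- as_points(P)
  eps <- c(3.7e-8, 1.9e-8)
  px <- P[, 1] + eps[1]; py <- P[, 2] + eps[2]; pz <- P[, 3]
  tr <- mesh_triangles(mesh)
  ax <- tr$A[, 1]; ay <- tr$A[, 2]; az <- tr$A[, 3]
  bx <- tr$B[, 1]; by <- tr$B[, 2]; bz <- tr$B[, 3]
  cx <- tr$C[, 1]; cy <- tr$C[, 2]; cz <- tr$C[, 3]

  nb <- max(1L, min(64L, as.integer(ceiling(sqrt(nrow(mesh$F) / 8)))))
  xr <- range(ax, bx, cx); yr <- range(ay, by, cy)
  hx <- max(xr[2] - xr[1], 1e-9) / nb
  hy <- max(yr[2] - yr[1], 1e-9) / nb
  bin_x <- function(x) pmin(nb - 1L, pmax(0L, as.integer(floor((x - xr[1]) / hx))))
  bin_y <- function(y) pmin(nb - 1L, pmax(0L, as.integer(floor((y - yr[1]) / hy))))

  # triangles can span several bins
  t_x0 <- bin_x(pmin(ax, bx, cx)); t_x1 <- bin_x(pmax(ax, bx, cx))
  t_y0 <- bin_y(pmin(ay, by, cy)); t_y1 <- bin_y(pmax(ay, by, cy))
  tri_bins <- vector("list", nb * nb)
  for (t in seq_along(ax)) {
    for (ix in t_x0[t]:t_x1[t]) for (iy in t_y0[t]:t_y1[t]) {
      k <- ix * nb + iy + 1L
      tri_bins[[k]] <- c(tri_bins[[k]], t)
    }
  }

  inside <- rep(FALSE, nrow(P))
  outside_xy <- px < xr[1] | px > xr[2] | py < yr[1] | py > yr[2]
  pk <- bin_x(px) * nb + bin_y(py) + 1L
  for (k in unique(pk[!outside_xy])) {
    tri <- tri_bins[[k]]
    if (is.null(tri)) next
    ip <- which(pk == k & !outside_xy)
    # 2-D barycentric test of (px,py) against each candidate triangle
    for (t in tri) {
      d1 <- (bx[t] - ax[t]) * (py[ip] - ay[t]) - (by[t] - ay[t]) * (px[ip] - ax[t])
      d2 <- (cx[t] - bx[t]) * (py[ip] - by[t]) - (cy[t] - by[t]) * (px[ip] - bx[t])
      d3 <- (ax[t] - cx[t]) * (py[ip] - cy[t]) - (ay[t] - cy[t]) * (px[ip] - cx[t])
      inside2d <- (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
      if (!any(inside2d)) next
      ii <- ip[inside2d]
      # plane of the triangle: z at (px, py)
      e1 <- c(bx[t] - ax[t], by[t] - ay[t], bz[t] - az[t])
      e2 <- c(cx[t] - ax[t], cy[t] - ay[t], cz[t] - az[t])
      nrm <- cross3(e1, e2)
      if (abs(nrm[3]) < 1e-14) next  # vertical triangle: ray parallel
      zhit <- az[t] - (nrm[1] * (px[ii] - ax[t]) + nrm[2] * (py[ii] - ay[t])) / nrm[3]
      above <- zhit > pz[ii]
      inside[ii[above]] <- !inside[ii[above]]
    }
  }
  inside
}

## ---- STL / PLY input-output --------------------------------------------

#' Write a mesh as ASCII STL
#' @param mesh an `ls_mesh`
#' @param path output file
#' @param name solid name recorded in the file
#' @export
write_stl <- function(mesh, path, name = "lumbosim") {
  tr <- mesh_triangles(mesh)
  e1 <- tr$B - tr$A; e2 <- tr$C - tr$A
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), 1e-30)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  fmt <- paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
                "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
                "  vertex %.9g %.9g %.9g\n endloop\nendfacet")
  writeLines(sprintf(fmt, nx / nn, ny / nn, nz / nn,
                     tr$A[, 1], tr$A[, 2], tr$A[, 3],
                     tr$B[, 1], tr$B[, 2], tr$B[, 3],
                     tr$C[, 1], tr$C[, 2], tr$C[, 3]), con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read an ASCII STL file
#' @param path input file
#' @param weld_tol vertex welding tolerance (mm)
#' @return an `ls_mesh`
#' @export
read_stl <- function(path, weld_tol = 1e-6) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  if (nrow(nums) %% 3 != 0) stop("malformed STL: vertex count not multiple of 3")
  F <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  mesh_weld(mesh_new(nums, F), tol = weld_tol)
}

#' Write a mesh as ASCII PLY
#' @param mesh an `ls_mesh`
#' @param path output file
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$V)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$F)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$V[, 1], mesh$V[, 2], mesh$V[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$F[, 1] - 1L, mesh$F[, 2] - 1L,
                     mesh$F[, 3] - 1L), con)
  invisible(path)
}
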