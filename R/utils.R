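# Small geometry helpers shared across modules.  All coordinates are in mm,
# frame convention: +x right, +y anterior, +z cranial.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Rotation matrix about the +x axis
#' @param deg angle in degrees
#' @return 3x3 rotation matrix
#' @keywords internal
rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0,
           0, cos(a), -sin(a),
           0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), -sin(a), 0,
           sin(a), cos(a), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# A frame is a rigid transform: origin (3-vector) and R (3x3, local -> world
# as columns of the local axes).
frame_new <- function(origin = c(0, 0, 0), R = diag(3)) {
  list(origin = as.numeric(origin), R = R)
}

frame_to_world <- function(frame, P) {
  P <- as_points(P)
  sweep(P %*% t(frame$R), 2, frame$origin, `+`)
}

frame_to_local <- function(frame, P) {
  P <- as_points(P)
  sweep(P, 2, frame$origin, `-`) %*% frame$R
}

frame_axis <- function(frame, i) frame$R[, i]

# Coerce a vector or matrix into an n x 3 point matrix.
as_points <- function(P) {
  if (is.null(dim(P))) P <- matrix(P, ncol = 3, byrow = TRUE)
  storage.mode(P) <- "double"
  P
}

# Axis-aligned bounding box utilities: bbox is a 2x3 matrix (min row, max row).
bbox_of <- function(P) {
  P <- as_points(P)
  rbind(apply(P, 2, min), apply(P, 2, max))
}

bbox_pad <- function(bb, pad) rbind(bb[1, ] - pad, bb[2, ] + pad)

bbox_intersect <- function(a, b) {
  lo <- pmax(a[1, ], b[1, ])
  hi <- pmin(a[2, ], b[2, ])
  if (any(lo >= hi)) return(NULL)
  rbind(lo, hi)
}

bbox_union <- function(a, b) rbind(pmin(a[1, ], b[1, ]), pmax(a[2, ], b[2, ]))

bbox_volume <- function(bb) prod(bb[2, ] - bb[1, ])

# Least-squares rigid transform (Kabsch) mapping point set A onto B = R A + t.
kabsch <- function(A, B) {
  A <- as_points(A); B <- as_points(B)
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cb - as.numeric(R %*% ca))
}

# Total rotation angle of a rotation matrix, degrees.
rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  rad2deg(acos(pmin(1, pmax(-1, ct))))
}
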