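# Analytic verification problems for the FE machinery: axial bar, patch
# test, cantilever bending and the truss bar formula.  These replace
# cadaveric corroboration at desk scale: each check has a closed-form
# reference.

#' Structured tetrahedral box model
#'
#' A rectangular block meshed on a regular lattice (six tetrahedra per
#' cell), with one face fixed.  Used by the verification suite.
#'
#' @param dims c(Lx, Ly, Lz) in mm
#' @param edge lattice spacing (mm)
#' @param E,nu material (MPa, -)
#' @param fix which face to fix: "z0", "x0" or "none"
#' @return a solver-ready `fe_model`
#' @export
fe_box_model <- function(dims, edge, E = 1000, nu = 0.3, fix = "x0") {
  xs <- seq(0, dims[1], by = edge)
  ys <- seq(0, dims[2], by = edge)
  zs <- seq(0, dims[3], by = edge)
  if (abs(max(xs) - dims[1]) > 1e-9) xs <- c(xs, dims[1])
  if (abs(max(ys) - dims[2]) > 1e-9) ys <- c(ys, dims[2])
  if (abs(max(zs) - dims[3]) > 1e-9) zs <- c(zs, dims[3])
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nodes <- as.matrix(expand.grid(xs, ys, zs))
  colnames(nodes) <- NULL
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  ii <- rep(seq_len(nx - 1), times = (ny - 1) * (nz - 1))
  jj <- rep(rep(seq_len(ny - 1), each = nx - 1), times = nz - 1)
  kk <- rep(seq_len(nz - 1), each = (nx - 1) * (ny - 1))
  corners <- cbind(nid(ii, jj, kk), nid(ii + 1, jj, kk),
                   nid(ii, jj + 1, kk), nid(ii + 1, jj + 1, kk),
                   nid(ii, jj, kk + 1), nid(ii + 1, jj, kk + 1),
                   nid(ii, jj + 1, kk + 1), nid(ii + 1, jj + 1, kk + 1))
  tets <- do.call(rbind, lapply(seq_len(6), function(r)
    corners[, .freudenthal[r, ], drop = FALSE]))
  vol <- tet_volumes(nodes, tets)
  neg <- vol < 0
  tets[neg, 3:4] <- tets[neg, c(4, 3)]
  fixed <- switch(fix,
                  x0 = which(nodes[, 1] < 1e-9),
                  z0 = which(nodes[, 3] < 1e-9),
                  none = integer(0))
  mt <- data.frame(name = "solid", E = E, nu = nu, area = NA)
  structure(list(nodes = nodes, tets = tets,
                 region = rep("solid", nrow(tets)),
                 region_map = c(solid = "solid"),
                 fixed_nodes = fixed,
                 load_nodes = which(nodes[, 1] > dims[1] - 1e-9),
                 trusses = NULL, fibers = NULL, springs_spec = list(),
                 springs = NULL, materials = mt,
                 frames = list(L3 = frame_new(c(0, 0, 0), diag(3))),
                 params = NULL, target_edge = edge),
            class = "fe_model")
}

# solve with a raw force vector (helper for the verification suite)
solve_with_forces <- function(fem, f, extra_fixed_dofs = NULL, K = NULL) {
  if (is.null(K)) K <- assemble_stiffness(fem)
  ndof <- 3L * nrow(fem$nodes)
  fixed_dofs <- as.vector(t(outer(3L * (fem$fixed_nodes - 1L), 1:3, `+`)))
  fixed_dofs <- union(fixed_dofs, extra_fixed_dofs)
  free <- setdiff(seq_len(ndof), fixed_dofs)
  Kff <- Matrix::forceSymmetric(K[free, free])
  u <- numeric(ndof)
  u[free] <- as.numeric(Matrix::solve(Kff, f[free]))
  matrix(u, ncol = 3, byrow = TRUE)
}

#' Axial bar check: tip displacement against FL/EA
#'
#' @param L,W bar length and square side (mm)
#' @param E Young's modulus; `nu` is zero so the closed form is exact in
#'   the lattice limit
#' @param F total axial load (N)
#' @param edge lattice spacing
#' @return list with `fe`, `exact` and relative error
#' @export
check_axial_bar <- function(L = 20, W = 4, E = 1000, F = 100, edge = 1) {
  fem <- fe_box_model(c(L, W, W), edge, E = E, nu = 0, fix = "x0")
  tip <- fem$load_nodes
  f <- numeric(3 * nrow(fem$nodes))
  # consistent uniform traction: tributary-area weights (1/2 on face edges,
  # 1/4 in face corners)
  wgt <- function(v) ifelse(v < 1e-9 | v > W - 1e-9, 0.5, 1)
  w <- wgt(fem$nodes[tip, 2]) * wgt(fem$nodes[tip, 3])
  f[3 * (tip - 1) + 1] <- F * w / sum(w)
  u <- solve_with_forces(fem, f)
  fe <- mean(u[tip, 1])
  exact <- F * L / (E * W * W)
  list(fe = fe, exact = exact, rel_err = abs(fe - exact) / exact)
}

#' Patch test: exact reproduction of a linear displacement field
#'
#' All boundary nodes of a distorted single-region mesh are prescribed a
#' linear field; interior nodes must reproduce it to machine precision
#' (constant-strain completeness).
#' @param edge lattice spacing before distortion
#' @return maximum interior nodal error (mm)
#' @export
check_patch_test <- function(edge = 1) {
  fem <- fe_box_model(c(4, 4, 4), edge, E = 500, nu = 0.3, fix = "none")
  set.seed(11)
  interior <- which(apply(fem$nodes, 1, function(p)
    all(p > 1e-9) && all(p < 4 - 1e-9)))
  fem$nodes[interior, ] <- fem$nodes[interior, ] +
    matrix(stats::runif(3 * length(interior), -0.2, 0.2), ncol = 3)
  A <- matrix(c(1e-3, 4e-4, -2e-4,
                3e-4, -5e-4, 1e-4,
                2e-4, 6e-4, 8e-4), 3, 3, byrow = TRUE)
  ulin <- fem$nodes %*% t(A)
  boundary <- setdiff(seq_len(nrow(fem$nodes)), interior)
  K <- assemble_stiffness(fem)
  ndof <- 3 * nrow(fem$nodes)
  fixed_dofs <- as.vector(t(outer(3L * (boundary - 1L), 1:3, `+`)))
  free <- setdiff(seq_len(ndof), fixed_dofs)
  ub <- as.vector(t(ulin)); ub[free] <- 0
  rhs <- -as.numeric(K %*% ub)
  uf <- Matrix::solve(Matrix::forceSymmetric(K[free, free]), rhs[free])
  u <- ub; u[free] <- as.numeric(uf)
  max(abs(matrix(u, ncol = 3, byrow = TRUE)[interior, ] - ulin[interior, ]))
}

#' Cantilever bending check against Euler-Bernoulli theory
#'
#' Slender cantilever, tip shear load; compares the FE tip deflection with
#' `FL^3/(3EI)` (plus first-order shear correction) and the maximum
#' von Mises stress with the root bending stress `M c / I`.
#' @param L beam length (mm); `W` square section side; `F` tip load (N)
#' @param edge lattice spacing
#' @export
check_cantilever <- function(L = 24, W = 3, E = 2000, F = 5, edge = 0.375) {
  nu <- 0.0
  fem <- fe_box_model(c(L, W, W), edge, E = E, nu = nu, fix = "x0")
  tip <- fem$load_nodes
  f <- numeric(3 * nrow(fem$nodes))
  f[3 * (tip - 1) + 3] <- -F / length(tip)
  u <- solve_with_forces(fem, f)
  fe_defl <- -mean(u[tip, 3])
  I <- W^4 / 12
  defl_bend <- F * L^3 / (3 * E * I)
  defl_shear <- 6 / 5 * F * L / (E / (2 * (1 + nu)) * W * W)
  vm <- compute_von_mises(fem, u, regions = "solid")
  sigma_exact <- F * L * (W / 2) / I
  list(fe_defl = fe_defl, exact_defl = defl_bend + defl_shear,
       rel_err_defl = abs(fe_defl - (defl_bend + defl_shear)) / (defl_bend + defl_shear),
       fe_sigma = max(vm$vm), exact_sigma = sigma_exact,
       rel_err_sigma = abs(max(vm$vm) - sigma_exact) / sigma_exact)
}

#' Truss bar formula check: axial force equals EA delta / L
#'
#' A single truss element stretched by a prescribed end displacement.
#' @param E,A,L truss properties
#' @param delta prescribed elongation (mm)
#' @export
check_truss_bar <- function(E = 455, A = 1.35, L = 10, delta = 0.1) {
  nodes <- rbind(c(0, 0, 0), c(L, 0, 0))
  fem <- structure(list(nodes = nodes,
                        tets = matrix(integer(0), 0, 4), region = character(0),
                        region_map = c(), fixed_nodes = integer(0),
                        load_nodes = 2L,
                        trusses = data.frame(n1 = 1L, n2 = 2L, group = "bar",
                                             level = "", side = "", area = A),
                        fibers = NULL, springs_spec = list(), springs = NULL,
                        materials = data.frame(name = "bar", E = E, nu = 0.3,
                                               area = A),
                        frames = NULL, params = NULL), class = "fe_model")
  # stiffness of the single truss along x
  K <- assemble_stiffness(fem)
  force_fe <- as.numeric(K[4, 4] * delta)
  list(fe = force_fe, exact = E * A * delta / L,
       rel_err = abs(force_fe - E * A * delta / L) / (E * A * delta / L))
}
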