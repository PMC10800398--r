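# Fixtures built in code: toy meshes and solids used across the suite.

# axis-aligned cube mesh [0, s]^3 (12 triangles, outward orientation)
cube_mesh <- function(s = 1, origin = c(0, 0, 0)) {
  V <- as.matrix(expand.grid(c(0, s), c(0, s), c(0, s)))
  V <- sweep(V, 2, origin, `+`)
  F <- rbind(
    c(1, 3, 7), c(1, 7, 5),   # x = 0 ... check orientation below
    c(2, 6, 8), c(2, 8, 4),
    c(1, 5, 6), c(1, 6, 2),
    c(3, 4, 8), c(3, 8, 7),
    c(1, 2, 4), c(1, 4, 3),
    c(5, 7, 8), c(5, 8, 6))
  m <- mesh_new(V, F)
  if (mesh_volume(m) < 0) m$F <- m$F[, c(1, 3, 2)]
  m
}

# analytic cylinder mesh along +z
cylinder_mesh <- function(r = 4, L = 12, nseg = 96, base = c(0, 0, 0)) {
  th <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
  ring <- cbind(r * cos(th), r * sin(th))
  Vb <- cbind(ring, 0); Vt <- cbind(ring, L)
  V <- sweep(rbind(Vb, Vt, c(0, 0, 0), c(0, 0, L)), 2, base, `+`)
  i <- seq_len(nseg); j <- c(2:nseg, 1)
  F <- rbind(cbind(i, j, nseg + j), cbind(i, nseg + j, nseg + i),
             cbind(2 * nseg + 1, j, i), cbind(2 * nseg + 2, nseg + i, nseg + j))
  m <- mesh_new(V, F)
  if (mesh_volume(m) < 0) m$F <- m$F[, c(1, 3, 2)]
  m
}

# concentric circular annulus/nucleus toy: nucleus radius r, annulus outer
# r * sqrt(2.5) so the nucleus holds 40% of the disc area
toy_disc_meshes <- function(r = 10, h = 8, nseg = 160) {
  th <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
  ring <- function(rr) cbind(rr * cos(th), rr * sin(th))
  fr <- lumbosim:::frame_new()
  lo <- list(point = c(0, 0, -h / 2), normal = c(0, 0, -1))
  hi <- list(point = c(0, 0, h / 2), normal = c(0, 0, 1))
  nucleus <- lumbosim:::loft_slab_mesh(fr, ring(r), lo, hi)
  annulus <- lumbosim:::loft_ring_mesh(fr, ring(r * sqrt(2.5)), ring(r), lo, hi)
  list(annulus = annulus, nucleus = nucleus)
}

# shared default phantom (built once per test run)
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom()
    cache
  }
})

default_frame <- function(model = default_phantom()) {
  build_interspace_frame(model, model$planes$L4_inferior,
                         model$planes$L5_superior)
}

# memoized FE builds of the default phantom, shared across test files
default_fem <- local({
  cache <- list()
  function(edge = 3) {
    key <- as.character(edge)
    if (is.null(cache[[key]]))
      cache[[key]] <<- build_fe_model(default_phantom(), target_edge = edge)
    cache[[key]]
  }
})
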