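test_that("mesh volume, area and watertightness are exact on a cube", {
  m <- cube_mesh(2)
  expect_true(mesh_is_watertight(m))
  expect_equal(mesh_volume(m), 8, tolerance = 1e-12)
  expect_equal(mesh_area(m), 24, tolerance = 1e-12)
  # removing one face breaks watertightness
  m2 <- mesh_new(m$V, m$F[-1, ])
  expect_false(mesh_is_watertight(m2))
})

test_that("plane sections produce closed loops with correct areas", {
  cyl <- cylinder_mesh(r = 4, L = 12, base = c(0, 0, -6))
  loops <- mesh_section(cyl, list(point = c(0, 0, 0), normal = c(0, 0, 1)))
  expect_length(loops, 1)
  expect_equal(loops[[1]]$area, pi * 16, tolerance = 0.005)
  # annulus section: outer and inner loop
  d <- toy_disc_meshes(r = 10)
  la <- mesh_section(d$annulus, list(point = c(0, 0, 0), normal = c(0, 0, 1)))
  expect_length(la, 2)
  expect_equal(la[[1]]$area, pi * 250, tolerance = 0.005 * pi * 250)
  expect_equal(la[[2]]$area, pi * 100, tolerance = 0.005 * pi * 100)
  expect_error(mesh_section(cyl, list(point = c(0, 0, 100), normal = c(0, 0, 1))),
               "does not intersect")
})

test_that("ray-cast containment classifies points correctly", {
  cyl <- cylinder_mesh(r = 4, L = 12, base = c(0, 0, -6))
  set.seed(3)
  P <- cbind(runif(3000, -6, 6), runif(3000, -6, 6), runif(3000, -8, 8))
  truth <- sqrt(P[, 1]^2 + P[, 2]^2) < 4 & abs(P[, 3]) < 6
  # keep points away from the faceted boundary where mesh and analytic
  # cylinder legitimately differ
  margin <- abs(sqrt(P[, 1]^2 + P[, 2]^2) - 4) > 0.1 & abs(abs(P[, 3]) - 6) > 0.1
  got <- point_in_mesh(cyl, P)
  expect_true(all(got[margin] == truth[margin]))
})

test_that("STL and PLY round trips preserve geometry", {
  m <- cylinder_mesh(r = 3, L = 5)
  tf <- tempfile(fileext = ".stl")
  write_stl(m, tf)
  m2 <- read_stl(tf)
  expect_true(mesh_is_watertight(m2))
  expect_equal(mesh_volume(m2), mesh_volume(m), tolerance = 1e-9)
  tp <- tempfile(fileext = ".ply")
  expect_silent(write_ply(m, tp))
  expect_true(file.exists(tp))
})
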