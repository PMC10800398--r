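test_that("primitive solids recover closed-form volumes via surface extraction", {
  b <- solid_box(c(0, 0, 0), c(5, 4, 3))
  expect_equal(solid_volume(b, 0.5), 480, tolerance = 0.005 * 480)
  cy <- solid_cylinder(c(0, 0, -6), c(0, 0, 1), 4, 12)
  expect_equal(solid_volume(cy, 0.3), pi * 16 * 12, tolerance = 0.005 * pi * 16 * 12)
  # an oval prism with exponent 2 is an elliptic cylinder
  pr <- solid_oval_prism(c(1, 2, 3), c(4, 2, 5), exponent = 2)
  expect_equal(solid_volume(pr, 0.25), pi * 4 * 2 * 10,
               tolerance = 0.01 * pi * 4 * 2 * 10)
})

test_that("CSG composition behaves like set algebra", {
  cy <- solid_cylinder(c(0, 0, -10), c(0, 0, 1), 4, 20)
  slab <- solid_box(c(0, 0, 0), c(10, 10, 2))
  inter <- solid_intersection(cy, slab)
  expect_equal(solid_volume(inter, 0.25), pi * 16 * 4, tolerance = 0.01 * pi * 16 * 4)
  # union of identical solids is idempotent
  uni <- solid_union(cy, cy)
  expect_equal(solid_volume(uni, 0.3), solid_volume(cy, 0.3), tolerance = 1e-9)
  # difference against a disjoint solid returns the original field
  far <- solid_box(c(100, 0, 0), c(1, 1, 1))
  diff <- solid_difference(cy, far)
  expect_equal(solid_volume(diff, 0.3), solid_volume(cy, 0.3), tolerance = 1e-9)
  # intersection of disjoint solids is empty
  empty <- solid_intersection(cy, far)
  expect_true(empty$empty)
  expect_equal(solid_volume(empty), 0)
})

test_that("marching tetrahedra surfaces are watertight and consistently oriented", {
  sol <- solid_difference(solid_box(c(0, 0, 0), c(6, 6, 6)),
                          solid_cylinder(c(0, 0, -7), c(0, 0, 1), 2.5, 14))
  m <- solid_surface(sol, pitch = 0.5)
  expect_true(mesh_is_watertight(m))
  expect_gt(mesh_volume(m), 0)
  expect_equal(mesh_volume(m), 12^3 - pi * 2.5^2 * 12,
               tolerance = 0.01 * 12^3)
})

test_that("mesh-backed solids agree with their source geometry", {
  cyl_mesh <- cylinder_mesh(r = 4, L = 12, base = c(0, 0, -6))
  sol <- solid_from_mesh(cyl_mesh)
  expect_equal(solid_volume(sol, 0.4), mesh_volume(cyl_mesh),
               tolerance = 0.015 * mesh_volume(cyl_mesh))
  expect_true(solid_contains(sol, c(0, 0, 0)))
  expect_false(solid_contains(sol, c(5, 0, 0)))
})
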