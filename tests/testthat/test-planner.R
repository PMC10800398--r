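test_that("plane fitting is exact on flat data and robust to roughness", {
  # flat horizontal sheet at z = 10
  g <- as.matrix(expand.grid(seq(-5, 5, 1), seq(-5, 5, 1)))
  flat <- cbind(g, 10)
  pl <- lumbosim:::fit_plane_points(flat)
  expect_equal(abs(sum(pl$normal * c(0, 0, 1))), 1, tolerance = 1e-12)
  expect_equal(sum(pl$point * pl$normal), 10 * pl$normal[3], tolerance = 1e-9)
  # sinusoidal roughness +-0.2 mm: normal within 1 degree of vertical
  rough <- cbind(g, 10 + 0.2 * sin(g[, 1]) * cos(g[, 2]))
  plr <- lumbosim:::fit_plane_points(rough)
  ang <- acos(abs(sum(plr$normal * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 1)
  # cross-check against an independently computed SVD best fit
  X <- sweep(rough, 2, colMeans(rough))
  n_ref <- svd(X)$v[, 3]
  expect_equal(abs(sum(plr$normal * n_ref)), 1, tolerance = 1e-9)
  expect_error(lumbosim:::fit_plane_points(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "collinear")
})

test_that("endplate planes fit the phantom with sub-half-millimetre residuals", {
  m <- default_phantom()
  pl <- fit_endplate_plane(m, "endplate_L5_superior")
  V <- region_mesh(m, "endplate_L5_superior")$V
  expect_lt(plane_rms(pl, V), 0.5)
  # fitted plane agrees with the analytic construction plane
  ana <- m$planes$L5_superior
  expect_gt(abs(sum(pl$normal * ana$normal)), cos(2 * pi / 180))
  expect_error(fit_endplate_plane(m, "endplate_nonsense"), "no such endplate")
})

test_that("the interspace centre is the midpoint of the posterior-edge landmarks", {
  fake <- list(landmarks = rbind(
    endplate_L4_inferior_posterior_midpoint = c(0, -18, 2),
    endplate_L5_superior_posterior_midpoint = c(0, -18, -2)),
    frames = NULL)
  frame <- build_interspace_frame(fake, plane_new(c(0, 0, 2), c(0, 0, 1)),
                                  plane_new(c(0, 0, -2), c(0, 0, 1)))
  expect_equal(frame$center, c(0, -18, 0))
  expect_equal(frame$reference_plane$normal, c(0, 0, 1))
  # axes: central posterior, lateral right, both in plane
  expect_equal(frame$central_axis, c(0, -1, 0))
  expect_equal(frame$lateral_axis, c(1, 0, 0))
  fake$landmarks <- fake$landmarks[1, , drop = FALSE]
  expect_error(build_interspace_frame(fake, plane_new(c(0, 0, 2), c(0, 0, 1)),
                                      plane_new(c(0, 0, -2), c(0, 0, 1))),
               "missing posterior-edge")
})

test_that("default phantom interspace centre lies at the posterior disc edge", {
  m <- default_phantom()
  frame <- default_frame(m)
  # C should sit within 1 mm of the posterior edge midpoint of the disc
  fd <- m$frames$disc_L4L5
  b_d <- m$params$body_depth / 2 * sqrt(m$params$disc_to_vertebra_area_fraction)
  edge <- as.numeric(lumbosim:::frame_to_world(fd, c(0, -b_d, 0)))
  expect_lt(lumbosim:::vnorm(frame$center - edge), 1)
})

test_that("trephine axes obey the planned in-plane angles", {
  frame <- default_frame()
  for (ang in c(20, 30, 40, 50, 60, 70)) {
    ax1 <- trephine_axis(frame, ang, 1)
    expect_equal(axis_inplane_angle(frame, ax1), ang, tolerance = 1e-9)
    expect_lt(abs(sum(ax1$direction * frame$reference_plane$normal)), 1e-9)
    ax2 <- trephine_axis(frame, ang, 2)
    expect_equal(axis_inplane_angle(frame, ax2), ang + 5, tolerance = 1e-9)
  }
  # fan opening: 50 degrees between the extreme axes
  a20 <- trephine_axis(frame, 20, 1)$direction
  a70 <- trephine_axis(frame, 70, 1)$direction
  expect_equal(acos(sum(a20 * a70)) * 180 / pi, 50, tolerance = 1e-9)
  expect_error(trephine_plan(45), "angle_deg")
  expect_error(trephine_plan(50, 6), "diameter")
  expect_silent(trephine_plan(50, 6, allow_nonstandard = TRUE))
})

test_that("trephine cylinders match closed-form volume and scaling", {
  frame <- default_frame()
  ax <- trephine_axis(frame, 50, 1)
  t8 <- trephine_cylinder(ax, 8, length = 120)
  expect_true(mesh_is_watertight(t8$mesh))
  expect_equal(mesh_volume(t8$mesh), pi * 16 * 120, tolerance = 0.005 * pi * 16 * 120)
  t7 <- trephine_cylinder(ax, 7, length = 120)
  t9 <- trephine_cylinder(ax, 9, length = 120)
  expect_equal(mesh_volume(t7$mesh) / mesh_volume(t9$mesh), (7 / 9)^2,
               tolerance = 1e-6)
  # centroid lies on the axis
  ctr <- lumbosim:::mesh_centroid(t8$mesh)
  rel <- ctr - ax$point
  perp <- rel - sum(rel * ax$direction) * ax$direction
  expect_lt(lumbosim:::vnorm(perp), 1e-6)
})

test_that("planning on the mirrored phantom reproduces mirrored axes", {
  m <- default_phantom()
  mm <- mirror_anatomy(m)
  fr_r <- default_frame(m)
  fr_m <- build_interspace_frame(mm, mm$planes$L4_inferior, mm$planes$L5_superior)
  for (ang in c(30, 60)) {
    ax_r <- trephine_axis(fr_r, ang, 1, side = "right")
    ax_l <- trephine_axis(fr_m, ang, 1, side = "left")
    expect_equal(ax_l$direction, ax_r$direction * c(-1, 1, 1), tolerance = 1e-9)
    expect_equal(ax_l$point, ax_r$point * c(-1, 1, 1), tolerance = 1e-9)
  }
})

test_that("plans serialise through YAML losslessly", {
  plans <- list(trephine_plan(50, 9, 2), trephine_plan(20, 7, 1))
  tf <- tempfile(fileext = ".yaml")
  write_plans(plans, tf)
  back <- read_plans(tf)
  expect_equal(back[[1]]$angle_deg, 50)
  expect_equal(back[[1]]$attempts, 2)
  expect_equal(back[[2]]$diameter_mm, 7)
})
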