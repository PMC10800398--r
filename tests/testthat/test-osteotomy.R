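test_that("intersection volume matches closed forms on toy geometry", {
  cube <- solid_box(c(0, 0, 0), c(25, 25, 25))
  cyl <- solid_cylinder(c(0, 0, -5), c(0, 0, 1), 4, 10)
  v <- intersect_volume(cube, cyl, pitch = 0.25)
  expect_equal(v, pi * 16 * 10, tolerance = 0.005 * pi * 16 * 10)
  # two coincident cylinders as "two attempts": union is idempotent
  uni <- solid_union(cyl, cyl)
  expect_equal(intersect_volume(cube, uni, pitch = 0.25), v, tolerance = 1e-9)
})

test_that("Monte Carlo oracle is exact on degenerate cases", {
  cube <- solid_box(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  mc <- monte_carlo_volume(cube, cube, n_samples = 1e5, seed = 2)
  expect_equal(mc$estimate, 1, tolerance = 1e-12)
  expect_equal(mc$stderr, 0)
  far <- solid_box(c(50, 0, 0), c(1, 1, 1))
  mc0 <- monte_carlo_volume(far, cube, n_samples = 1e4, seed = 2)
  expect_equal(mc0$estimate, 0)
  expect_error(monte_carlo_volume(cube, cube, n_samples = 100), "at least 1e4")
})

test_that("Monte Carlo deviations stay within 3 standard errors across seeds", {
  cube <- solid_box(c(0, 0, 0), c(6, 6, 6))
  cyl <- solid_cylinder(c(0, 0, -8), c(0, 0, 1), 3, 16)
  truth <- pi * 9 * 12  # cylinder clipped by the cube in z
  inside <- solid_intersection(cyl, cube)
  hits <- vapply(1:100, function(s) {
    mc <- monte_carlo_volume(cube, cyl, n_samples = 1e4, seed = s)
    abs(mc$estimate - truth) <= 3 * mc$stderr
  }, TRUE)
  expect_gte(mean(hits), 0.97)
})

test_that("Boolean and Monte Carlo agree on the phantom", {
  m <- default_phantom()
  frame <- default_frame(m)
  tool <- plan_tool(frame, trephine_plan(50, 9, 1))
  ex <- intersect_volume(m, tool$solid, pitch = 0.3)
  mc <- monte_carlo_volume(m, tool$solid, n_samples = 2e5, seed = 11)
  expect_lt(abs(ex$total - mc$estimate), 3 * mc$stderr)
  # breakdown sums to the total by construction of disjoint groups
  expect_equal(sum(ex$breakdown), ex$total, tolerance = 0.01 * ex$total)
})

test_that("resection preserves untouched regions bit-identically and drops engulfed ones", {
  m <- generate_phantom()
  invisible(region_mesh(m, "disc_L4L5_nucleus"))  # populate the cache
  far_tool <- solid_box(c(500, 0, 0), c(5, 5, 5))
  r0 <- resect(m, far_tool)
  expect_identical(names(r0$regions), names(m$regions))
  expect_identical(region_mesh(r0, "disc_L4L5_nucleus"),
                   region_mesh(m, "disc_L4L5_nucleus"))
  # a tool engulfing the right L4/5 facet cartilage removes that region
  jf <- m$joints$L4L5$right
  big <- solid_box(jf$center, c(12, 12, 14), cbind(jf$u, jf$n, jf$z))
  r1 <- resect(m, big)
  expect_false("facet_cartilage_L4L5_right" %in% names(r1$regions))
  rep1 <- attr(r1, "removal_report")
  expect_true(rep1$dropped[rep1$region == "facet_cartilage_L4L5_right"])
})

test_that("resection conserves volume: region = remainder + removed", {
  m <- default_phantom()
  frame <- default_frame(m)
  tool <- plan_tool(frame, trephine_plan(50, 8, 1))$solid
  reg <- m$regions$L5_posterior_elements
  v_orig <- solid_volume(reg, 0.4)
  v_cut <- solid_volume(solid_intersection(tool, reg), 0.3)
  v_rest <- solid_volume(solid_difference(reg, tool), 0.4)
  expect_equal(v_rest + v_cut, v_orig, tolerance = 0.01 * v_orig)
})

test_that("volume experiment has the right cardinality and monotonicity", {
  cohort <- sample_cohort(cohort_spec(2, jitter = 0.03, master_seed = 3))
  tab <- run_volume_experiment(cohort, angles = c(30, 50), diameters = c(7, 9),
                               attempts = c(1, 2), pitch = 0.7)
  expect_equal(nrow(tab), 2 * 2 * 2 * 2)
  # diameter monotonicity per subject/angle/attempts
  for (s in 1:2) for (ang in c(30, 50)) for (att in 1:2) {
    v7 <- tab$removed_volume[tab$subject == s & tab$angle_deg == ang &
                               tab$attempts == att & tab$diameter_mm == 7]
    v9 <- tab$removed_volume[tab$subject == s & tab$angle_deg == ang &
                               tab$attempts == att & tab$diameter_mm == 9]
    expect_lte(v7, v9)
  }
  # attempts monotonicity
  for (s in 1:2) for (ang in c(30, 50)) for (d in c(7, 9)) {
    v1 <- tab$removed_volume[tab$subject == s & tab$angle_deg == ang &
                               tab$attempts == 1 & tab$diameter_mm == d]
    v2 <- tab$removed_volume[tab$subject == s & tab$angle_deg == ang &
                               tab$attempts == 2 & tab$diameter_mm == d]
    expect_lte(v1, v2)
  }
})
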