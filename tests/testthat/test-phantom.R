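test_that("parameter validation rejects degenerate geometry with a named region", {
  expect_error(subject_params(nucleus_area_fraction = 1.2), "nucleus_area_fraction")
  expect_error(subject_params(cartilage_thickness = 1.4), "below 1 mm")
  expect_error(subject_params(body_width = -3), "positive")
  expect_error(subject_params(nucleus_area_fraction = 0.97), "nucleus")
  expect_error(subject_params(cortical_thickness = 12), "cortical")
})

test_that("phantom generation is deterministic (bit-identical repeat)", {
  m1 <- generate_phantom()
  m2 <- generate_phantom()
  expect_identical(m1$landmarks, m2$landmarks)
  expect_identical(region_mesh(m1, "disc_L4L5_annulus"),
                   region_mesh(m2, "disc_L4L5_annulus"))
  expect_identical(region_mesh(m1, "L4_posterior_elements"),
                   region_mesh(m2, "L4_posterior_elements"))
})

test_that("every regional mesh is watertight with positive volume", {
  m <- default_phantom()
  for (nm in names(m$regions)) {
    mm <- region_mesh(m, nm)
    expect_true(mesh_is_watertight(mm), label = paste(nm, "watertight"))
    expect_gt(mesh_volume(mm), 0)
  }
})

test_that("cancellous bone lies inside the cortical shell, nucleus inside annulus", {
  m <- default_phantom()
  # sampled containment: cancellous interior points are never cortical and
  # always inside the outer body; nucleus points never in the annulus
  set.seed(5)
  P <- cbind(runif(500, -20, 20), runif(500, -15, 15), runif(500, -33, -6))
  canc <- solid_contains(m$regions$L5_cancellous, P)
  cort <- solid_contains(m$regions$L5_cortical, P)
  expect_false(any(canc & cort))
  Pn <- cbind(runif(500, -15, 15), runif(500, -14, 10), runif(500, -3.5, 3.5))
  nuc <- solid_contains(m$regions$disc_L4L5_nucleus, Pn)
  ann <- solid_contains(m$regions$disc_L4L5_annulus, Pn)
  expect_false(any(nuc & ann))
})

test_that("measured section properties recover the construction targets", {
  m <- default_phantom()
  mf <- measure_area_fractions(m)
  expect_equal(mf$nucleus_over_disc, 0.40, tolerance = 0.008 / 0.40)
  expect_equal(mf$disc_over_vertebra, 0.95, tolerance = 0.02)
  expect_equal(mf$ap_offset_ratio, 1.62, tolerance = 0.05)
  # parameter-recovery away from the defaults
  m2 <- generate_phantom(subject_params(nucleus_area_fraction = 0.5,
                                        ap_offset_ratio = 1.3,
                                        disc_to_vertebra_area_fraction = 0.9))
  mf2 <- measure_area_fractions(m2)
  expect_equal(mf2$nucleus_over_disc, 0.5, tolerance = 0.02)
  expect_equal(mf2$ap_offset_ratio, 1.3, tolerance = 0.05)
  expect_equal(mf2$disc_over_vertebra, 0.9, tolerance = 0.02)
})

test_that("toy concentric disc gives the closed-form fractions", {
  d <- toy_disc_meshes(r = 10)
  fake <- structure(list(
    frames = list(disc_L4L5 = lumbosim:::frame_new()),
    params = list(body_height = 8),
    mesh_cache = local({
      e <- new.env()
      e
    }),
    regions = list(disc_L4L5_annulus = NULL, disc_L4L5_nucleus = NULL)),
    class = "anatomy_model")
  # direct section computation on the toy meshes
  pl <- list(point = c(0, 0, 0), normal = c(0, 0, 1))
  la <- mesh_section(d$annulus, pl)
  ln <- mesh_section(d$nucleus, pl)
  expect_equal(ln[[1]]$area / la[[1]]$area, 0.4, tolerance = 0.002)
  ys <- lumbosim:::polygon_line_crossings(la[[1]]$xy, 0)
  ctr <- lumbosim:::polygon_centroid(ln[[1]]$xy)
  expect_equal((max(ys) - ctr[2]) / (ctr[2] - min(ys)), 1, tolerance = 1e-6)
})

test_that("median cortical shell thickness matches the 1 mm specification", {
  th <- measure_shell_thickness(default_phantom(), "L4", n_rays = 36)
  expect_gte(th, 0.9)
  expect_lte(th, 1.1)
})

test_that("cohort sampling is deterministic, respects CVs and validates", {
  spec0 <- cohort_spec(n_subjects = 25, jitter = 0, master_seed = 7)
  cohort0 <- sample_cohort(spec0)
  expect_length(cohort0, 25)
  expect_true(all(vapply(cohort0, function(p) p$body_width, 0) == 46))
  spec <- cohort_spec(n_subjects = 25, jitter = 0.05, master_seed = 7)
  cohort <- sample_cohort(spec)
  for (nm in c("body_width", "disc_height", "facet_angle")) {
    v <- vapply(cohort, function(p) p[[nm]], 0)
    cv <- sd(v) / mean(v)
    expect_gte(cv, 0.02)
    expect_lte(cv, 0.09)
  }
  expect_identical(vapply(sample_cohort(spec), `[[`, 0, "body_width"),
                   vapply(cohort, `[[`, 0, "body_width"))
  expect_error(cohort_spec(n_subjects = 1), "at least 2")
})

test_that("phantom export writes STL, landmarks and parameters", {
  m <- default_phantom()
  dir <- tempfile()
  files <- export_phantom(m, dir, subject = "s1",
                          regions = c("disc_L4L5_nucleus", "endplate_L5_superior"))
  expect_true(all(file.exists(files)))
  back <- read_stl(file.path(dir, "s1_disc_L4L5_nucleus.stl"))
  expect_equal(mesh_volume(back), mesh_volume(region_mesh(m, "disc_L4L5_nucleus")),
               tolerance = 1e-6)
  # round trip through a mesh-backed anatomy
  am <- anatomy_from_meshes(c(nucleus = file.path(dir, "s1_disc_L4L5_nucleus.stl")))
  expect_s3_class(am, "anatomy_model")
  expect_true(solid_contains(am$regions$nucleus, c(0, -4, 0)))
})
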