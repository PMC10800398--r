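test_that("structured box meshes conserve volume and conform", {
  fem <- fe_box_model(c(1, 1, 1), 0.25, fix = "none")
  expect_equal(sum(lumbosim:::tet_volumes(fem$nodes, fem$tets)), 1,
               tolerance = 0.005)
  expect_true(all(lumbosim:::tet_volumes(fem$nodes, fem$tets) > 0))
})

test_that("material table matches the lumbar card and validates", {
  mt <- material_table(nucleus_nu_cap = 0.499)
  expect_equal(mt$E[mt$name == "cortical"], 12000)
  expect_equal(mt$nu[mt$name == "nucleus"], 0.499)
  expect_equal(mt$area[mt$name == "annulus_fiber"], 1.35)
  expect_equal(mt$area[mt$name == "ALL"], 63.7)
  # default near-incompressibility cap
  expect_equal(material_table()$nu[mt$name == "nucleus"], 0.495)
  bad <- mt; bad$E[1] <- -1
  expect_error(validate_materials(bad), "positive")
  bad2 <- mt; bad2$nu[2] <- 0.6
  expect_error(validate_materials(bad2), "Poisson")
})

test_that("axial bar, patch test and truss formula verify against closed forms", {
  bar <- check_axial_bar()
  expect_lt(bar$rel_err, 0.01)
  expect_lt(check_patch_test(), 1e-8)
  tb <- check_truss_bar()
  expect_lt(tb$rel_err, 1e-12)
})

test_that("cantilever bending converges to Euler-Bernoulli within 10%", {
  cb <- check_cantilever(edge = 0.375)
  expect_lt(cb$rel_err_defl, 0.10)
  expect_lt(cb$rel_err_sigma, 0.10)
})

test_that("von Mises invariants hold for uniaxial and hydrostatic states", {
  fem <- fe_box_model(c(2, 2, 2), 1, E = 100, nu = 0, fix = "none")
  # uniaxial strain (nu = 0): sigma_vm = E * eps
  u_uni <- cbind(1e-3 * fem$nodes[, 1], 0, 0)
  vm <- compute_von_mises(fem, u_uni, regions = "solid")
  expect_equal(max(abs(vm$vm - 100 * 1e-3)), 0, tolerance = 1e-12)
  # hydrostatic state: deviatoric stress vanishes
  femh <- fe_box_model(c(2, 2, 2), 1, E = 100, nu = 0.25, fix = "none")
  u_h <- 1e-3 * femh$nodes
  vmh <- compute_von_mises(femh, u_h, regions = "solid")
  expect_lt(max(vmh$vm), 1e-10)
})

test_that("rigid-fit range of motion recovers synthetic fields", {
  fem <- default_fem(3.5)
  R3 <- lumbosim:::rot_x(3)
  u <- matrix(0, nrow(fem$nodes), 3)
  l4 <- unique(as.vector(fem$tets[fem$region == "L4_cortical", ]))
  l3 <- unique(as.vector(fem$tets[fem$region == "L3_cortical", ]))
  up <- union(l4, l3)
  u[up, ] <- fem$nodes[up, ] %*% t(R3) - fem$nodes[up, ]
  expect_equal(compute_rom(fem, u, "L4L5"), 3, tolerance = 1e-6)
  # pure translation gives zero rotation
  u2 <- matrix(rep(c(1, 2, 3), each = nrow(fem$nodes)), ncol = 3)
  expect_lt(compute_rom(fem, u2, "L4L5"), 1e-5)
})

test_that("zero load gives zero displacement; reactions balance applied loads", {
  fem <- default_fem(3.5)
  K <- assemble_stiffness(fem)
  sol0 <- assemble_and_solve(fem, load_case("flexion", follower_load = 0,
                                            moment = 0), K = K)
  expect_equal(max(abs(sol0$u)), 0)
  sol <- assemble_and_solve(fem, load_case("extension"), K = K)
  applied <- colSums(matrix(sol$f, ncol = 3, byrow = TRUE))
  resultant <- colSums(sol$reactions) + applied
  expect_lt(max(abs(resultant)) / max(abs(applied)), 1e-6)
  expect_lt(sol$residual, 1e-8)
})

test_that("the intact phantom flexes within the physiological corridor", {
  fem <- default_fem(3)
  sol <- assemble_and_solve(fem, load_case("flexion"))
  rom <- compute_rom(fem, sol$u, "L4L5")
  expect_gt(rom, 2)
  expect_lt(rom, 10)
})

test_that("ligament attachment creates the prescribed truss sets", {
  fem <- default_fem(3)
  tr <- fem$trusses
  # four capsular trusses per facet joint per side
  for (lv in c("L4L5", "L3L4")) for (sd in c("right", "left"))
    expect_equal(sum(tr$group == "CL" & tr$level == lv & tr$side == sd), 4)
  expect_true(all(c("ALL", "PLL", "LF", "ISL", "SSL", "ITL",
                    "annulus_fiber") %in% tr$group))
  # fibre trusses carry the Table area
  expect_true(all(tr$area[tr$group == "annulus_fiber"] == 1.35))
})

test_that("surgical variants resect as prescribed", {
  m <- default_phantom()
  fem0 <- default_fem(3)
  # M1 is the identity
  fem1 <- apply_variant(fem0, m, surgical_variant("M1"))
  expect_identical(fem1$tets, fem0$tets)
  expect_identical(fem1$trusses, fem0$trusses)
  # M2 keeps 3 of 4 capsular trusses on the operated side
  fem2 <- apply_variant(fem0, m, surgical_variant("M2"))
  expect_equal(sum(fem2$trusses$group == "CL" & fem2$trusses$level == "L4L5" &
                     fem2$trusses$side == "right"), 3)
  # M3 removes the right ligamentum flavum
  fem3 <- apply_variant(fem0, m, surgical_variant("M3"))
  expect_equal(sum(fem3$trusses$group == "LF" & fem3$trusses$level == "L4L5" &
                     fem3$trusses$side == "right"), 0)
  expect_gt(sum(fem3$trusses$group == "LF" & fem3$trusses$side == "left" &
                  fem3$trusses$level == "L4L5"), 0)
  # cartilage removal ordering: M6 > M5 >= M4 > M2 (element counts)
  cart <- function(fem) sum(fem$region == "facet_cartilage_L4L5_right")
  fem4 <- apply_variant(fem0, m, surgical_variant("M4"))
  fem5 <- apply_variant(fem0, m, surgical_variant("M5"))
  fem6 <- apply_variant(fem0, m, surgical_variant("M6"))
  expect_lt(cart(fem4), cart(fem2))
  expect_lte(cart(fem5), cart(fem4))
  expect_lt(cart(fem6), cart(fem5))
  expect_equal(cart(fem6), 0)
})

test_that("mesh refinement changes flexion ROM by less than 5%", {
  fem_c <- default_fem(3)
  fem_f <- build_fe_model(default_phantom(), target_edge = 2)
  rom_c <- compute_rom(fem_c, assemble_and_solve(fem_c, load_case("flexion"))$u,
                       "L4L5")
  rom_f <- compute_rom(fem_f, assemble_and_solve(fem_f, load_case("flexion"))$u,
                       "L4L5")
  expect_lt(abs(rom_c - rom_f) / rom_f, 0.05)
})
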