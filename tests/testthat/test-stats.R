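test_that("condition summaries use the unbiased standard deviation", {
  tab <- data.frame(subject = rep(1:3, 2), group = "PEID", angle_deg = 20,
                    diameter_mm = rep(c(7, 8), each = 3), attempts = 1,
                    removed_volume = c(2, 4, 6, 5, 5, 5))
  s <- summarize_volumes(tab)
  r7 <- s[s$diameter_mm == 7, ]
  expect_equal(r7$mean, 4)
  expect_equal(r7$sd, 2)
  r8 <- s[s$diameter_mm == 8, ]
  expect_equal(r8$sd, 0)
})

test_that("pairwise tests behave under identity, symmetry and separation", {
  x <- c(1, 2, 3, 4, 5)
  same <- pairwise_test(x, x, paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate || same$p_value == 1)
  set.seed(42)
  a <- rnorm(25, 0, 1); b <- rnorm(25, 5, 1)
  sep <- pairwise_test(a, b, paired = FALSE)
  expect_lt(sep$p_value, 0.01)
  expect_identical(sep$flag, "**")
  swap <- pairwise_test(b, a, paired = FALSE)
  expect_equal(swap$statistic, -sep$statistic, tolerance = 1e-12)
  expect_equal(swap$p_value, sep$p_value, tolerance = 1e-12)
  expect_error(pairwise_test(1, 1:3), "at least 2")
  expect_error(pairwise_test(1:3, 1:4, paired = TRUE), "equal group sizes")
})

test_that("one-way ANOVA matches the hand-computed toy example", {
  # groups {1,2}, {3,4}, {5,6}: SSB = 16 over df 2 gives MSB = 8;
  # SSW = 1.5 over df 3 gives MSW = 0.5; F = 8 / 0.5 = 16
  r <- anova_volumes(c(1, 2), c(3, 4), c(5, 6))
  expect_equal(r$statistic, 16, tolerance = 1e-12)
  ident <- anova_volumes(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_lt(ident$statistic, 1e-12)
  expect_gt(ident$p_value, 0.99)
  set.seed(9)
  shifted <- anova_volumes(rnorm(20), rnorm(20), rnorm(20, 2))
  expect_lt(shifted$p_value, 0.05)
  expect_error(anova_volumes(1:3, 4:6), "at least 3")
})

test_that("paired t-test type-I error is calibrated under the null", {
  set.seed(1234)
  n_sim <- 2000
  rejections <- vapply(seq_len(n_sim), function(i) {
    x <- rnorm(25, 100, 10)
    y <- x + rnorm(25, 0, 5)  # same generating mean, paired noise
    pairwise_test(x, y, paired = TRUE)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("angle contrasts table covers the requested cells", {
  set.seed(7)
  tab <- expand.grid(subject = 1:6, angle_deg = c(20, 30, 40),
                     diameter_mm = 8, attempts = 1)
  tab$group <- "PEID"
  tab$removed_volume <- 100 + 10 * (tab$angle_deg - 20) / 10 + rnorm(nrow(tab), 0, 4)
  ct <- angle_contrasts(tab, contrasts = list(c(20, 30), c(20, 40)))
  expect_equal(nrow(ct), 2)
  expect_true(all(c("statistic", "p_value", "flag") %in% names(ct)))
})
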