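test_that("candidate fit forms recover exact generating laws", {
  x <- seq(0.5, 3, length.out = 20)

  lin <- fit_model(x, 2 * x + 1, "linear")
  expect_equal(lin$A, 2, tolerance = 1e-10)
  expect_equal(lin$B, 1, tolerance = 1e-10)
  expect_equal(lin$r2, 1, tolerance = 1e-12)

  p1 <- fit_model(x, 2 * x^0.5, "powerI")
  expect_equal(p1$A, 2, tolerance = 1e-7)
  expect_equal(p1$B, 0.5, tolerance = 1e-7)

  p2 <- fit_model(x, -0.5 * x^1.3 + 0.2, "powerII", C_fixed = 0.2)
  expect_equal(p2$A, -0.5, tolerance = 1e-6)
  expect_equal(p2$B, 1.3, tolerance = 1e-6)
  expect_equal(p2$C, 0.2)

  expect_error(fit_model(x[1:2], (2 * x)[1:2], "linear"), "at least 3")
  expect_error(fit_model(c(-1, x), c(1, 2 * x^0.5), "powerI"), "positive x")
  expect_error(fit_model(x, 2 * x, "powerII"), "C_fixed")
})

test_that("power fits on noiseless laws are exact across exponents", {
  x <- seq(0.3, 2, length.out = 30)
  for (B in c(-2, -0.8, -0.2, 0.4, 1.1, 2)) {
    f <- fit_model(x, 1.7 * x^B, "powerI")
    expect_equal(f$A, 1.7, tolerance = 1e-8)
    expect_equal(f$B, B, tolerance = 1e-8)
  }
})

test_that("noisy power-law coefficients are recovered within Monte-Carlo error", {
  A_hat <- numeric(50); B_hat <- numeric(50)
  x <- seq(0.3, 1.5, length.out = 200)
  for (s in 1:50) {
    set.seed(s)
    y <- 0.53 * x^-0.365 + stats::rnorm(200, 0, 0.02)
    f <- fit_model(x, y, "powerI")
    A_hat[s] <- f$A; B_hat[s] <- f$B
  }
  expect_lt(abs(mean(A_hat) - 0.53), 3 * stats::sd(A_hat) / sqrt(50))
  expect_lt(abs(mean(B_hat) + 0.365), 3 * stats::sd(B_hat) / sqrt(50))
})

test_that("pooled offset recovers the common vertical translation", {
  x <- seq(0.3, 1.5, length.out = 120)
  sp <- rep(c("a", "b", "c"), each = 40)
  y <- 1.2 * x^0.8 + 0.25
  expect_equal(pooled_offset(x, y, sp), 0.25, tolerance = 1e-5)

  set.seed(11)
  yn <- y + stats::rnorm(120, 0, 0.01)
  # the offset is weakly identified over a short x range; recovery is coarse
  expect_equal(pooled_offset(x, yn, sp), 0.25, tolerance = 0.1)

  expect_error(pooled_offset(x, y, rep("a", 120)), "more than one species")
})

test_that("AIC majority rule selects the consensus form and breaks ties simply", {
  mk <- function(type, aic) structure(list(fit_type = type, aic = aic),
                                      class = "fit_result")
  species_vote <- function(winner) {
    aics <- c(linear = 0, powerI = 0, powerII = 0)
    aics[winner] <- -10
    list(mk("linear", aics["linear"]), mk("powerI", aics["powerI"]),
         mk("powerII", aics["powerII"]))
  }
  expect_equal(select_fit(replicate(5, species_vote("linear"),
                                    simplify = FALSE)), "linear")
  votes <- c(replicate(7, species_vote("powerI"), simplify = FALSE),
             replicate(5, species_vote("linear"), simplify = FALSE))
  expect_equal(select_fit(votes), "powerI")
  tie <- c(replicate(6, species_vote("powerI"), simplify = FALSE),
           replicate(6, species_vote("linear"), simplify = FALSE))
  expect_warning(winner <- select_fit(tie), "tie")
  expect_equal(winner, "linear")
})

test_that("mass modulation returns the log-mass relation only when significant", {
  mass <- 10^seq(-1.3, 1.9, length.out = 12)

  exact <- suppressWarnings(mass_modulate(mass, -0.18 * log10(mass) + 1.4))
  expect_true(exact$modulated)
  expect_equal(exact$slope, -0.18, tolerance = 1e-10)
  expect_equal(exact$intercept, 1.4, tolerance = 1e-10)

  flat <- suppressWarnings(mass_modulate(mass, rep(0.53, 12)))
  expect_false(flat$modulated)
  expect_equal(flat$value, 0.53)

  slopes <- numeric(50)
  for (s in 1:50) {
    set.seed(s)
    mm <- mass_modulate(mass, -0.18 * log10(mass) + 1.4 +
                          stats::rnorm(12, 0, 0.05))
    slopes[s] <- if (mm$modulated) mm$slope else NA
  }
  expect_gt(mean(!is.na(slopes)), 0.9)
  expect_lt(abs(mean(slopes, na.rm = TRUE) + 0.18),
            3 * stats::sd(slopes, na.rm = TRUE) / sqrt(sum(!is.na(slopes))))

  expect_error(mass_modulate(mass[1:2], c(1, 2)), "3 species")
})

test_that("major-axis regression matches the eigenvector oracle", {
  x <- seq(0, 1, length.out = 30)
  expect_equal(ma_regression(x, x)$slope, 1, tolerance = 1e-12)
  expect_equal(ma_regression(x, x)$r2, 1, tolerance = 1e-12)
  expect_equal(ma_regression(x, 2 * x, through_origin = TRUE)$slope, 2,
               tolerance = 1e-12)

  set.seed(99)
  xx <- stats::rnorm(500); yy <- 0.6 * xx + stats::rnorm(500, 0, 0.4)
  got <- ma_regression(xx, yy)$slope
  ev <- eigen(stats::cov(cbind(xx, yy)))$vectors[, 1]
  expect_equal(got, ev[2] / ev[1], tolerance = 1e-10)

  expect_error(ma_regression(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("the permutation slope test is calibrated at its extremes", {
  x <- 1:10
  perfect <- permutation_slope_test(x, x, n_reps = 10000, seed = 1)
  expect_lt(perfect$p_value, 0.001)

  flat <- permutation_slope_test(x, rep(2, 10), n_reps = 1000, seed = 1)
  expect_equal(flat$slope_obs, 0)
  expect_equal(flat$p_value, 1)

  set.seed(5)
  null_case <- permutation_slope_test(stats::rnorm(50), stats::rnorm(50),
                                      n_reps = 2000, seed = 2)
  expect_gt(null_case$p_value, 0.01)

  # reproducible under a fixed seed
  a <- permutation_slope_test(x, x + c(1, -1), n_reps = 500, seed = 7)
  b <- permutation_slope_test(x, x + c(1, -1), n_reps = 500, seed = 7)
  expect_identical(a$p_value, b$p_value)
})
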