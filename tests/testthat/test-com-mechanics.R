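test_that("whole-stride superposition tiles, overlaps and gaps with duty factor", {
  n <- 401
  fz <- rep(1, n)   # boxcar footfall: loaded fraction is exactly beta

  # beta = 0.5: the two footfalls tile the stride with no gap or overlap
  s <- synthesize_whole_stride(fz, beta = 0.5, n_samples = 2000)
  expect_true(all(s$fz_total > 0))
  expect_equal(mean(s$fz_total), 1, tolerance = 5e-3)

  # beta = 0.6: double support of fraction 0.1 at each step
  s6 <- synthesize_whole_stride(fz, beta = 0.6, n_samples = 2000)
  expect_equal(mean(s6$fz_total == 2), 0.2, tolerance = 1e-2)

  # beta = 0.4: two aerial windows, each fraction 0.1, zero total force
  s4 <- synthesize_whole_stride(fz, beta = 0.4, n_samples = 2000)
  expect_equal(mean(s4$fz_total == 0), 0.2, tolerance = 1e-2)

  expect_error(synthesize_whole_stride(fz, beta = 1), "beta")
})

test_that("COM integration obeys static balance and the closed-form sinusoid", {
  n <- 2000
  m <- 10; v <- 2; Tstr <- 0.8; g <- 9.81

  # static balance: constant 1 BW support
  com <- integrate_com(rep(1, n), rep(0, n), m, v, Tstr, g = g)
  expect_equal(max(abs(com$vz)), 0, tolerance = 1e-12)
  expect_equal(max(abs(com$z)), 0, tolerance = 1e-12)
  expect_equal(com$ke, rep(0.5 * m * v^2, n), tolerance = 1e-12)
  expect_equal(max(abs(com$pe)), 0, tolerance = 1e-12)

  # fz = 1 + 0.1 sin(2 pi t/T): z is a sinusoid of amplitude 0.1 g T^2/(4 pi^2)
  tt <- (seq_len(n) - 1) / n
  com2 <- integrate_com(1 + 0.1 * sin(2 * pi * tt), rep(0, n), m, v, Tstr,
                        g = g)
  amp <- 0.1 * g * Tstr^2 / (4 * pi^2)
  expect_equal(max(com2$z) - min(com2$z), 2 * amp, tolerance = 1e-3)
  nvd <- net_vertical_displacement(com2$z, h = 0.5)
  expect_equal(nvd$nvd_m, 2 * amp, tolerance = 1e-3)
  expect_equal(nvd$nvd_star, nvd$nvd_m / 0.5)

  expect_error(integrate_com(rep(1, n), rep(0, n), -1, v, Tstr), "positive")
})

test_that("percent congruity hits its endpoints and quarter-phase midpoint", {
  t <- seq(0, 1, length.out = 2001)
  inphase <- sin(2 * pi * t)
  expect_equal(percent_congruity(inphase, 3 + 2 * inphase), 100)
  expect_equal(percent_congruity(inphase, -inphase), 0)
  expect_equal(percent_congruity(sin(2 * pi * t + pi / 2), inphase), 50,
               tolerance = 0.5)
  expect_error(percent_congruity(rep(1, 10), rep(2, 10)), "dead band")
})

test_that("congruity is invariant to affine rescaling of either energy", {
  set.seed(3)
  t <- seq(0, 1, length.out = 500)
  ke <- 2 + sin(2 * pi * t) + 0.2 * stats::rnorm(500)
  pe <- 1 + cos(2 * pi * t)
  base <- percent_congruity(ke, pe)
  expect_equal(percent_congruity(5 * ke + 3, pe), base)
  expect_equal(percent_congruity(ke, 0.01 * pe - 7), base)
})

test_that("impulse-consistent strides give periodic COM velocity and unit mean force", {
  tg <- seq(0, 1, length.out = 801)
  for (seed in 1:5) {
    set.seed(seed)
    za <- c(stats::runif(1, 1.0, 1.6), stats::runif(1, -0.3, 0.4),
            stats::runif(1, -0.1, 0.2))
    fz <- reconstruct(fourier_coefficients(za), tg)
    beta <- stats::runif(1, 0.35, 0.7)
    sm <- stride_mechanics(fz, -0.15 * sin(2 * pi * tg), beta = beta,
                           mass_kg = 2, v_mps = 1.5, t_stance_s = 0.25,
                           h = 0.3, t_stance = tg)
    expect_equal(mean(sm$fz_total), 1, tolerance = 1e-6)
    # periodic closure: no net change in vertical momentum over the stride
    expect_lt(abs(sm$net_dvz) / diff(range(sm$vz)), 1e-6)
    expect_lt(abs(sm$net_dvx) / max(abs(sm$vx)), 1e-6)
    expect_equal(mean(sm$vz), 0, tolerance = 1e-9)
    expect_equal(mean(sm$vx), 1.5, tolerance = 1e-9)
    expect_gte(sm$percent_congruity, 0)
    expect_lte(sm$percent_congruity, 100)
    expect_gte(sm$nvd_m, 0)
  }
})

test_that("bouncing and vaulting constructions separate in congruity", {
  tg <- seq(0, 1, length.out = 1001)
  # grounded bounce: single-humped vertical force at beta ~ 0.5
  bounce <- stride_mechanics(sin(pi * tg), -0.15 * sin(2 * pi * tg),
                             beta = 0.52, mass_kg = 1, v_mps = 1.2,
                             t_stance_s = 0.25, h = 0.25, t_stance = tg)
  # vaulting-like: two-humped vertical force at high duty factor
  fz2 <- 0.8 * sin(pi * tg) + 0.45 * sin(3 * pi * tg)
  vault <- stride_mechanics(fz2, -0.1 * sin(2 * pi * tg), beta = 0.75,
                            mass_kg = 1, v_mps = 0.4, t_stance_s = 0.5,
                            h = 0.25, t_stance = tg)
  expect_gt(bounce$percent_congruity, 80)
  expect_lt(vault$percent_congruity, 50)
  expect_gt(bounce$percent_congruity, vault$percent_congruity + 30)
})

test_that("net vertical displacement reads peak-to-peak excursion", {
  t <- seq(0, 1, length.out = 200)
  expect_equal(net_vertical_displacement(rep(0.2, 200))$nvd_m, 0)
  expect_equal(net_vertical_displacement(0.03 * sin(2 * pi * t))$nvd_m,
               0.06, tolerance = 1e-3)
  expect_error(net_vertical_displacement(t, h = 0), "positive")
})
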