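test_that("zero-lag low-pass filter has unit DC gain, no lag, and attenuates", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)

  # DC gain 1
  const <- rep(3.7, length(t))
  expect_equal(lowpass_filter(const, fs, 50), const, tolerance = 1e-6)

  # passband sine (0.1 * cutoff): amplitude within 1%, zero lag
  x <- sin(2 * pi * 5 * t)
  y <- lowpass_filter(x, fs, 50)
  expect_equal(max(abs(y)), 1, tolerance = 0.01)
  cc <- stats::ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # stopband sine (10 * cutoff): below 5% of input
  x_hi <- sin(2 * pi * 500 * t)
  expect_lt(max(abs(lowpass_filter(x_hi, fs, 50))), 0.05)

  expect_error(lowpass_filter(x, fs, fs / 2), "Nyquist")
})

test_that("filtering is near-idempotent on band-limited signals", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * 3 * t) + 0.5 * sin(2 * pi * 7 * t)
  y1 <- lowpass_filter(x, fs, 60)
  y2 <- lowpass_filter(y1, fs, 60)
  expect_equal(y2, y1, tolerance = 1e-3)
})

test_that("anatomical-frame orientation follows heading and foot side", {
  fx <- c(1, -2, 3); fy <- c(0.5, 0.2, -0.1); fz <- c(10, 20, 30)
  idc <- to_anatomical_frame(fx, fy, fz, heading = 1, side = "right")
  expect_equal(idc$fx, fx)
  expect_equal(idc$fy, fy)
  expect_equal(idc$fz, fz)

  rev_head <- to_anatomical_frame(fx, fy, fz, heading = -1, side = "right")
  expect_equal(rev_head$fx, -fx)
  expect_equal(rev_head$fz, fz)

  left <- to_anatomical_frame(fx, fy, fz, heading = 1, side = "left")
  expect_equal(left$fy, -idc$fy)
  expect_equal(left$fx, idc$fx)

  expect_error(to_anatomical_frame(fx, fy, fz, heading = 0), "\\+1 or -1")
})

test_that("stance detection finds the longest loaded run", {
  fs <- 1000
  fz <- numeric(1001)
  fz[101:500] <- 100                      # loaded 0.10-0.50 s
  st <- detect_stance(fz, fs, threshold = 5)
  expect_equal(st$touchdown, 101)
  expect_equal(st$liftoff, 500)
  expect_equal(st$t_stance_s, 0.399, tolerance = 1e-6)

  # isolated spike elsewhere is ignored by the longest-run rule
  fz_spike <- fz
  fz_spike[800] <- 500
  expect_warning(st2 <- detect_stance(fz_spike, fs, threshold = 5), NA)
  expect_equal(st2$touchdown, 101)
  expect_equal(st2$liftoff, 500)

  expect_error(detect_stance(numeric(100), fs, threshold = 5), "no sample")

  # comparable-length runs warn
  fz_two <- numeric(1000)
  fz_two[101:300] <- 50
  fz_two[601:795] <- 50
  expect_warning(detect_stance(fz_two, fs, threshold = 5), "comparable")
})

test_that("stance detection agrees with a brute-force run oracle", {
  fs <- 500
  for (seed in 1:20) {
    set.seed(seed)
    fz <- stats::rnorm(800, 0, 1)
    a <- sample(50:300, 1)
    len <- sample(100:400, 1)
    fz[a:(a + len)] <- fz[a:(a + len)] + 60 * sin(pi * seq(0, 1,
                                                           length.out = len + 1))
    thr <- 10
    orc <- stance_oracle(fz, thr)
    got <- suppressWarnings(detect_stance(fz, fs, threshold = thr))
    expect_equal(got$touchdown, unname(orc["touchdown"]))
    expect_equal(got$liftoff, unname(orc["liftoff"]))
  }
})

test_that("impulse correction rescales the vertical force to balance impulses", {
  m <- 2; g <- 9.81; t_st <- 0.3
  fz <- rep(m * g, 301)

  # balanced case: recorded impulse already equals half the BW stride impulse
  ic <- impulse_correction(fz, m, t_st, beta = 0.5, g = g)
  expect_equal(ic$alpha, 1, tolerance = 1e-12)
  expect_equal(ic$fz_adjusted, fz, tolerance = 1e-12)

  # lower duty factor raises the required impulse proportionally
  ic2 <- impulse_correction(fz, m, t_st, beta = 0.4, g = g)
  expect_equal(ic2$alpha, 1.25, tolerance = 1e-12)

  # doubling the recording halves alpha; corrected signal is unchanged
  ic3 <- impulse_correction(2 * fz, m, t_st, beta = 0.4, g = g)
  expect_equal(ic3$alpha, ic2$alpha / 2, tolerance = 1e-12)
  expect_equal(ic3$fz_adjusted, ic2$fz_adjusted, tolerance = 1e-12)

  # adjusted impulse is exactly m g t_stance / (2 beta)
  tt <- seq(0, t_st, length.out = 301)
  expect_equal(pracma::trapz(tt, ic2$fz_adjusted),
               m * g * t_st / (2 * 0.4), tolerance = 1e-12)

  expect_error(impulse_correction(-fz, m, t_st, 0.5), "positive")
  expect_error(impulse_correction(fz, m, t_st, 1.2), "beta")
})

test_that("footfall records round-trip through the CSV dialect", {
  rec <- make_footfall(za = c(1.2, 0.3), mass_kg = 1.5, t_stance_s = 0.2,
                       sampling_rate_hz = 500, beta = 0.55, v_mps = 1.1)
  path <- tempfile(fileext = ".csv")
  write_footfall(rec, path)
  back <- read_footfall(path)
  expect_equal(back$fz_n, rec$fz_n, tolerance = 1e-9)
  expect_equal(back$mass_kg, 1.5)
  expect_equal(back$beta, 0.55)
  expect_equal(back$side, rec$side)
})
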