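test_that("Savitzky-Golay preserves low-order polynomials everywhere", {
  x <- 2000:2300
  s_const <- profile_spectrum(x, rep(5, length(x)))
  out <- smooth_savitzky_golay(s_const, 7, 2)
  expect_equal(out$intensity, rep(5, length(x)), tolerance = 1e-10)

  s_quad <- profile_spectrum(x, (x - 2100)^2 / 50 + 3)
  out <- smooth_savitzky_golay(s_quad, 9, 2)
  expect_equal(out$intensity, s_quad$intensity, tolerance = 1e-8)
  # edges included (polynomial extrapolation of the terminal windows)
  expect_equal(out$intensity[1:4], s_quad$intensity[1:4], tolerance = 1e-8)

  expect_error(smooth_savitzky_golay(s_quad, 8, 2), "odd")
  expect_error(smooth_savitzky_golay(s_quad, 3, 3), "exceed")
  expect_error(
    smooth_savitzky_golay(profile_spectrum(2000:2004, rep(1, 5)), 7, 2),
    "shorter")
})

test_that("Savitzky-Golay reduces white-noise variance", {
  set.seed(11)
  x <- 2000:12000
  y <- rnorm(length(x), 0, 1)
  s <- smooth_savitzky_golay(profile_spectrum(x, y), 11, 2)
  expect_lt(var(s$intensity), var(y))
})

test_that("TopHat removes baseline, preserves narrow peaks, idempotent", {
  x <- 2000:6000
  # constant -> all zeros
  out <- subtract_baseline_tophat(profile_spectrum(x, rep(7, length(x))), 150)
  expect_equal(out$intensity, rep(0, length(x)))
  # all-zero -> all zeros
  out0 <- subtract_baseline_tophat(profile_spectrum(x, rep(0, length(x))), 150)
  expect_equal(out0$intensity, rep(0, length(x)))

  # linear ramp + narrow Gaussian: ramp removed, peak height preserved
  ramp <- (x - 2000) * 0.05
  sdev <- 5 / 2.355
  peak <- 1000 * exp(-(x - 4000)^2 / (2 * sdev^2))
  s <- profile_spectrum(x, ramp + peak)
  out <- subtract_baseline_tophat(s, 150)
  # oracle: brute-force sliding min then max windows
  half <- round(150 / 2)
  ero <- sapply(seq_along(x), function(i)
    min(s$intensity[max(1, i - half):min(length(x), i + half)]))
  opening <- sapply(seq_along(x), function(i)
    max(ero[max(1, i - half):min(length(x), i + half)]))
  expect_equal(out$intensity, s$intensity - opening)
  expect_true(all(out$intensity >= 0))
  peak_region <- abs(x - 4000) < 3
  expect_gt(max(out$intensity[peak_region]), 0.95 * 1000)
  off_peak <- abs(x - 4000) > 200 & x > 2200 & x < 5800
  expect_lt(max(out$intensity[off_peak]), 0.01 * max(ramp))

  # idempotence
  again <- subtract_baseline_tophat(out, 150)
  expect_equal(again$intensity, out$intensity, tolerance = 1e-10)

  expect_error(subtract_baseline_tophat(s, 0), "element_width")
})

test_that("noise estimate is robust and consistent with a normal sd", {
  x <- seq_len(10000) + 2000
  expect_equal(estimate_noise(profile_spectrum(x, rep(0, length(x)))), 0)
  set.seed(3)
  y <- rnorm(length(x), 0, 10)
  s <- profile_spectrum(x, y)
  expect_gt(estimate_noise(s), 9)
  expect_lt(estimate_noise(s), 11)
  # 5 sparse tall peaks do not inflate the estimate
  y2 <- y
  y2[sample(length(y2), 5)] <- 5000
  s2 <- profile_spectrum(x, y2)
  expect_gt(estimate_noise(s2), 9)
  expect_lt(estimate_noise(s2), 11)
  expect_error(estimate_noise(profile_spectrum(numeric(0), numeric(0))),
               "empty")
})

test_that("mass calibration recovers affine and quadratic distortions", {
  refs <- default_calibrants()
  x <- seq(2000, 20000, by = 100)
  s <- profile_spectrum(x, rep(1, length(x)))

  ident <- calibrate_mass_axis(s, refs$reference_mass, refs, "linear")
  expect_equal(ident$mz, x, tolerance = 1e-9)
  expect_lt(attr(ident, "max_residual"), 1e-9)

  shift <- calibrate_mass_axis(s, refs$reference_mass + 5, refs, "linear")
  expect_equal(shift$mz, x - 5, tolerance = 1e-9)

  # multiplicative distortion: all six calibrant masses restored
  obs <- refs$reference_mass * 1.001
  sobs <- profile_spectrum(obs, rep(1, 6), warn_window = FALSE)
  cal <- calibrate_mass_axis(sobs, obs, refs, "linear")
  expect_lt(max(abs(cal$mz - refs$reference_mass)), 0.01)

  # quadratic distortion: true mass is a quadratic in the observed axis
  cf <- c(5, 0.999, 1e-9)
  obs_q <- vapply(refs$reference_mass, function(r) {
    # invert r = cf[1] + cf[2] * o + cf[3] * o^2 for the observed position
    (-cf[2] + sqrt(cf[2]^2 - 4 * cf[3] * (cf[1] - r))) / (2 * cf[3])
  }, numeric(1))
  sq <- profile_spectrum(obs_q, rep(1, 6), warn_window = FALSE)
  cal_q <- calibrate_mass_axis(sq, obs_q, refs, "quadratic")
  expect_lt(max(abs(cal_q$mz - refs$reference_mass)), 1e-6)

  expect_error(
    calibrate_mass_axis(s, refs$reference_mass[1:2], refs[1:2, ],
                        "quadratic"),
    ">= 3")
  expect_error(calibrate_mass_axis(s, refs$reference_mass[1:3], refs),
               "pair")
})

test_that("burst quality gate applies criteria inclusively and in order", {
  q <- quality_params()
  mk <- function(snr, int, width, n_extra = 0) {
    peak_table(rep("b", 1 + n_extra),
               mz = seq(3000, by = 10, length.out = 1 + n_extra),
               intensity = c(int, rep(1, n_extra)),
               snr = c(snr, rep(1, n_extra)),
               width = c(width, rep(5, n_extra)))
  }
  expect_equal(burst_quality_gate(mk(1.5, 500, 9), q)$reason, "snr")
  # boundary values all accepted (inclusive thresholds)
  ok <- burst_quality_gate(mk(2, 100, 10, n_extra = 499), q)
  expect_true(ok$accept)
  r <- burst_quality_gate(mk(2, 100, 10, n_extra = 500), q)
  expect_equal(r$reason, "max_peaks")
  expect_equal(burst_quality_gate(mk(5, 99, 9), q)$reason, "intensity")
  expect_equal(burst_quality_gate(mk(5, 500, 11), q)$reason, "width")
  expect_equal(burst_quality_gate(peak_table(character(0), numeric(0)),
                                  q)$reason, "no peaks")
  # width as a minimum under the alternative reading
  qmin <- quality_params(width_is_max = FALSE)
  expect_true(burst_quality_gate(mk(5, 500, 11), qmin)$accept)
  expect_error(quality_params(snr_min = 0), "positive")
})
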