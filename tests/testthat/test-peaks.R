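test_that("single noise-free Gaussian yields one centroided peak", {
  s <- gaussian_spectrum(center = 5000, height = 1000, fwhm = 5)
  pk <- detect_peaks(s, snr_min = 2)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$mz - 5000), 0.5)
  expect_equal(pk$intensity, 1000, tolerance = 0.01)
  expect_lt(abs(pk$width - 5), 1.5)

  flat <- profile_spectrum(2000:3000, rep(0, 1001))
  expect_equal(nrow(detect_peaks(flat)), 0L)
})

test_that("detect_peaks recovers a seeded template within tolerance", {
  sc <- strain_scenario(seed = 5, n_peaks = 20)
  pk <- sc$peaks[[1]]
  m <- match_peaks(sort(sc$template$mz), pk$mz, 2)
  expect_equal(nrow(m$pairs), 20L)
})

test_that("match_peaks respects the inclusive +/- 2 boundary", {
  m <- match_peaks(6451, 6452, 2)
  expect_equal(nrow(m$pairs), 1L)
  m2 <- match_peaks(6422, 6425, 2)
  expect_equal(nrow(m2$pairs), 0L)
  m3 <- match_peaks(6422, 6424, 2)   # exactly 2 apart: same peak
  expect_equal(nrow(m3$pairs), 1L)
})

test_that("match_peaks is greedy by smallest gap and one-to-one", {
  # 1001.6 is nearer 1003 (1.4) than 1000 (1.6); brute-force optimum agrees
  m <- match_peaks(c(1000, 1003), 1001.6, 2)
  expect_equal(m$pairs[, "a"], 2L, ignore_attr = TRUE)
  expect_equal(m$unmatched_a, 1L)
  # never more pairs than the shorter list
  set.seed(4)
  for (i in 1:20) {
    a <- sort(runif(sample(0:10, 1), 2000, 2100))
    b <- sort(runif(sample(0:10, 1), 2000, 2100))
    m <- match_peaks(a, b, 2)
    expect_lte(nrow(m$pairs), min(length(a), length(b)))
    # symmetry up to orientation
    m2 <- match_peaks(b, a, 2)
    expect_equal(nrow(m$pairs), nrow(m2$pairs))
  }
})

test_that("consensus requires presence in all replicates", {
  r1 <- peak_table("s", c(6421, 9000), c(10, 5), c(8, 8), c(5, 5))
  r2 <- peak_table("s", c(6422, 9001), c(12, 6), c(8, 8), c(5, 5))
  r3 <- peak_table("s", 6423, 11, 8, 5)
  cons <- consensus_peaks(list(r1, r2, r3))
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$mz, 6422, tolerance = 1e-9)
  expect_equal(cons$support, 3L)
  expect_equal(cons$intensity, 11)

  cons2 <- consensus_peaks(list(r1, r2))
  expect_equal(nrow(cons2), 2L)

  empty <- peak_table(character(0), numeric(0))
  expect_equal(nrow(consensus_peaks(list(empty, empty))), 0L)
  expect_error(consensus_peaks(list(r1)), ">= 2")
})

test_that("consensus tolerance is monotone and output near every replicate", {
  set.seed(7)
  for (i in 1:10) {
    reps <- lapply(1:3, function(j) {
      mz <- sort(runif(15, 2000, 20000))
      peak_table("s", mz + rnorm(15, 0, 0.7), runif(15, 100, 1000),
                 runif(15, 5, 50), 5)
    })
    c1 <- consensus_peaks(reps, 1)
    c2 <- consensus_peaks(reps, 2)
    c5 <- consensus_peaks(reps, 5)
    expect_lte(nrow(c1), nrow(c2))
    expect_lte(nrow(c2), nrow(c5))
    # every consensus peak is within tol of some peak in every replicate
    for (r in reps) {
      if (nrow(c2)) {
        expect_true(all(vapply(c2$mz, function(x)
          min(abs(r$mz - x)) <= 2, logical(1))))
      }
    }
  }
})

test_that("composite spectrum applies the inclusive 65% threshold", {
  base <- gaussian_spectrum(center = 7000, height = 500, seed = 1)
  reps <- list(base, base, base)
  comp <- composite_spectrum(reps)
  expect_equal(comp$included, 1:3)
  expect_equal(comp$spectrum$intensity, base$intensity)

  # a partly decorrelated replicate (its peak moved elsewhere) drops below
  # the threshold and is excluded; the concordant pair stays above it
  odd <- gaussian_spectrum(center = 12000, height = 500, seed = 2)
  odd$intensity <- odd$intensity + 0.45 * base$intensity
  comp2 <- composite_spectrum(list(base, base, odd))
  expect_equal(comp2$excluded, 3L)
  expect_lt(comp2$similarity[3], 0.65)
  expect_gte(min(comp2$similarity[1:2]), 0.65)

  expect_error(composite_spectrum(list(base)), ">= 2")

  # mutually decorrelated replicates: nothing passes the threshold
  set.seed(22)
  mk_noise <- function() profile_spectrum(
    base$mz, rnorm(length(base$mz))^2, warn_window = FALSE)
  expect_error(composite_spectrum(list(mk_noise(), mk_noise(), mk_noise())),
               "no replicate meets threshold")
})

test_that("composite boundary: similarity exactly at threshold is included", {
  # two fingerprints engineered to correlate well below 1 but >= threshold
  x <- seq(2000, 2200)
  a <- profile_spectrum(x, c(rep(1, 100), rep(5, 101)),
                        mass_window = c(2000, 2200))
  b <- profile_spectrum(x, c(rep(1, 100), rep(2, 101)),
                        mass_window = c(2000, 2200))
  r <- pearson(resample_to_grid(a, 1), resample_to_grid(b, 1))
  comp <- composite_spectrum(list(a, b), threshold = r, bin_width = 1)
  expect_equal(comp$included, 1:2)
})

test_that("spectrum_stats reports range, count, base peak with tie-break", {
  p <- peak_table("s", c(2044, 6422, 10685), c(10, 400, 30), 5, 5)
  st <- spectrum_stats(p)
  expect_equal(st$mass_range, c(2044, 10685))
  expect_equal(st$n_peaks, 3L)
  expect_equal(st$base_peak, 6422)

  one <- peak_table("s", 5000, 9, 5, 5)
  expect_equal(spectrum_stats(one)$mass_range, c(5000, 5000))

  tie <- peak_table("s", c(3000, 4000), c(7, 7), 5, 5)
  expect_equal(spectrum_stats(tie)$base_peak, 3000)
  expect_error(spectrum_stats(peak_table(character(0), numeric(0))), "empty")
})

test_that("prominent_peaks filters by S:N and keeps NA rows", {
  p <- peak_table("s", c(3000, 4000, 5000), c(10, 20, 30), c(2, 6, NA), 5)
  f <- prominent_peaks(p, 5)
  expect_equal(f$mz, c(4000, 5000))
})
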