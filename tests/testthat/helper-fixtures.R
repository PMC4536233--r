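# Shared fixture builders; everything is generated in code.

# a single Gaussian peak on a 1 Da grid, optionally with noise/baseline
gaussian_spectrum <- function(center = 5000, height = 1000, fwhm = 5,
                              window = c(2000, 20000), noise_sd = 0,
                              seed = 1, sample_id = "g") {
  set.seed(seed)
  x <- seq(window[1], window[2], by = 1)
  sdev <- fwhm / (2 * sqrt(2 * log(2)))
  y <- height * exp(-(x - center)^2 / (2 * sdev^2))
  if (noise_sd > 0) y <- y + rnorm(length(x), 0, noise_sd)
  profile_spectrum(x, y, sample_id = sample_id, mass_window = window,
                   warn_window = FALSE)
}

# one preprocessed strain scenario: template + replicates + consensus
strain_scenario <- function(seed = 1, n_peaks = 20, n_rep = 3) {
  tpl <- make_template(seed = seed, n_peaks = n_peaks)
  nm <- noise_model(seed = seed)
  reps <- simulate_replicates(tpl, nm, n_rep)
  pre <- lapply(reps, preprocess_spectrum)
  peaks <- lapply(pre, detect_peaks)
  list(template = tpl, replicates = reps, preprocessed = pre, peaks = peaks,
       consensus = consensus_peaks(peaks))
}

# brute-force average-linkage clustering oracle: returns cophenetic matrix
average_linkage_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  co <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dij <- mean(D[clusters[[i]], clusters[[j]]])
      if (dij < best[1]) best <- c(dij, i, j)
    }
    i <- best[2]; j <- best[3]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      co[a, b] <- co[b, a] <- best[1]
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  co
}

expect_matched <- function(found, expected, tol = 2) {
  ok <- vapply(expected, function(x) any(abs(found - x) <= tol), logical(1))
  expect_true(all(ok),
              info = paste("unmatched:", paste(expected[!ok], collapse = ", ")))
}
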