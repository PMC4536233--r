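# Synthetic-data module: spectra, replicates, mixtures and aligned sequence
# pairs with the statistical structure the pipeline assumes, with ground
# truth attached to every object so downstream stages can be validated
# end to end.

#' Generate a strain peak template
#'
#' Peak positions are drawn uniformly over the mass window subject to a
#' minimum 4 Da separation; mean intensities are log-normal. Deterministic
#' for a fixed seed. Peak counts default to the 6--56 range observed for
#' microalgal protein fingerprints in m/z 2,000--20,000.
#'
#' @param seed Integer seed.
#' @param n_peaks Number of peaks (6--56 unless bounds overridden); if `NULL`
#'   drawn uniformly from `peak_bounds`.
#' @param mass_window `(lo, hi)` in Da.
#' @param peak_bounds Allowed `(min, max)` peak count.
#' @param min_separation Minimum distance between template peaks (Da).
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters.
#' @param cv Replicate-to-replicate intensity coefficient of variation.
#' @param width Peak full width at half maximum (Da).
#' @param strain_id Template identifier.
#' @return A `strain_template`: list with `strain_id`, `mz`, `intensity`,
#'   `cv`, `width`.
#' @export
make_template <- function(seed, n_peaks = NULL, mass_window = c(2000, 20000),
                          peak_bounds = c(6L, 56L), min_separation = 4,
                          intensity_meanlog = log(1500),
                          intensity_sdlog = 0.5, cv = 0.15, width = 5,
                          strain_id = sprintf("strain%d", seed)) {
  set.seed(seed)
  if (is.null(n_peaks)) {
    n_peaks <- sample(peak_bounds[1]:peak_bounds[2], 1L)
  }
  if (n_peaks < peak_bounds[1] || n_peaks > peak_bounds[2]) {
    stop(sprintf("n_peaks must be in [%d, %d]", peak_bounds[1],
                 peak_bounds[2]), call. = FALSE)
  }
  span <- diff(mass_window)
  if (n_peaks * min_separation >= span) {
    stop("peak separation infeasible for this many peaks", call. = FALSE)
  }
  # rejection sampling for the separation constraint; margin keeps peaks off
  # the window edges so their flanks stay inside
  for (try in 1:1000) {
    pos <- sort(stats::runif(n_peaks, mass_window[1] + 50,
                             mass_window[2] - 50))
    if (n_peaks < 2L || min(diff(pos)) >= min_separation) break
    pos <- NULL
  }
  if (is.null(pos)) stop("could not satisfy peak separation", call. = FALSE)
  intensity <- stats::rlnorm(n_peaks, intensity_meanlog, intensity_sdlog)
  structure(list(strain_id = strain_id, mz = pos, intensity = intensity,
                 cv = cv, width = width, mass_window = mass_window),
            class = "strain_template")
}

#' Noise model for simulated spectra
#'
#' Additive white noise, a smooth exponentially decaying baseline, and
#' replicate-to-replicate mass-axis jitter. The default jitter sd of 0.7 Da
#' keeps replicate centroids within the +/- 2 Da matching tolerance with
#' high probability; the default noise floor (sd 10 a.u.) gives the
#' log-normal template intensities a base-peak S:N well above 10.
#'
#' @param additive_sd Gaussian noise sd (a.u.).
#' @param baseline_amplitude Baseline height at the window start (a.u.).
#' @param baseline_scale Baseline exponential decay length (Da).
#' @param jitter_sd Mass-axis jitter sd (Da).
#' @param seed Base seed for replicate simulation.
#' @return A `noise_model` list.
#' @export
noise_model <- function(additive_sd = 10, baseline_amplitude = 200,
                        baseline_scale = 3000, jitter_sd = 0.7, seed = 1L) {
  vals <- c(additive_sd, baseline_amplitude, baseline_scale, jitter_sd)
  if (any(vals < 0)) stop("noise parameters must be non-negative",
                          call. = FALSE)
  structure(list(additive_sd = additive_sd,
                 baseline_amplitude = baseline_amplitude,
                 baseline_scale = baseline_scale, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Sum of Gaussian peaks on a grid, each evaluated only on its local support.
add_gaussians <- function(y, grid, pos, height, fwhm) {
  sdev <- fwhm / (2 * sqrt(2 * log(2)))
  lo <- grid[1]; step <- grid[2] - grid[1]
  for (k in seq_along(pos)) {
    i0 <- max(1L, floor((pos[k] - 6 * sdev - lo) / step) + 1L)
    i1 <- min(length(grid), ceiling((pos[k] + 6 * sdev - lo) / step) + 1L)
    idx <- i0:i1
    y[idx] <- y[idx] + height[k] * exp(-(grid[idx] - pos[k])^2 / (2 * sdev^2))
  }
  y
}

#' Simulate one profile spectrum from a template
#'
#' The trace is the sum of Gaussian peaks (template FWHM) at jittered
#' positions with log-normal intensity variation, a smooth exponential
#' baseline, and additive Gaussian noise, sampled on a 1 Da grid over the
#' mass window. Ground-truth realized peak positions/intensities are attached
#' as the `truth` attribute.
#'
#' @param template A [make_template()] result.
#' @param nm A [noise_model()].
#' @param replicate_index Replicate number (>= 1).
#' @param seed Seed for this draw; defaults to
#'   `nm$seed * 1000 + replicate_index` (kept below 2^31).
#' @return A [profile_spectrum()] with attribute `truth` (data.frame
#'   `mz`, `intensity`).
#' @export
simulate_spectrum <- function(template, nm = noise_model(),
                              replicate_index = 1L,
                              seed = NULL) {
  stopifnot(inherits(template, "strain_template"),
            inherits(nm, "noise_model"))
  if (is.null(seed)) {
    seed <- (nm$seed * 1000 + replicate_index) %% .Machine$integer.max
  }
  set.seed(seed)
  win <- template$mass_window
  grid <- seq(win[1], win[2], by = 1)
  k <- length(template$mz)
  pos <- template$mz + stats::rnorm(k, 0, nm$jitter_sd)
  mult <- if (template$cv > 0) {
    stats::rlnorm(k, -template$cv^2 / 2, template$cv)
  } else rep(1, k)
  height <- template$intensity * mult
  y <- numeric(length(grid))
  y <- add_gaussians(y, grid, pos, height, template$width)
  y <- y + nm$baseline_amplitude * exp(-(grid - win[1]) / nm$baseline_scale)
  y <- y + stats::rnorm(length(grid), 0, nm$additive_sd)
  s <- profile_spectrum(grid, y, sample_id = template$strain_id,
                        replicate_index = replicate_index,
                        mass_window = win, warn_window = FALSE)
  attr(s, "truth") <- data.frame(mz = pos, intensity = height)
  s
}

#' Simulate technical replicates of one strain
#'
#' Independent noise per replicate, shared template -- the simulated analogue
#' of triplicate deposits of one protein extract.
#'
#' @param template A [make_template()] result.
#' @param nm A [noise_model()].
#' @param n Number of replicates (>= 2, default 3).
#' @return A list of [profile_spectrum()]s with `truth` attributes.
#' @export
simulate_replicates <- function(template, nm = noise_model(), n = 3L) {
  if (n < 2L) stop("need n >= 2 replicates", call. = FALSE)
  lapply(seq_len(n), function(i) simulate_spectrum(template, nm, i))
}

#' Define a mixture of strain templates
#'
#' @param templates List of [make_template()] results.
#' @param proportions Mixing proportions (sum to 1); default equal.
#' @param suppression Per-strain ion-suppression factors in `[0, 1]`
#'   (1 = no suppression); default 1.
#' @param injected Optional data.frame `(mz, intensity)` of mixture-specific
#'   peaks to add verbatim.
#' @param mixture_id Identifier.
#' @return A `mixture_design` list.
#' @export
mixture_design <- function(templates, proportions = NULL, suppression = NULL,
                           injected = NULL, mixture_id = "mixture") {
  k <- length(templates)
  if (k < 1L) stop("need >= 1 template", call. = FALSE)
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  if (is.null(suppression)) suppression <- rep(1, k)
  if (any(suppression < 0 | suppression > 1)) {
    stop("suppression factors must be in [0, 1]", call. = FALSE)
  }
  structure(list(templates = templates, proportions = proportions,
                 suppression = suppression, injected = injected,
                 mixture_id = mixture_id),
            class = "mixture_design")
}

#' Simulate a mixed-culture spectrum
#'
#' Strain `k` contributes `proportion_k * suppression_k` times its template
#' intensities; injected novel peaks are added verbatim. The attached
#' `truth` attribute carries the expected peak classification: `M` for
#' constituent peaks whose scaled height stays detectable
#' (>= `detect_floor`), `P` for constituent peaks suppressed below it, `S`
#' for injected peaks.
#'
#' @param md A [mixture_design()].
#' @param nm A [noise_model()].
#' @param replicate_index Replicate number.
#' @param seed Seed (default derived from `nm$seed` and `replicate_index`).
#' @param detect_floor Height below which a contributed peak is expected to
#'   vanish from consensus peak lists (default `5 * nm$additive_sd`).
#' @return A [profile_spectrum()] with attribute `truth`
#'   (list `M`, `P`, `S` of expected m/z values).
#' @export
simulate_mixture <- function(md, nm = noise_model(), replicate_index = 1L,
                             seed = NULL, detect_floor = NULL) {
  stopifnot(inherits(md, "mixture_design"), inherits(nm, "noise_model"))
  if (is.null(seed)) {
    seed <- (nm$seed * 1000 + 500 + replicate_index) %% .Machine$integer.max
  }
  if (is.null(detect_floor)) detect_floor <- 5 * nm$additive_sd
  set.seed(seed)
  win <- md$templates[[1]]$mass_window
  grid <- seq(win[1], win[2], by = 1)
  y <- numeric(length(grid))
  expected_M <- expected_P <- numeric(0)
  for (k in seq_along(md$templates)) {
    tpl <- md$templates[[k]]
    scale <- md$proportions[k] * md$suppression[k]
    kk <- length(tpl$mz)
    pos <- tpl$mz + stats::rnorm(kk, 0, nm$jitter_sd)
    mult <- if (tpl$cv > 0) stats::rlnorm(kk, -tpl$cv^2 / 2, tpl$cv)
            else rep(1, kk)
    height <- scale * tpl$intensity * mult
    if (scale > 0) y <- add_gaussians(y, grid, pos, height, tpl$width)
    detectable <- scale * tpl$intensity >= detect_floor
    expected_M <- c(expected_M, tpl$mz[detectable])
    expected_P <- c(expected_P, tpl$mz[!detectable])
  }
  expected_S <- numeric(0)
  if (!is.null(md$injected) && nrow(md$injected)) {
    y <- add_gaussians(y, grid, md$injected$mz, md$injected$intensity,
                       md$templates[[1]]$width)
    expected_S <- md$injected$mz
  }
  y <- y + nm$baseline_amplitude * exp(-(grid - win[1]) / nm$baseline_scale)
  y <- y + stats::rnorm(length(grid), 0, nm$additive_sd)
  s <- profile_spectrum(grid, y, sample_id = md$mixture_id,
                        replicate_index = replicate_index,
                        mass_window = win, warn_window = FALSE)
  attr(s, "truth") <- list(M = sort(expected_M), P = sort(expected_P),
                           S = sort(expected_S))
  s
}

#' @rdname simulate_mixture
#' @param n Number of replicates.
#' @export
simulate_mixture_replicates <- function(md, nm = noise_model(), n = 3L) {
  if (n < 2L) stop("need n >= 2 replicates", call. = FALSE)
  lapply(seq_len(n), function(i) simulate_mixture(md, nm, i))
}

#' Pick m/z positions clear of every template peak
#'
#' Used to place injected mixture-specific peaks: a mixture-specific peak is
#' by definition novel, so its position must not coincide (within the
#' matching tolerance plus peak width) with any constituent peak.
#'
#' @param templates List of [make_template()] results.
#' @param n Number of positions.
#' @param clearance Minimum distance (Da) to any template peak and between
#'   picked positions (default 12: twice the matching tolerance plus a peak
#'   width, rounded up).
#' @param seed Integer seed.
#' @return Sorted numeric vector of length `n`.
#' @export
pick_clear_positions <- function(templates, n, clearance = 12, seed = 1L) {
  set.seed(seed)
  win <- templates[[1]]$mass_window
  occupied <- sort(unlist(lapply(templates, `[[`, "mz")))
  picked <- numeric(0)
  for (try in seq_len(10000)) {
    cand <- stats::runif(1, win[1] + 100, win[2] - 100)
    if (all(abs(cand - c(occupied, picked)) >= clearance)) {
      picked <- c(picked, cand)
      if (length(picked) == n) return(sort(picked))
    }
  }
  stop("could not place clear positions", call. = FALSE)
}

TRANSITION_MAP <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSION_MAP <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Mutate a sequence with exact event counts
#'
#' Produces an aligned pair (original, mutated) with exactly the requested
#' numbers of transitions, transversions and one-sided gap columns, at
#' distinct positions.
#'
#' @param seq A nucleotide string over `A,C,G,T`.
#' @param n_transitions,n_transversions,n_gaps Event counts.
#' @param seed Integer seed.
#' @return A list `(a, b)` of equal-length aligned sequences.
#' @export
mutate_sequence <- function(seq, n_transitions = 0L, n_transversions = 0L,
                            n_gaps = 0L, seed = 1L) {
  set.seed(seed)
  x <- strsplit(toupper(seq), "")[[1]]
  if (any(!x %in% c("A", "C", "G", "T"))) {
    stop("seq must be over A,C,G,T", call. = FALSE)
  }
  total <- n_transitions + n_transversions + n_gaps
  if (total > length(x)) stop("event counts exceed sequence length",
                              call. = FALSE)
  pos <- sample(length(x), total)
  b <- x
  i <- 0L
  for (p in pos[seq_len(n_transitions)]) b[p] <- TRANSITION_MAP[[x[p]]]
  i <- n_transitions
  for (p in pos[i + seq_len(n_transversions)]) {
    b[p] <- sample(TRANSVERSION_MAP[[x[p]]], 1L)
  }
  i <- i + n_transversions
  for (p in pos[i + seq_len(n_gaps)]) b[p] <- "-"
  list(a = paste(x, collapse = ""), b = paste(b, collapse = ""))
}

#' Random nucleotide sequence
#' @param length Sequence length.
#' @param seed Integer seed.
#' @return A character string over `A,C,G,T`.
#' @export
random_sequence <- function(length, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}
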