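#' Quality-gate parameters for shot bursts
#'
#' Defaults mirror routine linear-mode acquisition settings: base-peak
#' signal-to-noise >= 2, base-peak intensity >= 100 a.u., base-peak width
#' 10 m/z, at most 500 peaks per spectrum. All thresholds are applied
#' inclusively.
#'
#' @param snr_min Minimum base-peak S:N (dimensionless).
#' @param peak_width Base-peak full width at half maximum bound (Da). Read as
#'   a maximum by default; set `width_is_max = FALSE` to read it as a minimum.
#' @param intensity_min Minimum base-peak intensity (a.u.).
#' @param max_peaks Maximum number of peaks.
#' @param width_is_max Interpret `peak_width` as a maximum (default) or
#'   minimum.
#' @return A `quality_params` list.
#' @export
quality_params <- function(snr_min = 2, peak_width = 10, intensity_min = 100,
                           max_peaks = 500, width_is_max = TRUE) {
  vals <- c(snr_min = snr_min, peak_width = peak_width,
            intensity_min = intensity_min, max_peaks = max_peaks)
  if (any(vals <= 0)) stop("quality parameters must be strictly positive",
                           call. = FALSE)
  structure(list(snr_min = snr_min, peak_width = peak_width,
                 intensity_min = intensity_min,
                 max_peaks = as.integer(max_peaks),
                 width_is_max = isTRUE(width_is_max)),
            class = "quality_params")
}

#' Default protein calibrant set
#'
#' The six-protein external calibrant mixture spanning the acquisition window:
#' ACTH fragments, oxidized insulin B chain, insulin, cytochrome c and
#' apomyoglobin.
#'
#' @return A data.frame with columns `name` and `reference_mass` (Da),
#'   strictly increasing in mass.
#' @export
default_calibrants <- function() {
  data.frame(
    name = c("ACTH 1-17", "ACTH 18-39", "Insulin Oxidized B", "Insulin",
             "Cytochrome C", "Apomyoglobin"),
    reference_mass = c(2093.46, 2464.19, 3494.65, 5730.61, 12362.00, 16952.30),
    stringsAsFactors = FALSE)
}

check_calibrants <- function(refs) {
  if (!is.data.frame(refs) || !all(c("name", "reference_mass") %in% names(refs)))
    stop("calibrant set needs columns name, reference_mass", call. = FALSE)
  if (nrow(refs) < 2L) stop("need >= 2 calibrants", call. = FALSE)
  if (is.unsorted(refs$reference_mass, strictly = TRUE))
    stop("calibrant reference masses must be strictly increasing",
         call. = FALSE)
  refs
}

# Savitzky-Golay convolution coefficients for the central point of a window:
# first row of (A'A)^{-1} A' with A[i, j] = i^j over offsets -h..h.
sg_coefficients <- function(window_points, poly_order) {
  h <- (window_points - 1L) / 2L
  A <- outer(seq(-h, h), 0:poly_order, `^`)
  solve(crossprod(A), t(A))[1L, ]
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing on the spectrum's point grid.
#' Edge points are handled by fitting the stated polynomial to the terminal
#' window and evaluating it at the edge positions (so polynomials of degree
#' <= `poly_order` pass through unchanged everywhere, edges included).
#'
#' @param s A [profile_spectrum()].
#' @param window_points Odd window length in points (> `poly_order`).
#' @param poly_order Polynomial order.
#' @return The smoothed [profile_spectrum()] on the same m/z grid.
#' @export
smooth_savitzky_golay <- function(s, window_points = 7L, poly_order = 3L) {
  stopifnot(inherits(s, "profile_spectrum"))
  window_points <- as.integer(window_points)
  if (window_points %% 2L == 0L) stop("window_points must be odd",
                                      call. = FALSE)
  if (window_points <= poly_order) {
    stop("window_points must exceed poly_order", call. = FALSE)
  }
  n <- length(s$mz)
  if (n < window_points) {
    stop("spectrum shorter than smoothing window", call. = FALSE)
  }
  w <- sg_coefficients(window_points, poly_order)
  y <- s$intensity
  sm <- stats::filter(y, w, sides = 2)
  # polynomial extrapolation of terminal windows
  h <- (window_points - 1L) / 2L
  idx <- seq_len(window_points)
  fit_head <- stats::lm.fit(outer(idx, 0:poly_order, `^`), y[idx])$coefficients
  fit_tail <- stats::lm.fit(outer(idx, 0:poly_order, `^`),
                            y[n - window_points + idx])$coefficients
  sm[seq_len(h)] <- outer(seq_len(h), 0:poly_order, `^`) %*% fit_head
  sm[(n - h + 1L):n] <- outer(window_points - h + seq_len(h), 0:poly_order,
                              `^`) %*% fit_tail
  set_intensity(s, as.numeric(sm))
}

roll_min <- function(x, half) .Call(C_roll_min, as.numeric(x),
                                    as.integer(half))
roll_max <- function(x, half) .Call(C_roll_max, as.numeric(x),
                                    as.integer(half))

#' TopHat baseline subtraction
#'
#' Subtracts the morphological opening (erosion then dilation with a flat
#' structuring element of `element_width` Da) from the intensity trace. The
#' opening is the tightest "under-curve" that fits below the signal at the
#' chosen scale; subtracting it removes slowly varying baseline while
#' preserving peaks narrower than the element. Output intensities are >= 0 by
#' construction, and the operation is idempotent.
#'
#' @param s A [profile_spectrum()].
#' @param element_width Structuring element width in Da (must exceed the
#'   typical peak width).
#' @return Baseline-subtracted [profile_spectrum()].
#' @export
subtract_baseline_tophat <- function(s, element_width = 150) {
  stopifnot(inherits(s, "profile_spectrum"))
  if (element_width <= 0) stop("element_width must be > 0", call. = FALSE)
  n <- length(s$mz)
  if (n == 0L) return(s)
  spacing <- if (n > 1L) stats::median(diff(s$mz)) else 1
  half <- max(1L, as.integer(round(element_width / (2 * spacing))))
  opened <- roll_max(roll_min(s$intensity, half), half)
  set_intensity(s, s$intensity - opened)
}

#' Robust global noise estimate
#'
#' Median absolute deviation of the (baseline-subtracted) intensities, scaled
#' by 1.4826 for consistency with a normal standard deviation. Robust to the
#' sparse tall peaks that sit on top of the noise floor.
#'
#' @param s A [profile_spectrum()].
#' @return Noise level (a.u.).
#' @export
estimate_noise <- function(s) {
  stopifnot(inherits(s, "profile_spectrum"))
  if (length(s$mz) == 0L) stop("empty spectrum", call. = FALSE)
  stats::mad(s$intensity, center = stats::median(s$intensity))
}

#' Calibrate the mass axis against reference masses
#'
#' Fits `reference_mass ~ poly(observed)` by least squares (linear or
#' quadratic) and applies the fitted correction to every m/z value. Affine
#' distortions are recovered exactly by the linear model, quadratic
#' distortions by the quadratic model.
#'
#' @param s A [profile_spectrum()].
#' @param observed Observed calibrant m/z values, paired in order with `refs`.
#' @param refs Calibrant set (see [default_calibrants()]).
#' @param model `"linear"` or `"quadratic"`.
#' @return The calibrated [profile_spectrum()], with attributes
#'   `max_residual` (Da) and `calibration_coefficients`.
#' @export
calibrate_mass_axis <- function(s, observed, refs = default_calibrants(),
                                model = c("linear", "quadratic")) {
  stopifnot(inherits(s, "profile_spectrum"))
  model <- match.arg(model)
  refs <- check_calibrants(refs)
  observed <- as.numeric(observed)
  if (length(observed) != nrow(refs)) {
    stop("observed must pair one value to each calibrant", call. = FALSE)
  }
  need <- if (model == "linear") 2L else 3L
  if (length(observed) < need) {
    stop(sprintf("%s calibration needs >= %d calibrants", model, need),
         call. = FALSE)
  }
  deg <- if (model == "linear") 1L else 2L
  X <- outer(observed, 0:deg, `^`)
  beta <- stats::lm.fit(X, refs$reference_mass)$coefficients
  resid <- refs$reference_mass - as.numeric(X %*% beta)
  corrected <- as.numeric(outer(s$mz, 0:deg, `^`) %*% beta)
  if (is.unsorted(corrected, strictly = TRUE)) {
    stop("calibration produced a non-monotone mass axis", call. = FALSE)
  }
  s$mz <- corrected
  attr(s, "max_residual") <- max(abs(resid))
  attr(s, "calibration_coefficients") <- unname(beta)
  s
}

#' Accept or reject a shot burst from its peak list
#'
#' A burst is accepted iff its base peak (the most intense peak) has S:N
#' `>= snr_min`, intensity `>= intensity_min`, width within the `peak_width`
#' bound, and the burst has at most `max_peaks` peaks. Criteria are checked in
#' that order and the first failure is reported.
#'
#' @param peaks [peak_table()] rows for one burst.
#' @param q A [quality_params()].
#' @return A list `(accept: logical, reason: character)`; `reason` is `NA`
#'   on acceptance, else one of `"no peaks"`, `"snr"`, `"intensity"`,
#'   `"width"`, `"max_peaks"`.
#' @export
burst_quality_gate <- function(peaks, q = quality_params()) {
  stopifnot(inherits(q, "quality_params"))
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(list(accept = FALSE, reason = "no peaks"))
  }
  base <- peaks[which.max(peaks$intensity), , drop = FALSE]
  if (!is.na(base$snr) && base$snr < q$snr_min) {
    return(list(accept = FALSE, reason = "snr"))
  }
  if (!is.na(base$intensity) && base$intensity < q$intensity_min) {
    return(list(accept = FALSE, reason = "intensity"))
  }
  width_ok <- is.na(base$width) ||
    (if (q$width_is_max) base$width <= q$peak_width
     else base$width >= q$peak_width)
  if (!width_ok) return(list(accept = FALSE, reason = "width"))
  if (nrow(peaks) > q$max_peaks) {
    return(list(accept = FALSE, reason = "max_peaks"))
  }
  list(accept = TRUE, reason = NA_character_)
}

#' Run the default preprocessing chain on one spectrum
#'
#' Savitzky-Golay smoothing followed by TopHat baseline subtraction, with the
#' package defaults. Mass calibration is separate ([calibrate_mass_axis()])
#' because it needs observed calibrant positions.
#'
#' @param s A [profile_spectrum()].
#' @param window_points,poly_order Smoothing parameters.
#' @param element_width Baseline structuring-element width (Da).
#' @return Preprocessed [profile_spectrum()].
#' @export
preprocess_spectrum <- function(s, window_points = 7L, poly_order = 3L,
                                element_width = 150) {
  subtract_baseline_tophat(
    smooth_savitzky_golay(s, window_points, poly_order),
    element_width)
}
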