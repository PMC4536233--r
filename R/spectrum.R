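#' Construct a profile mass spectrum
#'
#' A `profile_spectrum` is the unit every preprocessing step transforms: a
#' continuous m/z--intensity trace from one MALDI deposit, windowed to the
#' acquisition mass range (default m/z 2,000--20,000 for linear-mode protein
#' profiles).
#'
#' Points outside `mass_window` are dropped (with a warning when `warn_window`
#' is `TRUE`); duplicate m/z values are merged by summing their intensities so
#' total ion signal is preserved.
#'
#' @param mz Numeric vector of mass-to-charge values (Da).
#' @param intensity Numeric vector of non-negative-or-finite abundances
#'   (arbitrary units), same length as `mz`.
#' @param sample_id Sample identifier.
#' @param replicate_index Integer replicate number (>= 1).
#' @param burst_index Optional integer shot-burst number.
#' @param mass_window Length-2 numeric `(lo, hi)` in Da.
#' @param warn_window Warn when points fall outside `mass_window`.
#' @return An object of class `profile_spectrum` with elements `mz`,
#'   `intensity`, `sample_id`, `replicate_index`, `burst_index`, `mass_window`.
#' @export
profile_spectrum <- function(mz, intensity, sample_id = "sample",
                             replicate_index = 1L, burst_index = NULL,
                             mass_window = c(2000, 20000),
                             warn_window = TRUE) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (anyNA(mz) || any(!is.finite(intensity))) {
    stop("mz and intensity must be finite", call. = FALSE)
  }
  if (length(mass_window) != 2L || mass_window[1] >= mass_window[2]) {
    stop("mass_window must be an increasing (lo, hi) pair", call. = FALSE)
  }
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  keep <- mz >= mass_window[1] & mz <= mass_window[2]
  if (any(!keep)) {
    if (warn_window) {
      warning(sprintf("%d point(s) outside mass window [%g, %g] dropped",
                      sum(!keep), mass_window[1], mass_window[2]),
              call. = FALSE)
    }
    mz <- mz[keep]
    intensity <- intensity[keep]
  }
  if (anyDuplicated(mz)) {
    # merge coincident points by intensity sum
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    stop("mz axis is not strictly increasing and cannot be repaired",
         call. = FALSE)
  }
  structure(
    list(mz = mz, intensity = intensity, sample_id = as.character(sample_id),
         replicate_index = as.integer(replicate_index),
         burst_index = if (is.null(burst_index)) NULL else
           as.integer(burst_index),
         mass_window = as.numeric(mass_window)),
    class = "profile_spectrum")
}

#' @export
print.profile_spectrum <- function(x, ...) {
  cat(sprintf(
    "<profile_spectrum> %s (replicate %d): %d points, m/z %.1f-%.1f\n",
    x$sample_id, x$replicate_index, length(x$mz),
    if (length(x$mz)) min(x$mz) else NA, if (length(x$mz)) max(x$mz) else NA))
  invisible(x)
}

#' @export
length.profile_spectrum <- function(x) length(x$mz)

# internal: replace intensities, keep everything else
set_intensity <- function(s, intensity) {
  s$intensity <- as.numeric(intensity)
  s
}

#' Construct a peak table
#'
#' The standardized peak-list representation: one row per centroided peak with
#' its signal-to-noise ratio and full width at half maximum.
#'
#' @param sample_id Character vector of sample ids (recycled if length 1).
#' @param mz Peak centroid m/z (Da).
#' @param intensity Peak height (a.u.).
#' @param snr Signal-to-noise ratio (dimensionless, >= 0).
#' @param width Full width at half maximum (Da).
#' @return A `data.frame` with class `peak_table`, columns
#'   `sample_id, mz, intensity, snr, width`, sorted by `sample_id` then `mz`.
#' @export
peak_table <- function(sample_id, mz, intensity = NA_real_, snr = NA_real_,
                       width = NA_real_) {
  n <- length(mz)
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    mz = as.numeric(mz),
    intensity = rep_len(as.numeric(intensity), n),
    snr = rep_len(as.numeric(snr), n),
    width = rep_len(as.numeric(width), n),
    stringsAsFactors = FALSE)
  if (any(!is.na(df$snr) & df$snr < 0)) {
    stop("snr must be >= 0", call. = FALSE)
  }
  df <- df[order(df$sample_id, df$mz), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_table", "data.frame")
  df
}
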