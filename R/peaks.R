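#' Detect peaks in a preprocessed profile spectrum
#'
#' Local-maximum centroiding with a signal-to-noise threshold. A candidate is
#' any point strictly greater than its neighbours (plateaus take the leftmost
#' point); it is kept if `height / noise >= snr_min`. The reported m/z is the
#' intensity-weighted centroid over the contiguous points at or above half the
#' peak height, and `width` is the interpolated full width at half maximum.
#'
#' @param s A preprocessed (smoothed, baseline-subtracted)
#'   [profile_spectrum()].
#' @param snr_min Minimum S:N for a peak (default 2).
#' @param noise Optional noise level; computed by [estimate_noise()] when
#'   `NULL`. When the noise is exactly zero (noise-free synthetic input) every
#'   positive local maximum is reported with infinite S:N.
#' @param edge_points Maxima whose apex lies within this many points of
#'   either spectrum end are discarded: smoothing fills the terminal windows
#'   by polynomial extrapolation, so apexes there are not measurements.
#' @return A [peak_table()] (possibly zero rows), sorted by m/z.
#' @export
detect_peaks <- function(s, snr_min = 2, noise = NULL, edge_points = 10L) {
  stopifnot(inherits(s, "profile_spectrum"))
  y <- s$intensity
  n <- length(y)
  if (n < 3L) return(peak_table(character(0), numeric(0)))
  if (is.null(noise)) noise <- estimate_noise(s)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  cand <- which(y > left & y >= right & y > 0)
  if (n > 2L * edge_points) {
    cand <- cand[cand > edge_points & cand <= n - edge_points]
  }
  if (!length(cand)) return(peak_table(character(0), numeric(0)))
  snr <- if (noise > 0) y[cand] / noise else Inf
  keep <- snr >= snr_min
  cand <- cand[keep]
  snr <- snr[keep]
  if (!length(cand)) return(peak_table(character(0), numeric(0)))

  mz <- s$mz
  cent <- wid <- numeric(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    half <- y[i] / 2
    lo <- i
    while (lo > 1L && y[lo - 1L] >= half && y[lo - 1L] <= y[lo]) lo <- lo - 1L
    hi <- i
    while (hi < n && y[hi + 1L] >= half && y[hi + 1L] <= y[hi]) hi <- hi + 1L
    seg <- lo:hi
    cent[k] <- sum(mz[seg] * y[seg]) / sum(y[seg])
    # FWHM: linear interpolation to the half-height crossings
    xl <- if (lo > 1L && y[lo - 1L] < half) {
      mz[lo - 1L] + (half - y[lo - 1L]) / (y[lo] - y[lo - 1L]) *
        (mz[lo] - mz[lo - 1L])
    } else mz[lo]
    xr <- if (hi < n && y[hi + 1L] < half) {
      mz[hi] + (y[hi] - half) / (y[hi] - y[hi + 1L]) * (mz[hi + 1L] - mz[hi])
    } else mz[hi]
    wid[k] <- xr - xl
  }
  peak_table(s$sample_id, cent, y[cand],
             if (noise > 0) snr else rep(Inf, length(cand)), wid)
}

#' Peak-matching tolerance
#'
#' Two peaks are the same feature iff their m/z values differ by at most
#' `tol` Da (the boundary is inclusive: a difference of exactly `tol` still
#' matches).
#'
#' @param tol Tolerance in Da (> 0), default 2.
#' @return A `match_tolerance` object.
#' @export
match_tolerance <- function(tol = 2) {
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  structure(list(tol = as.numeric(tol)), class = "match_tolerance")
}

as_tol <- function(t) {
  if (inherits(t, "match_tolerance")) t$tol else match_tolerance(t)$tol
}

#' Match two peak lists within a mass tolerance
#'
#' Greedy one-to-one matching: candidate pairs within tolerance are accepted
#' in order of ascending absolute m/z difference (ties broken by position in
#' `a`, then `b`), each peak used at most once.
#'
#' @param a,b Numeric m/z vectors (sorted ascending) or [peak_table()]s.
#' @param t A [match_tolerance()] or numeric tolerance in Da.
#' @return A list with `pairs` (two-column index matrix into `a` and `b`),
#'   `unmatched_a`, `unmatched_b` (index vectors).
#' @export
match_peaks <- function(a, b, t = match_tolerance()) {
  tol <- as_tol(t)
  ma <- if (is.data.frame(a)) a$mz else as.numeric(a)
  mb <- if (is.data.frame(b)) b$mz else as.numeric(b)
  if (is.unsorted(ma) || is.unsorted(mb)) {
    stop("peak lists must be sorted by mz", call. = FALSE)
  }
  if (!length(ma) || !length(mb)) {
    return(list(pairs = matrix(integer(0), ncol = 2,
                               dimnames = list(NULL, c("a", "b"))),
                unmatched_a = seq_along(ma), unmatched_b = seq_along(mb)))
  }
  d <- abs(outer(ma, mb, `-`))
  cand <- which(d <= tol, arr.ind = TRUE)
  ord <- order(d[cand], cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(length(ma))
  used_b <- logical(length(mb))
  pairs <- matrix(integer(0), ncol = 2)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- used_b[j] <- TRUE
      pairs <- rbind(pairs, c(i, j))
    }
  }
  colnames(pairs) <- c("a", "b")
  list(pairs = pairs, unmatched_a = which(!used_a),
       unmatched_b = which(!used_b))
}

#' All-replicate consensus peak list
#'
#' A peak enters the consensus only if it is present in every replicate.
#' Peaks of the first (anchor) replicate seed the groups; each further
#' replicate is matched one-to-one against the running mean position of each
#' group (candidates are captured within twice the tolerance of the running
#' mean), and a group is retained iff it has a member from every replicate
#' and every member lies within the tolerance of the final group mean -- the
#' consensus position. Consensus m/z and intensity are the means over the
#' group. The center-based acceptance makes group membership depend on the
#' distance to the consensus position rather than on worst-case pairwise
#' distances between replicates.
#'
#' @param replicates A list of [peak_table()]s (or m/z vectors), length >= 2,
#'   all from one sample.
#' @param t A [match_tolerance()] or numeric Da.
#' @param sample_id Consensus sample id (defaults to the anchor's).
#' @return A `consensus_peaks` data.frame with columns `mz`, `intensity`,
#'   `support` (`support == length(replicates)` for every row).
#' @export
consensus_peaks <- function(replicates, t = match_tolerance(),
                            sample_id = NULL) {
  if (length(replicates) < 2L) stop("need >= 2 replicates", call. = FALSE)
  tabs <- lapply(replicates, function(r) {
    if (is.data.frame(r)) r else peak_table("r", r, intensity = NA_real_)
  })
  if (is.null(sample_id)) {
    sample_id <- if (nrow(tabs[[1]])) tabs[[1]]$sample_id[1] else "consensus"
  }
  anchor <- tabs[[1]]
  n_rep <- length(tabs)
  empty <- data.frame(mz = numeric(0), intensity = numeric(0),
                      snr = numeric(0), support = integer(0))
  if (nrow(anchor) == 0L) {
    return(structure(empty, sample_id = sample_id,
                     class = c("consensus_peaks", "data.frame")))
  }
  mz_mat <- matrix(NA_real_, nrow(anchor), n_rep)
  it_mat <- matrix(NA_real_, nrow(anchor), n_rep)
  sn_mat <- matrix(NA_real_, nrow(anchor), n_rep)
  mz_mat[, 1L] <- anchor$mz
  it_mat[, 1L] <- anchor$intensity
  sn_mat[, 1L] <- if ("snr" %in% names(anchor)) anchor$snr else NA_real_
  tol <- as_tol(t)
  for (j in seq_len(n_rep)[-1L]) {
    # mean-position refinement: match replicate j against the running mean
    # of the positions matched so far (capture window 2 * tol; the final
    # center test below enforces the tolerance proper)
    ref <- rowMeans(mz_mat, na.rm = TRUE)
    o <- order(ref)
    m <- match_peaks(ref[o], tabs[[j]], 2 * tol)
    if (nrow(m$pairs)) {
      rows <- o[m$pairs[, "a"]]
      mz_mat[rows, j] <- tabs[[j]]$mz[m$pairs[, "b"]]
      it_mat[rows, j] <- tabs[[j]]$intensity[m$pairs[, "b"]]
      if ("snr" %in% names(tabs[[j]])) {
        sn_mat[rows, j] <- tabs[[j]]$snr[m$pairs[, "b"]]
      }
    }
  }
  center <- rowMeans(mz_mat)   # NA when any replicate missing
  keep <- !is.na(center) &
    apply(abs(mz_mat - center) <= tol, 1L, all)
  out <- data.frame(mz = rowMeans(mz_mat[keep, , drop = FALSE]),
                    intensity = rowMeans(it_mat[keep, , drop = FALSE]),
                    snr = rowMeans(sn_mat[keep, , drop = FALSE]),
                    support = rep(n_rep, sum(keep)))
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, sample_id = sample_id,
            class = c("consensus_peaks", "data.frame"))
}

#' Composite (summary) spectrum from replicates
#'
#' A replicate is included iff its mean Pearson similarity to the other
#' replicates, computed on profiles resampled to a common grid, is at least
#' `threshold` (inclusive, default 0.65). The composite is the point-wise mean
#' of the included replicates.
#'
#' @param replicates A list of [profile_spectrum()]s (>= 2) of one sample.
#' @param threshold Mean-similarity inclusion threshold in `[0, 1]`.
#' @param bin_width Grid bin width (Da) for the similarity computation.
#' @return A list of class `composite_spectrum`: `spectrum` (the composite
#'   [profile_spectrum()]), `included`, `excluded` (replicate indices),
#'   `similarity` (per-replicate mean similarity), `threshold`.
#' @export
composite_spectrum <- function(replicates, threshold = 0.65, bin_width = 3) {
  if (length(replicates) < 2L) stop("need >= 2 replicates", call. = FALSE)
  grids <- lapply(replicates, resample_to_grid, bin_width = bin_width)
  n <- length(grids)
  S <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    S[i, j] <- S[j, i] <- pearson(grids[[i]], grids[[j]])
  }
  mean_sim <- (rowSums(S) - 1) / (n - 1)
  inc <- which(mean_sim >= threshold)
  if (!length(inc)) stop("no replicate meets threshold", call. = FALSE)
  ref <- replicates[[inc[1]]]
  # composite on the raw point grid of the included replicates (equal grids
  # expected for replicates of one deposit series; otherwise resampled)
  same_grid <- all(vapply(replicates[inc], function(s)
    length(s$mz) == length(ref$mz) && all(s$mz == ref$mz), logical(1)))
  comp <- if (same_grid) {
    set_intensity(ref, rowMeans(vapply(replicates[inc],
                                       function(s) s$intensity,
                                       numeric(length(ref$mz)))))
  } else {
    g <- rowMeans(vapply(grids[inc], identity,
                         numeric(length(grids[[1]]))))
    lo <- ref$mass_window[1]
    profile_spectrum(lo + (seq_along(g) - 0.5) * bin_width, g,
                     sample_id = ref$sample_id, mass_window = ref$mass_window)
  }
  comp$replicate_index <- 0L
  structure(list(spectrum = comp, included = inc,
                 excluded = setdiff(seq_len(n), inc),
                 similarity = mean_sim, threshold = threshold),
            class = "composite_spectrum")
}

#' Filter a peak list to its prominent peaks
#'
#' Keeps peaks whose S:N is at least `snr_min`. Mixture characterization
#' compares prominent peaks only; at the default peak-picking threshold
#' (S:N >= 2) a peak list still carries noise-level features that are real
#' local maxima but not reportable fingerprint peaks. Rows without an S:N
#' value (e.g. externally supplied tables) are kept.
#'
#' @param p A [peak_table()] or `consensus_peaks`.
#' @param snr_min Prominence threshold (default 5).
#' @return The filtered object, same class.
#' @export
prominent_peaks <- function(p, snr_min = 5) {
  if (!"snr" %in% names(p)) return(p)
  p[is.na(p$snr) | p$snr >= snr_min, , drop = FALSE]
}

#' Summary statistics of a peak list
#'
#' @param p A [peak_table()] or `consensus_peaks` with >= 1 row.
#' @return A list `(mass_range = c(min, max), n_peaks, base_peak)`; the base
#'   peak is the m/z of the most intense peak, ties broken to the lower m/z.
#' @export
spectrum_stats <- function(p) {
  if (is.null(p) || nrow(p) == 0L) stop("empty peak list", call. = FALSE)
  o <- order(-p$intensity, p$mz)
  list(mass_range = c(min(p$mz), max(p$mz)),
       n_peaks = nrow(p),
       base_peak = p$mz[o[1]])
}
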