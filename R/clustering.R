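#' Resample a profile spectrum onto a fixed grid
#'
#' Bins the trace over the spectrum's mass window: bin `k` covers
#' `[lo + (k-1) w, lo + k w)` and takes the mean intensity of the points that
#' fall in it; empty bins are 0. All spectra with the same mass window and
#' bin width land on identical grids, which is what curve-based Pearson
#' similarity needs.
#'
#' @param s A [profile_spectrum()].
#' @param bin_width Bin width in Da (> 0, < window span).
#' @return Numeric vector of length `ceiling((hi - lo) / bin_width)`.
#' @export
resample_to_grid <- function(s, bin_width = 3) {
  stopifnot(inherits(s, "profile_spectrum"))
  lo <- s$mass_window[1]; hi <- s$mass_window[2]
  if (bin_width <= 0 || bin_width >= hi - lo) {
    stop("bin_width must be in (0, window span)", call. = FALSE)
  }
  nbin <- ceiling((hi - lo) / bin_width)
  idx <- pmin(nbin, floor((s$mz - lo) / bin_width) + 1L)
  out <- numeric(nbin)
  if (length(idx)) {
    sums <- tapply(s$intensity, idx, mean)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out
}

#' Pearson product-moment correlation between two fingerprints
#'
#' @param x,y Equal-length numeric vectors (length >= 3), neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3L) stop("need length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Pairwise Pearson similarity matrix
#'
#' @param fingerprints List of equal-length numeric vectors.
#' @param labels Sample labels (defaults to list names or `F1..Fn`).
#' @return A `similarity_matrix`: list with `labels` and symmetric matrix `S`
#'   (`diag == 1`).
#' @export
similarity_matrix <- function(fingerprints, labels = NULL) {
  n <- length(fingerprints)
  if (n < 2L) stop("need >= 2 fingerprints", call. = FALSE)
  lens <- lengths(fingerprints)
  if (length(unique(lens)) != 1L) stop("fingerprints on unequal grids",
                                       call. = FALSE)
  if (is.null(labels)) {
    labels <- names(fingerprints)
    if (is.null(labels)) labels <- paste0("F", seq_len(n))
  }
  S <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    S[i, j] <- S[j, i] <- pearson(fingerprints[[i]], fingerprints[[j]])
  }
  dimnames(S) <- list(labels, labels)
  structure(list(labels = as.character(labels), S = S),
            class = "similarity_matrix")
}

as_similarity_S <- function(S) {
  if (inherits(S, "similarity_matrix")) return(S$S)
  S <- as.matrix(S)
  if (is.null(rownames(S))) {
    dimnames(S) <- list(paste0("F", seq_len(nrow(S))),
                        paste0("F", seq_len(nrow(S))))
  }
  S
}

#' UPGMA dendrogram from a similarity matrix
#'
#' Average-linkage agglomeration on the distance `d = 1 - S`. The merge
#' height recorded for each agglomeration is half the average inter-cluster
#' distance (the classical ultrametric convention, so the cophenetic distance
#' between two leaves is twice the height of their last common merge). Ties
#' are broken deterministically toward the pair containing the lowest
#' original label index.
#'
#' @param S A [similarity_matrix()] or a square similarity matrix.
#' @return An object of classes `upgma_dendrogram` and `hclust` (so
#'   [stats::cophenetic()] and plotting work), with `$height` in halved
#'   distance units.
#' @export
upgma <- function(S) {
  S <- as_similarity_S(S)
  n <- nrow(S)
  if (n < 2L) stop("need >= 2 samples", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-12) stop("similarity matrix not symmetric",
                                       call. = FALSE)
  labels <- rownames(S)
  D <- 1 - S
  diag(D) <- Inf
  size <- rep(1L, n)          # active cluster sizes
  id <- -seq_len(n)           # hclust ids: negative leaf, positive merge
  minleaf <- seq_len(n)       # lowest original label index per cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    dmin <- Inf; bi <- bj <- 0L
    for (a in seq_along(act)) for (b in seq_along(act)) {
      if (b <= a) next
      i <- act[a]; j <- act[b]
      dij <- D[i, j]
      if (dij < dmin - 1e-12) {
        dmin <- dij; bi <- i; bj <- j
      } else if (abs(dij - dmin) <= 1e-12) {
        # tie: prefer the pair with lowest (then second-lowest) leaf index
        cur <- sort(c(minleaf[bi], minleaf[bj]))
        new <- sort(c(minleaf[i], minleaf[j]))
        if (new[1] < cur[1] || (new[1] == cur[1] && new[2] < cur[2])) {
          bi <- i; bj <- j
        }
      }
    }
    merge[step, ] <- sort(c(id[bi], id[bj]))
    height[step] <- dmin / 2
    # Lance-Williams average-linkage update into slot bi
    for (k in which(active)) {
      if (k == bi || k == bj) next
      D[bi, k] <- D[k, bi] <-
        (size[bi] * D[bi, k] + size[bj] * D[bj, k]) / (size[bi] + size[bj])
    }
    size[bi] <- size[bi] + size[bj]
    minleaf[bi] <- min(minleaf[bi], minleaf[bj])
    id[bi] <- step
    active[bj] <- FALSE
  }
  order <- dend_leaf_order(merge, n)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "upgma (average)",
                 dist.method = "1 - Pearson"),
            class = c("upgma_dendrogram", "hclust"))
}

# leaf ordering for plotting: left-to-right recursion over the merge matrix
dend_leaf_order <- function(merge, n) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1L]), rec(merge[node, 2L]))
  }
  rec(nrow(merge))
}

#' Cophenetic distances of a UPGMA dendrogram (full-distance units)
#'
#' Returns twice the merge heights (so on an ultrametric input matrix the
#' result reproduces `1 - S` exactly).
#'
#' @param dend A [upgma()] result.
#' @return A `dist` object.
#' @export
cophenetic_distances <- function(dend) {
  stopifnot(inherits(dend, "upgma_dendrogram"))
  2 * stats::cophenetic(structure(unclass(dend), class = "hclust"))
}

#' Convert a UPGMA dendrogram to an `ape::phylo` tree
#' @param x A [upgma()] result.
#' @param ... Unused.
#' @return A rooted `phylo` object with the dendrogram's branch lengths.
#' @importFrom ape as.phylo
#' @export
as.phylo.upgma_dendrogram <- function(x, ...) {
  ape::as.phylo(structure(unclass(x), class = "hclust"))
}

#' Render fingerprints as a pseudo-gel image
#'
#' One horizontal lane per sample; band darkness is monotone in intensity
#' (each lane scaled to its own maximum), with the m/z axis annotated.
#' Output pixels are deterministic for fixed input.
#'
#' @param fingerprints List of equal-length grid vectors
#'   (see [resample_to_grid()]).
#' @param labels Lane labels.
#' @param out_path PNG output path.
#' @param mass_window Mass window used to annotate the x axis.
#' @return `out_path`, invisibly.
#' @export
pseudo_gel <- function(fingerprints, labels = NULL, out_path,
                       mass_window = c(2000, 20000)) {
  lens <- lengths(fingerprints)
  if (length(unique(lens)) != 1L) stop("fingerprints on unequal grids",
                                       call. = FALSE)
  n <- length(fingerprints)
  if (is.null(labels)) labels <- paste0("F", seq_len(n))
  M <- t(vapply(fingerprints, function(f) {
    m <- max(f)
    if (m > 0) f / m else f
  }, numeric(lens[1])))
  grDevices::png(out_path, width = 900, height = 80 + 40 * n, res = 96)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 8, 1, 1))
  graphics::image(
    x = seq(mass_window[1], mass_window[2], length.out = lens[1]),
    y = seq_len(n), z = t(M[rev(seq_len(n)), , drop = FALSE]),
    col = grDevices::gray(seq(1, 0, length.out = 256)),
    zlim = c(0, 1), xlab = "m/z", ylab = "", yaxt = "n", useRaster = TRUE)
  graphics::axis(2, at = seq_len(n), labels = rev(labels), las = 2,
                 cex.axis = 0.8)
  invisible(out_path)
}
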