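PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

split_seq <- function(s) {
  x <- strsplit(toupper(s), "")[[1]]
  x[x == "U"] <- "T"
  x
}

#' Count nucleotide substitutions between two aligned sequences
#'
#' Positions where either sequence has a gap (`-`) or `N` are excluded;
#' `U` is treated as `T`.
#'
#' @param a,b Aligned sequences (equal-length character strings).
#' @return Integer substitution count.
#' @export
pairwise_differences <- function(a, b) {
  x <- split_seq(a); y <- split_seq(b)
  if (length(x) != length(y)) stop("unequal sequence lengths", call. = FALSE)
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  sum(x[ok] != y[ok])
}

#' Kimura two-parameter distance with a gap penalty
#'
#' Over the comparable sites (both characters in `A,C,G,T,U`; `U` read as
#' `T`) the transition proportion `P` and transversion proportion `Q` give
#' the two-parameter distance
#' \deqn{d = -\tfrac{1}{2}\ln\big((1 - 2P - Q)\sqrt{1 - 2Q}\big).}
#' Alignment columns where exactly one sequence has a gap each add
#' `gap_penalty / L` to `d`, where `L` is the number of comparable sites --
#' this package's declared reading of a fractional "gap penalty" setting;
#' set `gap_penalty = 0` to disable.
#'
#' @param a,b Aligned sequences (equal-length strings).
#' @param gap_penalty Per-gap-column additive penalty weight (default 0.12).
#' @return Distance in substitutions per site, with attributes `P`, `Q`,
#'   `n_comparable`, `n_gap_columns`.
#' @export
kimura_distance <- function(a, b, gap_penalty = 0.12) {
  x <- split_seq(a); y <- split_seq(b)
  if (length(x) != length(y)) stop("unequal sequence lengths", call. = FALSE)
  nuc <- c("A", "C", "G", "T")
  ok <- x %in% nuc & y %in% nuc
  L <- sum(ok)
  if (L == 0L) stop("no comparable sites", call. = FALSE)
  xs <- x[ok]; ys <- y[ok]
  diff <- xs != ys
  transition <- diff & ((xs %in% PURINES & ys %in% PURINES) |
                          (xs %in% PYRIMIDINES & ys %in% PYRIMIDINES))
  P <- sum(transition) / L
  Q <- sum(diff & !transition) / L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("distance saturated", call. = FALSE)
  d <- -0.5 * log(w1 * sqrt(w2))
  n_gap <- sum(xor(x == "-", y == "-"))
  d <- d + gap_penalty * n_gap / L
  structure(d, P = P, Q = Q, n_comparable = L, n_gap_columns = n_gap)
}

#' Pairwise Kimura distance matrix of an alignment
#'
#' @param aln A [read_alignment()] result (named character vector).
#' @param gap_penalty Passed to [kimura_distance()].
#' @return A symmetric labelled matrix (zero diagonal).
#' @export
kimura_distance_matrix <- function(aln, gap_penalty = 0.12) {
  n <- length(aln)
  labels <- names(aln)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- as.numeric(
      kimura_distance(aln[[i]], aln[[j]], gap_penalty))
  }
  D
}

check_distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix not square", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix not symmetric",
                                      call. = FALSE)
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be 0",
                              call. = FALSE)
  if (any(!is.finite(D))) stop("non-finite distances", call. = FALSE)
  if (is.null(rownames(D))) {
    dimnames(D) <- list(paste0("t", seq_len(nrow(D))),
                        paste0("t", seq_len(nrow(D))))
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining: at each step the pair minimizing the
#' Q-criterion
#' \eqn{Q(i,j) = (r - 2) d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)}
#' is agglomerated with the standard branch-length formulas; ties break to
#' the pair with the lowest label order. The tree is left unrooted. Negative
#' branch-length estimates are clamped to 0 and flagged in the
#' `negative_branches` attribute.
#'
#' @param D Symmetric distance matrix with labels (n >= 3).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- check_distance_matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need >= 3 taxa", call. = FALSE)
  labels <- rownames(D)
  # nodes are newick fragments; distances over active nodes
  frag <- labels
  act <- seq_len(n)
  M <- D
  n_neg <- 0L
  clamp <- function(x) {
    if (x < 0) { n_neg <<- n_neg + 1L; 0 } else x
  }
  while (length(act) > 3L) {
    r <- length(act)
    sub <- M[act, act]
    rs <- rowSums(sub)
    Qc <- (r - 2) * sub - outer(rs, rs, `+`)
    diag(Qc) <- Inf
    # deterministic arg-min: first (row-major by label order) minimal pair
    qmin <- min(Qc)
    hit <- which(Qc - qmin <= 1e-12, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    ai <- act[i]; aj <- act[j]
    li0 <- sub[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    li <- clamp(li0)
    lj <- clamp(sub[i, j] - li0)
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[ai], li, frag[aj], lj)
    # distances from the new node u: d(u,k) = (d(i,k)+d(j,k)-d(i,j))/2
    dnew <- (M[ai, act] + M[aj, act] - M[ai, aj]) / 2
    M <- rbind(cbind(M, 0), 0)
    u <- nrow(M)
    M[u, act] <- dnew
    M[act, u] <- dnew
    M[u, u] <- 0
    frag <- c(frag, new_frag)
    act <- c(setdiff(act, c(ai, aj)), u)
  }
  a <- act[1]; b <- act[2]; c3 <- act[3]
  la <- clamp((M[a, b] + M[a, c3] - M[b, c3]) / 2)
  lb <- clamp((M[a, b] + M[b, c3] - M[a, c3]) / 2)
  lc <- clamp((M[a, c3] + M[b, c3] - M[a, b]) / 2)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[a], la, frag[b], lb, frag[c3], lc)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_branches") <- n_neg
  tree
}

#' Compare an MS dendrogram with a sequence tree
#'
#' Reports, for each labelled class, whether its members form a monophyletic
#' group in each tree; the number of classes monophyletic in the sequence
#' tree but not the MS tree; and the Robinson-Foulds distance between the
#' two (both treated as unrooted).
#'
#' @param ms_tree A [upgma()] dendrogram or `phylo` tree.
#' @param seq_tree A `phylo` tree (e.g. from [neighbor_joining()]).
#' @param strain_to_class Named character vector mapping every leaf label to
#'   a class.
#' @return A list: `per_class` data.frame
#'   (`class`, `monophyletic_ms`, `monophyletic_seq`),
#'   `n_seq_only_monophyletic`, `rf_distance`.
#' @export
compare_partitions <- function(ms_tree, seq_tree, strain_to_class) {
  if (inherits(ms_tree, "upgma_dendrogram")) ms_tree <- ape::as.phylo(ms_tree)
  stopifnot(inherits(ms_tree, "phylo"), inherits(seq_tree, "phylo"))
  if (!setequal(ms_tree$tip.label, seq_tree$tip.label)) {
    stop("leaf sets differ between trees", call. = FALSE)
  }
  if (!all(ms_tree$tip.label %in% names(strain_to_class))) {
    stop("strain_to_class must cover every leaf", call. = FALSE)
  }
  classes <- sort(unique(strain_to_class[ms_tree$tip.label]))
  mono <- function(tree, members) {
    if (length(members) <= 1L) return(TRUE)
    ape::is.monophyletic(tree, members)
  }
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    members <- names(strain_to_class)[strain_to_class == cl]
    members <- intersect(members, ms_tree$tip.label)
    data.frame(class = cl,
               monophyletic_ms = mono(ms_tree, members),
               monophyletic_seq = mono(seq_tree, members),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  rf <- phangorn::RF.dist(ape::unroot(ms_tree), ape::unroot(seq_tree))
  list(per_class = per_class,
       n_seq_only_monophyletic =
         sum(per_class$monophyletic_seq & !per_class$monophyletic_ms),
       rf_distance = as.numeric(rf))
}
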