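#' Classify peaks across constituent and mixture spectra
#'
#' Reproduces the bookkeeping used to characterize polyculture spectra: every
#' distinct peak across all consensus lists is labelled
#' \describe{
#'   \item{M}{constituent-derived peak observed in at least one mixture,}
#'   \item{P}{constituent-derived peak observed in no mixture (suppressed),}
#'   \item{S}{mixture-specific peak, matching no constituent peak.}
#' }
#' Distinct peaks are formed by single-linkage chaining at the matching
#' tolerance over the pooled sorted m/z values (two adjacent pooled peaks
#' join one cluster iff they are within `tol`); the reported m/z is the
#' cluster centroid.
#'
#' @param constituents Named list of constituent peak lists
#'   (`consensus_peaks`, [peak_table()]s, or m/z vectors); >= 1.
#' @param mixtures Named list of mixture peak lists; >= 1.
#' @param t A [match_tolerance()] or numeric Da.
#' @return A `mixture_peak_table` data.frame: `mz`, one logical presence
#'   column per constituent and mixture, `label` (`M`/`P`/`S`), and
#'   `provenance` (comma-separated constituent names for M/P rows).
#' @export
classify_mixture_peaks <- function(constituents, mixtures,
                                   t = match_tolerance()) {
  tol <- as_tol(t)
  if (!length(constituents)) stop("empty constituent set", call. = FALSE)
  if (!length(mixtures)) stop("empty mixture set", call. = FALSE)
  get_mz <- function(x) sort(if (is.data.frame(x)) x$mz else as.numeric(x))
  cn <- names(constituents)
  if (is.null(cn)) cn <- paste0("constituent", seq_along(constituents))
  mn <- names(mixtures)
  if (is.null(mn)) mn <- paste0("mixture", seq_along(mixtures))
  if (any(cn %in% mn)) stop("constituent and mixture names must differ",
                            call. = FALSE)
  lists <- c(lapply(constituents, get_mz), lapply(mixtures, get_mz))
  names(lists) <- c(cn, mn)
  pooled <- data.frame(
    mz = unlist(lists, use.names = FALSE),
    src = rep(names(lists), lengths(lists)), stringsAsFactors = FALSE)
  if (!nrow(pooled)) {
    stop("no peaks in any list", call. = FALSE)
  }
  pooled <- pooled[order(pooled$mz), , drop = FALSE]
  cluster <- cumsum(c(1, diff(pooled$mz) > tol))
  rows <- lapply(split(pooled, cluster), function(g) {
    present <- names(lists) %in% g$src
    names(present) <- names(lists)
    in_c <- any(present[cn]); in_m <- any(present[mn])
    data.frame(mz = mean(g$mz), t(present),
               label = if (in_c && in_m) "M" else if (in_c) "P" else "S",
               provenance = paste(cn[present[cn]], collapse = ","),
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "constituents") <- cn
  attr(out, "mixtures") <- mn
  attr(out, "tol") <- tol
  class(out) <- c("mixture_peak_table", "data.frame")
  out
}

#' Mixture-specific peaks
#'
#' @param table A [classify_mixture_peaks()] result.
#' @return Sorted m/z values of the S-labelled rows.
#' @export
mixture_specific_peaks <- function(table) {
  stopifnot(inherits(table, "mixture_peak_table"))
  sort(table$mz[table$label == "S"])
}

#' Per-constituent ion-suppression report
#'
#' For each constituent: how many of its peaks were observed in at least one
#' mixture (M) versus suppressed in all mixtures (P), and the suppressed
#' fraction.
#'
#' @param table A [classify_mixture_peaks()] result.
#' @return A data.frame with columns `constituent`, `n_observed`,
#'   `n_suppressed`, `suppressed_fraction`.
#' @export
suppression_report <- function(table) {
  stopifnot(inherits(table, "mixture_peak_table"))
  cn <- attr(table, "constituents")
  rows <- lapply(cn, function(k) {
    sub <- table[table[[k]], , drop = FALSE]
    n_obs <- sum(sub$label == "M")
    n_sup <- sum(sub$label == "P")
    data.frame(constituent = k, n_observed = n_obs, n_suppressed = n_sup,
               suppressed_fraction =
                 if (n_obs + n_sup > 0) n_sup / (n_obs + n_sup) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged polyculture example peak lists
#'
#' The published model-mixture experiment: consensus peak lists of three
#' individual microalgae (*C. vulgaris* UTEX 395, *S. acutus* LRB-AP 401,
#' *C. sorokiniana* UTEX 1230) and of two mixed cultures (UTEX 395 +
#' LRB-AP 401; all three), shipped as TSV peak tables under `extdata`.
#'
#' @return A list with `constituents` and `mixtures`, each a named list of
#'   [peak_table()]s.
#' @export
polyculture_example <- function() {
  path <- function(f) system.file("extdata", f, package = "phycoMS",
                                  mustWork = TRUE)
  cons_tab <- read_peak_table(path("polyculture_constituents.tsv"))
  constituents <- split(cons_tab, cons_tab$sample_id)
  mixtures <- list(
    mixture1 = read_peak_table(path("polyculture_mixture1.tsv")),
    mixture2 = read_peak_table(path("polyculture_mixture2.tsv")))
  list(constituents = constituents, mixtures = mixtures)
}

#' Write a mixture peak table as TSV
#'
#' Layout mirrors the published mixture table: m/z, then per-sample columns
#' holding `M`/`P`/`S` where the peak is present (empty otherwise), then the
#' overall label.
#'
#' @param table A [classify_mixture_peaks()] result.
#' @param path Output path.
#' @export
write_mixture_table <- function(table, path) {
  stopifnot(inherits(table, "mixture_peak_table"))
  cn <- attr(table, "constituents")
  mn <- attr(table, "mixtures")
  out <- data.frame(mz = round(table$mz, 2), stringsAsFactors = FALSE)
  for (k in cn) out[[k]] <- ifelse(table[[k]], table$label, "")
  for (k in mn) {
    out[[k]] <- ifelse(table[[k]],
                       ifelse(table$label == "S", "S", "M"), "")
  }
  out$label <- table$label
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
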