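#' Read profile spectra from a file
#'
#' Supports two on-disk representations: `"xy_text"` -- a two-column
#' (m/z, intensity) whitespace- or comma-separated text file holding one
#' spectrum -- and `"mzml"` -- an mzML document, one `profile_spectrum` per
#' `<spectrum>` element (64/32-bit float arrays, plain or zlib-compressed
#' base64).
#'
#' All spectra are windowed to `mass_window`; duplicate m/z points are merged
#' by intensity sum (see [profile_spectrum()]).
#'
#' @param path File path.
#' @param format `"xy_text"` or `"mzml"`.
#' @param sample_id Sample id assigned to the spectra (defaults to the file
#'   base name).
#' @param mass_window Mass window `(lo, hi)` in Da.
#' @return A list of [profile_spectrum()] objects.
#' @export
read_profile_spectra <- function(path, format = c("xy_text", "mzml"),
                                 sample_id = NULL,
                                 mass_window = c(2000, 20000)) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (format == "xy_text") {
    raw <- tryCatch(
      utils::read.table(path, header = FALSE,
                        sep = "", comment.char = "#",
                        colClasses = "character"),
      error = function(e) stop(sprintf("cannot parse '%s' as xy text: %s",
                                       path, conditionMessage(e)),
                               call. = FALSE))
    if (ncol(raw) == 1L) {           # maybe comma separated
      raw <- utils::read.table(path, header = FALSE, sep = ",",
                               comment.char = "#", colClasses = "character")
    }
    if (ncol(raw) < 2L) {
      stop("xy text file must have two columns (mz, intensity)",
           call. = FALSE)
    }
    mz <- suppressWarnings(as.numeric(raw[[1]]))
    it <- suppressWarnings(as.numeric(raw[[2]]))
    if (anyNA(mz) || anyNA(it)) {
      stop("non-numeric values in xy text file", call. = FALSE)
    }
    list(profile_spectrum(mz, it, sample_id = sample_id,
                          mass_window = mass_window))
  } else {
    read_mzml(path, sample_id = sample_id, mass_window = mass_window)
  }
}

#' Write a profile spectrum as two-column xy text
#'
#' @param s A [profile_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xy <- function(s, path) {
  stopifnot(inherits(s, "profile_spectrum"))
  utils::write.table(
    data.frame(mz = format(s$mz, digits = 15, trim = TRUE, scientific = FALSE),
               intensity = format(s$intensity, digits = 15, trim = TRUE,
                                  scientific = FALSE)),
    path, sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- minimal mzML ----------------------------------------------------------
# CV accessions used: MS:1000514 m/z array, MS:1000515 intensity array,
# MS:1000523 64-bit float, MS:1000521 32-bit float, MS:1000574 zlib,
# MS:1000576 no compression.

decode_binary <- function(b64, bits, zlib, n_expected) {
  raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", b64))
  if (zlib) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, what = "double", size = bits / 8L,
          n = n_expected, endian = "little")
}

read_mzml <- function(path, sample_id, mass_window) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf(
                    "cannot parse '%s' as mzML: %s", path,
                    conditionMessage(e)), call. = FALSE))
  xml2::xml_ns_strip(doc)
  specs <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (length(specs) == 0L) stop("mzML file contains no spectra", call. = FALSE)
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    npts <- as.integer(xml2::xml_attr(sp, "defaultArrayLength"))
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- it <- NULL
    for (arr in arrays) {
      acc <- xml2::xml_attr(xml2::xml_find_all(arr, ".//cvParam"), "accession")
      bits <- if ("MS:1000521" %in% acc) 32L else 64L
      zlib <- "MS:1000574" %in% acc
      vals <- decode_binary(xml2::xml_text(xml2::xml_find_first(arr,
                                                                ".//binary")),
                            bits, zlib, npts)
      if ("MS:1000514" %in% acc) mz <- vals
      if ("MS:1000515" %in% acc) it <- vals
    }
    if (is.null(mz) || is.null(it)) {
      stop("mzML spectrum lacks m/z or intensity array", call. = FALSE)
    }
    out[[i]] <- profile_spectrum(mz, it, sample_id = sample_id,
                                 replicate_index = i,
                                 mass_window = mass_window)
  }
  out
}

#' Write spectra to a minimal mzML document
#'
#' Emits an uncompressed 64-bit little-endian mzML file sufficient for
#' round-tripping through [read_profile_spectra()] and for consumption by
#' standard mzML readers. Not a full psi-ms implementation (no chromatograms,
#' no indexing).
#'
#' @param spectra A list of [profile_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  if (inherits(spectra, "profile_spectrum")) spectra <- list(spectra)
  enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8L,
                                                   endian = "little"))
  spec_xml <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    n <- length(s$mz)
    paste0(
      sprintf('<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
              i - 1L, i, n),
      '<cvParam cvRef="MS" accession="MS:1000128" name="profile spectrum"/>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray>',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
      "<binary>", enc(s$mz), "</binary></binaryDataArray>",
      '<binaryDataArray>',
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
      "<binary>", enc(s$intensity), "</binary></binaryDataArray>",
      "</binaryDataArrayList></spectrum>")
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="run1"><spectrumList count="', length(spectra), '">',
    paste0(spec_xml, collapse = ""),
    "</spectrumList></run></mzML>")
  writeLines(xml, path)
  invisible(path)
}

# ---- peak tables -----------------------------------------------------------

PEAK_TABLE_COLS <- c("sample_id", "mz", "intensity", "snr", "width")

#' Read or write a peak table as TSV
#'
#' The TSV has a fixed header `sample_id, mz, intensity, snr, width` so that
#' `read_peak_table(write_peak_table(t)) == t`.
#'
#' @param path File path.
#' @param table A [peak_table()] (write only).
#' @return `read_peak_table` returns a [peak_table()]; `write_peak_table`
#'   returns `path` invisibly.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(PEAK_TABLE_COLS, names(df))
  if (length(missing)) {
    stop(sprintf("missing column %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  peak_table(df$sample_id, df$mz, df$intensity, df$snr, df$width)
}

#' @rdname read_peak_table
#' @export
write_peak_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(PEAK_TABLE_COLS, names(table))
  if (length(missing)) {
    stop(sprintf("missing column %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  utils::write.table(table[, PEAK_TABLE_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- alignments and trees --------------------------------------------------

ALIGN_ALPHABET <- c("A", "C", "G", "T", "U", "N", "-")

#' Read an aligned FASTA file
#'
#' All sequences must have equal length (it is an alignment, not a sequence
#' set) and use the alphabet `A C G T U N -` (case-insensitive).
#'
#' @param path Aligned FASTA path.
#' @return A named character vector of upper-case aligned sequences, class
#'   `seq_alignment`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty alignment file", call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not a FASTA file (no leading '>')", call. = FALSE)
  idx <- cumsum(hdr)
  labels <- sub("^>\\s*", "", lines[hdr])
  labels <- sub("\\s.*$", "", labels)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(gsub("[[:space:]]", "", x),
                                           collapse = "")),
                 character(1))
  if (length(seqs) != length(labels)) {
    stop("FASTA record without sequence", call. = FALSE)
  }
  names(seqs) <- labels
  if (anyDuplicated(labels)) stop("duplicate sequence labels", call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("ragged alignment: sequence lengths %s",
                 paste(sort(unique(lens)), collapse = ", ")), call. = FALSE)
  }
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% ALIGN_ALPHABET)
  }, logical(1))
  if (any(bad)) {
    stop(sprintf("sequence '%s' contains characters outside A,C,G,T,U,N,-",
                 labels[which(bad)[1]]), call. = FALSE)
  }
  structure(seqs, class = "seq_alignment")
}

#' Write an alignment as FASTA
#' @param aln A `seq_alignment` (named character vector).
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  writeLines(paste0(">", names(aln), "\n", unname(unclass(aln))), path)
  invisible(path)
}

#' Write a phylogenetic tree or dendrogram as Newick
#'
#' @param tree An `ape::phylo` object, or a [upgma()] dendrogram (converted
#'   via `as.phylo`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  if (inherits(tree, "upgma_dendrogram")) tree <- ape::as.phylo(tree)
  if (!inherits(tree, "phylo")) stop("not a tree", call. = FALSE)
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
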