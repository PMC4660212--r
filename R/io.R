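## Plain-text table I/O. Everything the pipeline writes is tab- or
## comma-separated text that round-trips byte-identically.

#' Write / read a screen measurement table
#'
#' Tab-separated with the canonical column order; missing paired-viability
#' values are written as empty fields.
#'
#' @param x a MeasurementTable data.frame.
#' @param path file path.
#' @return `read_measurements()` returns the validated data.frame.
#' @export
write_measurements <- function(x, path) {
  x <- validate_measurements(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = "", colClasses = list(
                           gene = "character", cell_line = "character",
                           reagent_id = "character", condition = "character"))
  x$paired_viability_value <- as.numeric(x$paired_viability_value)
  validate_measurements(x)
}

#' Write / read a presence matrix
#'
#' Comma-separated, genes as rows and cell lines as columns; cells are
#' TRUE/FALSE with NA for unresolved. Provenance is written alongside as
#' `<path>.provenance.csv`.
#'
#' @param x a `presence_matrix` or logical matrix.
#' @param path file path (CSV).
#' @return `read_presence()` returns a `presence_matrix`.
#' @export
write_presence <- function(x, path) {
  prov <- if (inherits(x, "presence_matrix")) x$provenance else NULL
  m <- presence_calls(x)
  utils::write.csv(m, path, row.names = TRUE)
  if (!is.null(prov))
    utils::write.csv(prov, paste0(path, ".provenance.csv"), row.names = TRUE)
  invisible(path)
}

#' @rdname write_presence
#' @export
read_presence <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  mode(m) <- "logical"
  prov_path <- paste0(path, ".provenance.csv")
  prov <- if (file.exists(prov_path))
    as.matrix(utils::read.csv(prov_path, row.names = 1, check.names = FALSE,
                              colClasses = "character"))
  else NULL
  as_presence_matrix(m, provenance = prov)
}

#' Write / read a count matrix (genes x cell lines, CSV)
#'
#' @param x numeric matrix.
#' @param path file path.
#' @export
write_counts <- function(x, path) {
  utils::write.csv(x, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
}

#' Write / read a generic result table as TSV
#'
#' Used for z-score tables, hit tables, qPCR tables, deconvolution and
#' integration summaries.
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a gene list (one identifier per line)
#'
#' @param path file path; blank lines and leading/trailing whitespace are
#'   dropped.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}
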