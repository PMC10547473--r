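# Plain-text readers/writers for the package's table and image formats.
# Trace tables and stain tables are CSV; images are tab-separated numeric
# matrices (one row per pixel row); ground truth sidecars are JSON.

#' Write / read a trajectory set as CSV
#'
#' Columns: `cell_id`, `reporter`, `time_min`, `value`, `missing`,
#' `intensity`, `condition`, `dose`.
#'
#' @param set a [trajectory_set()].
#' @param path file path.
#' @return `read_traces` returns a [trajectory_set()].
#' @export
write_traces <- function(set, path) {
  df <- as.data.frame(set)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @param background background intensity to attach on read.
#' @export
read_traces <- function(path, background = NA_real_) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  trajectory_set(df, background = background)
}

#' Write / read a stain table as CSV
#'
#' @param table a `stain_table`.
#' @param path file path.
#' @return `read_stains` returns a `stain_table`.
#' @export
write_stains <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stains
#' @export
read_stains <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("stain_table", "data.frame")
  tab
}

#' Write / read a numeric image matrix as plain text (TSV)
#'
#' @param img numeric matrix.
#' @param path file path.
#' @return `read_matrix_txt` returns a numeric matrix.
#' @export
write_matrix_txt <- function(img, path) {
  utils::write.table(img, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write a ground-truth sidecar as JSON
#'
#' Matrices are stored as nested arrays; `read_ground_truth` restores
#' the list (matrices come back as matrices).
#'
#' @param truth a `ground_truth` object (or plain list).
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  truth <- unclass(truth)
  truth$config <- NULL
  jsonlite::write_json(truth, path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
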