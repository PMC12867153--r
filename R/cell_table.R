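#' Marker columns of a cell table
#'
#' A cell table is a plain `data.frame` with one row per segmented cell and
#' the reserved columns `sample_id`, `cell_id`, `x`, `y`, and optionally
#' `area` and `cell_class`; every remaining column is a marker intensity.
#'
#' @param table A cell table (`data.frame`).
#' @return Character vector of marker column names.
#' @export
cell_markers <- function(table) {
  reserved <- c("sample_id", "cell_id", "x", "y", "area", "cell_class")
  setdiff(names(table), reserved)
}

#' Validate a cell table
#'
#' Checks the structural invariants of the per-cell format: finite
#' coordinates, nonnegative marker intensities, and `(sample_id, cell_id)`
#' uniqueness.
#'
#' Raw intensities must be nonnegative; tables that have passed through
#' [normalize_markers()] are centered and may be negative, so downstream
#' stages validate with `allow_negative = TRUE`.
#'
#' @param table A `data.frame` to validate.
#' @param allow_negative Permit negative marker values (normalized data).
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_cell_table <- function(table, allow_negative = FALSE) {
  stopifnot(is.data.frame(table))
  required <- c("sample_id", "cell_id", "x", "y")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0L) {
    stop("cell table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(is.finite(table$x)) || !all(is.finite(table$y))) {
    stop("cell coordinates must be finite")
  }
  key <- paste(table$sample_id, table$cell_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(sample_id, cell_id) pairs must be unique")
  }
  for (m in cell_markers(table)) {
    v <- table[[m]]
    if (!is.numeric(v) || anyNA(v) || (!allow_negative && any(v < 0))) {
      stop("marker '", m, "' must be numeric, nonnegative and non-missing")
    }
  }
  invisible(table)
}
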