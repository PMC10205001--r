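#' Cell tables
#'
#' A `cell_table` is a data.frame of cell center points with one row per
#' cell, columns `x`, `y`, `z` (physical µm), optional `size_vox`,
#' `intensity`, `region_id`, flatmap columns (`u`, `v`, `depth_frac`,
#' `depth_um`) and `sample` — plus a `space` attribute naming the coordinate
#' space the positions live in (`"stack"`, `"atlas"`, or a custom tag). All
#' operations that consume cells check the space tag, so a table registered
#' to atlas space can never be silently interpreted as raw stack
#' coordinates.
#'
#' @param df data.frame with at least numeric columns `x`, `y`, `z` (µm).
#' @param space character scalar space tag, e.g. `"stack"` or `"atlas"`.
#' @return A `cell_table` (a classed data.frame).
#' @export
cell_table <- function(df, space) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("cell table needs columns x, y, z")
  for (col in c("x", "y", "z")) df[[col]] <- as.numeric(df[[col]])
  if (nrow(df) > 0 && !all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("cell positions must be finite")
  if (!is.character(space) || length(space) != 1L || is.na(space) || space == "")
    stop("`space` must be a non-empty character scalar")
  attr(df, "space") <- space
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Space tag of a cell table
#' @param cells a [cell_table()].
#' @return Character scalar.
#' @export
cell_space <- function(cells) {
  sp <- attr(cells, "space")
  if (is.null(sp)) stop("cell table has no space tag")
  sp
}

check_space <- function(cells, expected) {
  sp <- cell_space(cells)
  if (!identical(sp, expected))
    stop(sprintf("cell table is in space '%s' but '%s' is required", sp, expected))
  invisible(TRUE)
}

cell_xyz <- function(cells) {
  m <- as.matrix(as.data.frame(cells)[, c("x", "y", "z")])
  storage.mode(m) <- "double"
  m
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells in space '%s'\n", nrow(x), cell_space(x)))
  NextMethod()
}

#' Import externally segmented cell coordinates from CSV
#'
#' Reads center-point tables exported by external segmentation tools
#' (machine-learning segmenters, manual annotation, any program that can
#' write XYZ CSV). The caller maps the file's column names onto x/y/z (and
#' optionally size/intensity), supplies a per-axis scale when the file is in
#' pixel rather than µm units, and may flip axes (`x' = extent_x - x`) when
#' the exporting tool counts from the opposite corner.
#'
#' Rows with non-numeric or missing coordinates are rejected and counted,
#' never silently dropped: the returned table carries a `rejected_rows`
#' attribute and a summary message is emitted. If every row is rejected the
#' import fails.
#'
#' @param path CSV file with a header row.
#' @param column_map named character vector mapping `x`, `y`, `z` (optionally
#'   `size_vox`, `intensity`, `sample`) to file column names. Default assumes
#'   the file already uses `x_um`,`y_um`,`z_um` or `x`,`y`,`z`.
#' @param scale_um_per_unit length-3 numeric; multiply file coordinates by
#'   this to obtain µm (e.g. `c(2.95, 2.95, 3)` for a pixel-unit export of an
#'   anisotropic stack). Default `c(1,1,1)` (file already in µm).
#' @param axis_flips logical length-3; where `TRUE`, apply `x' = extent - x`
#'   using `extent_um`.
#' @param extent_um length-3 physical extent, required where a flip is
#'   requested.
#' @param space space tag for the resulting table, default `"stack"`.
#' @return A [cell_table()]; attribute `rejected_rows` holds the count.
#' @export
read_cell_csv <- function(path, column_map = NULL,
                          scale_um_per_unit = c(1, 1, 1),
                          axis_flips = c(FALSE, FALSE, FALSE),
                          extent_um = NULL, space = "stack") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (is.null(column_map)) {
    cand <- list(c("x_um", "y_um", "z_um"), c("x", "y", "z"))
    hit <- Filter(function(cc) all(cc %in% names(raw)), cand)
    if (length(hit) == 0L)
      stop("cannot find coordinate columns; pass `column_map`")
    column_map <- stats::setNames(hit[[1]], c("x", "y", "z"))
    for (extra in c("size_vox", "intensity", "region_id", "sample"))
      if (extra %in% names(raw)) column_map[extra] <- extra
  }
  if (!all(c("x", "y", "z") %in% names(column_map)))
    stop("column_map must name x, y and z")
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0L)
    stop("columns not in file: ", paste(missing_cols, collapse = ", "))
  cols <- lapply(names(column_map), function(k) raw[[column_map[[k]]]])
  names(cols) <- names(column_map)
  out <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  for (k in c("x", "y", "z"))
    out[[k]] <- suppressWarnings(as.numeric(out[[k]]))
  bad <- !is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z)
  n_rej <- sum(bad)
  if (n_rej > 0L) {
    message(sprintf("read_cell_csv: rejected %d of %d rows with non-numeric coordinates",
                    n_rej, nrow(out)))
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L && n_rej > 0L)
    stop("all ", n_rej, " rows rejected: no numeric coordinates in ", path)
  scale_um_per_unit <- as.numeric(scale_um_per_unit)
  stopifnot(length(scale_um_per_unit) == 3L, all(scale_um_per_unit > 0))
  out$x <- out$x * scale_um_per_unit[1]
  out$y <- out$y * scale_um_per_unit[2]
  out$z <- out$z * scale_um_per_unit[3]
  if (any(axis_flips)) {
    if (is.null(extent_um)) stop("axis flips require `extent_um`")
    for (ax in which(axis_flips)) {
      col <- c("x", "y", "z")[ax]
      out[[col]] <- extent_um[ax] - out[[col]]
    }
  }
  rownames(out) <- NULL
  cells <- cell_table(out, space)
  attr(cells, "rejected_rows") <- n_rej
  cells
}

#' Write a cell table to CSV
#'
#' Writes all columns with full precision; the space tag goes into a
#' `# space: <tag>` comment line so a round-trip through
#' [read_cell_csv()] / [read_cells()] reconstructs the identical table.
#'
#' @param cells a [cell_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_csv <- function(cells, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# space: %s", cell_space(cells)), con)
  df <- as.data.frame(cells)
  # full-precision numerics so round-trips are bit-exact
  for (k in names(df))
    if (is.double(df[[k]])) df[[k]] <- sprintf("%.17g", df[[k]])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cell CSV written by [write_cell_csv()]
#'
#' Recovers the space tag from the header comment.
#' @param path CSV file.
#' @return A [cell_table()].
#' @export
read_cells <- function(path) {
  first <- readLines(path, n = 1)
  space <- if (grepl("^# space: ", first)) sub("^# space: ", "", first) else "stack"
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0L && !all(c("x", "y", "z") %in% names(df)))
    df <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0))
  cell_table(df, space)
}
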