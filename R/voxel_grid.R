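#' Construct a voxel grid
#'
#' A `voxel_grid` is the package's container for any 3D scalar volume: raw
#' light-sheet stacks, atlas annotation volumes, density heatmaps, and the
#' cortical depth potential all use it. It couples a numeric 3D array with
#' physical geometry: the voxel spacing in micrometres and the physical
#' position of the *center* of voxel `[1,1,1]`.
#'
#' Storage convention: `values` is an ordinary R array with
#' `dim = c(nx, ny, nz)`, so `values[i, j, k]` is the voxel at x-index `i`,
#' y-index `j`, z-index `k`. Every coordinate tuple in the API is `(x, y, z)`
#' in physical micrometres. The physical position of voxel `(i, j, k)`
#' (1-based) is `origin + ((i,j,k) - 1) * spacing`.
#'
#' @param values numeric or integer 3D array, `dim = c(nx, ny, nz)`.
#' @param spacing numeric length-3, µm per voxel along (x, y, z); all > 0.
#' @param origin numeric length-3, physical µm position of the center of
#'   voxel `[1,1,1]`. Default `c(0, 0, 0)`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (µm/voxel)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (µm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (%s)\n", d[1], d[2], d[3],
              storage.mode(x$values)))
  cat(sprintf("  spacing: %g x %g x %g um, origin: (%g, %g, %g) um\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  value range: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Convert voxel indices to physical coordinates
#'
#' Maps 1-based voxel indices to the physical µm position of the voxel
#' centers.
#'
#' @param grid a [voxel_grid()].
#' @param idx numeric matrix with 3 columns `(i, j, k)` (1-based), or a
#'   length-3 vector. Fractional indices are allowed.
#' @return Matrix with columns `x`, `y`, `z` (µm).
#' @export
index_to_physical <- function(grid, idx) {
  idx <- rbind_coords(idx)
  out <- sweep(sweep(idx - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Convert physical coordinates to fractional voxel indices
#'
#' Inverse of [index_to_physical()]: a point exactly at a voxel center maps
#' to that voxel's integer index.
#'
#' @param grid a [voxel_grid()].
#' @param xyz numeric matrix with columns `(x, y, z)` in µm, or a length-3
#'   vector.
#' @return Matrix of fractional 1-based indices, columns `i`, `j`, `k`.
#' @export
physical_to_index <- function(grid, xyz) {
  xyz <- rbind_coords(xyz)
  out <- sweep(sweep(xyz, 2, grid$origin, `-`), 2, grid$spacing, `/`) + 1
  colnames(out) <- c("i", "j", "k")
  out
}

#' Integer voxel ownership of physical points
#'
#' Each voxel owns the half-open box `[center - spacing/2, center + spacing/2)`
#' along every axis, so every physical point belongs to exactly one voxel.
#'
#' @inheritParams physical_to_index
#' @return Integer matrix of 1-based indices; rows falling outside the grid
#'   get `NA` in all three columns.
#' @export
owning_voxel <- function(grid, xyz) {
  frac <- physical_to_index(grid, xyz)
  idx <- floor(frac + 0.5)
  d <- dim(grid$values)
  bad <- idx[, 1] < 1 | idx[, 1] > d[1] |
         idx[, 2] < 1 | idx[, 2] > d[2] |
         idx[, 3] < 1 | idx[, 3] > d[3]
  idx[bad, ] <- NA_real_
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("i", "j", "k")
  idx
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3)
  else x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns (x, y, z)")
  storage.mode(x) <- "double"
  x
}

#' Total physical volume of one voxel
#' @param grid a [voxel_grid()].
#' @return Voxel volume in µm³.
#' @export
voxel_volume_um3 <- function(grid) prod(grid$spacing)

# ---------------------------------------------------------------------------
# Volume file I/O

#' Read a 3D volume from TIFF or NRRD
#'
#' Supports multi-page TIFF, a directory of single-plane TIFFs (a "series",
#' sorted by file name, one z-plane per file), and NRRD (raw or gzip
#' encoding, attached header). NRRD carries its spacing in the header; TIFF
#' does not reliably, so for TIFF inputs `spacing` must be given explicitly —
#' a missing spacing is an error, never silently defaulted, because every
#' downstream density is in physical units.
#'
#' @param path file (TIFF/NRRD) or directory (TIFF series).
#' @param spacing optional numeric length-3 (x, y, z) µm/voxel override;
#'   required for TIFF input.
#' @param origin optional numeric length-3 µm; default `c(0,0,0)` unless the
#'   file carries one (NRRD `space origin`).
#' @return A [voxel_grid()]. Integer volumes keep integer storage.
#' @export
read_volume <- function(path, spacing = NULL, origin = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF files found in series directory: ", path)
    pages <- lapply(files, read_tiff_pages)
    pages <- do.call(c, pages)
    meta <- read_tiff_sidecar(file.path(path, "volume_meta.json"))
    return(tiff_pages_to_grid(pages, spacing, origin, path, meta))
  }
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    read_nrrd(path, spacing = spacing, origin = origin)
  } else if (ext %in% c("tif", "tiff")) {
    meta <- read_tiff_sidecar(paste0(path, ".json"))
    tiff_pages_to_grid(read_tiff_pages(path), spacing, origin, path, meta)
  } else {
    stop("unsupported volume format: .", ext, " (use TIFF or NRRD)")
  }
}

read_tiff_sidecar <- function(path) {
  if (!file.exists(path)) return(NULL)
  jsonlite::fromJSON(path)
}

read_tiff_pages <- function(path) {
  # as.is recovers exact integers from 16-bit pages but misreads 32-bit
  # float pages, which must be read rescaled (a no-op for float storage)
  probe <- tiff::readTIFF(path, info = TRUE)
  float_pages <- identical(attr(probe, "bits.per.sample"), 32L)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !float_pages)
  if (!is.list(pages)) pages <- list(pages)
  pages
}

tiff_pages_to_grid <- function(pages, spacing, origin, path, meta = NULL) {
  shp <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("inconsistent slice shapes in TIFF series: ", path)
  if (is.null(spacing)) spacing <- meta$spacing
  if (is.null(spacing))
    stop("TIFF volumes carry no trusted spacing metadata; pass `spacing` ",
         "(µm/voxel, x/y/z) explicitly: ", path)
  if (is.null(origin)) origin <- meta$origin %||% c(0, 0, 0)
  # each page is [row=y, col=x]; assemble as [x, y, z]
  nz <- length(pages)
  ny <- shp[1, 1]; nx <- shp[2, 1]
  arr <- array(0, dim = c(nx, ny, nz))
  int_in <- all(vapply(pages, is.integer, logical(1)))
  for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
  if (int_in) storage.mode(arr) <- "integer"
  if (!is.null(meta$value_offset))
    arr <- arr * meta$value_scale + meta$value_offset
  voxel_grid(arr, spacing, origin)
}

#' Write a 3D volume to TIFF or NRRD
#'
#' NRRD round-trips are lossless: integer data is stored as int32, floats as
#' float64, and spacing/origin go in the header. TIFF stores integer data as
#' 16-bit pages (labels must fit in 0..65535; use NRRD for larger ids) and
#' float data as 32-bit float pages; TIFF has no trusted spacing tag, so the
#' caller must re-supply spacing when reading back.
#'
#' @param grid a [voxel_grid()].
#' @param path output file (`.tif`/`.tiff`/`.nrrd`) or, with
#'   `format = "tiff_series"`, an output directory.
#' @param format `"auto"` (from extension), `"tiff"`, `"tiff_series"`, or
#'   `"nrrd"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, format = c("auto", "tiff", "tiff_series", "nrrd")) {
  stopifnot(is_voxel_grid(grid))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, nrrd = "nrrd", tif = "tiff", tiff = "tiff",
                     stop("cannot infer volume format from extension: ", path))
  }
  if (format == "nrrd") return(invisible(write_nrrd(grid, path)))
  pages <- grid_to_tiff_pages(grid)
  sidecar <- list(spacing = grid$spacing, origin = grid$origin)
  if (!is.null(pages$offset)) {
    sidecar$value_offset <- pages$offset
    sidecar$value_scale <- pages$scale
  }
  if (format == "tiff") {
    tiff::writeTIFF(pages$pages, path, bits.per.sample = pages$bits,
                    reduce = FALSE)
    sidecar_path <- paste0(path, ".json")
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    nz <- length(pages$pages)
    for (k in seq_len(nz)) {
      tiff::writeTIFF(pages$pages[[k]],
                      file.path(path, sprintf("plane_%04d.tif", k)),
                      bits.per.sample = pages$bits, reduce = FALSE)
    }
    sidecar_path <- file.path(path, "volume_meta.json")
  }
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# TIFF pages must lie in [0, 1]: integers are stored as 16-bit fractions of
# 65535 (exact round-trip via as.is), floats as 32-bit after affine
# rescaling into [0, 1]; the scale/offset go in the JSON sidecar.
grid_to_tiff_pages <- function(grid) {
  v <- grid$values
  nz <- dim(v)[3]
  if (is.integer(v)) {
    if (min(v) < 0L || max(v) > 65535L)
      stop("integer TIFF output supports labels in 0..65535; use NRRD")
    pages <- lapply(seq_len(nz), function(k) t(v[, , k]) / 65535)
    list(pages = pages, bits = 16L)
  } else {
    lo <- min(v); hi <- max(v)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(nz), function(k) t((v[, , k] - lo) / scale))
    list(pages = pages, bits = 32L, offset = lo, scale = scale)
  }
}

# --- minimal NRRD (attached header, raw/gzip encodings) --------------------

read_nrrd <- function(path, spacing = NULL, origin = NULL) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header is text up to the first blank line (\n\n)
  nl <- which(bytes == as.raw(10L))
  blank <- nl[which(diff(nl) == 1L)[1] + 1L]
  if (is.na(blank) || length(blank) == 0L) stop("truncated NRRD header: ", path)
  header <- strsplit(rawToChar(bytes[seq_len(blank - 2L)]), "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD000", header[1])) stop("not an NRRD file: ", path)
  fields <- list()
  for (line in header[-1]) {
    if (grepl("^#", line) || line == "") next
    kv <- strsplit(line, ":=|: ", perl = TRUE)[[1]]
    if (length(kv) < 2L) next
    fields[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3D NRRD volumes are supported")
  type <- fields[["type"]]
  enc <- fields[["encoding"]]
  n <- prod(dims)
  raw_payload <- bytes[seq.int(blank + 1L, length(bytes))]
  if (identical(enc, "gzip") || identical(enc, "gz"))
    raw_payload <- memDecompress(raw_payload, type = "gzip")
  else if (!identical(enc, "raw"))
    stop("unsupported NRRD encoding: ", enc)
  endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
  vals <- switch(type,
    "int" = , "int32" = , "signed int" =
      readBin(raw_payload, "integer", n = n, size = 4, endian = endian),
    "short" = , "int16" = , "signed short" =
      readBin(raw_payload, "integer", n = n, size = 2, signed = TRUE, endian = endian),
    "uchar" = , "uint8" = , "unsigned char" =
      readBin(raw_payload, "integer", n = n, size = 1, signed = FALSE, endian = endian),
    "ushort" = , "uint16" = , "unsigned short" =
      readBin(raw_payload, "integer", n = n, size = 2, signed = FALSE, endian = endian),
    "float" =
      as.numeric(readBin(raw_payload, "double", n = n, size = 4, endian = endian)),
    "double" = , "float64" =
      readBin(raw_payload, "double", n = n, size = 8, endian = endian),
    stop("unsupported NRRD type: ", type))
  if (length(vals) != n) stop("NRRD payload shorter than `sizes` promise: ", path)
  arr <- array(vals, dim = dims)
  sp <- spacing
  if (is.null(sp)) {
    if (!is.null(fields[["spacings"]])) {
      sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    } else if (!is.null(fields[["space directions"]])) {
      vecs <- regmatches(fields[["space directions"]],
                         gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
      m <- vapply(vecs, function(v)
        as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
      sp <- sqrt(colSums(m^2))
    }
  }
  if (is.null(sp))
    stop("NRRD header has no spacing and no override was given: ", path)
  org <- origin
  if (is.null(org) && !is.null(fields[["space origin"]]))
    org <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  if (is.null(org)) org <- c(0, 0, 0)
  voxel_grid(arr, sp, org)
}

write_nrrd <- function(grid, path, encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  v <- grid$values
  type <- if (is.integer(v)) "int32" else "double"
  hdr <- c(
    "NRRD0004",
    "# written by brainmapr",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(v), collapse = " ")),
    paste0("spacings: ", paste(format(grid$spacing, digits = 17), collapse = " ")),
    paste0("space origin: (", paste(format(grid$origin, digits = 17), collapse = ","), ")"),
    paste0("encoding: ", encoding),
    "endian: little",
    "")
  payload <- if (is.integer(v)) writeBin(as.vector(v), raw(), size = 4, endian = "little")
             else writeBin(as.vector(v), raw(), size = 8, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con, sep = "\n")
  writeBin(payload, con)
  path
}
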