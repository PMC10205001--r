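#' Landmark sets
#'
#' Paired corresponding points clicked in two volumes: `moving` coordinates
#' in sample (downsampled-stack) space and `fixed` coordinates in atlas
#' space, both in µm. Each landmark has a name and an `active` flag;
#' inactive landmarks are retained for bookkeeping but excluded from every
#' fit.
#'
#' @param df data.frame with columns `name`, `active`, `mx`, `my`, `mz`,
#'   `fx`, `fy`, `fz`.
#' @return A `landmark_set` (classed data.frame).
#' @export
landmark_set <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("name", "active", "mx", "my", "mz", "fx", "fy", "fz")
  if (!all(req %in% names(df)))
    stop("landmark set needs columns: ", paste(req, collapse = ", "))
  df$name <- as.character(df$name)
  df$active <- as.logical(df$active)
  for (k in req[-(1:2)]) df[[k]] <- as.numeric(df[[k]])
  if (any(is.na(df$active))) stop("unparseable active flag")
  if (nrow(df) > 0 && !all(is.finite(as.matrix(df[, req[-(1:2)]]))))
    stop("landmark coordinates must be finite")
  class(df) <- c("landmark_set", "data.frame")
  df
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks (%d active)\n", nrow(x), sum(x$active)))
  NextMethod()
}

active_pairs <- function(landmarks) {
  lm <- as.data.frame(landmarks)[landmarks$active, , drop = FALSE]
  list(moving = as.matrix(lm[, c("mx", "my", "mz")]),
       fixed = as.matrix(lm[, c("fx", "fy", "fz")]),
       names = lm$name)
}

#' Read a BigWarp landmark CSV
#'
#' BigWarp's landmark dialect: no header row; per row a landmark name, an
#' active flag (`"true"`/`"false"`), three moving coordinates and three
#' fixed coordinates. Coordinates are taken as µm (BigWarp exports physical
#' units when the loaded images carry calibration); a message states this
#' assumption.
#'
#' The pipeline convention is moving = sample/downsampled-stack space and
#' fixed = atlas space. If the images were loaded into BigWarp in the
#' opposite order, set `swap = TRUE` to exchange the two triplets.
#'
#' @param path CSV file in the BigWarp dialect.
#' @param swap exchange moving and fixed triplets. Default `FALSE`.
#' @return A [landmark_set()].
#' @export
read_bigwarp_landmarks <- function(path, swap = FALSE) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) != 8L)
    stop("BigWarp landmark file must have 8 columns (name, active, 3 moving, 3 fixed); found ",
         ncol(raw))
  flag <- tolower(trimws(as.character(raw[[2]])))
  if (!all(flag %in% c("true", "false")))
    stop("unparseable active flag in landmark file (expect 'true'/'false')")
  df <- data.frame(name = trimws(gsub('"', "", as.character(raw[[1]]))),
                   active = flag == "true",
                   mx = as.numeric(raw[[3]]), my = as.numeric(raw[[4]]),
                   mz = as.numeric(raw[[5]]),
                   fx = as.numeric(raw[[6]]), fy = as.numeric(raw[[7]]),
                   fz = as.numeric(raw[[8]]),
                   stringsAsFactors = FALSE)
  if (swap) {
    df[, c("mx", "my", "mz", "fx", "fy", "fz")] <-
      df[, c("fx", "fy", "fz", "mx", "my", "mz")]
  }
  message("read_bigwarp_landmarks: coordinates interpreted as micrometres")
  landmark_set(df)
}

#' Write a landmark set in the BigWarp CSV dialect
#' @param landmarks a [landmark_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bigwarp_landmarks <- function(landmarks, path) {
  df <- as.data.frame(landmarks)
  lines <- sprintf('"%s",%s,%s,%s,%s,%s,%s,%s',
                   df$name, ifelse(df$active, "true", "false"),
                   sprintf("%.17g", df$mx), sprintf("%.17g", df$my),
                   sprintf("%.17g", df$mz),
                   sprintf("%.17g", df$fx), sprintf("%.17g", df$fy),
                   sprintf("%.17g", df$fz))
  writeLines(lines, path)
  invisible(path)
}
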