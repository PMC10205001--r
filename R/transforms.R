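#' Point transforms
#'
#' All spatial mappings in the pipeline are *point* transforms in the
#' sample-to-atlas (moving-to-fixed) direction: they move cell coordinates
#' forward into atlas space, the opposite of the image-resampling convention
#' used by intensity-based registration tools. Three kinds exist:
#'
#' * `affine_transform`: a 3x4 matrix `[L | t]` acting on column vectors,
#'   `p' = L p + t`; the 3x3 linear part must be non-singular.
#' * `tps_transform`: a 3D thin-plate spline with kernel `U(r) = r` (the
#'   biharmonic fundamental solution in 3D), an affine part plus kernel
#'   weights anchored at control points. The weights satisfy the standard
#'   orthogonality side conditions (they sum to zero and are orthogonal to
#'   the control-point coordinates, per output axis).
#' * `composite_transform`: an ordered list applied left to right.
#'
#' Transforms optionally carry `from`/`to` space tags; applying a transform
#' to a [cell_table()] checks the tag and relabels the result.
#'
#' @name point_transform
NULL

#' Create an affine point transform
#'
#' @param matrix 3x4 numeric matrix `[L | t]` mapping column vectors, µm.
#' @param from,to optional space tags (e.g. `"stack"`, `"atlas"`).
#' @return An `affine_transform`.
#' @export
affine_transform <- function(matrix, from = NULL, to = NULL) {
  matrix <- unname(as.matrix(matrix))
  dimnames(matrix) <- NULL
  if (!all(dim(matrix) == c(3L, 4L))) stop("affine matrix must be 3x4")
  if (abs(det(matrix[, 1:3])) < 1e-15)
    stop("affine linear part is singular")
  structure(list(matrix = matrix, from = from, to = to),
            class = c("affine_transform", "point_transform"))
}

#' Identity affine transform
#' @inheritParams affine_transform
#' @return An `affine_transform` equal to the identity map.
#' @export
identity_transform <- function(from = NULL, to = NULL)
  affine_transform(cbind(diag(3), 0), from = from, to = to)

tps_transform <- function(control_points, weights, affine, from = NULL, to = NULL) {
  stopifnot(ncol(control_points) == 3L, ncol(weights) == 3L,
            nrow(weights) == nrow(control_points),
            all(dim(affine) == c(4L, 3L)))
  # side conditions: t(P) %*% W == 0 with P = [1 | X]
  P <- cbind(1, control_points)
  side <- crossprod(P, weights)
  if (max(abs(side)) > 1e-6)
    stop("TPS weights violate the orthogonality side conditions")
  structure(list(control_points = control_points, weights = weights,
                 affine = affine, from = from, to = to),
            class = c("tps_transform", "point_transform"))
}

#' Compose point transforms
#'
#' @param ... point transforms, applied in the order given (first argument
#'   first).
#' @return A `composite_transform` (or the single argument unchanged).
#' @export
compose_transforms <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && inherits(parts[[1]], "point_transform"))
    return(parts[[1]])
  stopifnot(all(vapply(parts, inherits, logical(1), "point_transform")))
  from <- parts[[1]]$from
  to <- parts[[length(parts)]]$to
  structure(list(transforms = parts, from = from, to = to),
            class = c("composite_transform", "point_transform"))
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>", space_arrow(x), "\n")
  print(unname(x$matrix))
  invisible(x)
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("<tps_transform> %d control points %s\n",
              nrow(x$control_points), space_arrow(x)))
  invisible(x)
}

#' @export
print.composite_transform <- function(x, ...) {
  cat(sprintf("<composite_transform> %d stages %s\n",
              length(x$transforms), space_arrow(x)))
  invisible(x)
}

space_arrow <- function(x) {
  if (is.null(x$from) && is.null(x$to)) return("")
  sprintf("[%s -> %s]", x$from %||% "?", x$to %||% "?")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a point transform
#'
#' Maps 3D points forward through the transform. For a [cell_table()] input
#' the table's space tag is checked against the transform's `from` tag (when
#' both are set) and the result is retagged with the transform's `to` tag;
#' row order and all non-coordinate columns are preserved.
#'
#' @param transform a point transform.
#' @param points n x 3 matrix of (x, y, z) µm, a length-3 vector, or a
#'   [cell_table()].
#' @return Same shape as the input, transformed.
#' @export
apply_transform <- function(transform, points) {
  if (inherits(points, "cell_table")) {
    if (!is.null(transform$from)) check_space(points, transform$from)
    new_space <- transform$to %||% cell_space(points)
    xyz <- apply_transform_xyz(transform, cell_xyz(points))
    out <- as.data.frame(points)
    out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
    return(cell_table(out, new_space))
  }
  vec_in <- is.null(dim(points))
  out <- apply_transform_xyz(transform, rbind_coords(points))
  if (vec_in) drop(out) else out
}

apply_transform_xyz <- function(transform, xyz) {
  UseMethod("apply_transform_xyz")
}

#' @export
apply_transform_xyz.affine_transform <- function(transform, xyz) {
  out <- xyz %*% t(transform$matrix[, 1:3])
  out <- sweep(out, 2, transform$matrix[, 4], `+`)
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
apply_transform_xyz.tps_transform <- function(transform, xyz) {
  out <- cbind(1, xyz) %*% transform$affine
  U <- cross_dist(xyz, transform$control_points)  # kernel U(r) = r
  out <- out + U %*% transform$weights
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
apply_transform_xyz.composite_transform <- function(transform, xyz) {
  for (tr in transform$transforms) xyz <- apply_transform_xyz(tr, xyz)
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

cross_dist <- function(a, b) {
  # n x m Euclidean distance matrix
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Invert a point transform
#'
#' Affines invert in closed form; composites invert stage-wise in reverse.
#' Thin-plate splines have no closed-form inverse and are refused.
#'
#' @param transform a point transform.
#' @return The inverse transform.
#' @export
invert_transform <- function(transform) UseMethod("invert_transform")

#' @export
invert_transform.affine_transform <- function(transform) {
  L <- transform$matrix[, 1:3]
  t <- transform$matrix[, 4]
  Li <- solve(L)
  affine_transform(cbind(Li, -Li %*% t), from = transform$to, to = transform$from)
}

#' @export
invert_transform.composite_transform <- function(transform) {
  inv <- lapply(rev(transform$transforms), invert_transform)
  do.call(compose_transforms, inv)
}

#' @export
invert_transform.tps_transform <- function(transform) {
  stop("thin-plate splines have no closed-form inverse; fit the reverse direction instead")
}

# ---------------------------------------------------------------------------
# Fitting

#' Fit a least-squares affine transform from landmarks
#'
#' Solves `argmin_A sum ||A(moving) - fixed||^2` over 3x4 matrices. Needs at
#' least 4 active, non-coplanar landmark pairs; a degenerate (coplanar or
#' collinear) configuration is refused with the condition number of the
#' design matrix in the error message.
#'
#' @param landmarks a [landmark_set()].
#' @param from,to space tags for the fitted transform; defaults
#'   `"stack" -> "atlas"`.
#' @param max_condition condition-number threshold above which the
#'   configuration is declared degenerate.
#' @return An `affine_transform` (moving -> fixed direction).
#' @export
fit_affine <- function(landmarks, from = "stack", to = "atlas",
                       max_condition = 1e10) {
  ap <- active_pairs(landmarks)
  n <- nrow(ap$moving)
  if (n < 4L) stop("affine fit needs >= 4 active landmarks, have ", n)
  X <- cbind(ap$moving, 1)
  sv <- svd(X, nu = 0, nv = 0)$d
  kappa <- sv[1] / sv[length(sv)]
  if (!is.finite(kappa) || kappa > max_condition)
    stop(sprintf("degenerate (coplanar/collinear) landmark configuration: condition number %.3g",
                 kappa))
  B <- qr.solve(X, ap$fixed)  # 4 x 3; rows: linear part then intercept
  M <- cbind(t(B[1:3, , drop = FALSE]), B[4, ])
  affine_transform(M, from = from, to = to)
}

#' Fit a 3D thin-plate spline from landmarks
#'
#' Solves the standard TPS linear system with kernel `U(r) = r` and
#' smoothing parameter `lambda` added to the kernel diagonal:
#' `lambda = 0` interpolates the landmarks exactly; as `lambda` grows the
#' mapping tends to the least-squares affine. Landmarks generated by a pure
#' affine yield (numerically) zero kernel weights at any `lambda` — the
#' polynomial-reproduction property.
#'
#' @param landmarks a [landmark_set()].
#' @param lambda smoothing weight, >= 0 (µm units of the kernel). Default 0
#'   (exact interpolation). See [default_tps_lambda()] for the pipeline's
#'   noise-damping default.
#' @param from,to space tags; defaults `"stack" -> "atlas"`.
#' @return A `tps_transform`.
#' @export
fit_tps <- function(landmarks, lambda = 0, from = "stack", to = "atlas") {
  ap <- active_pairs(landmarks)
  n <- nrow(ap$moving)
  if (n < 5L) stop("TPS fit needs >= 5 active landmarks, have ", n)
  if (lambda < 0) stop("lambda must be >= 0")
  X <- ap$moving
  if (anyDuplicated(X)) stop("duplicate moving points make the TPS system singular")
  K <- cross_dist(X, X) + diag(lambda, n)
  P <- cbind(1, X)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(ap$fixed, matrix(0, 4, 3))
  sol <- tryCatch(solve(A, rhs),
                  error = function(e) stop("singular TPS system: ", conditionMessage(e)))
  W <- sol[1:n, , drop = FALSE]
  aff <- sol[(n + 1):(n + 4), , drop = FALSE]
  # re-project weights onto the side-condition space to kill round-off drift
  Q <- qr.Q(qr(P))
  W <- W - Q %*% crossprod(Q, W)
  tps_transform(X, W, aff, from = from, to = to)
}

#' Default TPS smoothing weight for landmark clicking noise
#'
#' The pipeline's coarse-then-fine default is an affine fit followed by a
#' TPS on the residual, lightly regularized so isolated clicking errors do
#' not bend the whole field: `lambda = 0.001 * n * mean squared pairwise
#' distance` between active moving points.
#'
#' @param landmarks a [landmark_set()].
#' @return Numeric scalar `lambda`.
#' @export
default_tps_lambda <- function(landmarks) {
  ap <- active_pairs(landmarks)
  d <- cross_dist(ap$moving, ap$moving)
  0.001 * nrow(ap$moving) * mean(d^2)
}

#' Fit the pipeline's default landmark transform
#'
#' `mode = "affine"` is the least-squares affine; `"tps"` a single TPS on
#' the raw pairs; `"affine+tps"` (default) fits the affine first and a TPS
#' on its residuals, mirroring coarse-then-fine interactive alignment.
#'
#' @param landmarks a [landmark_set()].
#' @param mode `"affine"`, `"tps"`, or `"affine+tps"`.
#' @param lambda TPS smoothing; `NULL` uses [default_tps_lambda()] for
#'   `"affine+tps"` and 0 for `"tps"`.
#' @param from,to space tags.
#' @return A point transform (moving -> fixed).
#' @export
fit_landmark_transform <- function(landmarks, mode = c("affine+tps", "affine", "tps"),
                                   lambda = NULL, from = "stack", to = "atlas") {
  mode <- match.arg(mode)
  if (mode == "affine") return(fit_affine(landmarks, from = from, to = to))
  if (mode == "tps")
    return(fit_tps(landmarks, lambda = lambda %||% 0, from = from, to = to))
  aff <- fit_affine(landmarks, from = from, to = "intermediate")
  moved <- apply_transform(aff, as.matrix(as.data.frame(landmarks)[, c("mx", "my", "mz")]))
  resid_lm <- landmark_set(data.frame(name = landmarks$name,
                                      active = landmarks$active,
                                      mx = moved[, 1], my = moved[, 2], mz = moved[, 3],
                                      fx = landmarks$fx, fy = landmarks$fy,
                                      fz = landmarks$fz))
  lam <- lambda %||% default_tps_lambda(resid_lm)
  tps <- fit_tps(resid_lm, lambda = lam, from = "intermediate", to = to)
  aff$to <- "intermediate"
  compose_transforms(aff, tps)
}

# ---------------------------------------------------------------------------
# QC report

#' Alignment quality report
#'
#' Residuals `fixed - transform(moving)` per active landmark, with RMS,
#' maximum and median residual norms in µm. This is the primary QC artifact
#' for judging a landmark alignment before trusting downstream counts.
#'
#' @param transform a fitted point transform.
#' @param landmarks the [landmark_set()] it was fitted on (or a held-out
#'   set).
#' @return A `registration_report`: list with `per_landmark` (name,
#'   residual components and norm), `rms_um`, `max_um`, `median_um`,
#'   `n_active`.
#' @export
registration_report <- function(transform, landmarks) {
  ap <- active_pairs(landmarks)
  pred <- apply_transform(transform, ap$moving)
  res <- ap$fixed - pred
  norms <- sqrt(rowSums(res^2))
  rep <- list(per_landmark = data.frame(name = ap$names,
                                        dx = res[, 1], dy = res[, 2], dz = res[, 3],
                                        norm_um = norms,
                                        stringsAsFactors = FALSE),
              rms_um = sqrt(mean(norms^2)),
              max_um = if (length(norms)) max(norms) else NA_real_,
              median_um = stats::median(norms),
              n_active = nrow(ap$moving))
  class(rep) <- "registration_report"
  rep
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("<registration_report> %d active landmarks\n", x$n_active))
  cat(sprintf("  RMS %.3f um | median %.3f um | max %.3f um\n",
              x$rms_um, x$median_um, x$max_um))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Transform JSON I/O

#' Write a point transform to JSON
#'
#' The schema stores the transform kind, the space tags, and the numeric
#' payload (3x4 matrix for affines; control points, weights and 4x3 affine
#' part for TPS; a stage list for composites), at full precision.
#'
#' @param transform a point transform.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(transform_to_list(transform), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

transform_to_list <- function(tr) {
  if (inherits(tr, "affine_transform")) {
    list(type = "affine", from = tr$from, to = tr$to,
         matrix = apply(unname(tr$matrix), 1, as.numeric, simplify = FALSE))
  } else if (inherits(tr, "tps_transform")) {
    list(type = "tps", from = tr$from, to = tr$to,
         control_points = apply(unname(tr$control_points), 1, as.numeric, simplify = FALSE),
         weights = apply(unname(tr$weights), 1, as.numeric, simplify = FALSE),
         affine = apply(unname(tr$affine), 1, as.numeric, simplify = FALSE))
  } else if (inherits(tr, "composite_transform")) {
    list(type = "composite", from = tr$from, to = tr$to,
         transforms = lapply(tr$transforms, transform_to_list))
  } else stop("unknown transform class")
}

#' Read a point transform from JSON written by [write_transform()]
#' @param path `.json` file.
#' @return A point transform.
#' @export
read_transform <- function(path) {
  transform_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

transform_from_list <- function(x) {
  rows <- function(l) do.call(rbind, lapply(l, as.numeric))
  switch(x$type,
    affine = affine_transform(rows(x$matrix), from = x$from, to = x$to),
    tps = tps_transform(rows(x$control_points), rows(x$weights),
                        rows(x$affine), from = x$from, to = x$to),
    composite = do.call(compose_transforms, lapply(x$transforms, transform_from_list)),
    stop("unknown transform type in JSON: ", x$type))
}

# ---------------------------------------------------------------------------
# Downsampling

#' Downsample a stack for interactive landmark clicking
#'
#' Integer spacing ratios use exact block-mean pooling; non-integer ratios
#' use a Gaussian prefilter (sigma = 0.5*sqrt(f^2-1) voxels per axis)
#' followed by trilinear resampling. The downsampled grid keeps *physical*
#' coordinates: its origin is the physical center of the first block, so a
#' landmark clicked at physical position p on the downsampled stack is
#' already the full-resolution physical position — the returned
#' stack-to-downsampled affine is therefore the identity on physical
#' coordinates.
#'
#' @param stack a [voxel_grid()].
#' @param target_spacing length-3 µm/voxel, each >= the native spacing.
#' @return List with `grid` (downsampled [voxel_grid()]) and `affine`
#'   (identity `affine_transform` on physical coordinates).
#' @export
downsample_stack <- function(stack, target_spacing) {
  stopifnot(is_voxel_grid(stack))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  if (any(target_spacing < stack$spacing - 1e-9))
    stop("target spacing must be >= native spacing on every axis")
  f <- target_spacing / stack$spacing
  if (all(abs(f - round(f)) < 1e-9)) {
    f <- as.integer(round(f))
    v <- stack$values
    d <- dim(v)
    nd <- d %/% f
    if (any(nd < 1L)) stop("stack too small for this downsampling factor")
    v <- v[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]), seq_len(nd[3] * f[3]), drop = FALSE]
    dim(v) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
    out <- apply(v, c(2, 4, 6), mean)
    new_origin <- stack$origin + (f - 1) / 2 * stack$spacing
    grid <- voxel_grid(out, stack$spacing * f, new_origin)
  } else {
    sig_vox <- 0.5 * sqrt(pmax(f^2 - 1, 0))
    sm <- gaussian_filter_grid(stack, sig_vox * stack$spacing, boundary = "reflect")
    d <- dim(stack$values)
    extent <- d * stack$spacing
    nd <- pmax(1L, as.integer(floor(extent / target_spacing)))
    new_origin <- stack$origin + (target_spacing - stack$spacing) / 2
    xi <- new_origin[1] + (seq_len(nd[1]) - 1) * target_spacing[1]
    yi <- new_origin[2] + (seq_len(nd[2]) - 1) * target_spacing[2]
    zi <- new_origin[3] + (seq_len(nd[3]) - 1) * target_spacing[3]
    pts <- as.matrix(expand.grid(x = xi, y = yi, z = zi))
    vals <- trilinear_interp(sm, pts)
    grid <- voxel_grid(array(vals, nd), target_spacing, new_origin)
  }
  list(grid = grid,
       affine = identity_transform(from = "stack", to = "downsampled"))
}

#' Trilinear interpolation of a voxel grid at physical points
#'
#' Values outside the grid are clamped to the border voxel (used only for
#' smooth fields; categorical volumes must use [owning_voxel()]).
#'
#' @param grid a [voxel_grid()].
#' @param xyz n x 3 matrix of physical µm positions.
#' @return Numeric vector of interpolated values.
#' @export
trilinear_interp <- function(grid, xyz) {
  idx <- physical_to_index(grid, xyz)
  d <- dim(grid$values)
  i0 <- pmin(pmax(floor(idx[, 1]), 1), d[1] - 1); fx <- pmin(pmax(idx[, 1] - i0, 0), 1)
  j0 <- pmin(pmax(floor(idx[, 2]), 1), d[2] - 1); fy <- pmin(pmax(idx[, 2] - j0, 0), 1)
  k0 <- pmin(pmax(floor(idx[, 3]), 1), d[3] - 1); fz <- pmin(pmax(idx[, 3] - k0, 0), 1)
  if (d[1] == 1L) { i0 <- rep(1, nrow(idx)); fx <- rep(0, nrow(idx)) }
  if (d[2] == 1L) { j0 <- rep(1, nrow(idx)); fy <- rep(0, nrow(idx)) }
  if (d[3] == 1L) { k0 <- rep(1, nrow(idx)); fz <- rep(0, nrow(idx)) }
  v <- grid$values
  at <- function(di, dj, dk)
    v[cbind(pmin(i0 + di, d[1]), pmin(j0 + dj, d[2]), pmin(k0 + dk, d[3]))]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(1, 0, 0)) +
              fy       * ((1 - fx) * at(0, 1, 0) + fx * at(1, 1, 0))) +
  fz       * ((1 - fy) * ((1 - fx) * at(0, 0, 1) + fx * at(1, 0, 1)) +
              fy       * ((1 - fx) * at(0, 1, 1) + fx * at(1, 1, 1)))
}
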