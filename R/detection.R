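#' Detection parameters
#'
#' Parameters for the intensity-based cell detection chain: morphological
#' background removal, difference-of-Gaussians band-pass, h-maxima seed
#' finding, marker-controlled watershed, and size/intensity filtering. All
#' length scales are physical µm and are converted per axis by the stack
#' spacing, so anisotropic stacks are handled correctly.
#'
#' @param background_radius µm; radius of the ball structuring element for
#'   grayscale opening. Must exceed a cell diameter.
#' @param dog_sigma_small,dog_sigma_large µm; band-pass sigmas, small < large.
#' @param seed_h h-maxima depth (intensity units): a local maximum survives
#'   only if it stands at least `seed_h` above the ridge connecting it to a
#'   higher maximum.
#' @param min_seed_distance µm; of two seeds closer than this, only the
#'   brighter (ties: first in lexicographic (z, y, x) voxel order) is kept.
#' @param watershed_threshold intensity units (after band-pass); defines the
#'   foreground mask.
#' @param size_min,size_max voxels; retained label size range.
#' @param intensity_min summed label intensity floor.
#' @return A `detection_params` list.
#' @export
detection_params <- function(background_radius = 15,
                             dog_sigma_small = 3,
                             dog_sigma_large = 9,
                             seed_h = 8,
                             min_seed_distance = 8,
                             watershed_threshold = 8,
                             size_min = 20,
                             size_max = 3000,
                             intensity_min = 0) {
  p <- list(background_radius = background_radius,
            dog_sigma_small = dog_sigma_small,
            dog_sigma_large = dog_sigma_large,
            seed_h = seed_h,
            min_seed_distance = min_seed_distance,
            watershed_threshold = watershed_threshold,
            size_min = size_min, size_max = size_max,
            intensity_min = intensity_min)
  validate_detection_params(p)
  structure(p, class = "detection_params")
}

validate_detection_params <- function(p) {
  if (p$dog_sigma_small >= p$dog_sigma_large)
    stop("dog_sigma_small must be < dog_sigma_large")
  if (p$size_min > p$size_max) stop("size_min must be <= size_max")
  lengths <- c(p$background_radius, p$dog_sigma_small, p$dog_sigma_large,
               p$min_seed_distance)
  if (any(lengths <= 0)) stop("all detection length scales must be > 0")
  invisible(TRUE)
}

#' Gaussian-filter a voxel grid
#'
#' Separable Gaussian with per-axis sigma `sigma_um / spacing` voxels.
#'
#' @param grid a [voxel_grid()].
#' @param sigma_um scalar or length-3 µm.
#' @param boundary `"reflect"` (edge-mirrored; used for band-pass filtering)
#'   or `"zero"` (zero-padded; conserves total mass for interior-supported
#'   data, used for density smoothing).
#' @return Filtered [voxel_grid()].
#' @export
gaussian_filter_grid <- function(grid, sigma_um, boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  if (length(sigma_um) == 1L) sigma_um <- rep(sigma_um, 3)
  if (any(sigma_um < 0)) stop("sigma must be >= 0")
  sig_vox <- sigma_um / grid$spacing
  out <- .gaussian3d_cpp(as.double(grid$values), dim(grid$values),
                         as.double(sig_vox), if (boundary == "reflect") 0L else 1L)
  voxel_grid(out, grid$spacing, grid$origin)
}

#' Remove slowly varying background by grayscale opening
#'
#' Subtracts the morphological opening (erosion then dilation with a ball
#' structuring element of physical radius `radius` µm) from the stack.
#' Structures smaller than the ball — cells — survive; smooth background,
#' which the opening reproduces, cancels. Output is clamped at 0.
#'
#' @param stack a [voxel_grid()].
#' @param radius µm; must be at least one voxel on every axis and larger
#'   than a cell diameter for the intended effect.
#' @return Background-subtracted [voxel_grid()].
#' @export
remove_background <- function(stack, radius) {
  stopifnot(is_voxel_grid(stack))
  r_vox <- radius / stack$spacing
  if (any(r_vox < 1))
    stop("background radius is smaller than one voxel on some axis")
  v <- as.double(stack$values)
  dim(v) <- dim(stack$values)
  er <- .erode_ball_cpp(v, dim(v), as.double(r_vox))
  op <- .dilate_ball_cpp(er, dim(v), as.double(r_vox))
  out <- pmax(stack$values - op, 0)
  dim(out) <- dim(stack$values)
  voxel_grid(out, stack$spacing, stack$origin)
}

#' Difference-of-Gaussians band-pass filter
#'
#' `G(sigma_small) - G(sigma_large)`, reflected boundaries, sigmas in µm
#' converted per axis by the stack spacing.
#'
#' @param stack a [voxel_grid()].
#' @param sigma_small,sigma_large µm; `sigma_small < sigma_large`.
#' @return Band-passed [voxel_grid()].
#' @export
dog_filter <- function(stack, sigma_small, sigma_large) {
  if (sigma_small >= sigma_large)
    stop("dog_filter: sigma_small must be < sigma_large")
  lo <- gaussian_filter_grid(stack, sigma_small, "reflect")
  hi <- gaussian_filter_grid(stack, sigma_large, "reflect")
  voxel_grid(lo$values - hi$values, stack$spacing, stack$origin)
}

#' Find watershed seeds as pruned h-maxima
#'
#' Regional maxima that persist after depth-`seed_h` suppression (computed
#' by morphological reconstruction of `f - seed_h` under `f`), reduced to
#' one voxel per maximum plateau (the plateau voxel first in lexicographic
#' (z, y, x) order), then greedily pruned so no two seeds lie within
#' `min_distance` µm — of a conflicting pair, the brighter survives, ties
#' resolved by the same lexicographic order.
#'
#' @param filtered band-passed [voxel_grid()].
#' @param seed_h h-maxima depth, intensity units.
#' @param min_distance µm.
#' @return Integer matrix of seed voxel indices (columns `i`, `j`, `k`,
#'   1-based), ordered by decreasing intensity.
#' @export
find_seeds <- function(filtered, seed_h, min_distance) {
  v <- as.double(filtered$values)
  dim(v) <- dim(filtered$values)
  d <- dim(v)
  rec <- .reconstruct_cpp(v - seed_h, v, d)
  lab <- .regional_maxima_cpp(rec, d)
  if (all(lab == 0L)) return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "k"))))
  # one representative voxel per plateau: first in lexicographic (z, y, x)
  pos <- which(lab != 0L)
  comp <- lab[pos]
  i <- (pos - 1L) %% d[1] + 1L
  j <- ((pos - 1L) %/% d[1]) %% d[2] + 1L
  k <- (pos - 1L) %/% (d[1] * d[2]) + 1L
  ord <- order(comp, k, j, i)
  first <- !duplicated(comp[ord])
  sel <- ord[first]
  seeds <- cbind(i = i[sel], j = j[sel], k = k[sel])
  val <- filtered$values[seeds]
  # brightness-descending, lexicographic (z,y,x) tie-break
  o <- order(-val, seeds[, 3], seeds[, 2], seeds[, 1])
  seeds <- seeds[o, , drop = FALSE]
  val <- val[o]
  # greedy min-distance pruning (physical metric)
  phys <- index_to_physical(filtered, seeds)
  keep <- logical(nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    kept <- which(keep)
    if (length(kept) == 0L) { keep[s] <- TRUE; next }
    d2 <- (phys[kept, 1] - phys[s, 1])^2 + (phys[kept, 2] - phys[s, 2])^2 +
          (phys[kept, 3] - phys[s, 3])^2
    keep[s] <- all(d2 >= min_distance^2)
  }
  seeds[keep, , drop = FALSE]
}

#' Marker-controlled watershed segmentation
#'
#' Floods `-filtered` from the seed markers, restricted to the foreground
#' mask `filtered > threshold` (6-connectivity); one label per seed. Seeds
#' falling outside the mask are dropped with a warning. Ties during flooding
#' are resolved first-queued-first-assigned, so results are deterministic.
#'
#' @param filtered band-passed [voxel_grid()].
#' @param seeds integer matrix (columns i, j, k; 1-based), e.g. from
#'   [find_seeds()].
#' @param threshold foreground threshold, intensity units.
#' @return List: `labels` (integer [voxel_grid()], 0 = background),
#'   `stats` data.frame with per-label `label`, `size_vox`,
#'   `sum_intensity`.
#' @export
watershed_cells <- function(filtered, seeds, threshold) {
  d <- dim(filtered$values)
  mask <- filtered$values > threshold
  if (nrow(seeds) > 0L) {
    lin0 <- (seeds[, 1] - 1L) + d[1] * ((seeds[, 2] - 1L) + d[2] * (seeds[, 3] - 1L))
    inmask <- mask[seeds]
    if (any(!inmask))
      warning(sum(!inmask), " seed(s) outside the foreground mask were dropped")
    lin0 <- lin0[inmask]
    kept_seed <- which(inmask)
  } else {
    lin0 <- integer(0)
    kept_seed <- integer(0)
  }
  v <- as.double(filtered$values)
  dim(v) <- d
  lab <- .watershed_cpp(v, d, as.integer(lin0), as.logical(mask))
  nlab <- length(lin0)
  if (nlab == 0L) {
    stats <- data.frame(label = integer(0), size_vox = integer(0),
                        sum_intensity = numeric(0))
  } else {
    lv <- as.vector(lab)
    sel <- lv != 0L
    size <- tabulate(lv[sel], nbins = nlab)
    sums <- as.vector(rowsum(as.double(filtered$values)[sel], lv[sel],
                             reorder = TRUE))
    # rowsum only covers labels that occur; expand
    occ <- sort(unique(lv[sel]))
    full <- numeric(nlab)
    full[occ] <- sums
    stats <- data.frame(label = seq_len(nlab), size_vox = size,
                        sum_intensity = full)
  }
  list(labels = voxel_grid(lab, filtered$spacing, filtered$origin),
       stats = stats, seed_rows = kept_seed)
}

#' Detect cells in a light-sheet stack
#'
#' The full intensity-based chain: background removal (grayscale opening),
#' difference-of-Gaussians band-pass, h-maxima seeds, marker-controlled
#' watershed, then size and intensity filtering. Cell positions are
#' intensity-weighted centroids of the watershed labels (weights from the
#' background-subtracted stack), reported in physical µm of stack space.
#'
#' @param stack a [voxel_grid()] (raw intensities).
#' @param params a [detection_params()].
#' @return A [cell_table()] (space `"stack"`) with columns `x`, `y`, `z`,
#'   `size_vox`, `intensity`.
#' @export
detect_cells <- function(stack, params) {
  validate_detection_params(params)
  bg <- remove_background(stack, params$background_radius)
  f <- dog_filter(bg, params$dog_sigma_small, params$dog_sigma_large)
  seeds <- find_seeds(f, params$seed_h, params$min_seed_distance)
  ws <- watershed_cells(f, seeds, params$watershed_threshold)
  st <- ws$stats
  lab <- ws$labels$values
  nlab <- nrow(st)
  if (nlab == 0L)
    return(cell_table(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                                 size_vox = integer(0), intensity = numeric(0)),
                      "stack"))
  # intensity-weighted centroids on the background-subtracted stack
  lv <- as.vector(lab)
  sel <- which(lv != 0L)
  w <- as.double(bg$values)[sel]
  g <- lv[sel]
  d <- dim(lab)
  i <- (sel - 1L) %% d[1] + 1L
  j <- ((sel - 1L) %/% d[1]) %% d[2] + 1L
  k <- (sel - 1L) %/% (d[1] * d[2]) + 1L
  wsum <- as.vector(rowsum(w, g))
  occ <- sort(unique(g))
  # fall back to unweighted centroid for labels with zero total weight
  zerow <- wsum <= 0
  if (any(zerow)) {
    cnt <- as.vector(rowsum(rep(1, length(g)), g))
    wfix <- w
    bad_labels <- occ[zerow]
    fixrows <- g %in% bad_labels
    wfix[fixrows] <- 1
    w <- wfix
    wsum <- as.vector(rowsum(w, g))
  }
  ci <- as.vector(rowsum(w * i, g)) / wsum
  cj <- as.vector(rowsum(w * j, g)) / wsum
  ck <- as.vector(rowsum(w * k, g)) / wsum
  cent <- matrix(NA_real_, nlab, 3)
  cent[occ, ] <- cbind(ci, cj, ck)
  phys <- index_to_physical(stack, cent)
  out <- data.frame(x = phys[, 1], y = phys[, 2], z = phys[, 3],
                    size_vox = st$size_vox, intensity = st$sum_intensity)
  keep <- st$size_vox >= params$size_min & st$size_vox <= params$size_max &
          st$sum_intensity >= params$intensity_min & is.finite(out$x)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  cell_table(out, "stack")
}
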