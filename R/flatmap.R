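#' Solve the cortical depth potential
#'
#' Discrete Laplace equation on the cortical mask (6-neighbor stencil,
#' anisotropic spacing) with Dirichlet boundaries phi = 0 on the pia mask
#' and phi = 1 on the white-matter mask; faces bordering none of the three
#' masks are insulating (zero flux). Solved by SOR iteration to a maximum
#' per-voxel residual below `tol`. The resulting harmonic potential is the
#' "streamlines" depth coordinate: following -grad(phi) from any cortical
#' point leads to the pia.
#'
#' @param cortex_mask,pia_mask,wm_mask disjoint logical arrays of one
#'   shape; pia and wm must be nonempty.
#' @param grid a [voxel_grid()] supplying spacing/origin (values unused),
#'   or a spacing vector.
#' @param tol maximum residual for convergence (default 1e-6).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual reached.
#' @return A `depth_field`: `phi` ([voxel_grid()], `NA` outside
#'   mask∪boundaries), `masks`, `iterations`, `residual`.
#' @export
solve_depth_field <- function(cortex_mask, pia_mask, wm_mask, grid,
                              tol = 1e-6, max_iter = 20000) {
  spacing <- if (is_voxel_grid(grid)) grid$spacing else as.numeric(grid)
  origin <- if (is_voxel_grid(grid)) grid$origin else c(0, 0, 0)
  d <- dim(cortex_mask)
  stopifnot(identical(dim(pia_mask), d), identical(dim(wm_mask), d))
  if (any(cortex_mask & (pia_mask | wm_mask)) || any(pia_mask & wm_mask))
    stop("cortex, pia and wm masks must be disjoint")
  if (!any(pia_mask) || !any(wm_mask)) stop("pia and wm masks must be nonempty")
  state <- array(0L, d)
  state[cortex_mask] <- 1L
  state[pia_mask] <- 2L
  state[wm_mask] <- 2L
  init <- array(0.5, d)
  init[pia_mask] <- 0
  init[wm_mask] <- 1
  init[state == 0L] <- 0
  omega <- 2 / (1 + sin(pi / (max(d) + 1)))
  sol <- .laplace_cpp(state, init, d, spacing, tol, as.integer(max_iter), omega)
  if (!sol$converged)
    stop(sprintf("Laplace solve did not converge in %d iterations (residual %.3g > tol %.3g)",
                 max_iter, sol$residual, tol))
  phi <- sol$phi
  phi[state == 0L] <- NA_real_
  structure(list(phi = voxel_grid(phi, spacing, origin),
                 masks = list(cortex = cortex_mask, pia = pia_mask, wm = wm_mask),
                 iterations = sol$iterations, residual = sol$residual,
                 tol = tol),
            class = "depth_field")
}

#' @export
print.depth_field <- function(x, ...) {
  cat(sprintf("<depth_field> %s voxels in cortex, converged to %.2g in %d iterations\n",
              format(sum(x$masks$cortex)), x$residual, x$iterations))
  invisible(x)
}

#' Flatmap parameterizations
#'
#' A parameterization maps a pia-surface voxel to 2D flatmap coordinates
#' (u, v). Two are built in:
#' * `shell_parameterization(center)`: for the toy hemispherical shell —
#'   u = azimuth (rad), v = polar angle from the +z axis (rad), measured
#'   about `center`.
#' * `slab_parameterization()`: for rectangular slabs — (u, v) = (x, y) µm.
#' A custom per-voxel lookup (e.g. an externally computed butterfly
#' projection) can be supplied as any `function(xyz_matrix) -> cbind(u, v)`.
#'
#' @param center dome center, µm.
#' @return A function mapping an n x 3 physical-coordinate matrix to an
#'   n x 2 matrix of (u, v).
#' @export
shell_parameterization <- function(center) {
  force(center)
  function(xyz) {
    dx <- xyz[, 1] - center[1]; dy <- xyz[, 2] - center[2]
    dz <- xyz[, 3] - center[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    cbind(u = atan2(dy, dx), v = acos(pmin(pmax(dz / pmax(r, 1e-12), -1), 1)))
  }
}

#' @rdname shell_parameterization
#' @export
slab_parameterization <- function() {
  function(xyz) cbind(u = xyz[, 1], v = xyz[, 2])
}

#' Project cortical cells onto the flatmap with a depth coordinate
#'
#' For each cell inside the cortical mask: `depth_frac` is the trilinear
#' interpolation of the potential at the cell position; the streamline to
#' the pia is traced by first-order Euler steps along the normalized
#' negative gradient (step `min(spacing)/2`) until the potential falls
#' below `eps`, giving `depth_um` (path length) and the pia endpoint whose
#' parameterization supplies `(u, v)`. Cells outside the cortex are
#' excluded (counted), and cells whose streamline leaves the mask are
#' flagged and excluded from depth statistics.
#'
#' @param cells [cell_table()] in atlas space.
#' @param depth_field a `depth_field` from [solve_depth_field()].
#' @param parameterization function mapping pia-point coordinates to
#'   (u, v); see [shell_parameterization()].
#' @param eps pia-proximity stop for streamlines (potential units).
#' @return A `flat_cell_table`: [cell_table()] in space `"flatmap"` with
#'   `u`, `v`, `depth_frac`, `depth_um`, `source_region_id` (when the
#'   input had `region_id`); attributes `n_outside_cortex`, `n_flagged`.
#' @export
project_cells <- function(cells, depth_field, parameterization, eps = 0.02) {
  check_space(cells, "atlas")
  phi <- depth_field$phi
  d <- dim(phi$values)
  inside_mask <- depth_field$masks$cortex | depth_field$masks$pia |
    depth_field$masks$wm
  n <- nrow(cells)
  if (n == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      u = numeric(0), v = numeric(0),
                      depth_frac = numeric(0), depth_um = numeric(0))
    fc <- cell_table(out, "flatmap")
    attr(fc, "n_outside_cortex") <- 0L
    attr(fc, "n_flagged") <- 0L
    return(fc)
  }
  xyz <- cell_xyz(cells)
  own <- owning_voxel(phi, xyz)
  inb <- !is.na(own[, 1])
  in_cortex <- inb
  in_cortex[inb] <- depth_field$masks$cortex[own[inb, , drop = FALSE]] |
    depth_field$masks$pia[own[inb, , drop = FALSE]] |
    depth_field$masks$wm[own[inb, , drop = FALSE]]
  n_outside <- sum(!in_cortex)
  sel <- which(in_cortex)
  # extend phi smoothly a few voxels outside the mask so interpolation and
  # gradients behave at the insulating boundary
  filled <- .fill_outside_cpp(ifelse(is.na(phi$values), 0, phi$values),
                              inside_mask, d, 4L)
  depth_frac <- rep(NA_real_, n)
  pf <- voxel_grid(filled, phi$spacing, phi$origin)
  depth_frac[sel] <- trilinear_interp(pf, xyz[sel, , drop = FALSE])
  depth_frac <- pmin(pmax(depth_frac, 0), 1)
  step <- min(phi$spacing) / 2
  tr <- .trace_streamlines_cpp(filled, inside_mask, d, phi$spacing, phi$origin,
                               xyz[sel, , drop = FALSE], step, eps,
                               as.integer(10 * max(d) * max(phi$spacing) / step))
  ok <- tr$status == 0L
  n_flagged <- sum(!ok)
  keep <- sel[ok]
  exit0 <- tr$exit_voxel0[ok]
  ei <- exit0 %% d[1] + 1L
  ej <- (exit0 %/% d[1]) %% d[2] + 1L
  ek <- exit0 %/% (d[1] * d[2]) + 1L
  pia_xyz <- index_to_physical(phi, cbind(ei, ej, ek))
  uv <- parameterization(pia_xyz)
  out <- data.frame(x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
                    u = uv[, 1], v = uv[, 2],
                    depth_frac = depth_frac[keep],
                    depth_um = tr$length_um[ok])
  if ("region_id" %in% names(cells)) out$source_region_id <- cells$region_id[keep]
  if ("sample" %in% names(cells)) out$sample <- cells$sample[keep]
  rownames(out) <- NULL
  fc <- cell_table(out, "flatmap")
  class(fc) <- c("flat_cell_table", class(fc))
  attr(fc, "n_outside_cortex") <- n_outside
  attr(fc, "n_flagged") <- n_flagged
  fc
}

#' 2D flatmap heatmap of projected cells
#'
#' Histogram of (u, v) within a depth window, optionally Gaussian-smoothed
#' in bin units. Depth windows select the whole cortex or a band of
#' `depth_frac` standing in for cortical layers. Normalizations: `"none"`
#' (counts), `"per_total"` (divides by the cells in scope so the
#' unsmoothed map sums to 1), or `"joint_minmax"` applied afterwards across
#' a set of maps via [joint_minmax_scale()].
#'
#' @param flat_cells a `flat_cell_table`.
#' @param u_breaks,v_breaks bin edge vectors (length nbins+1).
#' @param depth_window `c(lo, hi)` band on `depth_frac` (half-open), or
#'   `NULL` for all depths.
#' @param smooth_sigma_bins Gaussian sigma in bins (0 = none).
#' @param normalization `"none"` or `"per_total"`.
#' @return A `flat_heatmap`: `counts` matrix (u x v), bin edges, window,
#'   `n_in_scope`.
#' @export
flat_heatmap <- function(flat_cells, u_breaks, v_breaks, depth_window = NULL,
                         smooth_sigma_bins = 0,
                         normalization = c("none", "per_total")) {
  normalization <- match.arg(normalization)
  df <- as.data.frame(flat_cells)
  if (!is.null(depth_window))
    df <- df[df$depth_frac >= depth_window[1] & df$depth_frac < depth_window[2], ,
             drop = FALSE]
  inside <- df$u >= u_breaks[1] & df$u <= u_breaks[length(u_breaks)] &
    df$v >= v_breaks[1] & df$v <= v_breaks[length(v_breaks)]
  df <- df[inside, , drop = FALSE]
  if (nrow(df) == 0L) warning("flat_heatmap: empty selection, all-zero map")
  ui <- pmin(findInterval(df$u, u_breaks, rightmost.closed = TRUE),
             length(u_breaks) - 1L)
  vi <- pmin(findInterval(df$v, v_breaks, rightmost.closed = TRUE),
             length(v_breaks) - 1L)
  nu <- length(u_breaks) - 1L; nv <- length(v_breaks) - 1L
  counts <- matrix(tabulate(ui + nu * (vi - 1L), nbins = nu * nv), nu, nv)
  if (smooth_sigma_bins > 0) {
    arr <- array(counts, c(nu, nv, 1L))
    sm <- .gaussian3d_cpp(arr, dim(arr), c(smooth_sigma_bins, smooth_sigma_bins, 0), 1L)
    counts <- matrix(sm, nu, nv)
  }
  n_in <- nrow(df)
  if (normalization == "per_total" && n_in > 0) counts <- counts / n_in
  structure(list(counts = counts, u_breaks = u_breaks, v_breaks = v_breaks,
                 depth_window = depth_window, n_in_scope = n_in,
                 normalization = normalization),
            class = "flat_heatmap")
}

#' Scale a set of flat heatmaps to a shared min/max
#'
#' Joint min-max scaling maps the global minimum over all maps to 0 and the
#' global maximum to 1, so densities are directly comparable across
#' datasets.
#'
#' @param heatmaps list of `flat_heatmap`s.
#' @return The list with scaled `counts`.
#' @export
joint_minmax_scale <- function(heatmaps) {
  lo <- min(vapply(heatmaps, function(h) min(h$counts), numeric(1)))
  hi <- max(vapply(heatmaps, function(h) max(h$counts), numeric(1)))
  if (hi <= lo) stop("joint min/max scaling needs a nonzero range")
  lapply(heatmaps, function(h) {
    h$counts <- (h$counts - lo) / (hi - lo)
    h$normalization <- "joint_minmax"
    h
  })
}

#' Cortical depth profile
#'
#' Histogram of streamline depth (`depth_um`, measured from the pial
#' surface) divided by the bin width: normalized cell density in cells/µm
#' of depth. Optionally scoped to one source region (with its descendants)
#' and/or computed per sample with the across-sample mean attached.
#'
#' @param flat_cells a `flat_cell_table`.
#' @param bin_width_um depth bin width, µm (> 0).
#' @param max_depth_um histogram upper edge; default the deepest cell,
#'   rounded up to a bin.
#' @param scope_region optional region id(s); with `ontology`, an acronym
#'   whose descendants are included.
#' @param ontology optional [region_ontology()] for acronym scoping.
#' @param per_sample split by the `sample` column? Default `FALSE`.
#' @return A `depth_profile`: `breaks` (µm), per-bin `density` (n/µm;
#'   matrix bins x samples when `per_sample`), `mean_density`, `n_cells`.
#'   `sum(density * bin_width)` equals the cell count in scope exactly
#'   (per sample).
#' @export
depth_profile <- function(flat_cells, bin_width_um, max_depth_um = NULL,
                          scope_region = NULL, ontology = NULL,
                          per_sample = FALSE) {
  if (bin_width_um <= 0) stop("bin_width_um must be > 0")
  df <- as.data.frame(flat_cells)
  if (!is.null(scope_region)) {
    if (!"source_region_id" %in% names(df))
      stop("cells carry no source_region_id; cannot scope by region")
    ids <- if (!is.null(ontology))
      unlist(lapply(scope_region, function(r) descendants(ontology, r, include_self = TRUE)))
    else as.integer(scope_region)
    df <- df[df$source_region_id %in% ids, , drop = FALSE]
  }
  if (is.null(max_depth_um))
    max_depth_um <- if (nrow(df) == 0L) bin_width_um
                    else bin_width_um * ceiling(max(df$depth_um) / bin_width_um + 1e-12)
  breaks <- seq(0, max_depth_um, by = bin_width_um)
  if (breaks[length(breaks)] < max_depth_um)
    breaks <- c(breaks, breaks[length(breaks)] + bin_width_um)
  nb <- length(breaks) - 1L
  histo <- function(depths) {
    bi <- pmin(pmax(findInterval(depths, breaks, rightmost.closed = TRUE), 1L), nb)
    tabulate(bi, nbins = nb) / bin_width_um
  }
  if (per_sample) {
    if (!"sample" %in% names(df)) stop("per_sample profile needs a `sample` column")
    samples <- sort(unique(df$sample))
    dens <- vapply(samples, function(s) histo(df$depth_um[df$sample == s]),
                   numeric(nb))
    dens <- matrix(dens, nrow = nb,
                   dimnames = list(NULL, as.character(samples)))
    mean_density <- rowMeans(dens)
  } else {
    dens <- histo(df$depth_um)
    mean_density <- dens
  }
  structure(list(breaks = breaks, density = dens, mean_density = mean_density,
                 bin_width_um = bin_width_um, n_cells = nrow(df)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %d cells, %d bins of %g um\n",
              x$n_cells, length(x$breaks) - 1L, x$bin_width_um))
  invisible(x)
}
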