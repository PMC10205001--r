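#' Emit a complete synthetic dataset to disk
#'
#' Generates a toy atlas, plants cells at the given region densities,
#' renders a noisy stack under a known stack-to-atlas warp, simulates
#' clicked landmarks for that warp, and writes everything in the formats
#' the pipeline consumes: `atlas.nrrd`, `ontology.json`, a `stack/` TIFF
#' series, `truth_cells.csv` (atlas space, with true region ids),
#' `cells_stack_truth.csv` (the same cells pulled back to stack space),
#' `landmarks.csv` (BigWarp dialect) and `truth_warp.json`. The output is a
#' self-contained end-to-end fixture with exactly known ground truth.
#'
#' @param out_dir output directory (created if missing).
#' @param spec a [toy_atlas_spec()].
#' @param densities named numeric, cells/mm^3 by region id; default plants
#'   distinct densities in two cortical leaves.
#' @param warp stack -> atlas point transform; default a modest
#'   scale+translation affine.
#' @param n_landmarks,jitter_sd landmark simulation settings.
#' @param seed RNG seed for all stochastic steps.
#' @param noise noise model for [render_stack()]; `NULL` disables noise.
#' @param stack_spacing µm/voxel of the rendered stack; default the atlas
#'   spacing. Light-sheet stacks are normally acquired much finer than the
#'   atlas, so set e.g. `c(3, 3, 3)` for a realistic detection exercise.
#' @return List with the in-memory objects (`atlas`, `planted`, `stack`,
#'   `landmarks`, `warp`, `paths`).
#' @export
simulate_dataset <- function(out_dir, spec = toy_atlas_spec(),
                             densities = NULL,
                             warp = NULL, n_landmarks = 12, jitter_sd = 0,
                             seed = 1, noise = list(poisson = TRUE, read_sd = 2),
                             stack_spacing = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  atlas <- make_toy_atlas(spec)
  if (is.null(densities)) {
    leaves <- c(toy_leaf_id(1, 2), toy_leaf_id(2, 2))
    densities <- stats::setNames(c(5000, 500), leaves)
  }
  if (is.null(warp)) {
    warp <- affine_transform(cbind(diag(c(1.05, 1.0, 0.95)), c(20, -15, 10)),
                             from = "stack", to = "atlas")
  }
  planted <- plant_cells(atlas$annotation, densities, seed = seed)
  ann_dim <- dim(atlas$annotation$values)
  sp <- atlas$annotation$spacing
  # stack grid covers the warped-back atlas bounding box
  corners <- as.matrix(expand.grid(x = c(0, (ann_dim[1] - 1) * sp[1]),
                                   y = c(0, (ann_dim[2] - 1) * sp[2]),
                                   z = c(0, (ann_dim[3] - 1) * sp[3])))
  back <- apply_transform(invert_transform(warp), corners)
  sps <- if (is.null(stack_spacing)) sp else rep(as.numeric(stack_spacing), length.out = 3)
  lo <- apply(back, 2, min) - 2 * sps
  hi <- apply(back, 2, max) + 2 * sps
  grid_spec <- list(dims = ceiling((hi - lo) / sps) + 1, spacing = sps, origin = lo)
  stack <- render_stack(planted, grid_spec, warp = warp, noise = noise,
                        seed = seed + 1L)
  landmarks <- make_landmarks(warp, n_landmarks, jitter_sd = jitter_sd,
                              seed = seed + 2L,
                              domain = list(grid = atlas$annotation,
                                            mask = atlas$masks$brain))
  paths <- list(
    annotation = file.path(out_dir, "atlas.nrrd"),
    ontology = file.path(out_dir, "ontology.json"),
    stack = file.path(out_dir, "stack"),
    truth_cells = file.path(out_dir, "truth_cells.csv"),
    truth_cells_stack = file.path(out_dir, "cells_stack_truth.csv"),
    landmarks = file.path(out_dir, "landmarks.csv"),
    truth_warp = file.path(out_dir, "truth_warp.json"))
  write_volume(atlas$annotation, paths$annotation)
  write_ontology(atlas$ontology, paths$ontology)
  write_volume(stack, paths$stack, format = "tiff_series")
  write_cell_csv(planted, paths$truth_cells)
  stack_cells <- apply_transform(invert_transform(warp), planted)
  write_cell_csv(stack_cells, paths$truth_cells_stack)
  write_bigwarp_landmarks(landmarks, paths$landmarks)
  write_transform(warp, paths$truth_warp)
  list(atlas = atlas, planted = planted, stack = stack,
       landmarks = landmarks, warp = warp, grid_spec = grid_spec,
       paths = paths)
}
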