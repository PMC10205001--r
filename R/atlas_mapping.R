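#' Assign atlas-space cells to annotation regions
#'
#' Each cell gets the label of the voxel that owns its position under the
#' half-open ownership rule (`[center - spacing/2, center + spacing/2)` per
#' axis) — nearest-voxel lookup with no interpolation, since labels are
#' categorical. Cells outside the volume, or in background voxels, get
#' `region_id = 0`; they are kept in the table (unassigned cells are a QC
#' signal for bad registration, never silently dropped).
#'
#' @param cells a [cell_table()] in space `"atlas"`.
#' @param annotation integer [voxel_grid()].
#' @param exclude_regions optional integer ids (or acronyms, with
#'   `ontology`) whose labels — including all descendants — are zeroed
#'   before assignment, e.g. to mask out a structure that saturated the
#'   detector.
#' @param ontology needed only to resolve acronyms / descendants of
#'   `exclude_regions`.
#' @return The cell table with a `region_id` column.
#' @export
assign_regions <- function(cells, annotation, exclude_regions = NULL,
                           ontology = NULL) {
  check_space(cells, "atlas")
  stopifnot(is_voxel_grid(annotation))
  ann <- annotation$values
  if (!is.null(exclude_regions)) {
    if (is.null(ontology))
      stop("exclude_regions requires `ontology`")
    drop_ids <- unlist(lapply(exclude_regions, function(r)
      descendants(ontology, r, include_self = TRUE)))
    ann[ann %in% drop_ids] <- 0L
  }
  out <- as.data.frame(cells)
  if (nrow(out) == 0L) {
    out$region_id <- integer(0)
    return(cell_table(out, "atlas"))
  }
  idx <- owning_voxel(annotation, cell_xyz(cells))
  rid <- rep(0L, nrow(out))
  inb <- !is.na(idx[, 1])
  rid[inb] <- ann[idx[inb, , drop = FALSE]]
  out$region_id <- as.integer(rid)
  cell_table(out, "atlas")
}

#' Aggregate assigned cells into a hierarchical region table
#'
#' Counts cells per region and rolls them up the ontology:
#' `n_cells_direct` counts cells in voxels labeled exactly this id,
#' `n_cells_total` adds every descendant's total, and volumes come from the
#' annotation voxel counts (µm^3 -> mm^3). `density_total` is total cells
#' over total (self + descendant) volume — cells/mm^3 — which for a merged
#' region is *not* the mean of its children's densities. Unassigned cells
#' (`region_id` 0) get their own row.
#'
#' @param cells [cell_table()] with a `region_id` column.
#' @param ontology a [region_ontology()].
#' @param annotation integer [voxel_grid()] (for volumes).
#' @param all_regions keep regions with zero cells and zero volume?
#'   Default `FALSE`.
#' @return A `region_table` data.frame: `id`, `acronym`, `name`, `depth`,
#'   `n_cells_direct`, `n_cells_total`, `volume_mm3` (direct-labeled),
#'   `volume_total_mm3`, `density_total` (cells/mm^3), plus the unassigned
#'   row (id 0).
#' @export
aggregate_counts <- function(cells, ontology, annotation, all_regions = FALSE) {
  if (!"region_id" %in% names(cells))
    stop("cells have no region_id column; run assign_regions() first")
  ids <- ontology$nodes$id
  unknown <- setdiff(unique(cells$region_id), c(0L, ids))
  if (length(unknown) > 0)
    stop("cells assigned to region id(s) missing from the ontology: ",
         paste(unknown, collapse = ", "))
  direct <- table(factor(cells$region_id, levels = ids))
  direct <- as.integer(direct)
  vox_mm3 <- voxel_volume_um3(annotation) * 1e-9
  labcount <- table(factor(as.vector(annotation$values), levels = ids))
  vol_direct <- as.numeric(labcount) * vox_mm3
  # post-order accumulation: children before parents (deeper first)
  nodes <- ontology$nodes
  total <- direct
  vol_total <- vol_direct
  ord <- order(nodes$depth, decreasing = TRUE)
  pos <- stats::setNames(seq_along(ids), ids)
  for (r in ord) {
    p <- nodes$parent_id[r]
    if (is.na(p)) next
    pi <- pos[[as.character(p)]]
    total[pi] <- total[pi] + total[r]
    vol_total[pi] <- vol_total[pi] + vol_total[r]
  }
  out <- data.frame(id = ids, acronym = nodes$acronym, name = nodes$name,
                    depth = nodes$depth,
                    n_cells_direct = direct, n_cells_total = total,
                    volume_mm3 = vol_direct, volume_total_mm3 = vol_total,
                    density_total = ifelse(vol_total > 0, total / vol_total, NA_real_),
                    stringsAsFactors = FALSE)
  n_unassigned <- sum(cells$region_id == 0L)
  out <- rbind(data.frame(id = 0L, acronym = "unassigned", name = "unassigned",
                          depth = NA_integer_,
                          n_cells_direct = n_unassigned,
                          n_cells_total = n_unassigned,
                          volume_mm3 = NA_real_, volume_total_mm3 = NA_real_,
                          density_total = NA_real_, stringsAsFactors = FALSE),
               out)
  if (!all_regions)
    out <- out[out$id == 0L | out$n_cells_total > 0 | out$volume_total_mm3 > 0, ,
               drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_table", "data.frame")
  out
}

#' Map cells between reference spaces with a bridge transform
#'
#' Applies a pre-computed bridge (e.g. one published between two reference
#' atlas generations) to the cell coordinates and renames the space tag.
#'
#' @param cells a [cell_table()].
#' @param bridge_transform a point transform whose `from` tag matches the
#'   cells' space (when set); default identity (tag rename only).
#' @param to_space target space tag when the bridge carries none.
#' @return The cell table in the target space.
#' @export
bridge_spaces <- function(cells, bridge_transform = NULL, to_space = NULL) {
  if (is.null(bridge_transform))
    bridge_transform <- identity_transform(from = cell_space(cells),
                                           to = to_space %||% cell_space(cells))
  if (is.null(bridge_transform$to) && !is.null(to_space))
    bridge_transform$to <- to_space
  apply_transform(bridge_transform, cells)
}

#' Write a region table to CSV
#' @param region_table result of [aggregate_counts()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(region_table, path) {
  utils::write.csv(as.data.frame(region_table), path, row.names = FALSE)
  invisible(path)
}
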