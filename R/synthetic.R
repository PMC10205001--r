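#' Toy atlas specification
#'
#' The synthetic reference brain is a hemispherical cortical shell (a dome
#' over the z >= 0 plane): the shell between `inner_radius` and
#' `outer_radius` plays the cortex, partitioned into `n_angular_sectors`
#' azimuthal "areas" times `n_layers` radial "layers"; optional spherical
#' blobs inside the cavity play subcortical nuclei. The geometry is chosen
#' so the cortical depth field has a closed-form answer (harmonic radial
#' potential), which the flatmap tests exploit.
#'
#' @param outer_radius,inner_radius shell radii, µm (`inner < outer`).
#' @param n_angular_sectors number of azimuthal cortical "areas" (>= 1).
#' @param n_layers number of radial "layers" (>= 1).
#' @param subcortical_blobs list of `list(center = c(x,y,z) µm relative to
#'   the dome center, radius = µm, label = id)` spheres; must not overlap
#'   the shell.
#' @param spacing voxel spacing, µm (scalar or length-3).
#' @return A `toy_atlas_spec`.
#' @export
toy_atlas_spec <- function(outer_radius = 400, inner_radius = 250,
                           n_angular_sectors = 4, n_layers = 3,
                           subcortical_blobs = list(), spacing = 10) {
  if (inner_radius >= outer_radius) stop("inner_radius must be < outer_radius")
  if (n_angular_sectors < 1 || n_layers < 1) stop("sectors and layers must be >= 1")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  structure(list(outer_radius = outer_radius, inner_radius = inner_radius,
                 n_angular_sectors = as.integer(n_angular_sectors),
                 n_layers = as.integer(n_layers),
                 subcortical_blobs = subcortical_blobs,
                 spacing = as.numeric(spacing)),
            class = "toy_atlas_spec")
}

# id scheme for generated regions
TOY_ROOT_ID <- 997L
TOY_ISOCORTEX_ID <- 315L
TOY_SUBCORTEX_ID <- 8000L
toy_sector_id <- function(s) 2000L + as.integer(s)
toy_leaf_id <- function(s, l) 10000L + 100L * as.integer(s) + as.integer(l)

#' Generate a toy annotation volume, ontology and cortical masks
#'
#' Builds the hemispherical-shell atlas of a [toy_atlas_spec()]: an integer
#' annotation volume whose shell voxels carry sector-by-layer leaf labels
#' (layer 1 outermost), an ontology with the leaves under sector parents
#' under an "Isocortex" node (blobs under "Subcortex"), plus the mask trio
#' the depth-field solver consumes: `pia` (outermost shell voxel layer),
#' `wm` (innermost layer) and `cortex` (shell minus both boundary layers).
#' `brain` is the full dome (shell + cavity), used as the sampling domain
#' for landmarks and planted cells.
#'
#' @param spec a [toy_atlas_spec()].
#' @return List: `annotation` ([voxel_grid()], integer), `ontology`
#'   ([region_ontology()]), `masks` (list of logical arrays `cortex`,
#'   `pia`, `wm`, `brain`, `shell`), `center` (dome center, µm).
#' @export
make_toy_atlas <- function(spec) {
  stopifnot(inherits(spec, "toy_atlas_spec"))
  s <- spec$spacing
  Ro <- spec$outer_radius; Ri <- spec$inner_radius
  pad <- 2 * s
  nx <- ceiling((2 * Ro + 2 * pad[1]) / s[1])
  ny <- ceiling((2 * Ro + 2 * pad[2]) / s[2])
  nz <- ceiling((Ro + 2 * pad[3]) / s[3])
  grid <- voxel_grid(array(0L, c(nx, ny, nz)), s, c(0, 0, 0))
  cx <- (nx - 1) / 2 * s[1]
  cy <- (ny - 1) / 2 * s[2]
  cz <- pad[3]
  center <- c(cx, cy, cz)
  xs <- (seq_len(nx) - 1) * s[1] - cx
  ys <- (seq_len(ny) - 1) * s[2] - cy
  zs <- (seq_len(nz) - 1) * s[3] - cz
  dx2 <- array(rep(xs^2, times = ny * nz), c(nx, ny, nz))
  dy2 <- aperm(array(rep(ys^2, times = nx * nz), c(ny, nx, nz)), c(2, 1, 3))
  dz2 <- aperm(array(rep(zs^2, times = nx * ny), c(nz, nx, ny)), c(2, 3, 1))
  zpos <- aperm(array(rep(zs, times = nx * ny), c(nz, nx, ny)), c(2, 3, 1))
  r <- sqrt(dx2 + dy2 + dz2)
  dome <- zpos >= 0
  shell <- dome & r >= Ri & r <= Ro
  brain <- dome & r <= Ro
  # sector = azimuth bin, layer = radial bin (1 = outermost)
  xpos <- array(rep(xs, times = ny * nz), c(nx, ny, nz))
  ypos <- aperm(array(rep(ys, times = nx * nz), c(ny, nx, nz)), c(2, 1, 3))
  az <- atan2(ypos, xpos)            # (-pi, pi]
  sec <- pmin(floor((az + pi) / (2 * pi) * spec$n_angular_sectors) + 1L,
              spec$n_angular_sectors)
  lay <- pmin(floor((Ro - r) / (Ro - Ri) * spec$n_layers) + 1L, spec$n_layers)
  ann <- array(0L, c(nx, ny, nz))
  ann[shell] <- toy_leaf_id(sec[shell], lay[shell])
  # subcortical blobs
  nodes <- data.frame(id = c(TOY_ROOT_ID, TOY_ISOCORTEX_ID),
                      acronym = c("root", "Isocortex"),
                      name = c("root", "Isocortex"),
                      parent_id = c(NA_integer_, TOY_ROOT_ID),
                      stringsAsFactors = FALSE)
  for (sct in seq_len(spec$n_angular_sectors)) {
    nodes <- rbind(nodes, data.frame(
      id = toy_sector_id(sct), acronym = sprintf("SEC%d", sct),
      name = sprintf("Cortical sector %d", sct),
      parent_id = TOY_ISOCORTEX_ID, stringsAsFactors = FALSE))
    for (l in seq_len(spec$n_layers)) {
      nodes <- rbind(nodes, data.frame(
        id = toy_leaf_id(sct, l), acronym = sprintf("SEC%dL%d", sct, l),
        name = sprintf("Cortical sector %d, layer %d", sct, l),
        parent_id = toy_sector_id(sct), stringsAsFactors = FALSE))
    }
  }
  if (length(spec$subcortical_blobs) > 0) {
    nodes <- rbind(nodes, data.frame(
      id = TOY_SUBCORTEX_ID, acronym = "SUB", name = "Subcortex",
      parent_id = TOY_ROOT_ID, stringsAsFactors = FALSE))
    for (b in spec$subcortical_blobs) {
      bc <- b$center
      bm <- (sqrt((xpos - bc[1])^2 + (ypos - bc[2])^2 + (zpos - bc[3])^2)
             <= b$radius) & dome
      if (any(bm & shell))
        stop("subcortical blob with label ", b$label, " overlaps the cortical shell")
      ann[bm] <- as.integer(b$label)
      nodes <- rbind(nodes, data.frame(
        id = as.integer(b$label), acronym = sprintf("BLOB%d", b$label),
        name = sprintf("Subcortical blob %d", b$label),
        parent_id = TOY_SUBCORTEX_ID, stringsAsFactors = FALSE))
    }
  }
  ontology <- region_ontology(nodes)
  smax <- max(s)
  pia <- shell & (r > Ro - smax)
  wm <- shell & (r < Ri + smax)
  cortex <- shell & !pia & !wm
  annotation <- voxel_grid(ann, s, c(0, 0, 0))
  validate_annotation(annotation, ontology)
  list(annotation = annotation, ontology = ontology,
       masks = list(cortex = cortex, pia = pia, wm = wm,
                    brain = brain, shell = shell),
       center = center)
}

#' Rectangular-slab cortex masks
#'
#' A flat cortical slab with pia at the z = 0 face and white matter at the
#' deep face: the Laplace depth potential on it is exactly linear in z,
#' which gives the flatmap module an analytic ground truth. The (u, v)
#' parameterization of the slab is simply (x, y).
#'
#' @param nx,ny lateral voxel counts.
#' @param nz through-thickness voxel count (including the two boundary
#'   layers).
#' @param spacing µm (scalar or length-3).
#' @return List: `grid` (zero [voxel_grid()] of the slab shape), `masks`
#'   (logical arrays `cortex`, `pia`, `wm`), `thickness_um` (pia-face
#'   center to wm-face center distance).
#' @export
make_slab_masks <- function(nx = 24, ny = 24, nz = 30, spacing = 10) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  if (nz < 3) stop("slab needs at least 3 planes")
  dims <- c(nx, ny, nz)
  pia <- array(FALSE, dims); pia[, , 1] <- TRUE
  wm <- array(FALSE, dims); wm[, , nz] <- TRUE
  cortex <- array(TRUE, dims) & !pia & !wm
  list(grid = voxel_grid(array(0, dims), spacing, c(0, 0, 0)),
       masks = list(cortex = cortex, pia = pia, wm = wm),
       thickness_um = (nz - 1) * spacing[3])
}

#' Plant ground-truth cells at specified region densities
#'
#' Homogeneous Poisson placement: for each region id in
#' `densities_per_region` the cell count is drawn as
#' `Poisson(density * region volume)` and the cells are placed uniformly
#' inside the region's voxels. The true region id, per-cell amplitude and
#' Gaussian radius are recorded, so detection and mapping accuracy can be
#' scored exactly.
#'
#' @param annotation integer [voxel_grid()] atlas labels.
#' @param densities_per_region named numeric vector, cells/mm^3, names =
#'   region ids present in the annotation.
#' @param seed RNG seed (every stochastic call in the package takes one
#'   explicitly).
#' @param amplitude per-cell peak amplitude over background, intensity
#'   units. The default gives peak SNR ~8 over the default background of
#'   [render_stack()].
#' @param sigma_um per-cell Gaussian radius, µm.
#' @return A [cell_table()] in space `"atlas"` with columns `x,y,z`,
#'   `amplitude`, `sigma_um`, `true_region_id`.
#' @export
plant_cells <- function(annotation, densities_per_region, seed,
                        amplitude = 82, sigma_um = 5) {
  stopifnot(is_voxel_grid(annotation))
  ids <- as.integer(names(densities_per_region))
  if (any(is.na(ids))) stop("densities_per_region must be named by region id")
  present <- unique(as.vector(annotation$values))
  missing <- setdiff(ids, present)
  if (length(missing) > 0)
    stop("density given for region id(s) absent from the annotation: ",
         paste(missing, collapse = ", "))
  set.seed(seed)
  vox_mm3 <- voxel_volume_um3(annotation) * 1e-9
  d <- dim(annotation$values)
  rows <- list()
  for (t in seq_along(ids)) {
    dens <- as.numeric(densities_per_region[t])
    if (dens < 0) stop("densities must be >= 0")
    vox <- which(annotation$values == ids[t])
    lambda <- dens * length(vox) * vox_mm3
    nct <- stats::rpois(1, lambda)
    if (nct == 0) next
    pick <- vox[sample.int(length(vox), nct, replace = TRUE)]
    i <- (pick - 1L) %% d[1] + 1L
    j <- ((pick - 1L) %/% d[1]) %% d[2] + 1L
    k <- (pick - 1L) %/% (d[1] * d[2]) + 1L
    jit <- matrix(stats::runif(3 * nct, -0.5, 0.5), ncol = 3)
    phys <- index_to_physical(annotation, cbind(i, j, k) + jit)
    rows[[length(rows) + 1L]] <- data.frame(
      x = phys[, 1], y = phys[, 2], z = phys[, 3],
      amplitude = amplitude, sigma_um = sigma_um,
      true_region_id = ids[t])
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        amplitude = numeric(0), sigma_um = numeric(0),
                        true_region_id = integer(0))
  rownames(df) <- NULL
  cell_table(df, "atlas")
}

#' Render a synthetic light-sheet stack from planted cells
#'
#' Each cell becomes a 3D Gaussian of its amplitude and radius; the
#' expected image is `background + sum(cells)`, after which Poisson photon
#' noise and Gaussian read noise are applied. The stack lives in its own
#' "stack" space related to atlas space by `warp` (stack -> atlas), so the
#' registration stage has a known ground-truth transform to recover.
#'
#' @param planted a [cell_table()] from [plant_cells()] (atlas space).
#' @param grid_spec list `dims` (length-3), `spacing` (µm), `origin` (µm)
#'   describing the stack voxel grid in stack space.
#' @param warp a point transform mapping stack -> atlas coordinates;
#'   default identity. Must be invertible (cells are placed by pulling
#'   their atlas positions back to stack space).
#' @param background list `constant` (counts) and `gradient` (length-3,
#'   counts/µm linear shading); default constant 100, gradient
#'   `c(0.02, 0, 0)`.
#' @param noise list `poisson` (logical) and `read_sd` (counts); default
#'   Poisson on, read_sd 2. Use `NULL` for a noise-free stack.
#' @param seed RNG seed (used only when noise is enabled).
#' @return A [voxel_grid()] stack.
#' @export
render_stack <- function(planted, grid_spec, warp = identity_transform("stack", "atlas"),
                         background = list(constant = 100, gradient = c(0.02, 0, 0)),
                         noise = list(poisson = TRUE, read_sd = 2), seed = 1) {
  check_space(planted, "atlas")
  dims <- as.integer(grid_spec$dims)
  spacing <- as.numeric(grid_spec$spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  origin <- as.numeric(grid_spec$origin %||% c(0, 0, 0))
  grid <- voxel_grid(array(0, dims), spacing, origin)
  if (nrow(planted) > 0 && any(planted$sigma_um < max(spacing) / 2))
    warning("some cells have sigma below spacing/2: undersampled rendering")
  # background field
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  bgc <- background$constant %||% 0
  g <- background$gradient %||% c(0, 0, 0)
  img <- array(bgc, dims) +
    outer(outer(xs * g[1], ys * g[2], `+`), zs * g[3], `+`)
  if (nrow(planted) > 0) {
    stack_pos <- apply_transform(invert_transform(warp), cell_xyz(planted))
    for (c_i in seq_len(nrow(planted))) {
      p <- stack_pos[c_i, ]
      A <- planted$amplitude[c_i]
      sg <- planted$sigma_um[c_i]
      lo <- pmax(floor((p - 4 * sg - origin) / spacing) + 1, 1)
      hi <- pmin(ceiling((p + 4 * sg - origin) / spacing) + 1, dims)
      if (any(lo > hi)) next
      ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
      ex <- exp(-((xs[ix] - p[1])^2) / (2 * sg^2))
      ey <- exp(-((ys[iy] - p[2])^2) / (2 * sg^2))
      ez <- exp(-((zs[iz] - p[3])^2) / (2 * sg^2))
      img[ix, iy, iz] <- c(img[ix, iy, iz]) + c(A * outer(outer(ex, ey), ez))
    }
  }
  if (!is.null(noise)) {
    set.seed(seed)
    if (isTRUE(noise$poisson)) {
      img[] <- stats::rpois(length(img), pmax(img, 0))
    }
    rsd <- noise$read_sd %||% 0
    if (rsd > 0) img[] <- img + stats::rnorm(length(img), 0, rsd)
  }
  voxel_grid(img, spacing, origin)
}

#' Simulate clicked landmarks for a known warp
#'
#' Samples `n` moving points inside the brain (stack space, i.e. the known
#' warp's domain), sets `fixed = warp(moving) + N(0, jitter_sd)` per axis to
#' emulate human clicking error, and rejects coplanar/collinear moving
#' configurations so downstream fits are well posed.
#'
#' @param true_warp point transform, stack -> atlas.
#' @param n number of landmarks (>= 4).
#' @param jitter_sd per-axis Gaussian clicking error, µm.
#' @param seed RNG seed.
#' @param domain list with `grid` (atlas [voxel_grid()]) and `mask`
#'   (logical array): the atlas-space region to sample within (e.g.
#'   `masks$brain` of [make_toy_atlas()]).
#' @return A [landmark_set()] (all active).
#' @export
make_landmarks <- function(true_warp, n, jitter_sd = 0, seed = 1, domain) {
  if (n < 4) stop("need at least 4 landmarks for any fit")
  set.seed(seed)
  vox <- which(domain$mask)
  d <- dim(domain$mask)
  inv <- invert_transform(true_warp)
  for (try in 1:1000) {
    pick <- vox[sample.int(length(vox), n, replace = FALSE)]
    i <- (pick - 1L) %% d[1] + 1L
    j <- ((pick - 1L) %/% d[1]) %% d[2] + 1L
    k <- (pick - 1L) %/% (d[1] * d[2]) + 1L
    atlas_pts <- index_to_physical(domain$grid, cbind(i, j, k))
    moving <- apply_transform(inv, atlas_pts)
    ctr <- scale(moving, scale = FALSE)
    if (min(svd(ctr)$d) > 1e-6 * max(svd(ctr)$d + 1e-300)) break
    if (try == 1000) stop("could not find a non-coplanar landmark set in 1000 tries")
  }
  fixed <- apply_transform(true_warp, moving)
  if (jitter_sd > 0)
    fixed <- fixed + matrix(stats::rnorm(3 * n, 0, jitter_sd), ncol = 3)
  landmark_set(data.frame(name = sprintf("Pt-%d", seq_len(n) - 1L),
                          active = TRUE,
                          mx = moving[, 1], my = moving[, 2], mz = moving[, 3],
                          fx = fixed[, 1], fy = fixed[, 2], fz = fixed[, 3]))
}
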