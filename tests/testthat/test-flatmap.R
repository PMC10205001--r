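test_that("slab potential is linear through the thickness; boundaries exact", {
  sl <- fixture_slab()
  f <- sl$field
  nz <- dim(f$phi$values)[3]
  expect_true(all(f$phi$values[, , 1] == 0))
  expect_true(all(f$phi$values[, , nz] == 1))
  lin <- (seq_len(nz) - 1) / (nz - 1)
  dev <- vapply(seq_len(nz), function(k)
    max(abs(f$phi$values[, , k] - lin[k])), numeric(1))
  expect_lt(max(dev), 1e-3)
  # maximum principle: interior values strictly inside [0, 1]
  interior <- f$phi$values[, , 2:(nz - 1)]
  expect_true(all(interior > -1e-6 & interior < 1 + 1e-6))
  expect_true(all(interior >= 0 - 1e-6))
  expect_lt(max(interior), 1)
  expect_gt(min(interior), 0)
})

test_that("mask preconditions of the depth solver are enforced", {
  sl <- make_slab_masks(6, 6, 8, 10)
  m <- sl$masks
  overlap <- m$cortex; overlap[, , 1] <- TRUE  # collides with pia
  expect_error(solve_depth_field(overlap, m$pia, m$wm, sl$grid), "disjoint")
  empty <- array(FALSE, dim(m$pia))
  expect_error(solve_depth_field(m$cortex, empty, m$wm, sl$grid), "nonempty")
  expect_error(solve_depth_field(m$cortex, m$pia, m$wm, sl$grid,
                                 tol = 1e-14, max_iter = 2), "converge")
})

test_that("slab projection recovers geometric depth and keeps totals", {
  sl <- fixture_slab()
  set.seed(80)
  n <- 300L
  cells <- cell_table(data.frame(x = runif(n, 20, 170), y = runif(n, 20, 170),
                                 z = runif(n, 5, 235)), "atlas")
  fc <- project_cells(cells, sl$field, slab_parameterization())
  expect_identical(nrow(fc) + attr(fc, "n_outside_cortex") + attr(fc, "n_flagged"),
                   n)
  T_um <- sl$thickness_um
  # depth_um within one voxel of geometric depth; depth_frac within 0.02
  expect_lt(max(abs(fc$depth_um - fc$z)), 10 + 1e-9)
  expect_lt(max(abs(fc$depth_frac - fc$z / T_um)), 0.02)
  # (u, v) is the streamline's pia endpoint: directly above the cell
  expect_lt(max(abs(fc$u - fc$x)), 10)
  expect_lt(max(abs(fc$v - fc$y)), 10)
  # a cell essentially on the pia face
  pia_cell <- cell_table(data.frame(x = 95, y = 95, z = 1), "atlas")
  fp <- project_cells(pia_cell, sl$field, slab_parameterization())
  expect_lte(fp$depth_frac, 0.02)
  expect_lte(fp$depth_um, 10)
  # cells outside the grid are excluded and counted
  out_cell <- cell_table(data.frame(x = -500, y = 0, z = 0), "atlas")
  fo <- project_cells(out_cell, sl$field, slab_parameterization())
  expect_identical(nrow(fo), 0L)
  expect_identical(attr(fo, "n_outside_cortex"), 1L)
})

test_that("shell streamlines are radial: same ray, same flatmap bin", {
  at <- fixture_toy_atlas()
  f <- fixture_shell_field()
  ctr <- at$center
  set.seed(81)
  dirs <- matrix(rnorm(15), 5)
  dirs[, 3] <- abs(dirs[, 3]) + 0.3
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rows <- do.call(rbind, lapply(seq_len(5), function(i)
    rbind(ctr + 370 * dirs[i, ], ctr + 290 * dirs[i, ])))
  cells <- cell_table(data.frame(x = rows[, 1], y = rows[, 2], z = rows[, 3]),
                      "atlas")
  fc <- project_cells(cells, f, shell_parameterization(ctr))
  expect_identical(nrow(fc), 10L)
  du <- abs(fc$u[seq(1, 9, 2)] - fc$u[seq(2, 10, 2)])
  dv <- abs(fc$v[seq(1, 9, 2)] - fc$v[seq(2, 10, 2)])
  # one flatmap bin ~ one voxel on the pia: 10/400 rad
  expect_lt(max(du), 0.05)
  expect_lt(max(dv), 0.05)
  # deeper cell on the same ray has the larger depth
  expect_true(all(fc$depth_um[seq(2, 10, 2)] > fc$depth_um[seq(1, 9, 2)]))
})

test_that("flat heatmaps: per-total normalization, joint min/max, depth windows", {
  sl <- fixture_slab()
  set.seed(82)
  n <- 500
  cells <- cell_table(data.frame(x = runif(n, 20, 170), y = runif(n, 20, 170),
                                 z = runif(n, 15, 225)), "atlas")
  fc <- project_cells(cells, sl$field, slab_parameterization())
  ub <- seq(0, 190, by = 19); vb <- seq(0, 190, by = 19)
  hm <- flat_heatmap(fc, ub, vb, normalization = "per_total")
  expect_lt(abs(sum(hm$counts) - 1), 1e-9)
  raw <- flat_heatmap(fc, ub, vb)
  expect_identical(as.integer(sum(raw$counts)), nrow(fc))
  # depth window selects a band
  shallow <- flat_heatmap(fc, ub, vb, depth_window = c(0, 0.5))
  deep <- flat_heatmap(fc, ub, vb, depth_window = c(0.5, 1))
  expect_identical(shallow$n_in_scope + deep$n_in_scope, nrow(fc))
  # joint min/max: both maps share global 0 and 1
  js <- joint_minmax_scale(list(shallow, deep))
  expect_identical(min(vapply(js, function(h) min(h$counts), numeric(1))), 0)
  expect_identical(max(vapply(js, function(h) max(h$counts), numeric(1))), 1)
  expect_warning(flat_heatmap(fc, ub, vb, depth_window = c(0.99, 0.999)),
                 "empty")
})

test_that("depth profiles: exact conservation, region scoping, layered planting", {
  sl <- fixture_slab()
  set.seed(83)
  # cells only in the deep half: profile mass concentrates there
  n <- 400
  deep_cells <- cell_table(data.frame(x = runif(n, 20, 170),
                                      y = runif(n, 20, 170),
                                      z = runif(n, 120, 230),
                                      region_id = rep(c(7L, 8L), n / 2)), "atlas")
  fc <- project_cells(deep_cells, sl$field, slab_parameterization())
  prof <- depth_profile(fc, bin_width_um = 20, max_depth_um = 240)
  expect_equal(sum(prof$density * prof$bin_width_um), prof$n_cells)
  deep_bins <- prof$breaks[-length(prof$breaks)] >= 110
  expect_gte(sum(prof$density[deep_bins]) / sum(prof$density), 0.95)
  # region scoping via source ids
  p7 <- depth_profile(fc, 20, max_depth_um = 240, scope_region = 7L)
  p8 <- depth_profile(fc, 20, max_depth_um = 240, scope_region = 8L)
  expect_identical(p7$n_cells + p8$n_cells, nrow(fc))
  # per-sample profiles and their mean
  df <- as.data.frame(deep_cells)
  df$sample <- rep(c("m1", "m2"), each = n / 2)
  fc2 <- project_cells(cell_table(df, "atlas"), sl$field, slab_parameterization())
  ps <- depth_profile(fc2, 20, max_depth_um = 240, per_sample = TRUE)
  expect_identical(ncol(ps$density), 2L)
  expect_equal(ps$mean_density, rowMeans(ps$density))
  for (s in 1:2)
    expect_equal(sum(ps$density[, s]) * 20, sum(df$sample == colnames(ps$density)[s]))
  expect_error(depth_profile(fc, 0), "> 0")
})

test_that("refining the slab grid barely moves depth_frac (discretization convergence)", {
  coarse <- make_slab_masks(10, 10, 13, 10)
  fine <- make_slab_masks(20, 20, 25, 5)
  f_c <- solve_depth_field(coarse$masks$cortex, coarse$masks$pia, coarse$masks$wm,
                           coarse$grid, tol = 1e-8)
  f_f <- solve_depth_field(fine$masks$cortex, fine$masks$pia, fine$masks$wm,
                           fine$grid, tol = 1e-8)
  set.seed(84)
  pts <- cbind(runif(50, 15, 75), runif(50, 15, 75), runif(50, 10, 110))
  cells <- cell_table(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3]), "atlas")
  d_c <- project_cells(cells, f_c, slab_parameterization())$depth_frac
  d_f <- project_cells(cells, f_f, slab_parameterization())$depth_frac
  expect_lt(max(abs(d_c - d_f)), 0.01)
})
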