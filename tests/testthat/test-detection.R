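test_that("background removal: constants vanish, cells survive, gradients cancel", {
  g <- voxel_grid(array(37, c(16, 16, 16)), c(3, 3, 3))
  out <- remove_background(g, 15)
  expect_true(all(out$values == 0))
  # radius below one voxel is an error
  expect_error(remove_background(g, 2), "smaller than one voxel")
  # constant + small Gaussian cell: peak preserved within 10%, far field ~ 0
  one <- cell_table(data.frame(x = 24, y = 24, z = 24, amplitude = 80,
                               sigma_um = 4), "atlas")
  gs <- list(dims = c(16, 16, 16), spacing = c(3, 3, 3), origin = c(0, 0, 0))
  st <- render_stack(one, gs, noise = NULL,
                     background = list(constant = 50, gradient = c(0, 0, 0)))
  bg <- remove_background(st, 15)
  expect_gt(max(bg$values), 0.9 * 80)
  expect_lt(max(bg$values[1:3, , ]), 0.01)
  # smooth gradient without cells: interior residual < 5% of gradient range
  # (within one ball radius of the border, opening cannot track a ramp)
  ggrad <- render_stack(cell_table(data.frame(x = numeric(0), y = numeric(0),
                                              z = numeric(0), amplitude = numeric(0),
                                              sigma_um = numeric(0)), "atlas"),
                        gs, noise = NULL,
                        background = list(constant = 50, gradient = c(0.4, 0, 0)))
  res <- remove_background(ggrad, 15)
  grange <- diff(range(ggrad$values))
  expect_lt(max(res$values[6:11, , ]), 0.05 * grange)
})

test_that("DoG filter: zero on constants, maximum at the cell, matches direct convolution", {
  g <- voxel_grid(array(5, c(12, 12, 12)), c(3, 3, 3))
  expect_lt(max(abs(dog_filter(g, 3, 9)$values)), 1e-9)
  expect_error(dog_filter(g, 9, 3), "sigma_small")
  one <- cell_table(data.frame(x = 18, y = 18, z = 18, amplitude = 80,
                               sigma_um = 5), "atlas")
  st <- render_stack(one, list(dims = c(13, 13, 13), spacing = c(3, 3, 3),
                               origin = c(0, 0, 0)), noise = NULL,
                     background = list(constant = 0, gradient = c(0, 0, 0)))
  f <- dog_filter(st, 3, 9)
  peak <- which(f$values == max(f$values), arr.ind = TRUE)[1, ]
  expect_identical(as.integer(peak), c(7L, 7L, 7L))
  # independent oracle: direct truncated-kernel convolution at the center voxel
  kern1d <- function(sig_vox) {
    r <- ceiling(4 * sig_vox)
    k <- exp(-0.5 * (-r:r)^2 / sig_vox^2)
    k / sum(k)
  }
  conv_at_center <- function(v, sig_vox) {
    k <- kern1d(sig_vox)
    r <- (length(k) - 1) / 2
    n <- dim(v)[1]
    refl <- function(i) { while (i < 1 || i > n) { if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i }; i }
    acc <- 0
    ctr <- (n + 1) / 2
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r)
      acc <- acc + v[refl(ctr + dx), refl(ctr + dy), refl(ctr + dz)] *
        k[dx + r + 1] * k[dy + r + 1] * k[dz + r + 1]
    acc
  }
  direct <- conv_at_center(st$values, 1) - conv_at_center(st$values, 3)
  expect_lt(abs(f$values[7, 7, 7] - direct), 1e-6)
})

test_that("seed finding: flat stacks, separated peaks, lexicographic tie-break", {
  flat <- voxel_grid(array(1, c(10, 10, 10)), c(3, 3, 3))
  expect_identical(nrow(find_seeds(flat, 2, 6)), 0L)
  # two cells 3*min_distance apart: both found at their peak voxels
  two <- cell_table(data.frame(x = c(24, 72), y = c(45, 45), z = c(45, 45),
                               amplitude = 80, sigma_um = 5), "atlas")
  st <- render_stack(two, list(dims = c(32, 32, 32), spacing = c(3, 3, 3),
                               origin = c(0, 0, 0)), noise = NULL,
                     background = list(constant = 0, gradient = c(0, 0, 0)))
  f <- dog_filter(st, 3, 9)
  seeds <- find_seeds(f, 5, 8)
  expect_identical(nrow(seeds), 2L)
  expect_setequal(seeds[, "i"], c(9L, 25L))
  # two equal peaks closer than min_distance: one survives, first in (z,y,x) order
  v <- array(0, c(9, 9, 9))
  v[4, 5, 5] <- 10
  v[6, 5, 5] <- 10
  g <- voxel_grid(v, c(3, 3, 3))
  s2 <- find_seeds(g, 2, 12)
  expect_identical(nrow(s2), 1L)
  expect_identical(unname(s2[1, ]), c(4L, 5L, 5L))
})

test_that("watershed: blob sizes, saddle splits, empty masks, dropped seeds", {
  # one seed, one blob: label size equals the suprathreshold voxel count
  one <- cell_table(data.frame(x = 45, y = 45, z = 45, amplitude = 80,
                               sigma_um = 6), "atlas")
  st <- render_stack(one, list(dims = c(32, 32, 32), spacing = c(3, 3, 3),
                               origin = c(0, 0, 0)), noise = NULL,
                     background = list(constant = 0, gradient = c(0, 0, 0)))
  f <- dog_filter(st, 3, 9)
  seeds <- find_seeds(f, 5, 8)
  ws <- watershed_cells(f, seeds, 5)
  expect_identical(nrow(ws$stats), 1L)
  expect_identical(ws$stats$size_vox, sum(f$values > 5))
  # two overlapping Gaussians with two seeds: split at the saddle
  two <- cell_table(data.frame(x = c(33, 57), y = c(45, 45), z = c(45, 45),
                               amplitude = 80, sigma_um = 5), "atlas")
  st2 <- render_stack(two, list(dims = c(32, 32, 32), spacing = c(3, 3, 3),
                                origin = c(0, 0, 0)), noise = NULL,
                      background = list(constant = 0, gradient = c(0, 0, 0)))
  f2 <- dog_filter(st2, 3, 9)
  s2 <- find_seeds(f2, 2, 8)
  expect_identical(nrow(s2), 2L)
  ws2 <- watershed_cells(f2, s2, 2)
  expect_identical(nrow(ws2$stats), 2L)
  lab <- ws2$labels$values
  # every x-slice of the mask left of the saddle belongs to one label
  expect_setequal(unique(lab[lab > 0 & slice.index(lab, 1) <= 13]), 1:1)
  expect_setequal(unique(lab[lab > 0 & slice.index(lab, 1) >= 18]), 2:2)
  # empty mask: no labels
  ws3 <- watershed_cells(f2, s2, 1e9)
  expect_identical(nrow(ws3$stats), 0L)
  expect_warning(watershed_cells(f2, matrix(c(1L, 1L, 1L), 1,
                                            dimnames = list(NULL, c("i", "j", "k"))),
                                 2), "dropped")
})

test_that("detect_cells: empty stacks, size filters and filter monotonicity", {
  gs <- list(dims = c(24, 24, 24), spacing = c(3, 3, 3), origin = c(0, 0, 0))
  empty <- cell_table(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                                 amplitude = numeric(0), sigma_um = numeric(0)),
                      "atlas")
  st0 <- render_stack(empty, gs, noise = NULL)
  expect_identical(nrow(detect_cells(st0, detection_params())), 0L)
  set.seed(30)
  pts <- matrix(runif(15, 20, 52), 5)
  cells <- cell_table(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                 amplitude = 82, sigma_um = 5), "atlas")
  st <- render_stack(cells, gs, seed = 31)
  base <- detect_cells(st, detection_params())
  expect_gt(nrow(base), 0L)
  # raising size_min above the largest detected size discards everything
  huge <- detection_params(size_min = max(base$size_vox) + 1)
  expect_identical(nrow(detect_cells(st, huge)), 0L)
  # monotonicity: tightening intensity or size never increases the count
  n_tight_int <- nrow(detect_cells(st, detection_params(intensity_min = median(base$intensity))))
  expect_lte(n_tight_int, nrow(base))
  n_tight_size <- nrow(detect_cells(st, detection_params(size_min = median(base$size_vox))))
  expect_lte(n_tight_size, nrow(base))
  expect_error(detection_params(size_min = 10, size_max = 5), "size_min")
})

test_that("detection is deterministic and translation-equivariant", {
  gs <- list(dims = c(24, 24, 24), spacing = c(3, 3, 3), origin = c(0, 0, 0))
  set.seed(40)
  pts <- matrix(runif(9, 24, 48), 3)
  cells <- cell_table(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                 amplitude = 82, sigma_um = 5), "atlas")
  st <- render_stack(cells, gs, seed = 41)
  d1 <- detect_cells(st, detection_params())
  d2 <- detect_cells(st, detection_params())
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # moving interior cells by an integer number of voxels moves the detected
  # centroids by exactly that physical offset (noise-free stacks)
  off <- c(2, 1, -1) * 3
  st_a <- render_stack(cells, gs, noise = NULL)
  moved <- cell_table(transform(as.data.frame(cells), x = x + off[1],
                                y = y + off[2], z = z + off[3]), "atlas")
  st_b <- render_stack(moved, gs, noise = NULL)
  da <- detect_cells(st_a, detection_params())
  db <- detect_cells(st_b, detection_params())
  expect_identical(nrow(da), nrow(db))
  orda <- order(da$x); ordb <- order(db$x)
  expect_equal(xyz_of(db)[ordb, , drop = FALSE],
               sweep(xyz_of(da)[orda, , drop = FALSE], 2, off, `+`),
               tolerance = 1e-6, ignore_attr = TRUE)
})
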