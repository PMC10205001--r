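test_that("fit_affine recovers identity, pure translation and a known similarity", {
  # identity
  lm_id <- landmarks_from_matrix(cbind(diag(3), 0), n = 6, seed = 2)
  A <- fit_affine(lm_id)
  expect_lt(max(abs(A$matrix - cbind(diag(3), 0))), 1e-12)
  # pure translation from 4 points
  Mt <- cbind(diag(3), c(7, -2, 11))
  At <- fit_affine(landmarks_from_matrix(Mt, n = 4, seed = 3))
  expect_lt(max(abs(At$matrix - Mt)), 1e-12)
  # rotation + isotropic scale + translation
  M <- known_similarity()
  Ar <- fit_affine(landmarks_from_matrix(M, n = 6, seed = 1))
  expect_lt(max(abs(Ar$matrix - M)), 1e-9)
})

test_that("degenerate landmark configurations are refused with a condition number", {
  coplanar <- landmark_set(data.frame(name = paste0("p", 1:5), active = TRUE,
                                      mx = c(0, 1, 0, 1, 0.5), my = c(0, 0, 1, 1, 0.5),
                                      mz = 0,
                                      fx = c(0, 1, 0, 1, 0.5), fy = c(0, 0, 1, 1, 0.5),
                                      fz = 0))
  expect_error(fit_affine(coplanar), "condition number")
  few <- landmark_set(data.frame(name = paste0("p", 1:3), active = TRUE,
                                 mx = rnorm(3), my = rnorm(3), mz = rnorm(3),
                                 fx = rnorm(3), fy = rnorm(3), fz = rnorm(3)))
  expect_error(fit_affine(few), ">= 4")
})

test_that("fit_affine is rotation-equivariant and reorder-invariant", {
  M <- known_similarity()
  lm <- landmarks_from_matrix(M, n = 8, seed = 5, jitter_sd = 2)
  A <- fit_affine(lm)
  th <- 0.7
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  df <- as.data.frame(lm)
  mov_rot <- as.matrix(df[, c("mx", "my", "mz")]) %*% t(R)
  lm_rot <- landmark_set(transform(df, mx = mov_rot[, 1], my = mov_rot[, 2],
                                   mz = mov_rot[, 3]))
  A_rot <- fit_affine(lm_rot)
  expect_equal(A_rot$matrix[, 1:3], A$matrix[, 1:3] %*% t(R), tolerance = 1e-8)
  # permuting rows changes nothing
  lm_perm <- landmark_set(df[sample(nrow(df)), ])
  expect_equal(fit_affine(lm_perm)$matrix, A$matrix, tolerance = 1e-9)
})

test_that("TPS: exact interpolation at lambda 0, affine reproduction, large-lambda limit", {
  M <- known_similarity()
  # noisy correspondence: interpolation still exact at the landmarks
  lm <- landmarks_from_matrix(M, n = 10, seed = 7, jitter_sd = 8)
  tps <- fit_tps(lm, lambda = 0)
  rep0 <- registration_report(tps, lm)
  expect_lt(max(rep0$per_landmark$norm_um), 1e-9)
  # pure-affine landmarks: kernel weights vanish, mapping equals the affine
  lm_aff <- landmarks_from_matrix(M, n = 8, seed = 8)
  tps_aff <- fit_tps(lm_aff, lambda = 0)
  expect_lt(max(abs(tps_aff$weights)), 1e-8)
  set.seed(9)
  pts <- matrix(runif(60, 0, 100), 20)
  A <- fit_affine(lm_aff)
  expect_lt(max(abs(apply_transform(tps_aff, pts) - apply_transform(A, pts))), 1e-6)
  # lambda -> infinity converges to the least-squares affine
  A_ls <- fit_affine(lm)
  tps_inf <- fit_tps(lm, lambda = 1e6)
  expect_lt(max(abs(apply_transform(tps_inf, pts) - apply_transform(A_ls, pts))), 1e-3)
  # preconditions
  expect_error(fit_tps(landmarks_from_matrix(M, n = 4, seed = 1)), ">= 5")
  dup <- as.data.frame(lm)
  dup[2, c("mx", "my", "mz")] <- dup[1, c("mx", "my", "mz")]
  expect_error(fit_tps(landmark_set(dup), lambda = 0), "singular|duplicate")
})

test_that("apply_transform: identity, composition, cell_table space tags", {
  set.seed(10)
  pts <- matrix(runif(30, -50, 50), 10)
  idt <- identity_transform()
  expect_equal(apply_transform(idt, pts), pts, ignore_attr = TRUE)
  A <- affine_transform(known_similarity())
  B <- affine_transform(cbind(diag(c(2, 0.5, 1)), c(-1, 0, 4)))
  comp <- compose_transforms(A, B)
  expect_equal(apply_transform(comp, pts),
               apply_transform(B, apply_transform(A, pts)), tolerance = 1e-12)
  # inverse round trip
  expect_equal(apply_transform(compose_transforms(A, invert_transform(A)), pts),
               pts, tolerance = 1e-9, ignore_attr = TRUE)
  # cell tables: space checked and retagged
  cells <- cell_table(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3]), "stack")
  tr <- affine_transform(known_similarity(), from = "stack", to = "atlas")
  out <- apply_transform(tr, cells)
  expect_identical(cell_space(out), "atlas")
  expect_error(apply_transform(tr, out), "space")
})

test_that("transform JSON schema round-trips affine, TPS and composite", {
  tmp <- withr::local_tempdir()
  M <- known_similarity()
  lm <- landmarks_from_matrix(M, n = 8, seed = 11, jitter_sd = 5)
  tr <- fit_landmark_transform(lm, mode = "affine+tps")
  p <- file.path(tmp, "t.json")
  write_transform(tr, p)
  tr2 <- read_transform(p)
  set.seed(12)
  pts <- matrix(runif(30, 0, 100), 10)
  expect_equal(apply_transform(tr2, pts), apply_transform(tr, pts),
               tolerance = 1e-12)
  aff <- fit_affine(lm)
  write_transform(aff, p)
  expect_equal(read_transform(p)$matrix, aff$matrix, tolerance = 1e-12)
  expect_identical(read_transform(p)$from, "stack")
})

test_that("registration report: internal identity and clicking-noise scale", {
  M <- known_similarity()
  lm <- landmarks_from_matrix(M, n = 20, seed = 13, jitter_sd = 10)
  A <- fit_affine(lm)
  rep <- registration_report(A, lm)
  expect_equal(rep$rms_um^2, mean(rep$per_landmark$norm_um^2), tolerance = 1e-12)
  expect_identical(rep$n_active, 20L)
  # jitter sd 25 um: residual RMS of the *true* matrix ~ 25*sqrt(3) over seeds
  rms <- vapply(1:50, function(s) {
    lmj <- landmarks_from_matrix(M, n = 20, seed = 100 + s, jitter_sd = 25)
    registration_report(affine_transform(M), lmj)$rms_um
  }, numeric(1))
  expect_lt(abs(mean(rms) - 25 * sqrt(3)), 0.3 * 25 * sqrt(3))
})

test_that("downsampling preserves physical positions and block means", {
  # 8^3 ramp: block-mean equals brute-force 2^3 averaging
  v <- array(as.numeric(1:512), c(8, 8, 8))
  g <- voxel_grid(v, c(2, 2, 2))
  ds <- downsample_stack(g, c(4, 4, 4))
  expect_identical(dim(ds$grid$values), c(4L, 4L, 4L))
  brute <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    brute[i, j, k] <- mean(v[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j),
                             (2 * k - 1):(2 * k)])
  expect_equal(ds$grid$values, brute, tolerance = 1e-12)
  # constant stack stays constant at any factor
  gc <- voxel_grid(array(7, c(9, 9, 9)), c(1, 1, 1))
  expect_true(all(abs(downsample_stack(gc, c(3, 3, 3))$grid$values - 7) < 1e-12))
  expect_true(all(abs(downsample_stack(gc, c(2.5, 2.5, 2.5))$grid$values - 7) < 1e-9))
  # a bright point keeps its physical position within half a coarse voxel
  gp <- voxel_grid(array(0, c(16, 16, 16)), c(2, 2, 2))
  gp$values[9, 9, 9] <- 100
  true_pos <- index_to_physical(gp, c(9, 9, 9))
  ds2 <- downsample_stack(gp, c(4, 4, 4))
  peak <- which(ds2$grid$values == max(ds2$grid$values), arr.ind = TRUE)[1, ]
  peak_pos <- index_to_physical(ds2$grid, peak)
  expect_true(all(abs(peak_pos - true_pos) <= 2 + 1e-9))
  expect_error(downsample_stack(gp, c(1, 1, 1)), ">= native")
})
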