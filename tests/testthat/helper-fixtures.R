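# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default toy atlas at 10 um: 4 sectors x 3 layers, Ro 400 / Ri 250
fixture_toy_atlas <- function() {
  memo("toy_atlas", function() make_toy_atlas(toy_atlas_spec()))
}

# its solved depth field
fixture_shell_field <- function() {
  memo("shell_field", function() {
    at <- fixture_toy_atlas()
    solve_depth_field(at$masks$cortex, at$masks$pia, at$masks$wm,
                      at$annotation, tol = 1e-6, max_iter = 50000)
  })
}

fixture_slab <- function() {
  memo("slab", function() {
    sl <- make_slab_masks(20, 20, 25, 10)
    sl$field <- solve_depth_field(sl$masks$cortex, sl$masks$pia, sl$masks$wm,
                                  sl$grid, tol = 1e-6)
    sl
  })
}

# small landmark set generated by a known similarity transform
known_similarity <- function() {
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  cbind(1.1 * R, c(5, -3, 2))
}

landmarks_from_matrix <- function(M, n = 6, seed = 1, jitter_sd = 0) {
  set.seed(seed)
  mov <- matrix(stats::runif(3 * n, 0, 100), n)
  fix <- mov %*% t(M[, 1:3]) + rep(1, n) %o% M[, 4]
  if (jitter_sd > 0) fix <- fix + matrix(stats::rnorm(3 * n, 0, jitter_sd), n)
  landmark_set(data.frame(name = paste0("p", seq_len(n)), active = TRUE,
                          mx = mov[, 1], my = mov[, 2], mz = mov[, 3],
                          fx = fix[, 1], fy = fix[, 2], fz = fix[, 3]))
}

xyz_of <- function(cells) as.matrix(as.data.frame(cells)[, c("x", "y", "z")])

# greedy nearest matching within a radius; returns recall/precision/rms
match_cells <- function(truth, detected, radius_um) {
  if (nrow(truth) == 0L || nrow(detected) == 0L)
    return(list(recall = 0, precision = 0, rms = NA_real_))
  d2 <- outer(rowSums(truth^2), rowSums(detected^2), `+`) -
    2 * truth %*% t(detected)
  D <- sqrt(pmax(d2, 0))
  tmin <- apply(D, 1, min)
  dmin <- apply(D, 2, min)
  list(recall = mean(tmin <= radius_um),
       precision = mean(dmin <= radius_um),
       rms = sqrt(mean(tmin[tmin <= radius_um]^2)))
}
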