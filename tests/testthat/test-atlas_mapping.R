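test_that("region assignment follows half-open voxel ownership", {
  v <- array(0L, c(4, 4, 4))
  v[2, 3, 2] <- 315L
  ann <- voxel_grid(v, c(10, 10, 10))
  # exact center of the labeled voxel
  ctr <- index_to_physical(ann, c(2, 3, 2))
  cells <- cell_table(data.frame(x = c(ctr[1], 500), y = c(ctr[2], 0),
                                 z = c(ctr[3], 0)), "atlas")
  out <- assign_regions(cells, ann)
  expect_identical(out$region_id, c(315L, 0L))  # out-of-volume -> 0
  # idempotent and order-independent
  out2 <- assign_regions(out, ann)
  expect_identical(out2$region_id, out$region_id)
  rev_cells <- cell_table(as.data.frame(cells)[2:1, ], "atlas")
  expect_identical(assign_regions(rev_cells, ann)$region_id, c(0L, 315L))
  # stack-space cells are refused
  expect_error(assign_regions(cell_table(data.frame(x = 1, y = 1, z = 1), "stack"),
                              ann), "space")
})

test_that("assignment agrees with a brute-force per-cell per-voxel loop", {
  set.seed(50)
  spec <- toy_atlas_spec(outer_radius = 140, inner_radius = 80, spacing = 10)
  at <- make_toy_atlas(spec)
  d <- dim(at$annotation$values)
  n <- 300
  ext <- d * 10
  pts <- cbind(runif(n, -5, ext[1] - 5), runif(n, -5, ext[2] - 5),
               runif(n, -5, ext[3] - 5))
  cells <- cell_table(data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3]), "atlas")
  fast <- assign_regions(cells, at$annotation)$region_id
  # brute force: scan all voxels, test half-open ownership boxes
  brute <- integer(n)
  sp <- at$annotation$spacing
  for (c_i in seq_len(n)) {
    p <- pts[c_i, ]
    hit <- 0L
    for (i in seq_len(d[1])) {
      cx <- (i - 1) * sp[1]
      if (p[1] < cx - sp[1] / 2 || p[1] >= cx + sp[1] / 2) next
      for (j in seq_len(d[2])) {
        cy <- (j - 1) * sp[2]
        if (p[2] < cy - sp[2] / 2 || p[2] >= cy + sp[2] / 2) next
        for (k in seq_len(d[3])) {
          cz <- (k - 1) * sp[3]
          if (p[3] >= cz - sp[3] / 2 && p[3] < cz + sp[3] / 2)
            hit <- at$annotation$values[i, j, k]
        }
      }
    }
    brute[c_i] <- hit
  }
  expect_identical(fast, brute)
})

test_that("hierarchical aggregation: chain totals, conservation, merged densities", {
  at <- fixture_toy_atlas()
  pl <- plant_cells(at$annotation,
                    setNames(c(5000, 500), c("10102", "10203")), seed = 60)
  cells <- assign_regions(pl, at$annotation)
  rt <- aggregate_counts(cells, at$ontology, at$annotation, all_regions = TRUE)
  n <- nrow(cells)
  # conservation: leaf direct counts + unassigned = N exactly
  leaves <- rt$id[!rt$id %in% at$ontology$nodes$parent_id & rt$id != 0]
  expect_identical(sum(rt$n_cells_direct[rt$id %in% leaves]) +
                     rt$n_cells_direct[rt$id == 0], n)
  # parent totals = direct + sum of child totals, at every node
  for (rid in rt$id[rt$id != 0]) {
    kids <- at$ontology$nodes$id[which(at$ontology$nodes$parent_id == rid)]
    expect_identical(rt$n_cells_total[rt$id == rid],
                     rt$n_cells_direct[rt$id == rid] +
                       sum(rt$n_cells_total[rt$id %in% kids]))
  }
  # all cells in one leaf: that leaf and every ancestor report the same total
  one <- plant_cells(at$annotation, setNames(3000, "10102"), seed = 61)
  rt1 <- aggregate_counts(assign_regions(one, at$annotation), at$ontology,
                          at$annotation, all_regions = TRUE)
  chain <- c(10102L, ancestors(at$ontology, 10102L))
  expect_true(all(rt1$n_cells_total[rt1$id %in% chain] == nrow(one)))
  # merged density is total/volume, not the mean of child densities
  sec <- rt$id == 2001L
  kids <- at$ontology$nodes$id[which(at$ontology$nodes$parent_id == 2001L)]
  kd <- rt[rt$id %in% kids, ]
  expect_equal(rt$density_total[sec],
               sum(kd$n_cells_total) / sum(kd$volume_total_mm3))
  mean_child <- mean(kd$density_total)
  expect_false(isTRUE(all.equal(rt$density_total[sec], mean_child)))
  # planted densities recovered within 3 Poisson SE
  for (spec_r in c("10102", "10203")) {
    row <- rt[rt$id == as.integer(spec_r), ]
    lam <- c("10102" = 5000, "10203" = 500)[[spec_r]] * row$volume_total_mm3
    expect_lt(abs(row$n_cells_total - lam), 3 * sqrt(lam))
  }
  # unknown region id in cells is an error naming the id
  bad <- cells
  bad$region_id[1] <- 31337L
  expect_error(aggregate_counts(bad, at$ontology, at$annotation), "31337")
})

test_that("exclusion masks zero out a region and its descendants before assignment", {
  at <- fixture_toy_atlas()
  pl <- plant_cells(at$annotation,
                    setNames(c(3000, 3000), c("10102", "10203")), seed = 62)
  plain <- assign_regions(pl, at$annotation)
  masked <- assign_regions(pl, at$annotation, exclude_regions = "SEC1",
                           ontology = at$ontology)
  was_sec1 <- plain$region_id == 10102L
  expect_true(all(masked$region_id[was_sec1] == 0L))
  expect_identical(masked$region_id[!was_sec1], plain$region_id[!was_sec1])
})

test_that("space bridging: identity, inverse round-trip, pure scaling", {
  cells <- cell_table(data.frame(x = c(1, 2), y = c(3, 4), z = c(5, 6)), "atlas")
  idb <- bridge_spaces(cells, to_space = "ccf3")
  expect_identical(cell_space(idb), "ccf3")
  expect_equal(xyz_of(idb), xyz_of(cells), ignore_attr = TRUE)
  br <- affine_transform(cbind(diag(c(1.1, 1.1, 1.1)), c(0, 0, 0)),
                         from = "atlas", to = "ccf3")
  out <- bridge_spaces(cells, br)
  expect_equal(xyz_of(out), 1.1 * xyz_of(cells), ignore_attr = TRUE)
  back <- bridge_spaces(out, invert_transform(br))
  expect_equal(xyz_of(back), xyz_of(cells), tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(cell_space(back), "atlas")
})
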