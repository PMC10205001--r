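test_that("index/physical mapping is a bijection with half-open voxel ownership", {
  g <- voxel_grid(array(0, c(5, 6, 7)), c(2.95, 2.95, 3), origin = c(10, -4, 2))
  idx <- as.matrix(expand.grid(i = 1:5, j = 1:6, k = 1:7))
  phys <- index_to_physical(g, idx)
  back <- physical_to_index(g, phys)
  expect_equal(unname(back), unname(idx), tolerance = 1e-12)
  # ownership: points anywhere inside the half-open box map to the center voxel
  set.seed(4)
  jit <- matrix(runif(nrow(idx) * 3, -0.499, 0.499), ncol = 3)
  jit_phys <- phys + sweep(jit, 2, g$spacing, `*`)
  own <- owning_voxel(g, jit_phys)
  expect_identical(unname(own), unname(apply(idx, 2, as.integer)))
})

test_that("NRRD round-trips are lossless and carry spacing", {
  tmp <- withr::local_tempdir()
  gi <- voxel_grid(array(as.integer(sample.int(100, 64)), c(4, 4, 4)), c(25, 25, 25))
  p <- file.path(tmp, "a.nrrd")
  write_volume(gi, p)
  gi2 <- read_volume(p)
  expect_identical(gi2$values, gi$values)
  expect_equal(gi2$spacing, c(25, 25, 25))
  # float volume: bit-exact (stored as float64)
  gf <- voxel_grid(array(rnorm(4^3, 100, 40), c(4, 4, 4)), c(2.95, 2.95, 3),
                   origin = c(1, 2, 3))
  pf <- file.path(tmp, "f.nrrd")
  write_volume(gf, pf)
  gf2 <- read_volume(pf)
  expect_identical(gf2$values, gf$values)
  expect_equal(gf2$spacing, c(2.95, 2.95, 3))
  expect_equal(gf2$origin, c(1, 2, 3))
})

test_that("TIFF round-trips: integers exact, floats within float32, spacing via sidecar", {
  tmp <- withr::local_tempdir()
  gi <- voxel_grid(array(as.integer(sample.int(65535, 3 * 2 * 4)), c(3, 2, 4)),
                   c(2.95, 2.95, 3))
  p <- file.path(tmp, "a.tif")
  write_volume(gi, p)
  gi2 <- read_volume(p)
  expect_identical(gi2$values, gi$values)
  expect_equal(gi2$spacing, c(2.95, 2.95, 3))
  gf <- voxel_grid(array(rnorm(24, 120, 30), c(3, 2, 4)), c(2.95, 2.95, 3))
  pf <- file.path(tmp, "f.tif")
  write_volume(gf, pf)
  gf2 <- read_volume(pf)
  expect_lt(max(abs(gf2$values - gf$values)) / diff(range(gf$values)), 1e-6)
})

test_that("TIFF series: 3 slices of 2x2 give shape (x=2, y=2, z=3)", {
  tmp <- withr::local_tempdir()
  g <- voxel_grid(array(as.integer(1:12), c(2, 2, 3)), c(1, 1, 2))
  sdir <- file.path(tmp, "series")
  write_volume(g, sdir, format = "tiff_series")
  expect_length(list.files(sdir, pattern = "\\.tif$"), 3L)
  g2 <- read_volume(sdir)
  expect_identical(dim(g2$values), c(2L, 2L, 3L))
  expect_identical(g2$values, g$values)
})

test_that("missing TIFF spacing is an explicit error, never a silent default", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "bare.tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), p)
  expect_error(read_volume(p), "spacing")
})

test_that("inconsistent slice shapes in a series are rejected", {
  tmp <- withr::local_tempdir()
  sdir <- file.path(tmp, "bad")
  dir.create(sdir)
  tiff::writeTIFF(matrix(0.5, 4, 4), file.path(sdir, "p1.tif"))
  tiff::writeTIFF(matrix(0.5, 3, 4), file.path(sdir, "p2.tif"))
  expect_error(read_volume(sdir, spacing = c(1, 1, 1)), "inconsistent")
})

test_that("ontology: nested and flat JSON dialects parse to the same tree", {
  tmp <- withr::local_tempdir()
  nested <- list(id = 997, acronym = "root", name = "root",
                 children = list(
                   list(id = 315, acronym = "Isocortex", name = "Isocortex",
                        children = list(
                          list(id = 322, acronym = "SSp", name = "Primary somatosensory"),
                          list(id = 385, acronym = "VISp", name = "Primary visual"))),
                   list(id = 549, acronym = "TH", name = "Thalamus")))
  pn <- file.path(tmp, "nested.json")
  jsonlite::write_json(nested, pn, auto_unbox = TRUE)
  flat <- data.frame(id = c(997, 315, 322, 385, 549),
                     acronym = c("root", "Isocortex", "SSp", "VISp", "TH"),
                     name = c("root", "Isocortex", "x", "y", "z"),
                     parent_structure_id = c(NA, 997, 315, 315, 997))
  pfl <- file.path(tmp, "flat.json")
  jsonlite::write_json(flat, pfl, dataframe = "rows", na = "null", auto_unbox = TRUE)
  on <- read_ontology(pn)
  of <- read_ontology(pfl)
  expect_setequal(on$nodes$id, of$nodes$id)
  expect_identical(descendants(on, "Isocortex"), descendants(of, "Isocortex"))
  expect_identical(sort(descendants(on, 315)), c(322L, 385L))
  expect_identical(ancestors(on, 322), c(315L, 997L))
})

test_that("ontology invariants: duplicates, multiple roots and cycles are errors", {
  base <- data.frame(id = c(1, 2, 3), acronym = c("r", "a", "b"),
                     name = c("r", "a", "b"), parent_id = c(NA, 1, 1))
  expect_s3_class(region_ontology(base), "region_ontology")
  dup <- base; dup$id[3] <- 2
  expect_error(region_ontology(dup), "duplicate region id")
  two_roots <- base; two_roots$parent_id[3] <- NA
  expect_error(region_ontology(two_roots), "exactly one root")
  dup_acr <- base; dup_acr$acronym[3] <- "a"
  expect_error(region_ontology(dup_acr), "duplicate region acronym")
  cyc <- data.frame(id = c(1, 2, 3), acronym = c("r", "a", "b"),
                    name = c("r", "a", "b"), parent_id = c(NA, 3, 2))
  expect_error(region_ontology(cyc), "cycle")
})

test_that("ontology JSON writer round-trips", {
  tmp <- withr::local_tempdir()
  at <- fixture_toy_atlas()
  p <- file.path(tmp, "ont.json")
  write_ontology(at$ontology, p)
  o2 <- read_ontology(p)
  expect_identical(o2$nodes[, c("id", "acronym", "parent_id")],
                   at$ontology$nodes[, c("id", "acronym", "parent_id")])
})

test_that("annotation labels are validated against the ontology", {
  at <- fixture_toy_atlas()
  expect_true(validate_annotation(at$annotation, at$ontology))
  bad <- at$annotation
  bad$values[1, 1, 1] <- 99999L
  expect_error(validate_annotation(bad, at$ontology), "99999")
})
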