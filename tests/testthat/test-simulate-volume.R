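test_that("young cTEC truth respects the configured labyrinth ranges", {
  vs <- simulate_volume(volume_sim_config("young_cortex", seed = 2))
  tr <- vs$truth
  expect_equal(nrow(tr$cells), 1L)
  expect_true(tr$cells$void_count >= 20 && tr$cells$void_count <= 30)
  expect_true(tr$cells$enclosed_lymphocytes >= 40 &&
              tr$cells$enclosed_lymphocytes <= 300)
  # per-void lymphocyte counts inside the configured range
  per_void <- table(tr$lymphocytes$void)
  expect_true(all(per_void >= 2 & per_void <= 10))
  # voids are disjoint spheres strictly inside the cell ellipsoid
  expect_true(all(tr$voids$radius > 0))
  expect_setequal(names(vs$volume$channels),
                  c("reporter", "nuclei", "edu", "autofluor"))
})

test_that("zero EdU rate and zero pigment give identically zero channels", {
  cfg <- volume_sim_config("young_cortex", edu_rate = 0, seed = 4)
  vs <- simulate_volume(cfg)
  expect_true(all(vs$volume$channels$edu == 0))
  cfg2 <- volume_sim_config("aged_cortex", pigment_density = 0, seed = 4)
  vs2 <- simulate_volume(cfg2)
  expect_true(all(vs2$volume$channels$autofluor == 0))
})

test_that("aged pigment shows broad-spectrum emission in both channels", {
  vs <- simulate_volume(volume_sim_config("aged_cortex", seed = 9,
                                          pigment_density = 2e-4))
  af <- vs$volume$channels$autofluor
  expect_gt(sum(af > 0), 0)
  # every pigment voxel also lights the reporter channel
  rep_at <- vs$volume$channels$reporter[af > 100]
  expect_true(all(rep_at > 100))
  # subtraction removes pigment outside the cell body but keeps cell signal
  clean <- subtract_autofluorescence(vs$volume$channels$reporter, af)
  outside <- af > 100 & vs$truth$cell_labels == 0
  expect_lt(max(clean[outside]), 60)
})

test_that("volume generation is deterministic under a fixed seed", {
  cfg <- function(s) volume_sim_config("medulla", shape_vox = c(24, 96, 96),
                                       seed = s)
  a <- simulate_volume(cfg(7))
  b <- simulate_volume(cfg(7))
  c <- simulate_volume(cfg(8))
  expect_identical(a$volume$channels$reporter, b$volume$channels$reporter)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_false(identical(a$volume$channels$reporter,
                         c$volume$channels$reporter))
})

test_that("a cell larger than the volume raises a generation error", {
  cfg <- volume_sim_config("young_cortex", shape_vox = c(10, 40, 30),
                           seed = 1)
  expect_error(simulate_volume(cfg), "does not fit")
})

test_that("generated long axes follow the configured normal law", {
  # coarse spacing keeps 100 single-cell draws cheap; the drawn long axis
  # is the ground-truth feret along the radial (y) axis
  L <- vapply(1:100, function(s) {
    cfg <- volume_sim_config("young_cortex", shape_vox = c(30, 120, 70),
                             spacing_um = c(2, 1, 1), seed = 1000 + s,
                             channels = c("reporter", "nuclei"))
    simulate_volume(cfg)$truth$cells$long_axis_um
  }, numeric(1))
  ks <- stats::ks.test(L, "pnorm", 75, 10)
  expect_gt(ks$p.value, 0.01)
})

test_that("medulla packing yields non-overlapping cells with one nucleus", {
  vs <- simulate_volume(volume_sim_config("medulla",
                                          shape_vox = c(48, 128, 128),
                                          seed = 3))
  tr <- vs$truth
  expect_equal(nrow(tr$nuclei), nrow(tr$cells))
  # label mask is disjoint by construction: labelled voxels sum to cell sizes
  expect_equal(sum(tr$cell_labels > 0),
               length(unique(which(tr$cell_labels > 0))))
  # every nucleus centre sits inside its own cell's label
  sp <- vs$volume$spacing
  at <- tr$cell_labels[cbind(round(tr$nuclei$z / sp[1]) + 1,
                             round(tr$nuclei$y / sp[2]) + 1,
                             round(tr$nuclei$x / sp[3]) + 1)]
  expect_equal(at, tr$nuclei$cell)
})
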