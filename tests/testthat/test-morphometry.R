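test_that("filters are idempotent on constant volumes", {
  a <- array(42, c(8, 10, 9))
  for (rec in c("ctec_confetti", "mtec_segmentation", "nuclei_density")) {
    out <- preprocess_volume(a, rec)
    expect_true(all(abs(out - out[1]) < 1e-9))
  }
})

test_that("outlier removal replaces a lone bright voxel by the local median", {
  a <- array(10, c(5, 7, 7))
  a[3, 4, 4] <- 200
  out <- array(thymoscope:::cpp_remove_outliers(as.numeric(a), dim(a), 5L, 1),
               dim(a))
  expect_equal(out[3, 4, 4], 10)
  expect_true(all(out == 10))
})

test_that("median filter equals a brute-force sliding-window median", {
  set.seed(12)
  a <- array(runif(8^3, 0, 255), c(8, 8, 8))
  out <- array(thymoscope:::cpp_median3d(as.numeric(a), dim(a), 1L, 2L, 2L),
               dim(a))
  oracle <- array(NA_real_, dim(a))
  for (z in 1:8) for (y in 1:8) for (x in 1:8) {
    zz <- max(1, z - 1):min(8, z + 1)
    yy <- max(1, y - 2):min(8, y + 2)
    xx <- max(1, x - 2):min(8, x + 2)
    w <- sort(as.numeric(a[zz, yy, xx]))
    oracle[z, y, x] <- w[floor(0.5 * (length(w) - 1) + 0.5) + 1]
  }
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("autofluorescence subtraction clips at zero", {
  r <- array(100, c(3, 3, 3))
  af <- array(30, c(3, 3, 3))
  expect_equal(subtract_autofluorescence(r, af)[1], 70)
  expect_equal(subtract_autofluorescence(r, array(0, dim(af)))[1], 100)
  expect_true(all(subtract_autofluorescence(r, r) == 0))
  expect_error(subtract_autofluorescence(r, array(0, c(2, 2, 2))), "shape")
})

test_that("single-cell segmentation keeps the largest component only", {
  a <- array(0, c(12, 20, 20))
  a[3:10, 3:12, 3:12] <- 200       # large blob
  a[3:5, 16:18, 16:18] <- 200      # small distractor
  a <- a + 5
  obj <- segment_single_cell(a, spacing_um = c(1, 1, 1))
  expect_equal(obj$n, 1L)
  expect_false(any(obj$labels[, 14:20, 14:20] > 0))
  expect_error(segment_single_cell(array(0, c(4, 4, 4)),
                                   spacing_um = c(1, 1, 1)), "empty")
})

test_that("sphere descriptors match the analytic values", {
  mask <- ball_mask(20)
  sh <- measure_shape(mask, spacing_um = c(1, 1, 1))
  v_true <- 4 / 3 * pi * 20^3
  expect_lt(abs(sh$volume_um3 - v_true) / v_true, 0.02)
  expect_lt(abs(sh$feret_um - 40), 1)
  expect_lt(abs(sh$volume_ellipsoid_ratio - 1), 0.05)
})

test_that("cube descriptors match closed-form geometry", {
  mask <- cube_mask(10)
  sh <- measure_shape(mask, spacing_um = c(1, 1, 1))
  expect_equal(sh$volume_um3, 1000)
  expect_equal(sh$surface_area_um2, 600)          # voxel-face area is exact
  expect_equal(sh$compactness, 0.6)
  # hull of the voxel centres spans 9 um per side
  expect_equal(sh$feret_um, 9 * sqrt(3), tolerance = 1e-8)
  mvee_vol <- 4 / 3 * pi * (4.5 * sqrt(3))^3
  expect_lt(abs(sh$volume_ellipsoid_ratio - 1000 / mvee_vol), 0.02)
})

test_that("feret equals a brute-force pairwise maximum on random blobs", {
  set.seed(5)
  sp <- c(1, 0.6, 0.8)
  for (i in 1:4) {
    mask <- array(runif(10 * 9 * 8) < 0.25, c(10, 9, 8))
    if (sum(mask) < 2) next
    sh <- measure_shape(mask, spacing_um = sp)
    w <- which(mask, arr.ind = TRUE)
    pts <- sweep(w - 1, 2, sp, `*`)
    oracle <- max(dist(pts))
    expect_equal(sh$feret_um, oracle, tolerance = 1e-9)
  }
})

test_that("descriptors scale correctly with voxel spacing", {
  mask <- ball_mask(8)
  a <- measure_shape(mask, spacing_um = c(1, 1, 1))
  b <- measure_shape(mask, spacing_um = c(2, 2, 2))
  expect_equal(b$volume_um3 / a$volume_um3, 8)
  expect_equal(b$surface_area_um2 / a$surface_area_um2, 4)
  expect_equal(b$feret_um / a$feret_um, 2)
})

test_that("descriptors are invariant to axis permutation", {
  set.seed(9)
  mask <- array(FALSE, c(14, 14, 14))
  mask[3:11, 4:10, 5:9] <- TRUE
  mask[6:8, 6:8, 6:8] <- FALSE
  base <- measure_shape(mask, spacing_um = c(1, 1, 1))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    rot <- measure_shape(aperm(mask, perm), spacing_um = c(1, 1, 1))
    expect_equal(rot$volume_um3, base$volume_um3)
    expect_equal(rot$surface_area_um2, base$surface_area_um2)
    expect_equal(rot$feret_um, base$feret_um, tolerance = 1e-9)
    expect_equal(rot$volume_ellipsoid_ratio, base$volume_ellipsoid_ratio,
                 tolerance = 0.01)
  }
})

test_that("sphere digitization errors shrink as the radius grows", {
  errs <- vapply(c(5, 10, 20, 40), function(r) {
    sh <- measure_shape(ball_mask(r), spacing_um = c(1, 1, 1))
    abs(sh$volume_um3 - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("void counting distinguishes solid, hollow and border shapes", {
  solid <- ball_mask(6)
  expect_equal(count_voids(solid), 0L)
  hollow <- ball_mask(6) & !ball_mask(3, pad = 5)
  expect_equal(count_voids(hollow), 1L)
  # a cavity opened to the border by a tunnel is no longer a void
  box <- cube_mask(8)            # occupies 3:10 of a 12-cube array
  box[5:8, 5:8, 5:8] <- FALSE    # enclosed cavity
  expect_equal(count_voids(box), 1L)
  box[9:12, 6:7, 6:7] <- FALSE   # tunnel to the array face
  expect_equal(count_voids(box), 0L)
})

test_that("void count agrees with the Euler-characteristic cavity count", {
  # for a connected shape without handles: cavities = chi - 1, with chi
  # computed from the cubical complex of the voxel set
  euler_chi <- function(mask) {
    w <- which(mask, arr.ind = TRUE)
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    verts <- unique(do.call(rbind, lapply(0:7, function(b) {
      w + matrix(c(b %% 2, (b %/% 2) %% 2, b %/% 4), nrow(w), 3,
                 byrow = TRUE)
    })))
    edges <- unique(rbind(
      do.call(rbind, lapply(list(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1),
                                 c(0, 1, 1)), function(o) {
        cbind(w + matrix(o, nrow(w), 3, byrow = TRUE), 1)
      })),
      do.call(rbind, lapply(list(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1),
                                 c(1, 0, 1)), function(o) {
        cbind(w + matrix(o, nrow(w), 3, byrow = TRUE), 2)
      })),
      do.call(rbind, lapply(list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                 c(1, 1, 0)), function(o) {
        cbind(w + matrix(o, nrow(w), 3, byrow = TRUE), 3)
      }))))
    faces <- unique(rbind(
      do.call(rbind, lapply(list(c(0, 0, 0), c(1, 0, 0)), function(o) {
        cbind(w + matrix(o, nrow(w), 3, byrow = TRUE), 1)
      })),
      do.call(rbind, lapply(list(c(0, 0, 0), c(0, 1, 0)), function(o) {
        cbind(w + matrix(o, nrow(w), 3, byrow = TRUE), 2)
      })),
      do.call(rbind, lapply(list(c(0, 0, 0), c(0, 0, 1)), function(o) {
        cbind(w + matrix(o, nrow(w), 3, byrow = TRUE), 3)
      }))))
    nrow(verts) - nrow(edges) + nrow(faces) - nrow(w)
  }
  for (mask in list(ball_mask(5), ball_mask(5) & !ball_mask(2, pad = 5),
                    cube_mask(6))) {
    expect_equal(count_voids(mask), euler_chi(mask) - 1L)
  }
})
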