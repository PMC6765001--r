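test_that("an empty volume yields zero detections, not an error", {
  dets <- count_nuclei(array(0, c(16, 40, 40)), spacing_um = c(1, 0.5, 0.5))
  expect_equal(nrow(dets), 0L)
})

test_that("well-separated nuclei are counted exactly", {
  cfg <- volume_sim_config("young_cortex", shape_vox = c(40, 160, 160),
                           n_cells = 50, channels = c("nuclei", "edu"),
                           seed = 17)
  vs <- simulate_volume(cfg)
  dets <- count_nuclei(vs$volume)
  expect_equal(nrow(dets), 50L)
  # detections land near true centres (2-voxel match radius in xy)
  tr <- vs$truth$nuclei
  dmin <- vapply(seq_len(nrow(tr)), function(i) {
    min(sqrt((dets$z - tr$z[i])^2 + (dets$y - tr$y[i])^2 +
               (dets$x - tr$x[i])^2))
  }, numeric(1))
  expect_true(all(dmin < 3))
})

test_that("two nuclei inside the xy exclusion radius merge to one maximum", {
  a <- array(0, c(16, 60, 60))
  sp <- c(1, 0.5, 0.5)
  a <- thymoscope:::render_nucleus(a, dim(a), sp, c(8, 15, 15), c(3, 4, 4))
  a <- thymoscope:::render_nucleus(a, dim(a), sp, c(8, 15, 18.5), c(3, 4, 4))
  dets <- count_nuclei(a, spacing_um = sp, preprocess = FALSE)
  expect_equal(nrow(dets), 1L)   # centres 3.5 um apart < 5 um exclusion
  b <- array(0, c(16, 60, 60))
  b <- thymoscope:::render_nucleus(b, dim(b), sp, c(8, 8, 8), c(3, 4, 4))
  b <- thymoscope:::render_nucleus(b, dim(b), sp, c(8, 22, 22), c(3, 4, 4))
  expect_equal(nrow(count_nuclei(b, spacing_um = sp, preprocess = FALSE)),
               2L)
})

test_that("detection is translation-equivariant for interior content", {
  sp <- c(1, 0.5, 0.5)
  a <- array(0, c(20, 60, 60))
  a <- thymoscope:::render_nucleus(a, dim(a), sp, c(8, 12, 12), c(3, 4, 4))
  b <- array(0, c(20, 60, 60))
  b <- thymoscope:::render_nucleus(b, dim(b), sp, c(11, 16, 17), c(3, 4, 4))
  da <- count_nuclei(a, spacing_um = sp, preprocess = FALSE)
  db <- count_nuclei(b, spacing_um = sp, preprocess = FALSE)
  expect_equal(db$z - da$z, 3)
  expect_equal(db$y - da$y, 4)
  expect_equal(db$x - da$x, 5)
})

test_that("density is count over counted volume, with margin exclusion", {
  cfg <- volume_sim_config("young_cortex", shape_vox = c(32, 160, 160),
                           n_cells = 40, channels = c("nuclei", "edu"),
                           seed = 23)
  vs <- simulate_volume(cfg)
  dets <- count_nuclei(vs$volume)
  dens <- nucleus_density(dets, compartment = "cortex")
  ext <- dim(vs$truth$cell_labels) * vs$volume$spacing
  expect_equal(dens$volume_mm3, prod(ext) * 1e-9)
  expect_equal(dens$density_per_mm3, dens$count / dens$volume_mm3)
  # a capsule margin shrinks the counted volume and drops low-y detections
  dets_m <- count_nuclei(vs$volume, exclude_margin_um = 20)
  dens_m <- nucleus_density(dets_m)
  expect_lt(dens_m$volume_mm3, dens$volume_mm3)
  expect_true(all(dets_m$y >= 20))
})

test_that("aged cortex at constant cell number quadruples the density", {
  # aged tissue volume contracts to 25% while nuclei number is unchanged
  young <- simulate_volume(volume_sim_config(
    "young_cortex", shape_vox = c(32, 160, 160), n_cells = 12,
    channels = c("nuclei", "edu"), seed = 29))
  aged <- simulate_volume(volume_sim_config(
    "aged_cortex", shape_vox = c(40, 72, 72), n_cells = 12,
    channels = c("nuclei", "edu"), seed = 30))
  dy <- nucleus_density(count_nuclei(young$volume))
  da <- nucleus_density(count_nuclei(aged$volume))
  ratio <- da$density_per_mm3 / dy$density_per_mm3
  vol_ratio <- dy$volume_mm3 / da$volume_mm3
  # estimator reproduces the constructed volume contraction within 10%
  expect_lt(abs(ratio - vol_ratio) / vol_ratio, 0.10)
  expect_gt(ratio, 3.5)
})

test_that("compare_groups matches the textbook Welch formula", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  out <- compare_groups(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(out$t, t_hand)
  expect_equal(out$p, 2 * stats::pt(-abs(t_hand), df_hand))
  ident <- compare_groups(c(5, 5), c(5, 5))
  expect_equal(ident$p, 1)
  expect_equal(ident$t, 0)
  shifted <- compare_groups(a, b + 1000)
  expect_lt(shifted$p, 1e-4)
})

test_that("labeling index arithmetic and degenerate inputs", {
  dets <- tibble::tibble(z = seq(5, 5 + 1023 * 0.01, length.out = 1024),
                         y = 5, x = 5)
  edu <- array(0, c(12, 12, 12))
  li0 <- labeling_index(dets, edu, spacing_um = c(1, 1, 1))
  expect_equal(li0$percent_labeled, 0)
  # 1 labeled of 1024 total is 0.0977 percent
  li <- tibble::tibble(labeled = 1, total = 1024)
  expect_equal(100 * li$labeled / li$total, 0.09765625)
  expect_error(labeling_index(dets[0, ], edu, spacing_um = c(1, 1, 1)),
               "zero nuclei")
  expect_error(labeling_index(dets, edu, spacing_um = c(1, 1, 1),
                              method = "fixed"), "threshold")
})

test_that("labeling index is calibrated across S-phase rates", {
  rates <- c(0.001, 0.045, 0.15)
  for (r in rates) {
    lab <- 0L
    tot <- 0L
    for (i in 1:15) {
      vs <- simulate_volume(volume_sim_config(
        "young_cortex", shape_vox = c(32, 160, 160), n_cells = 30,
        channels = c("nuclei", "edu"), edu_rate = r,
        seed = 4000 + 100 * which(rates == r) + i))
      li <- labeling_index(vs$truth$nuclei, vs$volume$channels$edu,
                           spacing_um = vs$volume$spacing)
      lab <- lab + li$labeled
      tot <- tot + li$total
      # classification matches the generator labels volume by volume
      expect_equal(li$labeled, sum(vs$truth$nuclei$edu))
    }
    bias_pp <- abs(100 * lab / tot - 100 * r)
    mc_se_pp <- 100 * sqrt(r * (1 - r) / tot)
    expect_lte(bias_pp, 0.5 + 2 * mc_se_pp)
  }
})
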