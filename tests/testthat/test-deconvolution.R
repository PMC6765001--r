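test_that("detection filter implements the majority rules", {
  # 4 genes x one 3-replicate day, evaluated by brute force by hand
  vals <- matrix(c(5, 5, 5,      # below median, all absent -> excluded
                   100, 100, 100, # P calls -> kept
                   60, 60, 5,    # calls A but 2/3 above chip median -> kept
                   50, 4, 4),    # 1/3 above median, absent -> excluded
                 nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  sm <- toy_signal_matrix(vals, c("6" = 3))
  calls <- matrix(c("A", "A", "A",
                    "P", "P", "A",
                    "A", "A", "A",
                    "A", "A", "A"), nrow = 4, byrow = TRUE,
                  dimnames = dimnames(vals))
  kept <- detection_filter(sm, calls)
  expect_setequal(kept, c("g2", "g3"))
})

test_that("detection filter errors without an eligible timepoint", {
  vals <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  sm <- toy_signal_matrix(vals, c("6" = 1, "7" = 1))
  calls <- matrix("P", 2, 2, dimnames = dimnames(vals))
  expect_error(detection_filter(sm, calls), "replicates")
})

test_that("lymphoid proportion is the marker-mean tissue:lymphoid ratio", {
  # two markers with constant ratios 0.8 and 0.6 across all days -> p = 0.7
  days <- c("0" = 1, "6" = 1, "12" = 1, "17" = 1, "23" = 1)
  lv <- matrix(100, 2, 5, dimnames = list(c("m1", "m2"), NULL))
  tv <- rbind(m1 = rep(80, 5), m2 = rep(60, 5))
  colnames(tv) <- colnames(lv) <- paste0("s", 1:5)
  tissue <- toy_signal_matrix(tv, days, fraction = "tissue")
  lymph <- toy_signal_matrix(lv, days, fraction = "lymphoid")
  p <- estimate_lymphoid_proportion(tissue, lymph, c("m1", "m2"))
  expect_equal(p$p, rep(0.7, nrow(p)), tolerance = 1e-8)
})

test_that("pure-lymphoid markers give the clamped upper limit", {
  days <- c("0" = 1, "6" = 1, "12" = 1, "17" = 1, "23" = 1)
  v <- matrix(100, 2, 5, dimnames = list(c("m1", "m2"), paste0("s", 1:5)))
  tissue <- toy_signal_matrix(v, days, fraction = "tissue")
  lymph <- toy_signal_matrix(v, days, fraction = "lymphoid")
  p <- estimate_lymphoid_proportion(tissue, lymph, c("m1", "m2"))
  expect_equal(p$p, rep(1 - 1e-6, nrow(p)))
  expect_error(estimate_lymphoid_proportion(tissue, lymph, character(0)),
               "empty")
})

test_that("deconvolution applies the mixture inversion", {
  Tm <- matrix(8, 1, 1, dimnames = list("g", "0"))
  Lm <- matrix(10, 1, 1, dimnames = list("g", "0"))
  est <- deconvolve_stromal(Tm, Lm, c("0" = 0.6))
  expect_equal(unname(est$values[1, 1]), (8 - 10 * 0.6) / 0.4)  # = 5
  # p = 0 returns tissue unchanged
  est0 <- deconvolve_stromal(Tm, Lm, c("0" = 1e-9))
  expect_equal(unname(est0$values[1, 1]), 8, tolerance = 1e-6)
  # p >= 1 is a domain error naming the day
  expect_error(deconvolve_stromal(Tm, Lm, c("0" = 1)), "day 0")
  # negatives are floored and counted
  estn <- deconvolve_stromal(Tm, matrix(20, 1, 1, dimnames = list("g", "0")),
                             c("0" = 0.6))
  expect_equal(unname(estn$values[1, 1]), 0)
  expect_equal(estn$n_floored, 1L)
})

test_that("noise-free end-to-end recovery is exact", {
  sim <- simulate_expression(small_expr_config(n_genes = 250, seed = 8))
  expressed <- detection_filter(sim$tissue, sim$calls)
  tf <- fit_robust_spline(thymoscope:::sm_subset_genes(sim$tissue, expressed))
  lf <- fit_robust_spline(thymoscope:::sm_subset_genes(sim$lymphoid, expressed))
  p <- estimate_lymphoid_proportion(sim$tissue, sim$lymphoid,
                                    sim$truth$markers)
  est <- deconvolve_stromal(tf, lf, p)
  S <- sim$truth$stromal[expressed, colnames(est$values)]
  rel <- abs(est$values - S) / pmax(S, 1)
  expect_lt(max(rel), 1e-6)
})

test_that("quantile renormalization rank-maps onto the reference", {
  S <- matrix(c(1, 5, 3), 3, 1, dimnames = list(letters[1:3], "0"))
  R <- matrix(c(10, 20, 30), 3, 1, dimnames = list(letters[1:3], "0"))
  est <- structure(list(values = S, p = c("0" = 0.5), n_floored = 0L,
                        renormalized = FALSE), class = "stromal_estimate")
  out <- quantile_renormalize(est, R)
  expect_equal(unname(out$values[, 1]), c(10, 30, 20))
  # post-condition: per-day output multiset equals the reference multiset
  expect_equal(sort(out$values[, 1]), sort(R[, 1]), ignore_attr = TRUE)
  expect_true(out$renormalized)
})

test_that("stromal gene list thresholds at marker mean + k sd", {
  Tm <- matrix(c(0.5, 0.6, 0.7, 0.9, 0.8), 5, 1,
               dimnames = list(c("m1", "m2", "m3", "hi", "lo"), "0"))
  Lm <- matrix(1, 5, 1, dimnames = list(rownames(Tm), "0"))
  gl <- stromal_gene_list(Tm, Lm, c("m1", "m2", "m3"), k = 2.5)
  expect_equal(attr(gl, "threshold"), 0.6 + 2.5 * 0.1, tolerance = 1e-12)
  expect_true("hi" %in% gl$gene)
  expect_false("lo" %in% gl$gene)
  expect_error(stromal_gene_list(Tm, Lm, "m1", k = 2.5), ">= 2 markers")
})

test_that("the k = 2.5 list is nested in the k = 2.0 list", {
  sim <- simulate_expression(small_expr_config(n_genes = 300, seed = 13,
                                               noise_sd = 0.05))
  g25 <- stromal_gene_list(sim$tissue, sim$lymphoid, sim$truth$markers,
                           k = 2.5)
  g20 <- stromal_gene_list(sim$tissue, sim$lymphoid, sim$truth$markers,
                           k = 2.0)
  expect_true(all(g25$gene %in% g20$gene))
  # markers themselves are never called stromal at low noise
  expect_length(intersect(g20$gene, sim$truth$markers), 0)
})

test_that("dynamic-gene flagging uses the max/min fold rule", {
  S <- rbind(flat = rep(5, 4), up = c(4, 6, 8, 10), mild = c(6, 7, 8, 10))
  colnames(S) <- as.character(c(0, 6, 12, 23))
  fl <- flag_dynamic_genes(S, fold = 2)
  expect_equal(setNames(fl$dynamic, fl$gene),
               c(flat = FALSE, up = TRUE, mild = FALSE))
  expect_error(flag_dynamic_genes(S, fold = 0.5), "fold")
})

test_that("p recovery is accurate under noise", {
  errs <- vapply(1:5, function(s) {
    sim <- simulate_expression(
      expr_sim_config(n_genes = 120, n_marker_genes = 50, noise_sd = 0.05,
                      seed = 100 + s))
    p <- estimate_lymphoid_proportion(sim$tissue, sim$lymphoid,
                                      sim$truth$markers)
    mean(abs(p$p - 0.85))
  }, numeric(1))
  expect_lt(mean(errs), 0.01)
})
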