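# exhaustive oracle: enumerate all C(N, n) gene lists of size n and count
# those whose overlap with the set reaches k
enum_overrep_p <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- seq_len(K)
  combos <- utils::combn(N, n)
  hits <- apply(combos, 2, function(cc) sum(cc %in% inset) >= k)
  mean(hits)
}

test_that("fisher_overrep matches exhaustive enumeration on small universes", {
  cases <- list(c(N = 10, K = 4, n = 5), c(N = 12, K = 6, n = 4),
                c(N = 20, K = 8, n = 6), c(N = 15, K = 3, n = 7))
  for (cs in cases) {
    N <- cs["N"]; K <- cs["K"]; n <- cs["n"]
    universe <- sprintf("g%02d", seq_len(N))
    set <- universe[seq_len(K)]
    for (k in 0:min(K, n)) {
      lst <- c(set[seq_len(k)],
               setdiff(universe, set)[seq_len(n - k)])
      r <- fisher_overrep(lst, set, universe)
      expect_equal(r$overlap, as.integer(k))
      expect_lt(abs(r$p - enum_overrep_p(N, K, n, k)), 1e-12)
    }
  }
})

test_that("fisher_overrep agrees with the one-sided Fisher exact test", {
  universe <- sprintf("g%03d", 1:100)
  set <- universe[1:20]
  lst <- c(universe[1:5], universe[51:55])
  r <- fisher_overrep(lst, set, universe)
  tab <- matrix(c(5, 5, 15, 75), 2, 2)
  expect_equal(r$p, stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
  # degenerate: list = background gives p = 1 with full overlap
  r2 <- fisher_overrep(universe, set, universe)
  expect_equal(r2$overlap, 20L)
  expect_equal(r2$p, 1)
  expect_error(fisher_overrep(lst, "absent_gene", universe), "background")
})

test_that("p decreases monotonically in overlap at fixed margins", {
  universe <- sprintf("g%03d", 1:60)
  set <- universe[1:15]
  ps <- vapply(0:10, function(k) {
    lst <- c(set[seq_len(k)], setdiff(universe, set)[seq_len(10 - k)])
    fisher_overrep(lst, set, universe)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("BH correction matches the hand computation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(max(q) <= 1)
  # q is monotone nondecreasing in p-rank
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("enrichment time course normalizes to day 0 with signed logs", {
  coll <- toy_collection()
  set.seed(11)
  lists <- list(
    "0" = c(coll$sets$projection_assembly[1:4],
            sample(setdiff(coll$universe,
                           coll$sets$projection_assembly), 16)),
    "10" = c(coll$sets$projection_assembly[1:12],
             sample(setdiff(coll$universe,
                            coll$sets$projection_assembly), 8))
  )
  es <- enrichment_timecourse(lists, coll, min_size = 10, name_filter = NULL)
  expect_true(all(es$normalized[es$day == "0"] == 0))
  pa <- es[es$set == "projection_assembly", ]
  d10 <- pa[pa$day == "10", ]
  d0 <- pa[pa$day == "0", ]
  expect_equal(d10$normalized,
               d10$direction * (-log10(d10$p) + log10(d0$p)))
  expect_gt(d10$normalized, 0)  # stronger over-representation at day 10
})

test_that("size and name filters drop the right sets", {
  coll <- toy_collection()
  lists <- list("0" = coll$universe[1:10], "5" = coll$universe[1:10])
  es <- enrichment_timecourse(lists, coll, min_size = 10,
                              name_filter = "projection")
  expect_setequal(unique(es$set),
                  c("projection_assembly", "cell_projection_organization"))
  # 9-member set excluded even though its name matches
  expect_false("small_projection_set" %in% es$set)
  expect_warning(
    empty <- enrichment_timecourse(lists, coll, min_size = 50,
                                   name_filter = "projection"),
    "no gene set")
  expect_equal(nrow(empty), 0)
})

test_that("pathway enrichment applies size/keyword filters and sorts by q", {
  universe <- sprintf("g%03d", 1:300)
  sets <- list(
    big_signaling_pathway = universe[1:250],     # > 200: excluded
    mTOR_signalling = universe[1:12],
    IL1_signaling = universe[c(1:6, 100:105)],
    WNT_signaling = universe[200:230],
    metabolism = universe[1:15],                 # no keyword: excluded
    ERK_signaling = universe[c(2:9, 150:155)]
  )
  coll <- gene_set_collection(sets, universe)
  lst <- universe[1:20]
  out <- pathway_enrich(lst, coll, max_size = 200)
  expect_false("big_signaling_pathway" %in% out$set)
  expect_false("metabolism" %in% out$set)
  expect_true("mTOR_signalling" %in% out$set)  # spelling variant retained
  # ranking equals the brute-force sort of per-pathway p
  keep <- setdiff(names(sets), c("big_signaling_pathway", "metabolism"))
  ps <- vapply(keep, function(s) {
    fisher_overrep(lst, sets[[s]], universe)$p
  }, numeric(1))
  expect_equal(out$set, names(sort(ps)))
  expect_true(all(diff(out$q) >= -1e-12))
})

test_that("temporal patterns are classified by early/late window signs", {
  days <- c(0, 2, 6, 10, 14, 18, 22)
  expect_equal(
    classify_temporal_pattern(days, c(0, -2, -2, -1.5, 0.5, 0.4, 0.2)),
    "neg_early_restored_late")
  expect_equal(
    classify_temporal_pattern(days, c(0, 2, 2, 1.5, -0.5, -1, -0.2)),
    "pos_early_depleted_late")
  expect_equal(classify_temporal_pattern(days, rep(0, 7)), "other")
  expect_equal(
    classify_temporal_pattern(days, c(0, 1, 1, 1, 1, 1, 1)), "other")
  expect_error(classify_temporal_pattern(c(0, 5), c(0, 1)), ">= 3 days")
})

test_that("null gene lists keep the q < 0.05 discovery fraction controlled", {
  set.seed(31)
  universe <- sprintf("g%04d", 1:400)
  sets <- lapply(1:40, function(i) sample(universe, 20))
  names(sets) <- sprintf("set%02d", 1:40)
  coll <- gene_set_collection(sets, universe)
  hits <- 0L
  n_draws <- 100L
  for (i in seq_len(n_draws)) {
    lst <- sample(universe, 25)
    qs <- bh_fdr(vapply(sets, function(s) {
      fisher_overrep(lst, s, universe)$p
    }, numeric(1)))
    hits <- hits + sum(qs < 0.05)
  }
  frac <- hits / (n_draws * length(sets))
  expect_lt(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / (n_draws * length(sets))))
})
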