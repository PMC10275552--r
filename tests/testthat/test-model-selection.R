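test_that("the percentile decision rule follows the stated thresholds and is monotone", {
  d_cs <- seq(-0.29, 8, length.out = 500) # 5th percentile near -0.29
  d_iw <- seq(-5, 1.11, length.out = 500) # 95th percentile near 1.11
  p5 <- stats::quantile(d_cs, 0.05, type = 7, names = FALSE)
  p95 <- stats::quantile(d_iw, 0.95, type = 7, names = FALSE)
  expect_identical(decide_model(6.43, d_cs, d_iw), "CS")
  expect_identical(decide_model(0.5, d_cs, d_iw), "indecisive")
  expect_identical(decide_model(-4, d_cs, d_iw), "IW")
  decisions <- vapply(seq(-6, 8, by = 0.25), decide_model,
                      character(1), d_cs, d_iw)
  ord <- c(IW = 1L, indecisive = 2L, CS = 3L)
  expect_true(all(diff(ord[decisions]) >= 0))
})

test_that("goodness-of-fit statistics follow the rank and tie conventions", {
  ds <- make_table1_fixture(seed = 1)
  expect_equal(unname(gof_statistics(ds)), c(65, 5, 28, 1))
  empty <- island_dataset(30, 10, list())
  expect_equal(unname(gof_statistics(empty)), c(0, 0, 0, 0))
  tie <- island_dataset(30, 10, list(end_clade(10, c(5, 2), 1L, "a"),
                                     end_clade(5, c(4, 1), 2L, "b")))
  s <- gof_statistics(tie)
  expect_equal(unname(s["largest_clade_size"]), 3)
  expect_equal(unname(s["largest_clade_rank"]), 1) # tie goes to the older clade
})

test_that("bootstrap with identical models on both sides gives zero deltas and no decision", {
  ds <- small_two_clade()
  p <- island_params(0.35, 0.1, 9, 0.004, 0)
  f <- island_fit_from_params(ds, "CS_noA", p)
  b <- bootstrap_lrt(ds, f, f, n_reps = 6, seed = 2, eval_budget = 400,
                     models = c("CS_noA", "CS_noA"))
  expect_true(all(abs(b$deltas_under_cs) < 1e-9))
  expect_true(all(abs(b$deltas_under_iw) < 1e-9))
  expect_identical(decide_model(0, b$deltas_under_cs, b$deltas_under_iw),
                   "indecisive")
})

test_that("identical seeds reproduce identical bootstrap results", {
  ds <- small_two_clade()
  f_cs <- island_fit_from_params(ds, "CS_noA",
                                 island_params(0.35, 0.1, 9, 0.004, 0))
  f_iw <- island_fit_from_params(ds, "IW_noA",
                                 island_params(0.3, 0.12, 14, 0.005, 0))
  b1 <- suppressWarnings(
    bootstrap_lrt(ds, f_cs, f_iw, n_reps = 4, seed = 77, eval_budget = 400))
  b2 <- suppressWarnings(
    bootstrap_lrt(ds, f_cs, f_iw, n_reps = 4, seed = 77, eval_budget = 400))
  expect_identical(b1[c("deltas_under_cs", "deltas_under_iw", "pct5_cs",
                        "pct95_iw", "decision")],
                   b2[c("deltas_under_cs", "deltas_under_iw", "pct5_cs",
                        "pct95_iw", "decision")])
})

test_that("gof comparison reports medians and empirical percentiles", {
  ds <- small_two_clade()
  p <- island_params(0.35, 0.1, 9, 0.004, 0)
  f <- island_fit_from_params(ds, "CS_noA", p)
  g <- gof_compare(ds, f, n_sims = 200, seed = 3)
  expect_equal(dim(g$sims), c(200, 4))
  expect_true(all(g$percentile >= 0 & g$percentile <= 1))

  # an essentially zero colonization rate: every simulation is empty and the
  # non-empty data sit at the top of the simulated distribution
  f0 <- island_fit_from_params(ds, "CS_noA",
                               island_params(0.35, 0.1, 9, 1e-12, 0))
  g0 <- gof_compare(ds, f0, n_sims = 50, seed = 4)
  expect_true(all(g0$sims == 0))
  expect_true(all(g0$percentile == 1))
})

test_that("self-fit percentiles are uniform (calibration of the gof ensemble)", {
  # simulate from a model, refit-free calibration: percentile of data drawn
  # from the same parameters must be uniform after randomized tie-breaking
  p <- island_params(0.5, 0.15, 6, 0.02, 0)
  ds0 <- island_dataset(6, 25, list(end_clade(4, 2)))
  f <- island_fit_from_params(ds0, "CS_noA", p)
  set.seed(42)
  sims <- simulate(f, nsim = 160)
  stat <- vapply(sims, function(s) gof_statistics(s)[["total_species"]],
                 numeric(1))
  ref <- vapply(simulate(f, nsim = 400), function(s)
    gof_statistics(s)[["total_species"]], numeric(1))
  pit <- vapply(stat, function(x) {
    lo <- mean(ref < x); hi <- mean(ref <= x)
    stats::runif(1, lo, hi)
  }, numeric(1))
  expect_gt(stats::ks.test(pit, "punif")$p.value, 0.01)
})
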