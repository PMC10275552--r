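test_that("fitting is refused when the dataset holds no events", {
  empty <- island_dataset(10, 50, list())
  expect_error(fit_island_model(empty, "CS_noA"), "no events")
})

test_that("information criteria reproduce the published model-comparison arithmetic", {
  # the five fitted models of the empirical analysis: (df, LL) pairs
  lls <- c(DI = -215.87, CS = -208.67, CS_noA = -208.67,
           IW = -215.10, IW_noA = -215.10)
  dfs <- c(4L, 5L, 4L, 5L, 4L)
  fits <- Map(function(m, ll, df) {
    structure(list(model = m, loglik = ll, df = df, n_events = 65L),
              class = "island_fit")
  }, names(lls), lls, dfs)
  tab <- information_criteria(fits)
  expect_equal(tab$AIC[tab$model == "CS_noA"], 425.34, tolerance = 1e-9)
  expect_equal(tab$AIC[tab$model == "CS"], 427.34, tolerance = 1e-9)
  expect_equal(tab$AIC_weight[tab$model == "CS_noA"], 0.73, tolerance = 0.01)
  single <- information_criteria(fits[2])
  expect_equal(single$AIC_weight, 1)
  expect_equal(single$BIC_weight, 1)
})

test_that("a fit reports a loglikelihood that re-evaluates through the likelihood modules", {
  set.seed(14)
  p <- island_params(0.4, 0.1, 10, 0.02, 0)
  repeat {
    sim <- simulate_cs(p, 8, 30)
    if (length(sim$clades) >= 2 && !anyDuplicated(
      vapply(sim$clades, `[[`, integer(1), "mainland_species_id"))) break
  }
  f <- fit_island_model(sim, "CS_noA", n_starts = 2, seed = 3,
                        eval_budget = 1500)
  expect_equal(f$loglik, loglik_cs(sim, f$params), tolerance = 1e-6)
  expect_equal(unname(coef(f)["lambda_a"]), 0)
  expect_s3_class(logLik(f), "logLik")
  expect_equal(attr(logLik(f), "df"), 4L)
  expect_equal(AIC(f), 2 * 4 - 2 * f$loglik)

  f_iw <- fit_island_model(sim, "IW_noA", n_starts = 1, seed = 3,
                           eval_budget = 1500)
  expect_equal(f_iw$loglik, loglik_iw(sim, f_iw$params), tolerance = 1e-6)
})

test_that("rescaling time rescales the rate estimates (unit covariance)", {
  ds <- island_dataset(10, 30, list(
    end_clade(7, c(4.1, 2.3), 1L, "a"),
    end_clade(5, c(1.7), 2L, "b"),
    nes_clade(3.2, 3L, "c")))
  scale_ds <- function(ds, c) {
    ds$island_age <- ds$island_age * c
    ds$clades <- lapply(ds$clades, function(cl) {
      cl$colonization_age <- cl$colonization_age * c
      cl$branching_ages <- cl$branching_ages * c
      cl
    })
    ds
  }
  f1 <- fit_island_model(ds, "CS_noA", n_starts = 1, seed = 5,
                         eval_budget = 2500)
  f2 <- fit_island_model(scale_ds(ds, 2), "CS_noA", n_starts = 1, seed = 5,
                         eval_budget = 2500)
  co1 <- coef(f1); co2 <- coef(f2)
  for (nm in c("lambda_c0", "mu", "gamma0")) {
    expect_equal(co2[[nm]], co1[[nm]] / 2, tolerance = 0.02)
  }
  expect_equal(co2[["K"]], co1[["K"]], tolerance = 0.02)
})

test_that("a fixed-parameter fit evaluates and simulates", {
  ds <- make_table1_fixture(seed = 1)
  p <- island_params(0.44, 0.11, 36.45, 2e-4, 0)
  f <- island_fit_from_params(ds, "CS_noA", p)
  expect_equal(f$loglik, loglik_cs(ds, p))
  expect_identical(f$df, 4L)
  sims <- simulate(f, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "island_dataset")
  # noA variants force the anagenesis rate to zero
  expect_equal(f$params$lambda_a, 0)
})
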