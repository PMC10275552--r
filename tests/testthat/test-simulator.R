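test_that("no colonization rate means an empty island, always", {
  p <- island_params(0.5, 0.1, 20, 0, 0.1)
  set.seed(1)
  for (i in 1:20) {
    expect_length(simulate_iw(p, 10, 100)$clades, 0)
    expect_length(simulate_cs(p, 10, 100)$clades, 0)
  }
})

test_that("a carrying capacity of one forbids cladogenesis: all clades are singletons", {
  p <- island_params(5, 0.05, 1, 0.05, 0)
  set.seed(2)
  for (i in 1:10) {
    sim <- simulate_iw(p, 20, 30, debug_cap = TRUE)
    sizes <- vapply(sim$clades, function(cl) 1L + length(cl$branching_ages),
                    integer(1))
    if (length(sizes)) expect_true(all(sizes == 1L))
  }
})

test_that("diversity never exceeds the cap during simulation", {
  p <- island_params(1.2, 0.3, 7.5, 0.02, 0.05)
  set.seed(3)
  for (i in 1:15) {
    sim <- simulate_iw(p, 25, 100, keep_log = TRUE, debug_cap = TRUE)
    expect_lte(total_species(sim), diversity_cap(p))
    simulate_cs(p, 25, 40, debug_cap = TRUE)
  }
  succeed()
})

test_that("pure-immigration islands are colonized at the Poisson rate", {
  p <- island_params(0, 0, Inf, 0.1, 0)
  set.seed(4)
  n <- 1e4
  hits <- sum(vapply(seq_len(n), function(i)
    length(simulate_iw(p, 10, 1)$clades) > 0, logical(1)))
  target <- 1 - exp(-1)
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(hits / n - target), 3 * se)
})

test_that("without feedback (K = Inf) the CS and IW simulators coincide in law", {
  p <- island_params(0.25, 0.1, Inf, 0.02, 0)
  set.seed(5)
  n <- 2000
  tot_iw <- vapply(seq_len(n), function(i) total_species(simulate_iw(p, 8, 25)),
                   numeric(1))
  tot_cs <- vapply(seq_len(n), function(i) total_species(simulate_cs(p, 8, 25)),
                   numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(tot_iw, tot_cs))$p.value, 0.01)
})

test_that("reconstructed output prunes extinct lineages and keeps only surviving splits", {
  p <- island_params(0.6, 0.35, 12, 0.03, 0.05)
  set.seed(6)
  for (i in 1:25) {
    sim <- simulate_iw(p, 15, 50, keep_log = TRUE)
    lg <- attr(sim, "log")
    if (!length(sim$clades)) next
    idx <- seq_len(lg$n_sp)
    extant_by_clade <- table(factor(lg$clade[idx][lg$alive[idx]],
                                    levels = seq_len(lg$n_cl)))
    # per surviving clade: extant count = 1 + number of reconstructed branchings
    surv <- vapply(sim$clades, `[[`, character(1), "name")
    sizes <- vapply(sim$clades, function(cl) 1L + length(cl$branching_ages),
                    integer(1))
    expect_equal(sort(as.integer(sizes)),
                 sort(as.integer(extant_by_clade[extant_by_clade > 0])))
    # every branching age lies strictly inside (0, colonization age)
    for (cl in sim$clades) {
      if (length(cl$branching_ages)) {
        expect_true(all(cl$branching_ages < cl$colonization_age))
        expect_true(all(cl$branching_ages > 0))
      }
    }
  }
})

test_that("with no extinction and no anagenesis, surviving clade counts are thinned Poisson", {
  # with no cladogenesis the reset rule folds all repeat colonizations of a
  # mainland species into one clade: a species contributes a clade iff it
  # colonizes at least once
  p <- island_params(0, 0, Inf, 0.05, 0)
  set.seed(7)
  n <- 2000
  M <- 10; T <- 6
  counts <- vapply(seq_len(n), function(i)
    length(simulate_iw(p, T, M)$clades), numeric(1))
  target <- M * (1 - exp(-p$gamma0 * T))
  se <- sqrt(M * (1 - exp(-p$gamma0 * T)) * exp(-p$gamma0 * T) / n)
  expect_lt(abs(mean(counts) - target), 3 * se)
})

test_that("replicate simulation is reproducible under a seed", {
  p <- island_params(0.3, 0.1, 10, 0.03, 0)
  a <- simulate_island(p, 10, 20, "IW", reps = 5, seed = 11)
  b <- simulate_island(p, 10, 20, "IW", reps = 5, seed = 11)
  expect_identical(a, b)
})
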