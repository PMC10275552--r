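test_that("Q-state propagation honours the trivial cases", {
  p <- island_params(0.3, 0.1, 20, 0.01, 0.05)
  st <- qstate(10, age = 5)
  expect_identical(propagate_Q(st, 5, p, M = 10), st) # zero-length interval

  p0 <- island_params(0, 0, Inf, 0, 0)
  st2 <- propagate_Q(qstate(10, age = 5), 0, p0, M = 10)
  expect_equal(st2$q[1, 1], 1)
  expect_equal(st2$log_scale, 0)

  # k = 0, only colonization active: Q_0 decays at rate M * gamma0
  pg <- island_params(0, 0, Inf, 0.01, 0)
  st3 <- propagate_Q(qstate(40, age = 5), 0, pg, M = 10)
  expect_equal(log(st3$q[1, 1]) + st3$log_scale, -0.5, tolerance = 1e-10)
})

test_that("event operators scale by the clamped rates and advance k", {
  pinf <- island_params(0.44, 0, Inf, 0.01, 0)
  st <- qstate(5, age = 3)
  st <- apply_colonization(st, pinf, M = 10, status = "non_endemic_singleton")
  expect_equal(st$k, 1L)
  expect_equal(st$k_ne, 1L)
  expect_equal(st$log_scale, log(0.01), tolerance = 1e-12)

  st <- apply_branching(qstate(5, age = 3, e_max = 0), pinf)
  # branching of a singleton clade: q0 scaled by lambda_c0
  expect_equal(st$log_scale, log(0.44), tolerance = 1e-12)
  expect_equal(st$k, 1L)

  # entries at and beyond the cap are zeroed by the clamped rate
  pK <- island_params(0.44, 0.1, 36.45, 0.01, 0)
  st2 <- qstate(40, age = 3)
  st2$q[, 1] <- 1
  st2 <- apply_colonization(st2, pK, M = 10, status = "endemic_clade")
  n <- 0:40
  expect_true(all(st2$q[n + st2$k - 1L >= 37, 1] == 0))

  p_nolam <- island_params(0, 0.1, Inf, 0.01, 0)
  st3 <- apply_branching(qstate(5, age = 3), p_nolam)
  expect_true(isTRUE(attr(st3, "vanished")))
})

test_that("closed-form toy likelihoods are reproduced by both engines", {
  suite <- make_toy_suite()
  for (nm in names(suite)) {
    s <- suite[[nm]]
    ll_cpp <- loglik_iw(s$ds, s$p)
    ll_r <- loglik_iw(s$ds, s$p, loglik_opts(engine = "r"))
    expect_equal(ll_cpp, ll_r, tolerance = 1e-5,
                 label = paste("engines agree on", nm))
    if (!is.na(s$analytic)) {
      expect_equal(ll_cpp, s$analytic, tolerance = 1e-6,
                   label = paste("analytic", nm))
    }
  }
})

test_that("interval dynamics match the closed-form single-descendant probability", {
  # the probability that one observed lineage leaves exactly one extant
  # descendant (all side branches extinct) pins the hidden-birth coefficients
  lam <- 0.5; mu <- 0.3; t <- 5
  r <- lam - mu; E <- exp(r * t)
  alpha <- mu * (E - 1) / (lam * E - mu)
  beta <- lam * alpha / mu
  p1 <- (1 - alpha) * (1 - beta)
  p <- island_params(lam, mu, Inf, 0, 0)
  for (k in c(1L, 3L)) {
    st <- qstate(250, age = t)
    st$k <- k
    st <- propagate_Q(st, 0, p, M = 0)
    expect_equal(log(st$q[1, 1]) + st$log_scale, k * log(p1),
                 tolerance = 1e-8)
  }
})

test_that("data beyond the diversity cap are impossible", {
  ds <- make_table1_fixture(seed = 1) # 65 + 1 species would exceed K = 60
  p <- island_params(0.44, 0.11, 60, 3e-4, 0)
  expect_identical(loglik_iw(ds, p), -Inf)
  expect_identical(loglik_cs(island_dataset(10, 5, list(end_clade(7, c(4, 2)))),
                             island_params(0.3, 0.1, 2, 0.01, 0)), -Inf)
})

test_that("tightening solver tolerances tenfold leaves the loglikelihood stable", {
  ds <- small_two_clade()
  p <- island_params(0.35, 0.12, 15, 0.004, 0.01)
  base <- loglik_iw(ds, p, loglik_opts(tol = 1e-12, tail_tol = 1e-10))
  tight <- loglik_iw(ds, p, loglik_opts(tol = 1e-13, tail_tol = 1e-11))
  expect_lt(abs(base - tight), 1e-4)
})

test_that("raw-mass and extinction-weighted truncation agree", {
  ds <- small_two_clade()
  p <- island_params(0.35, 0.12, Inf, 0.004, 0.01)
  a <- loglik_iw(ds, p, loglik_opts(weighted_tail = TRUE))
  b <- loglik_iw(ds, p, loglik_opts(weighted_tail = FALSE, nmax0 = 150L))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("the refined colonization bookkeeping stays close to the pooled default", {
  ds <- small_two_clade()
  p <- island_params(0.3, 0.1, Inf, 0.004, 0)
  pool <- loglik_iw(ds, p)
  exact <- loglik_iw(ds, p,
                     loglik_opts(colonization_multiplicity = "pool_minus_active"))
  expect_false(identical(pool, exact))
  # the corrections are O(C/M)
  expect_lt(abs(pool - exact), 0.2)
})
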