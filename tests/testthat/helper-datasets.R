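# Shared builders for small test datasets.

nes_clade <- function(a, id = 1L, name = paste0("c", id)) {
  clade_record(name, id, "non_endemic_singleton", a)
}

end_clade <- function(a, b, id = 1L, name = paste0("c", id)) {
  clade_record(name, id, "endemic_clade", a, b)
}

small_two_clade <- function() {
  island_dataset(10, 50, list(
    end_clade(7, c(4, 2), 1L),
    nes_clade(3, 2L)
  ))
}

# a random valid dataset (construction-level randomness, not the simulator)
random_dataset <- function() {
  island_age <- stats::runif(1, 5, 40)
  M <- sample(2:2000, 1)
  n_clades <- sample(0:4, 1)
  ids <- sample.int(M, n_clades)
  clades <- lapply(seq_len(n_clades), function(j) {
    a <- stats::runif(1, 0.05, island_age * 0.99)
    m <- sample(1:6, 1)
    if (m == 1L) {
      st <- sample(c("non_endemic_singleton", "endemic_singleton"), 1)
      clade_record(paste0("cl", j), ids[j], st, a)
    } else {
      b <- sort(stats::runif(m - 1, 0, a * 0.999), decreasing = TRUE)
      clade_record(paste0("cl", j), ids[j], "endemic_clade", a, b)
    }
  })
  island_dataset(island_age, M, clades, validate = FALSE)
}

expect_loglik_equal <- function(ds, p, expected, tol = 1e-6) {
  expect_equal(loglik_iw(ds, p), expected, tolerance = tol)
}
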