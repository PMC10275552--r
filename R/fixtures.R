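#' Synthetic five-clade Hispaniola-style test dataset
#'
#' A deterministic surrogate for the five-clade island community used
#' throughout the package's tests and examples: island age 30 My, mainland
#' pool of 1000, and five endemic clades with colonization ages 22.09,
#' 13.75, 11.03, 8.85 and 8.43 My and sizes 28, 21, 3, 5 and 8 species.
#' The within-clade branching ages are not part of the published summary
#' table, so they are synthesized reproducibly as order statistics of
#' uniforms below each colonization age; the fixture emulates the clade
#' structure, not the real branching tempo.
#'
#' @param seed Integer seed for the branching-age synthesis.
#' @return A valid [island_dataset()] with 65 species in 5 clades.
#' @examples
#' ds <- make_table1_fixture(seed = 1)
#' gof_statistics(ds)
#' @export
make_table1_fixture <- function(seed = 1L) {
  set.seed(seed)
  ages <- c(22.09, 13.75, 11.03, 8.85, 8.43)
  sizes <- c(28L, 21L, 3L, 5L, 8L)
  clades <- lapply(seq_along(ages), function(j) {
    branch <- sort(stats::runif(sizes[j] - 1L, 0, ages[j]), decreasing = TRUE)
    clade_record(sprintf("clade_%d", j), j, "endemic_clade", ages[j], branch)
  })
  island_dataset(30, 1000L, clades, validate = FALSE)
}

#' Toy datasets with known or oracle-checkable likelihoods
#'
#' A named collection of minimal island datasets (at most three events each)
#' paired with parameter sets, used to pin down the likelihood machinery.
#' Cases with `mu = 0` carry closed-form loglikelihoods in `$analytic`
#' (derived by hand from the no-event survivorship factors and the event
#' densities); cases with extinction or a finite carrying capacity have
#' `analytic = NA` and are checked against the Monte-Carlo oracle
#' ([loglik_oracle_mc()]) instead. `$bin_width` suggests an oracle matching
#' window.
#'
#' @return A named list; each element has `ds` (an [island_dataset()]),
#'   `p` ([island_params()]), `analytic` and `bin_width`.
#' @export
make_toy_suite <- function() {
  T <- 5; M <- 10L
  mk <- function(clades) island_dataset(T, M, clades, validate = FALSE)
  nes <- function(a, id = 1L) clade_record(paste0("c", id), id,
                                           "non_endemic_singleton", a)
  es <- function(a, id = 1L) clade_record(paste0("c", id), id,
                                          "endemic_singleton", a)
  ec <- function(a, b, id = 1L) clade_record(paste0("c", id), id,
                                             "endemic_clade", a, b)
  suite <- list(
    empty_pure_colonization = list(
      p = island_params(0, 0, Inf, 0.01, 0),
      ds = mk(list()),
      analytic = -M * 0.01 * T, bin_width = 0.5),
    single_colonist = list(
      p = island_params(0, 0, Inf, 0.01, 0),
      ds = mk(list(nes(2.5))),
      analytic = log(0.01) - M * 0.01 * T, bin_width = 0.5),
    colonist_plus_branching = list(
      p = island_params(0.3, 0, Inf, 0.01, 0),
      ds = mk(list(ec(3, 1.5))),
      analytic = log(0.01) + log(0.3) - M * 0.01 * T - 0.3 * (3 - 1.5) -
        2 * 0.3 * 1.5,
      bin_width = 0.5),
    clade_of_three = list(
      p = island_params(0.3, 0, Inf, 0.01, 0),
      ds = mk(list(ec(3.5, c(2.5, 1)))),
      # second branching carries multiplicity 2 (either of the two lineages)
      analytic = log(0.01) + log(0.3) + log(2 * 0.3) - M * 0.01 * T -
        0.3 * (3.5 - 2.5) - 2 * 0.3 * (2.5 - 1) - 3 * 0.3 * 1,
      bin_width = 0.6),
    two_colonists = list(
      p = island_params(0, 0, Inf, 0.01, 0),
      ds = mk(list(nes(3, 1L), nes(1.5, 2L))),
      analytic = 2 * log(0.01) - M * 0.01 * T, bin_width = 0.5),
    anagenesis_endemic_singleton = list(
      p = island_params(0, 0, Inf, 0.01, 0.2),
      ds = mk(list(es(2.5))),
      analytic = log(0.01) - M * 0.01 * T + log(1 - exp(-0.2 * 2.5)),
      bin_width = 0.5),
    anagenesis_survivor = list(
      p = island_params(0, 0, Inf, 0.01, 0.2),
      ds = mk(list(nes(2.5))),
      analytic = log(0.01) - M * 0.01 * T - 0.2 * 2.5, bin_width = 0.5),
    single_colonist_extinction = list(
      p = island_params(0.2, 0.1, Inf, 0.01, 0),
      ds = mk(list(nes(2.5))),
      analytic = NA_real_, bin_width = 0.5),
    branching_extinction_capped = list(
      p = island_params(0.4, 0.15, 4, 0.02, 0),
      ds = mk(list(ec(3, 1.5))),
      analytic = NA_real_, bin_width = 0.6),
    two_colonists_extinction_capped = list(
      p = island_params(0.3, 0.1, 3, 0.02, 0),
      ds = mk(list(ec(3.5, 2), nes(1.5, 2L))),
      analytic = NA_real_, bin_width = 0.6)
  )
  suite
}
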