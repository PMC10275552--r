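#' Parametric-bootstrap likelihood-ratio test between CS and IW
#'
#' Model selection between clade-specific and island-wide
#' diversity-dependence is troublesome with information criteria alone, so
#' the comparison is bootstrapped: `n_reps` datasets are simulated under the
#' fitted CS parameters and `n_reps` under the fitted IW parameters; both
#' models are refitted to every simulated dataset; and the empirical
#' loglikelihood difference `LL_CS - LL_IW` is located within the two
#' simulated difference distributions (see [decide_model()]).
#'
#' Per-replicate fits start from the empirical MLEs (a single start by
#' default), with the starting carrying capacity raised to the largest clade
#' size (CS) or total island diversity (IW) of the simulated dataset when
#' that exceeds the empirical estimate, so the starting point always has
#' positive likelihood.
#'
#' @param ds The empirical [island_dataset()].
#' @param fit_cs,fit_iw Fitted CS-type and IW-type models (class
#'   `island_fit`), e.g. from [fit_island_model()] with models `"CS_noA"`
#'   and `"IW_noA"`.
#' @param n_reps Number of bootstrap replicates per generating model.
#' @param seed Optional seed.
#' @param n_starts,eval_budget,reltol Per-replicate fitting effort and
#'   optimizer tolerance (see [fit_island_model()]).
#' @param models Length-2 character vector: the model variants fitted to
#'   every simulated dataset (default: the variants of `fit_cs` and
#'   `fit_iw`).
#' @param opts Numerical options for the likelihood, see [loglik_opts()].
#' @param progress Print a dot every 10 replicates.
#' @return An object of class `island_boot`: the two delta distributions
#'   (`deltas_under_cs`, `deltas_under_iw`), their 5th/95th percentiles
#'   (`pct5_cs`, `pct95_iw`, inclusive linear-interpolation quantiles, R
#'   type 7), `empirical_delta`, the `decision`, per-replicate failure and
#'   incomplete-run counts, and metadata.
#' @export
bootstrap_lrt <- function(ds, fit_cs, fit_iw, n_reps = 100L, seed = NULL,
                          n_starts = 1L, eval_budget = 2500L, reltol = 1e-8,
                          models = NULL, opts = loglik_opts(),
                          progress = FALSE) {
  stopifnot(inherits(fit_cs, "island_fit"), inherits(fit_iw, "island_fit"))
  if (!fit_cs$converged || !fit_iw$converged) {
    warning("bootstrap_lrt: one of the fits did not converge")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(models)) models <- c(fit_cs$model, fit_iw$model)

  one_side <- function(gen_fit) {
    sims <- simulate(gen_fit, nsim = n_reps)
    deltas <- rep(NA_real_, n_reps)
    incomplete <- 0L
    for (i in seq_len(n_reps)) {
      sim <- dedup_mainland_ids(sims[[i]])
      if (length(sim$clades) == 0L) next # empty island: nothing to fit
      d <- tryCatch({
        f1 <- refit_boot(sim, models[1L], fit_cs, n_starts, eval_budget,
                         reltol, opts)
        f2 <- refit_boot(sim, models[2L], fit_iw, n_starts, eval_budget,
                         reltol, opts)
        if (!f1$converged || !f2$converged) incomplete <- incomplete + 1L
        f1$loglik - f2$loglik
      }, error = function(e) NA_real_)
      deltas[i] <- d
      if (progress && i %% 10L == 0L) cat(".")
    }
    list(deltas = deltas, incomplete = incomplete)
  }

  under_cs <- one_side(fit_cs)
  under_iw <- one_side(fit_iw)
  d_cs <- under_cs$deltas[is.finite(under_cs$deltas)]
  d_iw <- under_iw$deltas[is.finite(under_iw$deltas)]
  fail <- 2L * n_reps - length(d_cs) - length(d_iw)
  if (fail > 0.05 * 2 * n_reps) {
    warning(sprintf("bootstrap_lrt: %d of %d replicates failed or were empty",
                    fail, 2L * n_reps))
  }
  empirical_delta <- fit_cs$loglik - fit_iw$loglik
  out <- list(
    deltas_under_cs = d_cs, deltas_under_iw = d_iw,
    pct5_cs = unname(stats::quantile(d_cs, 0.05, type = 7)),
    pct95_iw = unname(stats::quantile(d_iw, 0.95, type = 7)),
    empirical_delta = empirical_delta,
    decision = decide_model(empirical_delta, d_cs, d_iw),
    n_reps = n_reps, n_failed = fail,
    n_incomplete = under_cs$incomplete + under_iw$incomplete,
    quantile_convention = "inclusive linear interpolation (R type 7)",
    models = models)
  class(out) <- "island_boot"
  out
}

refit_boot <- function(sim, model, emp_fit, n_starts, eval_budget, reltol,
                       opts) {
  start <- emp_fit$params
  scope_max <- if (model %in% c("CS", "CS_noA")) {
    max(vapply(sim$clades, clade_size, integer(1)))
  } else {
    total_species(sim)
  }
  if (is.finite(start$K)) start$K <- max(start$K, scope_max + 1)
  fit_island_model(sim, model, n_starts = n_starts, start = start,
                   eval_budget = eval_budget, reltol = reltol, opts = opts)
}

# The simulators can produce recolonization doublets (a mainland species
# founding two surviving clades); the likelihood treats clades as descending
# from distinct mainland ancestors, so bootstrap replicates relabel the
# duplicates with unused identifiers.
dedup_mainland_ids <- function(ds) {
  ids <- vapply(ds$clades, `[[`, integer(1), "mainland_species_id")
  dup <- duplicated(ids)
  if (!any(dup)) return(ds)
  free <- setdiff(seq_len(ds$M), ids)
  for (i in which(dup)) {
    ds$clades[[i]]$mainland_species_id <- free[1L]
    free <- free[-1L]
  }
  ds
}

#' @export
print.island_boot <- function(x, ...) {
  cat("Parametric-bootstrap likelihood-ratio test (LL_CS - LL_IW)\n")
  cat(sprintf("  replicates: %d per model (%d failed, %d incomplete)\n",
              x$n_reps, x$n_failed, x$n_incomplete))
  cat(sprintf("  5th percentile under CS:  %8.4f\n", x$pct5_cs))
  cat(sprintf("  95th percentile under IW: %8.4f\n", x$pct95_iw))
  cat(sprintf("  empirical delta: %.4f  ->  decision: %s\n",
              x$empirical_delta, x$decision))
  invisible(x)
}

#' @export
plot.island_boot <- function(x, ...) {
  rng <- range(c(x$deltas_under_cs, x$deltas_under_iw, x$empirical_delta))
  br <- pretty(rng, 30)
  h1 <- graphics::hist(x$deltas_under_cs, breaks = br, plot = FALSE)
  h2 <- graphics::hist(x$deltas_under_iw, breaks = br, plot = FALSE)
  ylim <- c(0, max(h1$counts, h2$counts))
  graphics::plot(h1, col = grDevices::adjustcolor("steelblue", 0.5),
                 ylim = ylim, main = "Bootstrap loglikelihood differences",
                 xlab = "LL(CS) - LL(IW)", ...)
  graphics::plot(h2, col = grDevices::adjustcolor("tomato", 0.5), add = TRUE)
  graphics::abline(v = x$empirical_delta, lwd = 2)
  graphics::abline(v = c(x$pct5_cs, x$pct95_iw), lty = 2)
  graphics::legend("topright", fill = c("steelblue", "tomato"),
                   legend = c("simulated under CS", "simulated under IW"),
                   bty = "n")
  invisible(x)
}

#' Percentile decision rule for the bootstrap likelihood-ratio test
#'
#' CS is selected when the empirical loglikelihood difference lies to the
#' right of the 95th percentile of the differences simulated under IW while
#' remaining inside the CS distribution (at or above its 5th percentile); IW
#' is selected symmetrically; anything else is indecisive. The rule is
#' monotone in the empirical difference.
#'
#' @param empirical_delta Observed `LL_CS - LL_IW`.
#' @param deltas_under_cs,deltas_under_iw Simulated difference distributions.
#' @return `"CS"`, `"IW"` or `"indecisive"`.
#' @export
decide_model <- function(empirical_delta, deltas_under_cs, deltas_under_iw) {
  stopifnot(length(deltas_under_cs) > 0, length(deltas_under_iw) > 0)
  p5 <- stats::quantile(deltas_under_cs, 0.05, type = 7, names = FALSE)
  p95 <- stats::quantile(deltas_under_iw, 0.95, type = 7, names = FALSE)
  if (empirical_delta > p95 && empirical_delta >= p5) return("CS")
  if (empirical_delta < p5 && empirical_delta <= p95) return("IW")
  "indecisive"
}

#' Goodness-of-fit summary statistics of an island dataset
#'
#' The four statistics used to compare simulated and empirical island
#' communities: total species count, number of colonizations leading to
#' extant clades, size of the largest clade, and the colonization-order rank
#' of the largest clade (rank 1 = oldest colonization; ties in size go to
#' the earlier colonization). An empty island reports zeros.
#'
#' @param ds An [island_dataset()].
#' @return A named numeric vector with elements `total_species`,
#'   `n_colonizations`, `largest_clade_size`, `largest_clade_rank`.
#' @export
gof_statistics <- function(ds) {
  if (!length(ds$clades)) {
    return(c(total_species = 0, n_colonizations = 0, largest_clade_size = 0,
             largest_clade_rank = 0))
  }
  ages <- vapply(ds$clades, `[[`, numeric(1), "colonization_age")
  sizes <- vapply(ds$clades, clade_size, integer(1))
  ord <- order(-ages)
  sizes <- sizes[ord]
  rank_largest <- which.max(sizes) # first maximum = earliest colonization
  c(total_species = sum(sizes), n_colonizations = length(sizes),
    largest_clade_size = max(sizes), largest_clade_rank = rank_largest)
}

#' Goodness-of-fit comparison of a fitted model against the data
#'
#' Simulates `n_sims` datasets from the fitted model, computes
#' [gof_statistics()] for each, and reports the simulated distributions
#' alongside the empirical values, their medians, and the empirical
#' percentile `P(simulated <= empirical)`.
#'
#' @param ds The empirical [island_dataset()].
#' @param fit An `island_fit`.
#' @param n_sims Number of simulated datasets.
#' @param seed Optional seed.
#' @return An object of class `island_gof`: list with `sims` (an
#'   `n_sims x 4` matrix), `empirical`, `median` and `percentile`.
#' @export
gof_compare <- function(ds, fit, n_sims = 1000L, seed = NULL) {
  stopifnot(inherits(fit, "island_fit"))
  if (!is.null(seed)) set.seed(seed)
  sims <- simulate(fit, nsim = n_sims)
  mat <- t(vapply(sims, gof_statistics, numeric(4)))
  emp <- gof_statistics(ds)
  out <- list(sims = mat, empirical = emp,
              median = apply(mat, 2, stats::median),
              percentile = colMeans(mat <= rep(emp, each = nrow(mat))),
              model = fit$model, n_sims = n_sims)
  class(out) <- "island_gof"
  out
}

#' @export
print.island_gof <- function(x, ...) {
  cat(sprintf("Goodness of fit, %d simulations from model %s\n",
              x$n_sims, x$model))
  tab <- rbind(empirical = x$empirical, simulated_median = x$median,
               empirical_percentile = x$percentile)
  print(round(tab, 3))
  invisible(x)
}

#' @export
plot.island_gof <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(op))
  for (j in seq_len(4L)) {
    nm <- colnames(x$sims)[j]
    graphics::hist(x$sims[, j], breaks = 30, main = nm, xlab = nm,
                   col = "grey80", border = "white")
    graphics::abline(v = x$empirical[j], lwd = 2, col = "firebrick")
    graphics::abline(v = x$median[j], lwd = 2, lty = 2)
  }
  invisible(x)
}
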