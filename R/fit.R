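#' Maximum-likelihood fitting of island diversification models
#'
#' Fits one of five model variants to an island dataset by maximizing the
#' corresponding loglikelihood over the rate parameters, with rates on the
#' log scale and the carrying capacity on a shifted log scale bounded below
#' by the largest observed diversity in its scope:
#'
#' * `"DI"`: diversity-independent (`K = Inf`); free parameters
#'   `lambda_c0`, `mu`, `gamma0`, `lambda_a`.
#' * `"CS"` / `"CS_noA"`: clade-specific diversity-dependence, with
#'   `lambda_a` free or fixed at zero.
#' * `"IW"` / `"IW_noA"`: island-wide diversity-dependence, likewise.
#'
#' Optimization is a derivative-free Nelder-Mead search repeated from
#' `n_starts` random starting points (log-uniform multiplicative
#' perturbations in `[0.1, 10]` of moment-matched defaults) to avoid local
#' optima; the best start is returned.
#'
#' @param ds A valid [island_dataset()] with at least one colonization.
#' @param model Model variant, see above.
#' @param n_starts Number of random starts (the first uses the unperturbed
#'   defaults).
#' @param seed Optional seed for the start perturbations.
#' @param start Optional [island_params()] (or named list) overriding the
#'   default starting values.
#' @param eval_budget Likelihood-evaluation cap per start; starts that
#'   exhaust it are flagged incomplete and their best value so far is kept.
#' @param reltol Relative convergence tolerance of the Nelder-Mead search.
#' @param opts Numerical options for the likelihood, see [loglik_opts()].
#' @return An object of class `island_fit` with components `model`, `params`
#'   (the MLEs as [island_params()]), `loglik`, `df`, `converged`, `starts`
#'   (per-start diagnostics), `data`, and supporting metadata. Methods:
#'   [print()], [summary()], [coef()], [logLik()] (so [AIC()] and [BIC()]
#'   work), [simulate()] and [plot()].
#' @examples
#' \donttest{
#' ds <- make_table1_fixture(seed = 1)
#' fit <- fit_island_model(ds, "CS_noA", n_starts = 1, seed = 1)
#' coef(fit)
#' }
#' @export
fit_island_model <- function(ds, model = c("DI", "CS", "CS_noA", "IW", "IW_noA"),
                             n_starts = 5L, seed = NULL, start = NULL,
                             eval_budget = 5000L, reltol = 1e-10,
                             opts = loglik_opts()) {
  model <- match.arg(model)
  stop_if_invalid(ds)
  if (length(ds$clades) == 0L) {
    stop("fit_island_model: dataset contains no colonizations; ",
         "there are no events to fit a model to")
  }
  if (!is.null(seed)) set.seed(seed)

  sizes <- vapply(ds$clades, clade_size, integer(1))
  has_K <- model != "DI"
  has_ana <- model %in% c("DI", "CS", "IW")
  K_low <- if (model %in% c("CS", "CS_noA")) max(sizes) else total_species(ds)
  llfun_ds <- make_loglik_closure(ds, model, opts)
  llfun <- function(ds_ignored, p, opts_ignored) llfun_ds(p)

  defaults <- default_start(ds, K_low)
  if (!is.null(start)) {
    start <- as_island_params(start)
    defaults$lambda_c0 <- start$lambda_c0
    defaults$mu <- max(start$mu, 1e-6)
    defaults$gamma0 <- start$gamma0
    defaults$lambda_a <- max(start$lambda_a, 1e-4)
    if (has_K && is.finite(start$K)) defaults$K <- max(start$K, K_low + 1e-3)
  }

  pack <- function(par) {
    th <- c(log(par$lambda_c0), log(par$mu))
    if (has_K) th <- c(th, log(par$K - K_low))
    th <- c(th, log(par$gamma0))
    if (has_ana) th <- c(th, log(par$lambda_a))
    th
  }
  unpack <- function(th) {
    i <- 2L
    lc <- exp(th[1L]); mu <- exp(th[2L])
    K <- if (has_K) { i <- i + 1L; K_low + exp(th[i]) } else Inf
    g0 <- exp(th[i + 1L]); i <- i + 1L
    la <- if (has_ana) exp(th[i + 1L]) else 0
    island_params(lambda_c0 = lc, mu = mu, K = K, gamma0 = g0, lambda_a = la)
  }

  evals <- 0L
  objective <- function(th) {
    evals <<- evals + 1L
    if (any(!is.finite(th)) || any(th[1:2] > log(50)) ||
        th[length(th) - has_ana] > log(20)) {
      return(1e10)
    }
    p <- tryCatch(unpack(th), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ll <- tryCatch(llfun(ds, p, opts), error = function(e) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- vector("list", n_starts)
  best <- NULL
  for (s in seq_len(n_starts)) {
    par_s <- defaults
    if (s > 1L) par_s <- perturb_start(defaults, K_low, has_K)
    th0 <- pack(par_s)
    tries <- 0L
    while (objective(th0) >= 1e10 && tries < 20L) {
      par_s <- perturb_start(defaults, K_low, has_K)
      th0 <- pack(par_s)
      tries <- tries + 1L
    }
    evals <- 0L
    res <- stats::optim(th0, objective, method = "Nelder-Mead",
                        control = list(maxit = eval_budget,
                                       reltol = reltol))
    starts[[s]] <- list(start = par_s, end = unpack(res$par),
                        loglik = -res$value, converged = res$convergence == 0L,
                        evaluations = evals, resampled = tries)
    if (is.null(best) || res$value < best$value) best <- res
  }

  mle <- unpack(best$par)
  ll <- llfun(ds, mle, opts)
  df <- 2L + has_K + has_ana + 1L # lambda_c0, mu, [K], gamma0, [lambda_a]
  out <- list(model = model, params = mle, loglik = ll, df = as.integer(df),
              converged = best$convergence == 0L,
              starts = starts, data = ds, K_low = K_low,
              n_events = total_species(ds), opts = opts)
  class(out) <- "island_fit"
  out
}

#' Evaluate a model variant at fixed parameters
#'
#' Builds an `island_fit` object at given parameter values without
#' optimizing: the loglikelihood is computed once. Useful as a simulation
#' template ([simulate()] works on the result), for bootstrapping at
#' externally estimated parameters, and for comparing fixed parameter sets
#' by [information_criteria()].
#'
#' @param ds A valid [island_dataset()].
#' @param model Model variant, as in [fit_island_model()].
#' @param params An [island_params()] object (or named list).
#' @param opts See [loglik_opts()].
#' @return An `island_fit` with `converged = TRUE` and no start history.
#' @export
island_fit_from_params <- function(ds, model = c("DI", "CS", "CS_noA", "IW",
                                                 "IW_noA"),
                                   params, opts = loglik_opts()) {
  model <- match.arg(model)
  stop_if_invalid(ds)
  params <- as_island_params(params)
  if (model == "DI") params$K <- Inf
  if (model %in% c("CS_noA", "IW_noA")) params$lambda_a <- 0
  llfun <- make_loglik_closure(ds, model, opts)
  df <- 2L + (model != "DI") + (model %in% c("DI", "CS", "IW")) + 1L
  out <- list(model = model, params = params, loglik = llfun(params),
              df = as.integer(df), converged = TRUE, starts = list(),
              data = ds, K_low = NA_real_, n_events = total_species(ds),
              opts = opts)
  class(out) <- "island_fit"
  out
}

default_start <- function(ds, K_low) {
  sizes <- vapply(ds$clades, clade_size, integer(1))
  ages <- vapply(ds$clades, `[[`, numeric(1), "colonization_age")
  # Yule-style moment match: clade of size m after time a grows at ~ log(m)/a
  lc <- mean(pmax(log(pmax(sizes, 2)) / ages, 1e-3))
  list(lambda_c0 = max(lc, 0.01), mu = max(lc / 2, 0.005),
       K = max(2 * K_low, K_low + 1),
       gamma0 = max(length(sizes) / (ds$M * ds$island_age), 1e-8),
       lambda_a = 0.05)
}

perturb_start <- function(defaults, K_low, has_K) {
  f <- function(x) x * 10^stats::runif(1L, -1, 1)
  out <- defaults
  out$lambda_c0 <- f(defaults$lambda_c0)
  out$mu <- f(defaults$mu)
  out$gamma0 <- f(defaults$gamma0)
  out$lambda_a <- f(defaults$lambda_a)
  if (has_K) out$K <- K_low + f(defaults$K - K_low)
  out
}

#' @export
print.island_fit <- function(x, ...) {
  cat(sprintf("Island diversification model fit: %s\n", x$model))
  cat(sprintf("  loglik %.4f  df %d  converged %s\n", x$loglik, x$df,
              x$converged))
  co <- coef(x)
  cat("  ", paste(sprintf("%s=%.4g", names(co), co), collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.island_fit <- function(object, ...) {
  print(object)
  lls <- vapply(object$starts, `[[`, numeric(1), "loglik")
  cat(sprintf("  %d start(s); loglik range across starts: %.6f .. %.6f\n",
              length(lls), min(lls), max(lls)))
  cat(sprintf("  AIC %.2f  BIC %.2f (n_eff = %d observed events)\n",
              stats::AIC(object), stats::BIC(object), object$n_events))
  invisible(object)
}

#' @export
coef.island_fit <- function(object, ...) {
  p <- object$params
  c(lambda_c0 = p$lambda_c0, mu = p$mu, K = p$K, gamma0 = p$gamma0,
    lambda_a = p$lambda_a)
}

#' @export
logLik.island_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n_events,
            class = "logLik")
}

#' @export
nobs.island_fit <- function(object, ...) object$n_events

#' Simulate datasets from a fitted model
#'
#' Parametric simulation at the fitted parameters: the CS-type models (and
#' DI, whose clades are independent) use [simulate_cs()], the IW-type models
#' [simulate_iw()].
#'
#' @param object An `island_fit`.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` [island_dataset()] objects.
#' @export
simulate.island_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fun <- if (object$model %in% c("IW", "IW_noA")) simulate_iw else simulate_cs
  replicate(nsim,
            fun(object$params, object$data$island_age, object$data$M),
            simplify = FALSE)
}

#' Compare fitted models by information criteria
#'
#' @param fits A list of `island_fit` objects (typically the five variants
#'   fitted to one dataset).
#' @param n_eff Effective sample size for the BIC; defaults to the number of
#'   observed events (colonizations plus branchings) of the first fit.
#' @return A data frame with one row per model: loglikelihood, df, AIC, AIC
#'   weight, BIC and BIC weight.
#' @details AIC = 2 df - 2 LL; weights are
#'   `exp(-dAIC/2) / sum(exp(-dAIC/2))`; BIC = df log(n_eff) - 2 LL. The
#'   choice of `n_eff` for island data is a convention; it is exposed rather
#'   than hard-wired.
#' @export
information_criteria <- function(fits, n_eff = NULL) {
  if (inherits(fits, "island_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L)
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  df <- vapply(fits, `[[`, integer(1), "df")
  if (is.null(n_eff)) n_eff <- fits[[1L]]$n_events
  aic <- 2 * df - 2 * ll
  bic <- df * log(n_eff) - 2 * ll
  wt <- function(x) { d <- x - min(x); w <- exp(-d / 2); w / sum(w) }
  data.frame(model = vapply(fits, `[[`, character(1), "model"),
             loglik = ll, df = df,
             AIC = aic, AIC_weight = wt(aic),
             BIC = bic, BIC_weight = wt(bic),
             stringsAsFactors = FALSE)
}
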