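# Q-approach likelihood for the island-wide (IW) model. The consistency
# probability Q[n, e] is indexed by the hidden-species count n (island
# species alive at time t that leave no sampled extant descendant) and by the
# number e of observed endemic-singleton lineages that have not yet acquired
# the event (anagenesis or cladogenesis) that makes them endemic. Between
# observed events Q obeys a linear master equation; at each observed
# colonization or branching it is multiplied by the event rate. Under
# complete sampling the likelihood is Q[0, 0] at the present.

#' Numerical options for the likelihood functions
#'
#' @param tol Relative truncation tolerance of the uniformization series used
#'   to propagate Q between events (`engine = "cpp"`).
#' @param rtol,atol Solver tolerances for the `deSolve`-based reference
#'   engine (`engine = "r"`); `atol` applies to the internally rescaled
#'   vector.
#' @param tail_tol Adaptive-truncation tolerance: the hidden-state dimension
#'   grows until the top entry's (weighted) relative mass drops below this.
#' @param weighted_tail If `TRUE` (default), the truncation criterion weights
#'   the entry at hidden count `n` by `p_ext^n`, the probability that a
#'   hidden lineage leaves no extant descendant in the remaining time; this
#'   keeps the state space small when `K` is infinite. `FALSE` uses raw mass.
#' @param nmax0 Initial hidden-state truncation; defaults to a size based on
#'   the dataset.
#' @param nmax_limit Hard ceiling on the truncation (an error-guard for
#'   pathological parameter values during optimization).
#' @param colonization_multiplicity `"pool"` (default): unobserved
#'   colonizations founding hidden clades carry the full mainland
#'   multiplicity `M`. `"pool_minus_active"`: multiplicity `M - r`, where `r`
#'   counts observed lineages still exposed to the colonization-time reset
#'   rule, with the reset risk `r * gamma_N` kept as a pure loss term.
#' @param engine `"cpp"` (uniformization, fast) or `"r"` (`deSolve::lsoda`
#'   on the same generator; independent numerics used for cross-checks).
#' @return A list of class `loglik_opts`.
#' @export
loglik_opts <- function(tol = 1e-14, rtol = 1e-8, atol = 1e-60,
                        tail_tol = 1e-12, weighted_tail = TRUE, nmax0 = NULL,
                        nmax_limit = 2000L,
                        colonization_multiplicity = c("pool", "pool_minus_active"),
                        engine = c("cpp", "r")) {
  out <- list(tol = tol, rtol = rtol, atol = atol, tail_tol = tail_tol,
              weighted_tail = isTRUE(weighted_tail), nmax0 = nmax0,
              nmax_limit = as.integer(nmax_limit),
              colonization_multiplicity = match.arg(colonization_multiplicity),
              engine = match.arg(engine))
  class(out) <- "loglik_opts"
  out
}

status_code <- function(status) {
  unname(c(endemic_clade = 0L, non_endemic_singleton = 1L,
           endemic_singleton = 2L)[status])
}

# Flatten a dataset into the event schedule the C++ core consumes.
build_event_schedule <- function(ds, opts) {
  tl <- event_timeline(ds)
  ev <- tl[tl$event %in% c("colonization", "branching"), , drop = FALSE]
  nev <- nrow(ev)
  status_by_clade <- stats::setNames(
    vapply(ds$clades, `[[`, character(1), "status"),
    vapply(ds$clades, `[[`, character(1), "name"))
  ev_type <- ifelse(ev$event == "branching", 1L, 0L)
  ev_status <- integer(nev)
  ev_mult <- numeric(nev)
  branch_count <- stats::setNames(integer(length(ds$clades)), names(status_by_clade))
  reset_prone <- stats::setNames(logical(length(ds$clades)), names(status_by_clade))
  reset_r <- numeric(nev + 1L) # per interval, intervals follow events 0..nev
  for (i in seq_len(nev)) {
    cl <- ev$clade[i]
    if (ev_type[i] == 0L) {
      ev_status[i] <- status_code(status_by_clade[[cl]])
      ev_mult[i] <- 1
      reset_prone[cl] <- TRUE
    } else {
      ev_mult[i] <- branch_count[cl] + 1L
      branch_count[cl] <- branch_count[cl] + 1L
      reset_prone[cl] <- FALSE # crowned: recolonization no longer resets
    }
    reset_r[i + 1L] <- sum(reset_prone)
  }
  if (opts$colonization_multiplicity == "pool") reset_r[] <- 0
  list(age = ev$age, type = ev_type, status = ev_status, mult = ev_mult,
       reset_r = reset_r)
}

default_nmax0 <- function(ds, p) {
  cap <- diversity_cap(p)
  n0 <- max(20L, 2L * total_species(ds) + 10L)
  as.integer(min(cap, n0))
}

#' Loglikelihood of an island dataset under island-wide diversity-dependence
#'
#' Computes the exact model loglikelihood of the colonization and branching
#' data by integrating the consistency-probability vector `Q_n(t)` over the
#' event timeline, from the island's emergence to the present, assuming
#' complete sampling of the extant island species. `n` indexes the hidden
#' species count; diversity-dependent rates are evaluated at `n + k`, with
#' `k` the number of reconstructed lineages present at time `t`.
#'
#' @param ds A valid [island_dataset()].
#' @param p An [island_params()] object.
#' @param opts Numerical options, see [loglik_opts()].
#' @return The loglikelihood (natural log). `-Inf` when the data are
#'   impossible under `p` (e.g. more species than the diversity cap, or a
#'   branching with a zero cladogenesis rate).
#' @seealso [loglik_cs()], [loglik_di()], [loglik_oracle_mc()]
#' @export
loglik_iw <- function(ds, p, opts = loglik_opts()) {
  p <- as_island_params(p)
  stop_if_invalid(ds)
  cap <- diversity_cap(p)
  if (total_species(ds) > cap) return(-Inf)
  sched <- build_event_schedule(ds, opts)
  loglik_iw_prepped(ds, sched, p, opts)
}

loglik_iw_prepped <- function(ds, sched, p, opts) {
  if (total_species(ds) > diversity_cap(p)) return(-Inf)
  nmax0 <- if (is.null(opts$nmax0)) default_nmax0(ds, p) else as.integer(opts$nmax0)
  if (opts$engine == "cpp") {
    res <- loglik_core_cpp(ds$island_age, ds$M, p$lambda_c0, p$mu, p$K,
                           p$gamma0, p$lambda_a, sched$age, sched$type,
                           sched$status, sched$mult, sched$reset_r, opts$tol,
                           opts$tail_tol, opts$weighted_tail, nmax0,
                           opts$nmax_limit)
    res$loglik
  } else {
    loglik_iw_r(ds, p, sched, nmax0, opts)
  }
}

# Precompiled likelihood closure: validates and builds event schedules once,
# so that repeated evaluations during optimization pay only the ODE cost.
make_loglik_closure <- function(ds, model, opts) {
  stop_if_invalid(ds)
  if (model %in% c("IW", "IW_noA")) {
    sched <- build_event_schedule(ds, opts)
    function(p) loglik_iw_prepped(ds, sched, p, opts)
  } else {
    empty <- island_dataset(ds$island_age, 1L, list(), validate = FALSE)
    sched_empty <- build_event_schedule(empty, opts)
    subs <- lapply(canonical_clade_order(ds$clades), function(cl) {
      cl$mainland_species_id <- 1L
      sub <- island_dataset(ds$island_age, 1L, list(cl), validate = FALSE)
      list(ds = sub, sched = build_event_schedule(sub, opts))
    })
    n_empty <- ds$M - length(ds$clades)
    force_di <- model == "DI"
    function(p) {
      if (force_di) p$K <- Inf
      ll <- n_empty * loglik_iw_prepped(empty, sched_empty, p, opts)
      for (s in subs) {
        ll <- ll + loglik_iw_prepped(s$ds, s$sched, p, opts)
        if (!is.finite(ll)) return(-Inf)
      }
      ll
    }
  }
}

# ---- modular Q-state surface -------------------------------------------------

#' Q-state of the island-wide likelihood computation
#'
#' A lightweight container holding the consistency-probability vector between
#' events: `q` is a matrix over hidden-species count `n` (rows, `0..n_max`)
#' and pending-endemization count `e` (columns), `log_scale` the accumulated
#' log normalizer, `k` the current observed-lineage count, `k_ne` how many of
#' those are non-endemic singletons, and `age` the current time.
#'
#' @param n_max Hidden-state truncation.
#' @param age Starting age (usually the island age).
#' @param e_max Number of pending-endemization columns to allocate.
#' @return An object of class `qstate`; the initial state has all mass at
#'   `n = 0, e = 0`.
#' @export
qstate <- function(n_max, age, e_max = 0L) {
  q <- matrix(0, nrow = n_max + 1L, ncol = e_max + 1L)
  q[1L, 1L] <- 1
  structure(list(q = q, log_scale = 0, k = 0L, k_ne = 0L, e = 0L, age = age),
            class = "qstate")
}

#' @export
print.qstate <- function(x, ...) {
  cat(sprintf("Q-state at age %g: k = %d (%d non-endemic), n_max = %d, log_scale = %g\n",
              x$age, x$k, x$k_ne, nrow(x$q) - 1L, x$log_scale))
  invisible(x)
}

#' Propagate the Q-state between observed events
#'
#' Solves the linear master equation for the consistency probabilities over
#' `[to_age, state$age]` with the observed-lineage count held fixed: hidden
#' species are born by cladogenesis of any of the `n + k` species or by
#' unobserved colonizations (mainland multiplicity `M`), and die at rate
#' `mu` each; observed lineages cannot die. Diversity-dependent rates are
#' evaluated at `N = n + k`. The vector is renormalized and the log scale
#' accumulated.
#'
#' @param state A [qstate()].
#' @param to_age Target age (`<= state$age`).
#' @param p An [island_params()] object.
#' @param M Mainland pool size.
#' @param opts See [loglik_opts()].
#' @param reset_r Reset-loss colonization multiplicity (0 under the default
#'   pooled convention).
#' @return The propagated `qstate` at `to_age`.
#' @export
propagate_Q <- function(state, to_age, p, M, opts = loglik_opts(), reset_r = 0) {
  stopifnot(inherits(state, "qstate"), to_age <= state$age)
  p <- as_island_params(p)
  nmax <- nrow(state$q) - 1L
  eact <- state$e
  dt <- state$age - to_age
  if (dt == 0) return(state)
  if (opts$engine == "cpp") {
    res <- propagate_interval_cpp(as.numeric(state$q), state$log_scale, nmax,
                                  eact, state$k, state$k_ne, dt, p$lambda_c0,
                                  p$mu, p$K, p$gamma0, p$lambda_a, M - reset_r,
                                  reset_r, opts$tol)
    if (!res$ok) stop("propagate_Q: probability vector vanished (data impossible?)")
    state$q <- matrix(res$q, nrow = nmax + 1L)
    state$log_scale <- res$log_scale
  } else {
    out <- propagate_desolve(state$q, state$k, state$k_ne, eact, dt, p, M,
                             reset_r, opts)
    state$q <- out$q
    state$log_scale <- state$log_scale + out$log_inc
  }
  state$age <- to_age
  state
}

# deSolve-based propagation over one interval: an independent numerical route
# through the same generator, used to cross-validate the uniformization core.
propagate_desolve <- function(qmat, k, kne, eact, dt, p, M, reset_r, opts) {
  nmax <- nrow(qmat) - 1L
  ncol_q <- ncol(qmat)
  n <- 0:nmax
  N <- n + k
  lam <- clado_rate(N, p)
  gam <- colonization_rate(N, p)
  lam_m1 <- c(0, lam[-length(lam)]) # rates at N - 1, aligned with n
  gam_m1 <- c(0, gam[-length(gam)])
  mu <- p$mu; la <- p$lambda_a
  Mfound <- M - reset_r
  deriv <- function(t, y, parms) {
    q <- matrix(y, nrow = nmax + 1L)
    dq <- matrix(0, nrow = nmax + 1L, ncol = ncol_q)
    for (e in 0:(ncol_q - 1L)) {
      g <- max(0L, k - kne - e)
      col <- q[, e + 1L]
      diag <- (Mfound + reset_r) * gam + lam * N + mu * N + la * (e + kne)
      d <- -diag * col
      # observed-lineage splits count twice: either daughter may continue
      # the observed line, and the two designations are disjoint futures
      d[-1L] <- d[-1L] + (Mfound * gam_m1[-1L] + lam_m1[-1L] * (n[-1L] - 1L + 2L * g)) *
        col[-length(col)]
      if (e + 1L < ncol_q) {
        nxt <- q[, e + 2L]
        d[-1L] <- d[-1L] + lam_m1[-1L] * 2L * (e + 1L) * nxt[-length(nxt)]
        d <- d + la * (e + 1L) * nxt
      }
      d[-length(d)] <- d[-length(d)] + mu * (n[-1L]) * col[-1L]
      dq[, e + 1L] <- d
    }
    list(as.numeric(dq))
  }
  sol <- deSolve::ode(y = as.numeric(qmat), times = c(0, dt), func = deriv,
                      parms = NULL, method = "lsoda", rtol = opts$rtol,
                      atol = opts$atol)
  qv <- pmax(0, sol[2L, -1L])
  m <- max(qv)
  if (!is.finite(m) || m <= 0) stop("deSolve propagation produced a vanished vector")
  list(q = matrix(qv / m, nrow = nmax + 1L), log_inc = log(m))
}

#' Apply an observed colonization or branching to the Q-state
#'
#' `apply_colonization()` multiplies every entry by the per-mainland-species
#' colonization rate at `N = n + k` (the colonist's identity is part of the
#' data) and increments `k`; `apply_branching()` multiplies by the
#' cladogenesis rate at `N = n + k` times `lineage_count`, the number of
#' observed lineages of the branching clade just before the event (the data
#' record which clade branched, not which of its lineages), and increments
#' `k`. Entries at diversities where the clamped rate is zero vanish; if the
#' whole vector vanishes the data are impossible and the likelihood is
#' `-Inf`.
#'
#' @param state A [qstate()].
#' @param p An [island_params()] object.
#' @param M Mainland pool size (kept for interface symmetry; the per-species
#'   rate applies).
#' @param status Status of the colonizing clade: `"endemic_clade"`,
#'   `"non_endemic_singleton"` or `"endemic_singleton"`.
#' @return The updated `qstate`; attribute `"vanished"` is `TRUE` when all
#'   mass was lost.
#' @export
apply_colonization <- function(state, p, M, status = "endemic_clade") {
  stopifnot(inherits(state, "qstate"))
  p <- as_island_params(p)
  nmax <- nrow(state$q) - 1L
  gam <- colonization_rate(0:nmax + state$k, p)
  state$q <- state$q * gam
  code <- status_code(match.arg(status, c("endemic_clade",
                                          "non_endemic_singleton",
                                          "endemic_singleton")))
  if (code == 2L) {
    if (state$e + 2L > ncol(state$q)) {
      state$q <- cbind(state$q, 0)
    }
    for (e in rev(seq_len(state$e + 1L))) state$q[, e + 1L] <- state$q[, e]
    state$q[, 1L] <- 0
    state$e <- state$e + 1L
  } else if (code == 1L) {
    state$k_ne <- state$k_ne + 1L
  }
  state$k <- state$k + 1L
  renorm_qstate(state)
}

#' @rdname apply_colonization
#' @param lineage_count Number of observed lineages of the branching clade
#'   before the event.
#' @export
apply_branching <- function(state, p, lineage_count = 1) {
  stopifnot(inherits(state, "qstate"))
  p <- as_island_params(p)
  nmax <- nrow(state$q) - 1L
  lam <- clado_rate(0:nmax + state$k, p)
  state$q <- state$q * lam * lineage_count
  state$k <- state$k + 1L
  renorm_qstate(state)
}

renorm_qstate <- function(state) {
  m <- max(state$q)
  if (!is.finite(m) || m <= 0) {
    state$q[] <- 0
    attr(state, "vanished") <- TRUE
    return(state)
  }
  state$q <- state$q / m
  state$log_scale <- state$log_scale + log(m)
  state
}

# Reference R driver: steps a qstate through the schedule with the deSolve
# engine and the same adaptive truncation rule as the C++ core.
loglik_iw_r <- function(ds, p, sched, nmax0, opts) {
  cap <- diversity_cap(p)
  hard_max <- as.integer(min(cap, opts$nmax_limit))
  nmax <- min(nmax0, hard_max)
  ecap <- sum(sched$type == 0L & sched$status == 2L)
  repeat {
    st <- qstate(nmax, ds$island_age, e_max = ecap)
    grown <- FALSE
    ages <- c(sched$age, 0)
    for (i in seq_along(ages)) {
      rr <- sched$reset_r[i]
      st <- propagate_Q(st, ages[i], p, ds$M, opts, reset_r = rr)
      w <- if (opts$weighted_tail) p_ext_r(p$lambda_c0, p$mu, ages[i]) else 1
      wn <- w^(0:nmax)
      tot <- sum(st$q * wn)
      top <- sum(st$q[nmax + 1L, ] * wn[nmax + 1L])
      if (tot > 0 && top > opts$tail_tol * tot && nmax < hard_max) {
        nmax <- min(hard_max, nmax + nmax %/% 2L + 10L)
        grown <- TRUE
        break
      }
      if (i > length(sched$age)) break
      if (sched$type[i] == 0L) {
        status <- c("endemic_clade", "non_endemic_singleton",
                    "endemic_singleton")[sched$status[i] + 1L]
        st <- apply_colonization(st, p, ds$M, status = status)
      } else {
        st <- apply_branching(st, p, lineage_count = sched$mult[i])
      }
      if (isTRUE(attr(st, "vanished"))) return(-Inf)
    }
    if (!grown) break
  }
  q00 <- st$q[1L, 1L]
  if (q00 <= 0) -Inf else log(q00) + st$log_scale
}

p_ext_r <- function(lambda, mu, t) {
  if (mu <= 0 || t <= 0) return(0)
  r <- lambda - mu
  if (abs(r) * t < 1e-8) return(mu * t / (1 + mu * t))
  if (r * t > 700) return(mu / lambda)
  e <- exp(r * t)
  min(1 - 1e-12, max(0, mu * (e - 1) / (lambda * e - mu)))
}

# ---- CS and DI likelihoods ---------------------------------------------------

#' Loglikelihood under clade-specific diversity-dependence
#'
#' The clade-specific (CS) model treats each mainland species' island
#' descendants as an independent island-wide process with a mainland pool of
#' one and its own copy of `K`. Its loglikelihood is therefore the sum of
#' single-clade IW loglikelihoods (at `M = 1`) over the observed clades, plus
#' `M - C` times the empty-island loglikelihood (at `M = 1`) for the mainland
#' species that left no surviving clade.
#'
#' @inheritParams loglik_iw
#' @return The loglikelihood; `-Inf` if any clade exceeds the per-clade
#'   diversity cap.
#' @export
loglik_cs <- function(ds, p, opts = loglik_opts()) {
  p <- as_island_params(p)
  stop_if_invalid(ds)
  cap <- diversity_cap(p)
  sizes <- vapply(ds$clades, clade_size, integer(1))
  if (length(sizes) && max(sizes) > cap) return(-Inf)
  empty <- island_dataset(ds$island_age, 1L, list(), validate = FALSE)
  ll <- (ds$M - length(ds$clades)) * loglik_iw(empty, p, opts)
  for (cl in canonical_clade_order(ds$clades)) {
    one <- cl
    one$mainland_species_id <- 1L
    sub <- island_dataset(ds$island_age, 1L, list(one), validate = FALSE)
    ll <- ll + loglik_iw(sub, p, opts)
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

# summation order is canonical so that permuting the clades of a dataset
# leaves the CS loglikelihood bit-identical
canonical_clade_order <- function(clades) {
  ages <- vapply(clades, `[[`, numeric(1), "colonization_age")
  nms <- vapply(clades, `[[`, character(1), "name")
  clades[order(-ages, nms, method = "radix")]
}

#' Loglikelihood under diversity-independent rates
#'
#' The DI model fixes `K` at infinity, removing the feedback of diversity on
#' colonization and cladogenesis; the clades are then independent and the CS
#' and IW likelihoods coincide.
#'
#' @inheritParams loglik_iw
#' @export
loglik_di <- function(ds, p, opts = loglik_opts()) {
  p <- as_island_params(p)
  p$K <- Inf
  loglik_cs(ds, p, opts)
}

# ---- Monte-Carlo oracle ------------------------------------------------------

#' Brute-force Monte-Carlo estimate of the IW loglikelihood
#'
#' Estimates the likelihood of a small dataset by simulation: runs
#' [simulate_iw()] `n_sims` times and counts realizations whose reconstructed
#' dataset matches `ds`'s clade structure (clade count, sizes, statuses) with
#' every event age within `bin_width / 2` of the data. The density estimate
#' divides by `bin_width` per continuous event age, and by the number of
#' ordered mainland-identity assignments, since the likelihood is a density
#' for clades with specific mainland ancestors. Intended for datasets with at
#' most a few events; this is the independent oracle the ODE likelihood is
#' validated against.
#'
#' @inheritParams loglik_iw
#' @param n_sims Number of simulated islands.
#' @param bin_width Age-matching window, My.
#' @param seed Optional seed.
#' @return A list with `loglik` (estimate), `se` (delta-method standard error
#'   of the log estimate), `matches` and `n_sims`.
#' @export
loglik_oracle_mc <- function(ds, p, n_sims = 1e5, bin_width = 0.5, seed = NULL) {
  p <- as_island_params(p)
  stop_if_invalid(ds)
  if (!is.null(seed)) set.seed(seed)
  target <- ds$clades[order(-vapply(ds$clades, `[[`, numeric(1), "colonization_age"))]
  C <- length(target)
  n_cont <- C + sum(vapply(target, function(cl) length(cl$branching_ages), integer(1)))
  half <- bin_width / 2
  matches <- 0L
  for (s in seq_len(n_sims)) {
    sim <- simulate_iw(p, ds$island_age, ds$M)
    if (length(sim$clades) != C) next
    ok <- TRUE
    for (j in seq_len(C)) {
      a <- sim$clades[[j]]; b <- target[[j]]
      if (a$status != b$status ||
          length(a$branching_ages) != length(b$branching_ages) ||
          abs(a$colonization_age - b$colonization_age) > half ||
          (length(b$branching_ages) &&
           any(abs(a$branching_ages - b$branching_ages) > half))) {
        ok <- FALSE
        break
      }
    }
    if (ok) matches <- matches + 1L
  }
  if (matches == 0L) {
    warning("loglik_oracle_mc: no matching realizations; increase n_sims or bin_width")
    return(list(loglik = -Inf, se = NA_real_, matches = 0L, n_sims = n_sims))
  }
  phat <- matches / n_sims
  id_correction <- if (C > 0) -sum(log(ds$M - seq_len(C) + 1)) else 0
  ll <- log(phat) - n_cont * log(bin_width) + id_correction
  se <- sqrt((1 - phat) / matches)
  list(loglik = ll, se = se, matches = matches, n_sims = n_sims)
}
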