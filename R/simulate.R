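# Event-driven (Gillespie) simulation of island assembly. The process state
# is a flat species table grown by doubling; reconstruction prunes extinct
# lineages and returns only what a phylogeny of the extant species shows.

new_sim_state <- function(island_age) {
  env <- new.env(parent = emptyenv())
  env$n_sp <- 0L
  cap0 <- 64L
  env$clade <- integer(cap0); env$endemic <- logical(cap0)
  env$alive <- logical(cap0); env$parent <- integer(cap0)
  env$birth <- numeric(cap0)
  env$n_cl <- 0L
  env$cl_mainland <- integer(8L); env$cl_col_age <- numeric(8L)
  env$age <- island_age
  env
}

grow_sp <- function(env) {
  n <- length(env$clade)
  for (f in c("clade", "parent")) env[[f]] <- c(env[[f]], integer(n))
  for (f in c("endemic", "alive")) env[[f]] <- c(env[[f]], logical(n))
  env$birth <- c(env$birth, numeric(n))
}

add_species <- function(env, clade, endemic, parent, birth) {
  if (env$n_sp == length(env$clade)) grow_sp(env)
  i <- env$n_sp + 1L
  env$n_sp <- i
  env$clade[i] <- clade; env$endemic[i] <- endemic
  env$alive[i] <- TRUE; env$parent[i] <- parent; env$birth[i] <- birth
  i
}

add_clade <- function(env, mainland, col_age) {
  if (env$n_cl == length(env$cl_mainland)) {
    n <- length(env$cl_mainland)
    env$cl_mainland <- c(env$cl_mainland, integer(n))
    env$cl_col_age <- c(env$cl_col_age, numeric(n))
  }
  i <- env$n_cl + 1L
  env$n_cl <- i
  env$cl_mainland[i] <- mainland; env$cl_col_age[i] <- col_age
  i
}

# One colonization by mainland species m at the current age. Applies the
# reset rule: a repeat colonization while m's only island descendant is a
# still-unspeciated non-endemic singleton resets that lineage's colonization
# age instead of founding a new clade.
do_colonization <- function(env, m) {
  if (env$n_cl > 0L) {
    cls <- which(env$cl_mainland[seq_len(env$n_cl)] == m)
    for (cid in cls) {
      al <- which(env$alive[seq_len(env$n_sp)] & env$clade[seq_len(env$n_sp)] == cid)
      if (length(al) == 1L && !env$endemic[al]) {
        env$cl_col_age[cid] <- env$age
        return(invisible(NULL))
      }
    }
  }
  cid <- add_clade(env, m, env$age)
  add_species(env, cid, endemic = FALSE, parent = 0L, birth = env$age)
  invisible(NULL)
}

# Core Gillespie loop shared by the IW and (per-mainland-species) CS runs.
# `debug_cap` asserts the diversity cap invariant at every event.
run_gillespie <- function(env, p, M, debug_cap = FALSE) {
  cap <- diversity_cap(p)
  repeat {
    idx <- seq_len(env$n_sp)
    al <- which(env$alive[idx])
    N <- length(al)
    if (debug_cap && N > cap) stop("simulator invariant violated: N > diversity cap")
    ne <- al[!env$endemic[al]]
    r_col <- M * colonization_rate(N, p)
    r_cla <- N * clado_rate(N, p)
    r_ext <- N * p$mu
    r_ana <- length(ne) * p$lambda_a
    r_tot <- r_col + r_cla + r_ext + r_ana
    if (r_tot <= 0) break
    env$age <- env$age - stats::rexp(1L, r_tot)
    if (env$age <= 0) break
    u <- stats::runif(1L) * r_tot
    if (u < r_col) {
      do_colonization(env, sample.int(M, 1L))
    } else if (u < r_col + r_cla) {
      w <- if (N == 1L) al else al[sample.int(N, 1L)]
      env$alive[w] <- FALSE
      add_species(env, env$clade[w], endemic = TRUE, parent = w, birth = env$age)
      add_species(env, env$clade[w], endemic = TRUE, parent = w, birth = env$age)
    } else if (u < r_col + r_cla + r_ext) {
      w <- if (N == 1L) al else al[sample.int(N, 1L)]
      env$alive[w] <- FALSE
    } else {
      w <- if (length(ne) == 1L) ne else ne[sample.int(length(ne), 1L)]
      env$endemic[w] <- TRUE
    }
  }
  env$age <- 0
  env
}

# Prune extinct lineages and emit clade records for the surviving clades.
reconstruct_clades <- function(env) {
  idx <- seq_len(env$n_sp)
  if (!env$n_sp) return(list())
  desc <- env$alive[idx]
  for (i in rev(idx)) {
    if (desc[i] && env$parent[i] > 0L) desc[env$parent[i]] <- TRUE
  }
  recs <- list()
  for (cid in seq_len(env$n_cl)) {
    members <- idx[env$clade[idx] == cid]
    extant <- members[env$alive[members]]
    if (!length(extant)) next
    parents <- unique(env$parent[members])
    parents <- parents[parents > 0L]
    branch <- numeric(0)
    for (w in parents) {
      kids <- members[env$parent[members] == w]
      if (length(kids) == 2L && desc[kids[1L]] && desc[kids[2L]]) {
        branch <- c(branch, env$birth[kids[1L]])
      }
    }
    status <- if (length(extant) >= 2L) "endemic_clade"
      else if (env$endemic[extant]) "endemic_singleton" else "non_endemic_singleton"
    recs[[length(recs) + 1L]] <- clade_record(
      name = sprintf("clade_%d", cid),
      mainland_species_id = env$cl_mainland[cid],
      status = status,
      colonization_age = env$cl_col_age[cid],
      branching_ages = branch)
  }
  if (length(recs)) {
    ord <- order(-vapply(recs, `[[`, numeric(1), "colonization_age"))
    recs <- recs[ord]
    for (i in seq_along(recs)) recs[[i]]$name <- sprintf("clade_%d", i)
  }
  recs
}

#' Simulate island assembly under island-wide diversity-dependence
#'
#' Exact continuous-time (Gillespie) simulation of colonization,
#' cladogenesis, anagenesis and extinction from the island's emergence to the
#' present, with per-capita colonization and cladogenesis rates declining
#' with the total island diversity `N` (island-wide scope). The output is the
#' reconstructed dataset: extinct lineages are pruned and only colonization
#' and branching events visible in a phylogeny of the extant species remain.
#'
#' @param p An [island_params()] object.
#' @param island_age Island age, My.
#' @param M Mainland pool size.
#' @param seed Optional integer seed.
#' @param keep_log If `TRUE`, attach the raw species/clade tables as
#'   attribute `"log"` (used by tests and diagnostics).
#' @param debug_cap If `TRUE`, assert at every event that diversity never
#'   exceeds [diversity_cap()].
#' @return An [island_dataset()] (possibly with zero clades). Clades are
#'   ordered by decreasing colonization age. Note the simulator can produce
#'   recolonization doublets (two surviving clades sharing a mainland
#'   ancestor); [validate_dataset()] flags them, and the likelihood functions
#'   do not accept them.
#' @seealso [simulate_cs()] for the clade-specific counterpart.
#' @export
simulate_iw <- function(p, island_age, M, seed = NULL, keep_log = FALSE,
                        debug_cap = FALSE) {
  p <- as_island_params(p)
  if (!is.null(seed)) set.seed(seed)
  env <- new_sim_state(island_age)
  run_gillespie(env, p, M, debug_cap = debug_cap)
  ds <- island_dataset(island_age, M, reconstruct_clades(env), validate = FALSE)
  if (keep_log) attr(ds, "log") <- as.list(env)
  ds
}

#' Simulate island assembly under clade-specific diversity-dependence
#'
#' Identical event semantics to [simulate_iw()], but the diversity feedback
#' on colonization and cladogenesis is scoped to the species descending from
#' the same mainland ancestor: each of the `M` mainland species evolves as an
#' independent island-wide process with a mainland pool of one and its own
#' copy of `K`. Exploits that independence: mainland species whose first
#' potential colonization falls after the present are skipped.
#'
#' @inheritParams simulate_iw
#' @return An [island_dataset()], clades ordered by decreasing colonization
#'   age.
#' @export
simulate_cs <- function(p, island_age, M, seed = NULL, debug_cap = FALSE) {
  p <- as_island_params(p)
  if (!is.null(seed)) set.seed(seed)
  recs <- list()
  if (p$gamma0 > 0) {
    first <- stats::rexp(M, p$gamma0)
    active <- which(first < island_age)
    for (m in active) {
      env <- new_sim_state(island_age)
      env$age <- island_age - first[m]
      do_colonization(env, 1L)
      run_gillespie(env, p, M = 1L, debug_cap = debug_cap)
      cl <- reconstruct_clades(env)
      for (rec in cl) {
        rec$mainland_species_id <- m
        recs[[length(recs) + 1L]] <- rec
      }
    }
  }
  if (length(recs)) {
    ord <- order(-vapply(recs, `[[`, numeric(1), "colonization_age"))
    recs <- recs[ord]
    for (i in seq_along(recs)) recs[[i]]$name <- sprintf("clade_%d", i)
  }
  island_dataset(island_age, M, recs, validate = FALSE)
}

#' Simulate replicate island datasets
#'
#' Convenience wrapper running [simulate_iw()] or [simulate_cs()] `reps`
#' times under one seed.
#'
#' @inheritParams simulate_iw
#' @param model `"IW"` or `"CS"`.
#' @param reps Number of replicate datasets.
#' @return A list of `reps` [island_dataset()] objects.
#' @export
simulate_island <- function(p, island_age, M, model = c("IW", "CS"), reps = 1L,
                            seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  fun <- if (model == "IW") simulate_iw else simulate_cs
  replicate(reps, fun(p, island_age, M), simplify = FALSE)
}
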