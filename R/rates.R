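#' Model parameters for island diversity-dependent diversification
#'
#' Bundles the five rate parameters shared by the simulator and the
#' likelihood functions. All rates are per million years (My).
#'
#' @param lambda_c0 Cladogenesis rate at zero diversity, per island species
#'   per My.
#' @param mu Extinction rate, per island species per My
#'   (diversity-independent).
#' @param K Carrying capacity, in species. May be `Inf` (no
#'   diversity-dependence) and need not be an integer. Its scope -- per clade
#'   or island-wide -- is decided by the model the parameters are used with,
#'   not by this object.
#' @param gamma0 Colonization rate at zero diversity, per mainland species
#'   per My.
#' @param lambda_a Anagenesis rate, per non-endemic island species per My
#'   (diversity-independent).
#'
#' @return An object of class `island_params`: a named list with the five
#'   parameters.
#'
#' @details The diversity-dependent per-capita rates are linear,
#'   \eqn{\lambda_c(N) = \lambda_{c0} (1 - N/K)} and
#'   \eqn{\gamma(N) = \gamma_0 (1 - N/K)}, clamped at zero, where `N` is the
#'   relevant species count. `"inf"`, `"Inf"` and `NA` are accepted for `K`
#'   and mapped to `Inf`.
#'
#' @examples
#' p <- island_params(lambda_c0 = 0.44, mu = 0.11, K = 36.45, gamma0 = 2e-4)
#' clado_rate(18, p)
#' @export
island_params <- function(lambda_c0, mu, K = Inf, gamma0, lambda_a = 0) {
  if (is.character(K)) {
    K <- if (tolower(K) %in% c("inf", "infinite", "infinity")) Inf else as.numeric(K)
  }
  if (is.na(K)) K <- Inf
  p <- list(
    lambda_c0 = as.numeric(lambda_c0), mu = as.numeric(mu), K = as.numeric(K),
    gamma0 = as.numeric(gamma0), lambda_a = as.numeric(lambda_a)
  )
  bad <- vapply(p, function(x) length(x) != 1L || is.na(x) || x < 0, logical(1))
  if (any(bad)) {
    stop("island_params: all parameters must be single non-negative numbers (got ",
         paste(names(p)[bad], collapse = ", "), ")")
  }
  if (p$K <= 0) stop("island_params: K must be positive (or Inf)")
  class(p) <- "island_params"
  p
}

#' @export
print.island_params <- function(x, ...) {
  cat("Island diversification parameters (per My):\n")
  cat(sprintf("  lambda_c0 = %g  mu = %g  K = %g  gamma0 = %g  lambda_a = %g\n",
              x$lambda_c0, x$mu, x$K, x$gamma0, x$lambda_a))
  invisible(x)
}

as_island_params <- function(p) {
  if (inherits(p, "island_params")) return(p)
  if (is.numeric(p) && !is.null(names(p))) p <- as.list(p)
  do.call(island_params, p[c("lambda_c0", "mu", "K", "gamma0", "lambda_a")])
}

#' Diversity-dependent per-capita rates
#'
#' `clado_rate()` evaluates the per-species cladogenesis rate
#' \eqn{\max(0, \lambda_{c0}(1 - N/K))}; `colonization_rate()` the
#' per-mainland-species colonization rate \eqn{\max(0, \gamma_0 (1 - N/K))}.
#'
#' @param N Current diversity (non-negative count, vectorised).
#' @param p An [island_params()] object.
#' @return Numeric vector of rates (per My).
#' @export
clado_rate <- function(N, p) {
  p <- as_island_params(p)
  if (is.infinite(p$K)) rep(p$lambda_c0, length(N)) else pmax(0, p$lambda_c0 * (1 - N / p$K))
}

#' @rdname clado_rate
#' @export
colonization_rate <- function(N, p) {
  p <- as_island_params(p)
  if (is.infinite(p$K)) rep(p$gamma0, length(N)) else pmax(0, p$gamma0 * (1 - N / p$K))
}

#' Maximum attainable species count under rate clamping
#'
#' The smallest diversity at which both the cladogenesis and the colonization
#' rate are exactly zero: `ceiling(K)` for finite non-integer `K`, `K` itself
#' for integer `K`, and `Inf` for infinite `K`.
#'
#' @param p An [island_params()] object.
#' @return A count (possibly `Inf`).
#' @export
diversity_cap <- function(p) {
  p <- as_island_params(p)
  if (is.infinite(p$K)) Inf else ceiling(p$K)
}
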