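#' Birth-rate sequence of a pure-birth chain
#'
#' The ordered rates \eqn{B_{N_0}, \ldots, B_{K-1}} at which the population
#' climbs from `N0` to the absorbing size `K`, one individual at a time,
#' together with their degeneracy grouping. The waiting time in state `N` is
#' exponential with mean \eqn{1/B_N}, so the hitting time of size `N + 1` is a
#' sum of independent exponentials -- a hypoexponential random variable whose
#' parameters are exactly this sequence.
#'
#' Rates are grouped as equal when they differ by at most
#' `tol * max(rates)`; the logistic model's exact mirror degeneracy
#' \eqn{B_k = B_{K-k}} is caught this way.
#'
#' @param model A [growth_model()] with `d = 0` and `alpha = 1`.
#' @param N0 Starting population size, `1 <= N0 < K`.
#' @param tol Relative grouping tolerance for degenerate rates.
#' @return An object of class `rate_sequence` with fields `N0`, `K`, `rates`,
#'   and `groups` (unique values, multiplicities).
#' @export
rate_sequence <- function(model, N0, tol = 1e-9) {
  check_model(model)
  check_stochastic(model)
  K <- model$K
  if (!is.finite(K))
    stop("a finite 'K' (carrying capacity or truncation size) is required")
  stopifnot(N0 >= 1, N0 < K, N0 == round(N0))
  rates <- birth_rate(model, N0:(K - 1))
  if (any(rates <= 0)) stop("all rates B_N for N0 <= N < K must be positive")
  new_rate_sequence(rates, N0 = as.integer(N0), K = K, tol = tol)
}

new_rate_sequence <- function(rates, N0, K, tol = 1e-9) {
  structure(list(N0 = N0, K = K, rates = rates,
                 groups = group_rates(rates, tol)),
            class = "rate_sequence")
}

# Partition a positive rate list into unique values with multiplicities,
# invariant under permutation of the input.
group_rates <- function(rates, tol = 1e-9) {
  stopifnot(length(rates) >= 1, all(rates > 0))
  s <- sort(rates)
  eps <- tol * max(s)
  grp <- cumsum(c(TRUE, diff(s) > eps))
  values <- as.numeric(tapply(s, grp, mean))
  mult <- as.integer(tabulate(grp))
  case <- if (length(values) == 1L) 1L else if (all(mult == 1L)) 2L else 3L
  list(values = values, multiplicities = mult, case = case)
}

check_stochastic <- function(model) {
  if (model$d > 0)
    stop("the pure-birth machinery requires d = 0 (use the birth-death simulator)")
  if (model$alpha != 1)
    stop("stochastic solvers require alpha = 1: only then does the jump ",
         "process have the deterministic rate law as its mean-field limit")
  invisible(model)
}

#' @export
print.rate_sequence <- function(x, ...) {
  g <- x$groups
  cat(sprintf("<rate_sequence> N0 = %d -> K = %d (%d rates, %d unique, case %d)\n",
              x$N0, x$K, length(x$rates), length(g$values), g$case))
  invisible(x)
}
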