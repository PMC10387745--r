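#' Exact population-size distribution of a pure-birth process
#'
#' Solves the master equation
#' \deqn{\frac{dP_{N_0,N}(t)}{dt} = B_{N-1} P_{N_0,N-1}(t) - B_N P_{N_0,N}(t)}
#' exactly. Because a pure-birth population must pass through every size in
#' order, the hitting time of size `N + 1` is hypoexponential with parameters
#' \eqn{B_{N_0}, \ldots, B_N}, and
#' \deqn{P_{N_0,N}(t) = H_t(B_{N_0}, \ldots, B_N) / B_N, \quad N < K,}
#' with the absorbing state carrying the remaining mass
#' \eqn{P_{N_0,K}(t) = 1 - \sum_{N<K} P_{N_0,N}(t)}.
#'
#' @section Methods:
#' * `"hypoexp"`: the closed-form hypoexponential solution (handles
#'   degenerate rate sets such as the logistic mirror symmetry
#'   \eqn{B_k = B_{K-k}}). The alternating sums become ill-conditioned for
#'   long rate lists, in which case the estimated round-off is reported.
#' * `"uniformization"`: transient probabilities of the underlying Markov
#'   chain through a Poisson-randomized discrete chain; numerically stable
#'   (all terms non-negative) with truncation error below `1e-12`. The
#'   production path for large `K`.
#' * `"ode"`: direct stiff integration of the coupled master equation (see
#'   [master_equation_oracle()]).
#' * `"spectral"`: eigen-decomposition of the transition-rate matrix (see
#'   [spectral_distribution()]); distinct rates only.
#' * `"auto"` (default): the closed form, falling back to uniformization
#'   when the estimated round-off exceeds `1e-10` or a row normalization
#'   check fails.
#'
#' @param model A [growth_model()] with `d = 0` and `alpha = 1`. For the
#'   exponential family `K` is a truncation size and the final state
#'   aggregates all sizes `>= K`.
#' @param N0 Initial population size, `1 <= N0 < K` (`N0 = K` gives the
#'   degenerate point-mass distribution).
#' @param times Non-negative, non-decreasing time grid.
#' @param method See Methods.
#' @return A `size_distribution`: list with `times`, `sizes` (`N0:K`), and
#'   `probs`, a `length(times) x length(sizes)` matrix with rows summing
#'   to one.
#' @examples
#' m <- growth_model("logistic", K = 30)
#' d <- exact_distribution(m, N0 = 1, times = seq(0, 10, 0.5))
#' rowSums(d$probs)[1:3]
#' @export
exact_distribution <- function(model, N0, times,
                               method = c("auto", "hypoexp", "uniformization",
                                          "ode", "spectral")) {
  method <- match.arg(method)
  check_model(model)
  check_stochastic(model)
  if (N0 == model$K)
    return(new_size_distribution(matrix(1, length(times), 1), times,
                                 N0 = N0, K = model$K, method = "point"))
  rs <- rate_sequence(model, N0)
  birth_chain_distribution(rs, times, method = method)
}

#' Size distribution of an arbitrary pure-birth chain
#'
#' Workhorse behind [exact_distribution()]: takes any positive rate sequence
#' (not necessarily derived from a growth-model rate law) and returns the
#' time-dependent occupation probabilities of the chain
#' `N0 -> N0+1 -> ... -> K`.
#'
#' @param rates A [rate_sequence()], or a bare vector of positive rates
#'   \eqn{B_{N_0}, \ldots, B_{K-1}} (then `N0` defaults to 1).
#' @inheritParams exact_distribution
#' @param N0 Starting size when `rates` is a bare vector.
#' @return A `size_distribution`.
#' @export
birth_chain_distribution <- function(rates, times,
                                     method = c("auto", "hypoexp",
                                                "uniformization", "ode",
                                                "spectral"),
                                     N0 = 1L) {
  method <- match.arg(method)
  if (!inherits(rates, "rate_sequence"))
    rates <- new_rate_sequence(as.numeric(rates), N0 = as.integer(N0),
                               K = as.integer(N0 + length(rates)))
  stopifnot(all(times >= 0), !is.unsorted(times))
  if (method == "spectral") return(spectral_chain_distribution(rates, times))
  if (method == "ode") return(ode_chain_distribution(rates, times))
  if (method == "uniformization")
    return(uniformization_distribution(rates, times))
  hypo <- hypoexp_chain_distribution(rates, times)
  if (method == "hypoexp") return(hypo)
  # auto: accept the closed form only if well-conditioned and normalized
  ok <- attr(hypo, "roundoff") < 1e-10 &&
    max(abs(rowSums(hypo$probs) - 1)) < 1e-9 &&
    attr(hypo, "clamped") < 1e-9
  if (ok) hypo else uniformization_distribution(rates, times)
}

hypoexp_chain_distribution <- function(rs, times) {
  N0 <- rs$N0; K <- rs$K; B <- rs$rates
  S <- K - N0 + 1L
  probs <- matrix(0, length(times), S)
  roundoff <- 0
  for (N in N0:(K - 1L)) {
    j <- N - N0 + 1L
    h <- hypoexp_pdf(B[seq_len(j)], times)
    roundoff <- max(roundoff, attr(h, "roundoff"))
    probs[, j] <- as.numeric(h) / B[j]
  }
  probs[times == 0, ] <- 0
  probs[times == 0, 1] <- 1
  probs[, S] <- 1 - rowSums(probs[, -S, drop = FALSE])
  out <- new_size_distribution(probs, times, N0, K, method = "hypoexp")
  attr(out, "roundoff") <- roundoff
  out
}

# Transient solution by uniformization: with Lambda >= max(B), the jump chain
# A = I + Q/Lambda is substochastic-free and
# P(t) = sum_k dpois(k, Lambda t) A^k e_{N0}, truncated at Poisson tail 1e-13.
uniformization_distribution <- function(rs, times) {
  N0 <- rs$N0; K <- rs$K
  S <- K - N0 + 1L
  B <- c(rs$rates, 0)                      # per-state exit rates, absorbing K
  Lambda <- max(B)
  tmax <- max(times)
  if (Lambda * tmax == 0) {
    probs <- matrix(0, length(times), S); probs[, 1] <- 1
    return(new_size_distribution(probs, times, N0, K, "uniformization"))
  }
  kmax <- stats::qpois(1e-13, Lambda * tmax, lower.tail = FALSE) + 10L
  V <- matrix(0, S, kmax + 1L)
  v <- numeric(S); v[1] <- 1
  V[, 1] <- v
  stay <- 1 - B / Lambda
  move <- B[-S] / Lambda
  for (k in seq_len(kmax)) {
    v <- stay * v + c(0, move * v[-S])
    V[, k + 1L] <- v
  }
  W <- vapply(times, function(t) stats::dpois(0:kmax, Lambda * t),
              numeric(kmax + 1L))
  probs <- t(V %*% W)
  # assign the truncated Poisson tail mass to the absorbing state
  probs[, S] <- probs[, S] + pmax(0, 1 - rowSums(probs))
  new_size_distribution(probs, times, N0, K, method = "uniformization")
}

ode_chain_distribution <- function(rs, times) {
  N0 <- rs$N0; K <- rs$K
  S <- K - N0 + 1L
  B <- c(rs$rates, 0)
  rhs <- function(t, p, parms) {
    gain <- c(0, B[-S] * p[-S])
    list(gain - B * p)
  }
  p0 <- numeric(S); p0[1] <- 1
  tgrid <- if (times[1] > 0) c(0, times) else times
  out <- deSolve::ode(y = p0, times = tgrid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12,
                      jactype = "bandint", bandup = 0, banddown = 1)
  probs <- unname(out[match(times, tgrid), -1, drop = FALSE])
  new_size_distribution(probs, times, N0, K, method = "ode")
}

#' Spectral (transition-rate matrix) solution of the pure-birth master equation
#'
#' Writes the master equation in matrix form \eqn{dP/dt = R P} with the lower
#' bidiagonal generator \eqn{R} and expands the solution over its
#' eigenstructure. Because \eqn{R} is triangular its eigenvalues are the
#' diagonal entries \eqn{\mu_k = -B_k}, and imposing the initial condition
#' yields
#' \deqn{P_{N_0,N}(t) = \frac{1}{B_N} \sum_{k=N_0}^{N} B_k e^{-B_k t}
#'       \prod_{q \ne k} \frac{B_q}{B_q - B_k}.}
#' The eigenvectors are ill-defined when any two rates coincide, so this
#' route requires all rates pairwise distinct; degenerate models (e.g. the
#' logistic, whose rates obey the mirror symmetry \eqn{B_k = B_{K-k}}) raise
#' an error naming the colliding states. Use [exact_distribution()] for
#' those.
#'
#' @inheritParams exact_distribution
#' @return A `size_distribution`.
#' @export
spectral_distribution <- function(model, N0, times) {
  check_model(model)
  check_stochastic(model)
  spectral_chain_distribution(rate_sequence(model, N0), times)
}

spectral_chain_distribution <- function(rs, times) {
  g <- rs$groups
  if (g$case != 2L) {
    mult <- g$multiplicities
    bad <- which(abs(outer(rs$rates, rs$rates, "-")) <=
                   1e-9 * max(rs$rates) & upper.tri(diag(length(rs$rates))),
                 arr.ind = TRUE)
    states <- unique(rs$N0 - 1L + sort(c(bad)))
    stop("degenerate birth rates: states {",
         paste(utils::head(states, 8L), collapse = ", "),
         if (length(states) > 8L) ", ..." else "",
         "} share rates; the spectral solution requires distinct rates")
  }
  N0 <- rs$N0; K <- rs$K; B <- rs$rates
  S <- K - N0 + 1L
  probs <- matrix(0, length(times), S)
  roundoff <- 0
  for (N in N0:(K - 1L)) {
    j <- N - N0 + 1L
    res <- cpp_hypoexp_distinct_dd(B[seq_len(j)], times)
    roundoff <- max(roundoff, res$maxterm * 1e-31)
    probs[, j] <- res$value / B[j]
  }
  if (roundoff > 1e-8)
    stop("the eigenvector expansion is numerically unstable for this rate ",
         "sequence (estimated round-off ", signif(roundoff, 2),
         "); use exact_distribution()")
  probs[times == 0, ] <- 0
  probs[times == 0, 1] <- 1
  probs[, S] <- 1 - rowSums(probs[, -S, drop = FALSE])
  out <- new_size_distribution(probs, times, N0, K, method = "spectral")
  attr(out, "roundoff") <- roundoff
  out
}

#' Independent master-equation oracle
#'
#' Direct stiff numerical integration of the \eqn{K - N_0 + 1} coupled master
#' equations with a banded Jacobian. Shares no code with the analytic
#' solutions and serves as the internal ground truth for validating them;
#' intended for `K` up to a few hundred.
#'
#' @inheritParams exact_distribution
#' @return A `size_distribution`.
#' @export
master_equation_oracle <- function(model, N0, times) {
  check_model(model)
  check_stochastic(model)
  ode_chain_distribution(rate_sequence(model, N0), times)
}

new_size_distribution <- function(probs, times, N0, K, method) {
  neg <- probs < 0
  clamped <- if (any(neg)) max(-probs[neg]) else 0
  probs[neg] <- 0
  probs <- probs / rowSums(probs)
  structure(list(times = times, sizes = N0:K, probs = probs,
                 N0 = N0, K = K, method = method),
            class = "size_distribution", clamped = clamped)
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(
    "<size_distribution> sizes %d..%d, %d times in [%g, %g] (method: %s)\n",
    x$N0, x$K, length(x$times), min(x$times), max(x$times), x$method))
  invisible(x)
}

#' @export
as.data.frame.size_distribution <- function(x, ...) {
  data.frame(time = rep(x$times, times = length(x$sizes)),
             size = rep(x$sizes, each = length(x$times)),
             prob = as.vector(x$probs))
}

#' Moments of a size distribution
#'
#' Computes \eqn{\langle N^m \rangle(t) = \sum_N N^m P_{N_0,N}(t)} for the
#' requested orders.
#'
#' @param dist A `size_distribution`.
#' @param orders Positive integer moment orders.
#' @return A `moment_trajectory`: list with `times` and a matrix `values`
#'   whose columns are the requested orders (named `m1`, `m2`, ...).
#' @export
distribution_moments <- function(dist, orders = 1:2) {
  stopifnot(inherits(dist, "size_distribution"), all(orders >= 1))
  vals <- vapply(orders, function(m) as.numeric(dist$probs %*% dist$sizes^m),
                 numeric(length(dist$times)))
  vals <- matrix(vals, ncol = length(orders),
                 dimnames = list(NULL, paste0("m", orders)))
  new_moment_trajectory(dist$times, vals)
}

new_moment_trajectory <- function(times, values) {
  structure(list(times = times, values = values), class = "moment_trajectory")
}

#' @export
print.moment_trajectory <- function(x, ...) {
  cat(sprintf("<moment_trajectory> orders {%s}, %d times in [%g, %g]\n",
              paste(colnames(x$values), collapse = ", "),
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Relative error of a deterministic prediction
#'
#' \deqn{\eta(t) = \frac{N_d(t) - N_s(t)}{N_s(t)}}
#' where `deterministic` is the prediction \eqn{N_d} and `stochastic_mean`
#' the reference mean \eqn{N_s} on the same time grid. Positive values mean
#' the deterministic curve overestimates the mean.
#'
#' @param deterministic,stochastic_mean Numeric vectors on a common grid.
#' @return The vector \eqn{\eta(t)}.
#' @export
relative_error <- function(deterministic, stochastic_mean) {
  stopifnot(length(deterministic) == length(stochastic_mean))
  if (any(stochastic_mean <= 0)) stop("'stochastic_mean' must be positive")
  (deterministic - stochastic_mean) / stochastic_mean
}
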