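#' Two-strain community specification
#'
#' A wild-type strain (intrinsic birth rate `b_w`) and a mutant strain
#' (`b_m`) grow in one environment with shared carrying capacity `K` and
#' shared density factor \eqn{g(N)} taken from the growth family. The
#' relative fitness is \eqn{r = b_M / b_W}.
#'
#' @param model A [growth_model()] supplying the family and `K` (its own `b`
#'   and `d` are not used; `d` must be 0, `alpha` must be 1).
#' @param b_w,b_m Strain intrinsic birth rates, positive.
#' @param N0 Initial community size.
#' @param n0 Initial mutant count, `0 <= n0 <= N0`.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(model, b_w = 1, b_m = 1, N0, n0) {
  check_model(model)
  check_stochastic(model)
  stopifnot(is.finite(model$K), b_w > 0, b_m > 0,
            N0 >= 1, N0 <= model$K, N0 == round(N0),
            n0 >= 0, n0 <= N0, n0 == round(n0))
  structure(list(model = model, b_w = b_w, b_m = b_m, r = b_m / b_w,
                 N0 = as.integer(N0), n0 = as.integer(n0), K = model$K),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf(
    "<community_spec> %s, K = %d; b_W = %g, b_M = %g (r = %g); N0 = %d, n0 = %d\n",
    x$model$family, x$K, x$b_w, x$b_m, x$r, x$N0, x$n0))
  invisible(x)
}

#' Probability that a birth is a mutant birth
#'
#' When a community of size `N` with `n` mutants gains one individual, the
#' newborn is a mutant with probability
#' \deqn{\Gamma(N, n) = \frac{r n}{(r - 1) n + N}
#'     = \frac{b_M n}{b_M n + b_W (N - n)},}
#' independent of the growth family (the shared density factor cancels).
#'
#' @param r Relative fitness `b_m / b_w`.
#' @param N Community size (at least 1).
#' @param n Mutant count, `0 <= n <= N`. Vectorized over `N` and `n`.
#' @return Probabilities in `[0, 1]`.
#' @export
mutant_birth_probability <- function(r, N, n) {
  stopifnot(r > 0, all(N >= 1), all(n >= 0), all(n <= N))
  r * n / ((r - 1) * n + N)
}

#' Composition of the community conditioned on its size
#'
#' The conditional law \eqn{P(N, n \mid N_0, n_0)} of the mutant count `n`
#' given total size `N` follows the recursion
#' \deqn{P(N+1, n) = (1 - \Gamma(N, n)) P(N, n) + \Gamma(N, n-1) P(N, n-1)}
#' from the point mass at \eqn{(N_0, n_0)}. It depends on the strains only
#' through the fitness ratio `r` and is independent of the growth family. In
#' the neutral case `r = 1` starting from \eqn{(2, 1)} the composition is
#' uniform on \eqn{1 \le n \le N - 1} (Polya-urn uniformity).
#'
#' @param spec A [community_spec()].
#' @return A `composition_distribution`: matrix with rows indexed by total
#'   size `N0..K` and columns by mutant count `0..K`; each row sums to 1.
#' @export
composition_distribution <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  K <- spec$K; N0 <- spec$N0; n0 <- spec$n0; r <- spec$r
  P <- matrix(0, nrow = K - N0 + 1L, ncol = K + 1L,
              dimnames = list(N = N0:K, n = 0:K))
  P[1L, n0 + 1L] <- 1
  if (K > N0) {
    for (N in N0:(K - 1L)) {
      i <- N - N0 + 1L
      ns <- n0:(n0 + (N - N0))            # reachable mutant counts at size N
      Gam <- mutant_birth_probability(r, N, ns)
      row <- P[i, ns + 1L]
      nxt <- numeric(length(ns) + 1L)
      nxt[seq_along(ns)] <- nxt[seq_along(ns)] + (1 - Gam) * row
      nxt[seq_along(ns) + 1L] <- nxt[seq_along(ns) + 1L] + Gam * row
      P[i + 1L, n0 + seq_along(nxt) - 1L + 1L] <- nxt
    }
  }
  structure(P, class = "composition_distribution", N0 = N0, n0 = n0, r = r)
}

#' @export
print.composition_distribution <- function(x, ...) {
  cat(sprintf(
    "<composition_distribution> P(n | N) for N = %s..%s (r = %g, n0 = %d)\n",
    rownames(x)[1], rownames(x)[nrow(x)], attr(x, "r"), attr(x, "n0")))
  invisible(x)
}

#' Composition-averaged community birth rates
#'
#' The total community reproduction rate at size `N`, averaged over the
#' conditional composition:
#' \deqn{B_N = \sum_n P(N, n \mid N_0, n_0) (B^M_{N,n} + B^W_{N,n})
#'     = g(N) (b_M \langle n \mid N \rangle +
#'             b_W (N - \langle n \mid N \rangle)),}
#' with strain rates \eqn{B^M_{N,n} = b_M g(N) n} and
#' \eqn{B^W_{N,n} = b_W g(N) (N - n)}. These rates define the pure-birth
#' chain of the total community size.
#'
#' @param spec A [community_spec()].
#' @param composition Optional precomputed [composition_distribution()].
#' @return A [rate_sequence()] for `N = N0 .. K-1`.
#' @export
aggregate_rates <- function(spec, composition = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  if (is.null(composition)) composition <- composition_distribution(spec)
  K <- spec$K; N0 <- spec$N0
  Ns <- N0:(K - 1L)
  nbar <- as.numeric(composition[seq_along(Ns), , drop = FALSE] %*% (0:K))
  g <- per_capita_factor(spec$model, Ns)
  rates <- g * (spec$b_m * nbar + spec$b_w * (Ns - nbar))
  new_rate_sequence(rates, N0 = N0, K = K)
}

#' Exact distribution of the total community size
#'
#' The total size of the two-strain community is itself a pure-birth chain
#' with the composition-averaged rates of [aggregate_rates()]; its exact
#' distribution follows from the same hypoexponential solution as the
#' single-strain case.
#'
#' @inheritParams aggregate_rates
#' @param times Time grid.
#' @param method Passed to [birth_chain_distribution()].
#' @return A `size_distribution`.
#' @export
community_size_distribution <- function(spec, times, method = "auto") {
  birth_chain_distribution(aggregate_rates(spec), times, method = method)
}

#' Exact distribution of the mutant count
#'
#' Marginalizes the joint law over the total size:
#' \deqn{P_{n_0,n}(t) = \sum_N P_{N_0,N}(t) \, P(N, n \mid N_0, n_0).}
#'
#' @inheritParams community_size_distribution
#' @return A list with `times`, `counts` (mutant counts `0..K`), and `probs`
#'   (`length(times) x (K+1)` matrix, rows summing to 1), of class
#'   `count_distribution`.
#' @export
mutant_count_distribution <- function(spec, times, method = "auto") {
  comp <- composition_distribution(spec)
  sdist <- birth_chain_distribution(aggregate_rates(spec, comp), times,
                                    method = method)
  probs <- sdist$probs %*% comp          # times x (K+1)
  structure(list(times = times, counts = 0:spec$K, probs = unname(probs)),
            class = "count_distribution")
}

#' @export
print.count_distribution <- function(x, ...) {
  cat(sprintf("<count_distribution> counts 0..%d, %d times in [%g, %g]\n",
              max(x$counts), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Exact mean community and mutant sizes
#'
#' \eqn{\langle N \rangle(t)} and \eqn{\langle n \rangle(t)} from the exact
#' size and mutant-count distributions.
#'
#' @inheritParams community_size_distribution
#' @return A data frame with columns `time`, `N_mean`, `n_mean`.
#' @export
community_means <- function(spec, times, method = "auto") {
  comp <- composition_distribution(spec)
  sdist <- birth_chain_distribution(aggregate_rates(spec, comp), times,
                                    method = method)
  Nbar <- as.numeric(sdist$probs %*% sdist$sizes)
  cprobs <- sdist$probs %*% comp
  nbar <- as.numeric(cprobs %*% (0:spec$K))
  data.frame(time = times, N_mean = Nbar, n_mean = nbar)
}

#' Deterministic (mean-field) community dynamics
#'
#' Integrates the coupled system
#' \deqn{dn/dt = b_M \, n \, g(N), \quad
#'       dN/dt = (b_M n + b_W (N - n)) \, g(N),}
#' the mean-field limit of the two-strain jump process (for the logistic
#' family \eqn{g(N) = 1 - N/K}, recovering the classical competition
#' equations).
#'
#' @inheritParams community_size_distribution
#' @return A data frame with columns `time`, `N`, `n`.
#' @export
deterministic_community <- function(spec, times) {
  stopifnot(inherits(spec, "community_spec"), all(times >= 0),
            !is.unsorted(times))
  model <- spec$model; K <- spec$K
  # the density factor evaluated continuously in N
  gcont <- function(N) {
    N <- min(max(N, 1e-12), K)
    switch(model$family,
      exponential = 1,
      logistic = 1 - N / K,
      blumberg = (1 - N / K)^model$gamma,
      richards = 1 - (N / K)^model$beta,
      gompertz = if (N >= K) 0 else log(K / N))
  }
  rhs <- function(t, y, parms) {
    n <- y[1]; N <- y[2]
    g <- gcont(N)
    list(c(spec$b_m * n * g,
           (spec$b_m * n + spec$b_w * (N - n)) * g))
  }
  tgrid <- if (times[1] > 0) c(0, times) else times
  out <- deSolve::ode(y = c(spec$n0, spec$N0), times = tgrid, func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  out <- out[match(times, tgrid), , drop = FALSE]
  data.frame(time = times, N = unname(out[, 3]), n = unname(out[, 2]))
}
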