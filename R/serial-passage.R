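#' Serial-passage experiment specification
#'
#' Repeated growth-dilution cycles: the community grows for a time `tau`,
#' then a bottleneck resamples it down to `N0 = D * K` individuals by
#' binomial draws (sampling with replacement, success probability `n/N`).
#' The mutant count after successive bottlenecks forms a Markov chain on
#' `0..N0` whose absorbing states are loss (0) and fixation (`N0`).
#'
#' @param model A [growth_model()] supplying the family and `K`.
#' @param b_w,b_m Strain intrinsic birth rates.
#' @param dilution Dilution ratio `D = N0/K`; `D * K` must be a whole number
#'   `>= 2`.
#' @param tau Growth time between bottlenecks (`> 0`).
#' @param n0 Initial mutant count, `0 <= n0 <= N0`.
#' @return An object of class `passage_spec`.
#' @export
passage_spec <- function(model, b_w = 1, b_m = 1, dilution, tau, n0) {
  check_model(model)
  check_stochastic(model)
  K <- model$K
  stopifnot(is.finite(K), b_w > 0, b_m > 0, tau > 0)
  N0 <- dilution * K
  if (abs(N0 - round(N0)) > 1e-9 || round(N0) < 2)
    stop("'dilution' must give an integer post-bottleneck size D * K >= 2")
  N0 <- as.integer(round(N0))
  stopifnot(n0 >= 0, n0 <= N0, n0 == round(n0))
  structure(list(model = model, b_w = b_w, b_m = b_m, r = b_m / b_w,
                 dilution = dilution, tau = tau, K = K, N0 = N0,
                 n0 = as.integer(n0)),
            class = "passage_spec")
}

#' @export
print.passage_spec <- function(x, ...) {
  cat(sprintf(
    "<passage_spec> %s, K = %d, D = %g (N0 = %d), tau = %g, r = %g, n0 = %d\n",
    x$model$family, x$K, x$dilution, x$N0, x$tau, x$r, x$n0))
  invisible(x)
}

#' Bottleneck transition matrix of the mutant count
#'
#' The probability that the post-bottleneck mutant count moves from `k` to
#' `l` in one growth-dilution cycle.
#'
#' With `approach = "stochastic"` the growth phase is treated exactly: for
#' each starting count `k` the composition law, the composition-averaged
#' rates, and the exact size distribution at `tau` are recomputed from
#' \eqn{(N_0, k)}, and binomial sampling laws are mixed over the joint
#' \eqn{(N, n)} distribution,
#' \deqn{\Pi_{k \to l} = \sum_{N}\sum_{n} P_{N_0,N}(\tau)
#'   P(N, n \mid N_0, k) \binom{N_0}{l} (n/N)^l (1 - n/N)^{N_0 - l}.}
#'
#' With `approach = "deterministic"` the growth phase follows the mean-field
#' community system and each row is a single binomial with success
#' probability \eqn{n(\tau)/N(\tau)}.
#'
#' Rows `k = 0` and `k = N0` are point masses (absorbing states).
#'
#' @param spec A [passage_spec()].
#' @param approach `"stochastic"` (exact growth law) or `"deterministic"`.
#' @return A `bottleneck_chain`: list with the `(N0+1) x (N0+1)`
#'   row-stochastic matrix `Pi` (rows = starting count `k = 0..N0`), the
#'   `approach`, and the `spec`.
#' @export
bottleneck_matrix <- function(spec, approach = c("stochastic",
                                                 "deterministic")) {
  approach <- match.arg(approach)
  stopifnot(inherits(spec, "passage_spec"))
  N0 <- spec$N0; K <- spec$K; tau <- spec$tau
  Pi <- matrix(0, N0 + 1L, N0 + 1L,
               dimnames = list(k = 0:N0, l = 0:N0))
  Pi[1L, 1L] <- 1
  Pi[N0 + 1L, N0 + 1L] <- 1
  if (N0 > 1L) for (k in 1:(N0 - 1L)) {
    cs <- community_spec(spec$model, b_w = spec$b_w, b_m = spec$b_m,
                         N0 = N0, n0 = k)
    if (approach == "stochastic") {
      comp <- composition_distribution(cs)
      sdist <- birth_chain_distribution(aggregate_rates(cs, comp), tau)
      # joint weights over (N, n) at tau
      w <- as.numeric(sdist$probs) * comp        # (K - N0 + 1) x (K + 1)
      Ns <- N0:K
      keep <- which(w > 0, arr.ind = TRUE)
      frac <- (keep[, 2] - 1) / Ns[keep[, 1]]    # n / N
      wts <- w[keep]
      row <- vapply(0:N0, function(l) {
        sum(wts * stats::dbinom(l, N0, frac))
      }, numeric(1))
    } else {
      traj <- deterministic_community(cs, tau)
      frac <- traj$n[1] / traj$N[1]
      row <- stats::dbinom(0:N0, N0, frac)
    }
    Pi[k + 1L, ] <- row
  }
  structure(list(Pi = Pi, approach = approach, spec = spec),
            class = "bottleneck_chain")
}

#' @export
print.bottleneck_chain <- function(x, ...) {
  cat(sprintf("<bottleneck_chain> %s growth, N0 = %d (%d states)\n",
              x$approach, x$spec$N0, nrow(x$Pi)))
  invisible(x)
}

#' Fixation probability of the mutant strain
#'
#' Embeds the bottleneck chain in continuous time via the rate matrix
#' \eqn{R_{ij} = \Pi_{j \to i}} (off-diagonal), \eqn{R_{jj} = -\sum_{i \ne j}
#' \Pi_{j \to i}}, removes the rows and columns of the absorbing states 0 and
#' `N0` to form \eqn{\tilde R}, and evaluates
#' \deqn{p_{fix} = -\sum_{i=1}^{N_0 - 1} \Pi_{i \to N_0}
#'       \left(\tilde R^{-1}\right)_{i, n_0}.}
#' The continuous-time embedding leaves absorption probabilities unchanged,
#' so this equals the absorption probability of the discrete chain.
#'
#' @param chain A [bottleneck_matrix()] result.
#' @param n0 Starting mutant count; `0` and `N0` return 0 and 1 directly.
#' @return The fixation probability.
#' @export
fixation_probability <- function(chain, n0) {
  stopifnot(inherits(chain, "bottleneck_chain"))
  N0 <- chain$spec$N0
  stopifnot(n0 >= 0, n0 <= N0, n0 == round(n0))
  if (n0 == 0) return(0)
  if (n0 == N0) return(1)
  Pi <- chain$Pi
  interior <- 2:N0                       # states 1 .. N0-1 (1-based offset)
  R <- t(Pi)                             # R[i, j] = Pi_{j -> i}
  diag(R) <- diag(R) - colSums(R)        # R_jj = -sum_{i != j} Pi_{j -> i}
  Rt <- R[interior, interior, drop = FALSE]
  x <- solve(Rt, replace(numeric(N0 - 1L), n0, 1))  # column n0 of Rt^{-1}
  pf <- -sum(Pi[interior, N0 + 1L] * x)
  min(max(pf, 0), 1)
}

#' Fixation probability across dilution ratios
#'
#' Builds both the stochastic and the deterministic bottleneck chains for
#' each dilution ratio and reports the two fixation probabilities, starting
#' from a mutant fraction `n0_frac` of the post-bottleneck community.
#'
#' @param model A [growth_model()].
#' @param b_w,b_m Strain intrinsic birth rates.
#' @param tau Growth time between bottlenecks.
#' @param dilutions Dilution ratios `D`; each `D * K` must be an even integer
#'   `>= 2` when `n0_frac = 0.5`.
#' @param n0_frac Initial mutant fraction of `N0` (default one half).
#' @return A data frame with columns `D`, `N0`, `n0`, `pfix_stochastic`,
#'   `pfix_deterministic`.
#' @export
pfix_dilution_sweep <- function(model, b_w = 1, b_m = 1.1, tau = 3,
                                dilutions, n0_frac = 0.5) {
  rows <- lapply(dilutions, function(D) {
    N0 <- as.integer(round(D * model$K))
    n0 <- as.integer(round(n0_frac * N0))
    sp <- passage_spec(model, b_w = b_w, b_m = b_m, dilution = D, tau = tau,
                       n0 = n0)
    data.frame(
      D = D, N0 = N0, n0 = n0,
      pfix_stochastic = fixation_probability(bottleneck_matrix(sp), n0),
      pfix_deterministic =
        fixation_probability(bottleneck_matrix(sp, "deterministic"), n0))
  })
  do.call(rbind, rows)
}
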