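#' Hypoexponential probability density
#'
#' Density of a sum of independent exponential random variables with rates
#' `rates` (repeats allowed). Three regimes are handled:
#'
#' * all rates identical: the Erlang density
#'   \eqn{\lambda^n t^{n-1} e^{-\lambda t} / (n-1)!};
#' * all rates distinct:
#'   \eqn{H_t = \sum_i \lambda_i e^{-\lambda_i t}
#'        \prod_{j \ne i} \lambda_j / (\lambda_j - \lambda_i)};
#' * partial degeneracy (unique rates \eqn{\lambda_i} with multiplicities
#'   \eqn{n_i}):
#'   \eqn{H_t = \left(\prod_i \lambda_i^{n_i}\right) \sum_i
#'        \sum_{k=0}^{n_i-1} \frac{C_{i,k}}{k!\,(n_i-k-1)!}
#'        t^{n_i-k-1} e^{-\lambda_i t}}
#'   with \eqn{C_{i,k} = \frac{d^k}{ds^k} \prod_{j\ne i}
#'        (s+\lambda_j)^{-n_j} \big|_{s=-\lambda_i}}.
#'
#' The degenerate-case coefficients are computed by the logarithmic-derivative
#' recursion: with \eqn{f_i(s) = \prod_{j \ne i} (s+\lambda_j)^{-n_j}}, the
#' derivatives of \eqn{\log f_i} are elementary power sums, and
#' \eqn{f^{(k)} = \sum_{p<k} \binom{k-1}{p} f^{(p)} (\log f)^{(k-p)}}.
#'
#' The distinct-rate and degenerate closed forms are alternating sums and can
#' lose precision for long, closely spaced rate lists; an estimate of the
#' round-off (largest term times machine epsilon) is attached as attribute
#' `"roundoff"`.
#'
#' @param rates Positive rates, or a [rate_sequence()].
#' @param t Non-negative time(s); vectorized.
#' @param tol Relative tolerance used to group equal rates.
#' @return Density values, one per element of `t`.
#' @examples
#' hypoexp_pdf(c(1, 2), log(2))  # 0.5
#' @export
hypoexp_pdf <- function(rates, t, tol = 1e-9) {
  if (inherits(rates, "rate_sequence")) rates <- rates$rates
  if (length(rates) == 0L) stop("'rates' must contain at least one rate")
  if (any(rates <= 0)) stop("all rates must be positive")
  if (any(t < 0)) stop("'t' must be non-negative")
  g <- group_rates(rates, tol)
  out <- switch(g$case,
    erlang_pdf(g$values, length(rates), t),
    hypoexp_pdf_distinct(g$values, t),
    hypoexp_pdf_degenerate(g$values, g$multiplicities, t))
  structure(pmax(out$value, 0), roundoff = out$roundoff)
}

erlang_pdf <- function(lambda, n, t) {
  list(value = stats::dgamma(t, shape = n, rate = lambda), roundoff = 0)
}

# Case 2: all rates distinct. Weights computed in log magnitude + sign;
# escalates to the double-double kernel when binary64 cancellation would
# leave more than ~1e-12 absolute error in the alternating sum.
hypoexp_pdf_distinct <- function(lam, t) {
  n <- length(lam)
  logw <- numeric(n); sgn <- numeric(n)
  for (i in seq_len(n)) {
    d <- lam[-i] - lam[i]
    logw[i] <- log(lam[i]) + sum(log(lam[-i])) - sum(log(abs(d)))
    sgn[i] <- prod(sign(d))
  }
  # value(t) = sum_i sign_i exp(logw_i - lam_i t)
  logterms <- outer(t, lam, function(tt, ll) -ll * tt)
  logterms <- sweep(logterms, 2, logw, "+")
  terms <- exp(logterms)
  value <- as.numeric(terms %*% sgn)
  roundoff <- max(terms) * .Machine$double.eps
  if (roundoff > 1e-12 && all(is.finite(lam))) {
    res <- cpp_hypoexp_distinct_dd(lam, t)
    value <- res$value
    roundoff <- res$maxterm * 1e-31
  }
  list(value = value, roundoff = roundoff)
}

# Case 3: partial degeneracy (Erlang-like mixture with C_{i,k} coefficients).
hypoexp_pdf_degenerate <- function(lam, mult, t) {
  m <- length(lam)
  logpre <- sum(mult * log(lam))
  value <- numeric(length(t))
  maxterm <- 0
  for (i in seq_len(m)) {
    Ci <- c_coefficients(lam, mult, i)       # C_{i,0} .. C_{i,n_i-1}
    ni <- mult[i]
    for (k in seq_len(ni) - 1L) {
      p <- ni - k - 1L                        # power of t
      if (Ci[k + 1L] == 0) next
      lt <- logpre + log(abs(Ci[k + 1L])) - lfactorial(k) - lfactorial(p) +
        ifelse(t > 0, p * log(t), if (p == 0) 0 else -Inf) - lam[i] * t
      term <- sign(Ci[k + 1L]) * exp(lt)
      value <- value + term
      maxterm <- max(maxterm, max(abs(term)))
    }
  }
  list(value = value, roundoff = maxterm * .Machine$double.eps)
}

# C_{i,k} = d^k/ds^k prod_{j != i} (s + lambda_j)^(-n_j) at s = -lambda_i,
# for k = 0..n_i-1, via the logarithmic-derivative recursion.
c_coefficients <- function(lam, mult, i) {
  ni <- mult[i]
  d <- lam[-i] - lam[i]                       # s + lambda_j at s = -lambda_i
  nj <- mult[-i]
  f0 <- prod(d^(-nj))
  if (ni == 1L) return(f0)
  # derivatives of g = log f at s = -lambda_i:
  # g^(p) = sum_j (-n_j) (-1)^(p-1) (p-1)! / d_j^p
  gp <- vapply(seq_len(ni - 1L), function(p) {
    sum(-nj * (-1)^(p - 1) * factorial(p - 1) / d^p)
  }, numeric(1))
  f <- numeric(ni); f[1] <- f0
  for (k in seq_len(ni - 1L)) {
    acc <- 0
    for (p in 0:(k - 1L))
      acc <- acc + choose(k - 1L, p) * f[p + 1L] * gp[k - p]
    f[k + 1L] <- acc
  }
  f
}
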