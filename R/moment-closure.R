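#' Moment hierarchy of a polynomial pure-birth process
#'
#' For any function `f`, the master equation implies
#' \eqn{d\langle f(N) \rangle/dt = \langle (f(N+1) - f(N)) B(N) \rangle}.
#' With \eqn{f(N) = N^m} and a polynomial rate law this expands exactly into
#' a linear combination of moments: for the exponential model
#' (\eqn{B(N) = bN}) the hierarchy closes order by order, e.g.
#' \eqn{d\langle N \rangle/dt = b\langle N \rangle}, while for the logistic
#' model (\eqn{B(N) = b(N - N^2/K)}) each order pulls in the next one up:
#' \deqn{d\langle N \rangle/dt = b(\langle N \rangle - \langle N^2 \rangle/K),}
#' \deqn{d\langle N^2 \rangle/dt = b(\langle N \rangle +
#'   (2 - 1/K)\langle N^2 \rangle - (2/K)\langle N^3 \rangle).}
#' The non-polynomial families (Gompertz, Blumberg, Richards with non-integer
#' `beta`) have no such expansion and are rejected.
#'
#' `moment_ode_coefficients` returns the exact coefficients of
#' \eqn{d\langle N^m\rangle/dt} on \eqn{\langle N^1\rangle, \ldots,
#' \langle N^{m+p}\rangle} (where `p` is the degree excess of `B`);
#' `moment_rhs` evaluates the derivative given moment values.
#'
#' @param model A [growth_model()] of the exponential or logistic family.
#' @param m Moment order (positive integer).
#' @return For `moment_ode_coefficients`, a named numeric vector of
#'   coefficients on `m1`, `m2`, ...; for `moment_rhs`, the scalar
#'   \eqn{d\langle N^m \rangle/dt}.
#' @examples
#' moment_ode_coefficients(growth_model("logistic", K = 100), 2)
#' @export
moment_ode_coefficients <- function(model, m) {
  check_model(model)
  stopifnot(m >= 1, m == round(m))
  if (!model$family %in% c("exponential", "logistic"))
    stop("the moment hierarchy is polynomial only for the exponential and ",
         "logistic families; the ", model$family,
         " rate law has no exact moment expansion")
  b <- model$b
  # (N+1)^m - N^m = sum_{j=0}^{m-1} choose(m, j) N^j
  js <- 0:(m - 1)
  cs <- choose(m, js)
  deg <- if (model$family == "logistic") m + 1L else m
  coef <- numeric(deg)
  for (idx in seq_along(js)) {
    j <- js[idx]
    # N^j * B(N): exponential b N^(j+1); logistic b (N^(j+1) - N^(j+2)/K)
    coef[j + 1L] <- coef[j + 1L] + b * cs[idx]
    if (model$family == "logistic")
      coef[j + 2L] <- coef[j + 2L] - b * cs[idx] / model$K
  }
  names(coef) <- paste0("m", seq_len(deg))
  coef
}

#' @param moments Numeric vector of moment values
#'   \eqn{\langle N \rangle, \langle N^2 \rangle, \ldots} of length at least
#'   the order required by the expansion (`m` for exponential, `m + 1` for
#'   logistic).
#' @rdname moment_ode_coefficients
#' @export
moment_rhs <- function(model, m, moments) {
  coef <- moment_ode_coefficients(model, m)
  if (length(moments) < length(coef))
    stop("need moment values up to order ", length(coef))
  sum(coef * moments[seq_along(coef)])
}

#' Third-moment closure approximations
#'
#' Expresses \eqn{\langle N^3 \rangle} as a function of the first two moments
#' under a distributional assumption, truncating the moment hierarchy:
#'
#' | closure | \eqn{\langle N^3 \rangle} |
#' |---|---|
#' | `binomial` | \eqn{2\sigma^4/m_1 - \sigma^2 + 3 m_2 m_1 - 2 m_1^3} |
#' | `lognormal`, `sdm` | \eqn{m_2^3 / m_1^3} |
#' | `nasell_poisson` | \eqn{m_1 + 3 m_2 m_1 - 2 m_1^3} |
#' | `new_poisson` | \eqn{\sigma^2 + 3 m_2 m_1 - 2 m_1^3} |
#' | `normal` | \eqn{3 m_2 m_1 - 2 m_1^3} |
#'
#' with \eqn{\sigma^2 = m_2 - m_1^2} the variance (`sdm` is separable
#' derivative matching, identical to the lognormal closure). A point mass
#' (\eqn{m_2 = m_1^2}) yields exactly \eqn{m_1^3} under the normal closure.
#'
#' @param closure Closure name (see table).
#' @param m1,m2 First and second moments; `m1 > 0`.
#' @return The closed third moment.
#' @export
third_moment_closure <- function(closure = c("binomial", "lognormal", "sdm",
                                             "nasell_poisson", "new_poisson",
                                             "normal"),
                                 m1, m2) {
  closure <- match.arg(closure)
  stopifnot(all(m1 > 0))
  s2 <- m2 - m1^2
  switch(closure,
    binomial = 2 * s2^2 / m1 - s2 + 3 * m2 * m1 - 2 * m1^3,
    lognormal = ,
    sdm = m2^3 / m1^3,
    nasell_poisson = m1 + 3 * m2 * m1 - 2 * m1^3,
    new_poisson = s2 + 3 * m2 * m1 - 2 * m1^3,
    normal = 3 * m2 * m1 - 2 * m1^3)
}

#' Two-moment closure trajectory for logistic growth
#'
#' Integrates the first two moment equations of the logistic pure-birth
#' process,
#' \deqn{dm_1/dt = b(m_1 - m_2/K), \quad
#'       dm_2/dt = b(m_1 + (2 - 1/K) m_2 - (2/K)\,\widehat{m_3}(m_1, m_2)),}
#' from \eqn{(N_0, N_0^2)}, with the third moment closed by
#' [third_moment_closure()]. The special closure `"mean_field"` assumes a
#' point-mass distribution (\eqn{m_2 = m_1^2}), which collapses the system to
#' the deterministic logistic equation and reproduces its closed form.
#'
#' If a closure drives the variance negative (\eqn{m_2 < m_1^2}) the
#' integration continues, but the first violation time is recorded in the
#' `"validity_breach"` attribute of the result.
#'
#' @param model A logistic [growth_model()].
#' @param closure A [third_moment_closure()] name, or `"mean_field"`.
#' @param N0 Initial population size.
#' @param times Time grid.
#' @return A `moment_trajectory` with columns `m1`, `m2`.
#' @export
closure_trajectory <- function(model, closure, N0, times) {
  check_model(model)
  if (model$family != "logistic")
    stop("closure trajectories are defined for the logistic family only")
  stopifnot(N0 >= 1, all(times >= 0), !is.unsorted(times))
  K <- model$K; b <- model$b
  tgrid <- if (times[1] > 0) c(0, times) else times
  if (identical(closure, "mean_field")) {
    m1 <- deterministic_trajectory(model, N0, times)
    out <- new_moment_trajectory(times, cbind(m1 = m1, m2 = m1^2))
    attr(out, "validity_breach") <- NA_real_
    return(out)
  }
  rhs <- function(t, y, parms) {
    m3 <- third_moment_closure(closure, y[1], y[2])
    list(b * c(y[1] - y[2] / K,
               y[1] + (2 - 1 / K) * y[2] - (2 / K) * m3))
  }
  sol <- deSolve::ode(y = c(N0, N0^2), times = tgrid, func = rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  sol <- sol[match(times, tgrid), , drop = FALSE]
  vals <- cbind(m1 = sol[, 2], m2 = sol[, 3])
  out <- new_moment_trajectory(times, vals)
  breach <- which(vals[, "m2"] < vals[, "m1"]^2 - 1e-9)
  attr(out, "validity_breach") <-
    if (length(breach)) times[breach[1]] else NA_real_
  out
}
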