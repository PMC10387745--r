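#' Define a population growth model
#'
#' Constructs a growth model from the generalized-logistic family, in which a
#' population of size `N` gains individuals at total rate
#' \deqn{B(N) = b N^\alpha \left(1 - (N/K)^\beta\right)^\gamma,}
#' with `b` the intrinsic per-capita birth rate and `K` the carrying capacity.
#' Each named family fixes the exponents:
#'
#' * `exponential`: \eqn{B(N) = bN} (Malthusian growth, no density limit);
#' * `logistic`: \eqn{\alpha = \beta = \gamma = 1}, \eqn{B(N) = bN(1 - N/K)};
#' * `blumberg`: \eqn{\beta = 1}, free \eqn{\alpha} and \eqn{\gamma},
#'   \eqn{B(N) = bN^\alpha(1 - N/K)^\gamma};
#' * `richards`: \eqn{\alpha = \gamma = 1}, free \eqn{\beta},
#'   \eqn{B(N) = bN(1 - (N/K)^\beta)};
#' * `gompertz`: the \eqn{\beta \to 0} limit, \eqn{B(N) = bN \log(K/N)}.
#'
#' For all density-limited families \eqn{B(0) = B(K) = 0}: an empty population
#' cannot grow and no population grows beyond the carrying capacity. An
#' optional linear death term with per-capita rate `d` turns the pure-birth
#' process into a birth-death process.
#'
#' @param family One of `"exponential"`, `"logistic"`, `"blumberg"`,
#'   `"richards"`, `"gompertz"`.
#' @param b Intrinsic per-capita birth rate (1/time), positive. Defaults to 1,
#'   i.e. time measured in units of `1/b`.
#' @param K Carrying capacity (integer number of individuals, at least 2). For
#'   the exponential family `K` is not a carrying capacity; a finite value is
#'   interpreted by the stochastic solvers as a truncation size and may be
#'   `Inf` for purely deterministic use.
#' @param alpha,beta,gamma Exponents of the generalized-logistic rate law.
#'   Values inconsistent with the chosen family are an error; unset values
#'   take the family's defaults.
#' @param d Per-capita death rate (1/time), non-negative; default 0.
#'
#' @return An object of class `growth_model`.
#' @examples
#' m <- growth_model("logistic", K = 100)
#' birth_rate(m, 50)    # maximal rate at K/2
#' inflection_size(m)   # 50
#' @export
growth_model <- function(family = c("logistic", "exponential", "blumberg",
                                    "richards", "gompertz"),
                         b = 1, K = Inf, alpha = NULL, beta = NULL,
                         gamma = NULL, d = 0) {
  family <- match.arg(family)
  stopifnot(is.numeric(b), length(b) == 1L, b > 0,
            is.numeric(d), length(d) == 1L, d >= 0,
            is.numeric(K), length(K) == 1L)
  if (family != "exponential") {
    if (!is.finite(K) || K < 2 || K != round(K))
      stop("'K' must be a finite integer >= 2 for the ", family, " family")
    K <- as.integer(K)
  } else if (is.finite(K)) {
    if (K < 2 || K != round(K))
      stop("a finite truncation 'K' must be an integer >= 2")
    K <- as.integer(K)
  }
  fix <- function(given, fixed, name) {
    if (!is.null(given) && !isTRUE(all.equal(given, fixed)))
      stop(sprintf("the %s family requires %s = %g", family, name, fixed))
    fixed
  }
  exps <- switch(family,
    exponential = {
      alpha <- fix(alpha, 1, "alpha"); beta <- fix(beta, 0, "beta")
      gamma <- fix(gamma, 0, "gamma"); c(alpha, beta, gamma)
    },
    logistic = {
      alpha <- fix(alpha, 1, "alpha"); beta <- fix(beta, 1, "beta")
      gamma <- fix(gamma, 1, "gamma"); c(alpha, beta, gamma)
    },
    blumberg = {
      beta <- fix(beta, 1, "beta")
      if (is.null(alpha)) alpha <- 1
      if (is.null(gamma)) gamma <- 1
      if (alpha <= 0 || gamma <= 0) stop("'alpha' and 'gamma' must be > 0")
      c(alpha, beta, gamma)
    },
    richards = {
      alpha <- fix(alpha, 1, "alpha"); gamma <- fix(gamma, 1, "gamma")
      if (is.null(beta)) beta <- 1
      if (beta <= 0) stop("'beta' must be > 0")
      c(alpha, beta, gamma)
    },
    gompertz = {
      # beta -> 0 limit of the generalized law; store the marker beta = 0
      alpha <- fix(alpha, 1, "alpha"); beta <- fix(beta, 0, "beta")
      if (is.null(gamma)) gamma <- 1
      if (gamma <= 0) stop("'gamma' must be > 0")
      c(alpha, beta, gamma)
    })
  structure(list(family = family, b = b, K = K,
                 alpha = exps[1], beta = exps[2], gamma = exps[3], d = d),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  law <- switch(x$family,
    exponential = "B(N) = b N",
    logistic    = "B(N) = b N (1 - N/K)",
    blumberg    = sprintf("B(N) = b N^%g (1 - N/K)^%g", x$alpha, x$gamma),
    richards    = sprintf("B(N) = b N (1 - (N/K)^%g)", x$beta),
    gompertz    = "B(N) = b N log(K/N)")
  cat(sprintf("<growth_model> %s: %s\n", x$family, law))
  cat(sprintf("  b = %g, K = %s, d = %g\n", x$b,
              if (is.finite(x$K)) format(x$K) else "Inf", x$d))
  invisible(x)
}

is_growth_model <- function(x) inherits(x, "growth_model")

check_model <- function(model) {
  if (!is_growth_model(model)) stop("'model' must be a growth_model object")
  invisible(model)
}

#' Population birth rate B(N)
#'
#' Total birth rate of a population of size `N` under a growth model,
#' \eqn{B(N) = b N^\alpha (1 - (N/K)^\beta)^\gamma} (or \eqn{bN\log(K/N)} for
#' Gompertz). Vectorized over `N`.
#'
#' @param model A [growth_model()].
#' @param N Population size(s), `0 <= N <= K` for density-limited families.
#' @return Birth rate(s), 1/time.
#' @export
birth_rate <- function(model, N) {
  check_model(model)
  if (any(N < 0)) stop("'N' must be non-negative")
  if (model$family != "exponential" && any(N > model$K))
    stop("'N' exceeds the carrying capacity K")
  b <- model$b; K <- model$K
  switch(model$family,
    exponential = b * N,
    logistic = b * N * (1 - N / K),
    blumberg = b * N^model$alpha * (1 - N / K)^model$gamma,
    richards = b * N * (1 - (N / K)^model$beta),
    gompertz = ifelse(N == 0, 0, b * N * log(K / N)))  # N log(K/N) -> 0
}

#' Per-capita density factor g(N) = B(N) / (b N)
#'
#' The dimensionless density-dependence factor shared by all individuals, so
#' that an individual reproduces at rate `b * g(N)`. Used by the two-strain
#' community extension, where each strain keeps its own `b` but both feel the
#' same crowding through `g`.
#'
#' @inheritParams birth_rate
#' @return `g(N)` for `1 <= N <= K`.
#' @export
per_capita_factor <- function(model, N) {
  check_model(model)
  if (any(N < 1)) stop("'N' must be >= 1")
  birth_rate(model, N) / (model$b * N)
}

#' Population size at the inflection point
#'
#' The size `N*` at which the birth rate `B(N)` is maximal, equivalently where
#' the deterministic sigmoid changes concavity:
#' \eqn{N^* = K (1 + \beta\gamma/\alpha)^{-1/\beta}}, with the Gompertz limit
#' \eqn{\beta \to 0} giving \eqn{K e^{-\gamma}}.
#'
#' @inheritParams birth_rate
#' @return The (real-valued) inflection size.
#' @export
inflection_size <- function(model) {
  check_model(model)
  if (model$family == "exponential")
    stop("the exponential family has no inflection point")
  K <- model$K
  if (model$family == "gompertz") return(K * exp(-model$gamma))
  K * (1 + model$beta * model$gamma / model$alpha)^(-1 / model$beta)
}

#' Deterministic growth trajectory
#'
#' Solves \eqn{dN/dt = B(N)} from `N0`. Closed forms are used where they
#' exist:
#' \deqn{N_L(t) = K / (1 + (K/N_0 - 1) e^{-bt})}
#' \deqn{N_R(t) = K / (1 + ((K/N_0)^\beta - 1) e^{-\beta b t})^{1/\beta}}
#' \deqn{N_G(t) = K (N_0/K)^{e^{-bt}}}
#' for the logistic, Richards, and Gompertz families, and \eqn{N_0 e^{bt}} for
#' exponential growth. The Blumberg model has no closed form and is integrated
#' with an adaptive scheme (relative tolerance 1e-10, absolute 1e-12).
#'
#' @inheritParams birth_rate
#' @param N0 Initial population size, `1 <= N0 <= K`.
#' @param times Non-decreasing, non-negative time grid.
#' @return Numeric vector of population sizes along `times`.
#' @export
deterministic_trajectory <- function(model, N0, times) {
  check_model(model)
  stopifnot(N0 >= 1, is.infinite(model$K) || N0 <= model$K,
            all(times >= 0), !is.unsorted(times))
  b <- model$b; K <- model$K
  switch(model$family,
    exponential = N0 * exp(b * times),
    logistic = K / (1 + (K / N0 - 1) * exp(-b * times)),
    richards = {
      beta <- model$beta
      K / (1 + ((K / N0)^beta - 1) * exp(-beta * b * times))^(1 / beta)
    },
    gompertz = K * (N0 / K)^exp(-b * times),
    blumberg = ode_trajectory(model, N0, times))
}

ode_trajectory <- function(model, N0, times, d = 0) {
  tgrid <- if (times[1] > 0) c(0, times) else times
  rhs <- function(t, y, parms) {
    N <- min(max(y, 0), if (is.finite(model$K)) model$K else y)
    list(birth_rate(model, N) - d * N)
  }
  out <- deSolve::ode(y = c(N = N0), times = tgrid, func = rhs, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  unname(out[match(times, tgrid), "N"])
}

#' Deterministic birth-death trajectory
#'
#' Solves \eqn{dN/dt = B(N) - dN}, the mean-field limit of the birth-death
#' jump process. Reduces to [deterministic_trajectory()] when `d = 0`.
#'
#' @inheritParams deterministic_trajectory
#' @return Numeric vector of population sizes along `times`.
#' @export
deterministic_bd_trajectory <- function(model, N0, times) {
  check_model(model)
  stopifnot(N0 >= 0, all(times >= 0), !is.unsorted(times))
  ode_trajectory(model, N0, times, d = model$d)
}

#' Rapid-extinction probability of a birth-death process
#'
#' Probability that demographic stochasticity drives the population extinct
#' during the early, density-independent phase of growth (population size
#' small compared to `K`). From the linear birth-death process this is
#' \eqn{p_0 = (d/b)^{N_0}}; for the Gompertz model the initial per-capita
#' birth rate is density dependent, \eqn{b \log(K/N_0)}, giving
#' \eqn{p_0 = (d / (b \log(K/N_0)))^{N_0}}. If the death rate is at least the
#' initial per-capita birth rate the process is not supercritical and
#' extinction is certain.
#'
#' @inheritParams deterministic_trajectory
#' @return A probability.
#' @export
rapid_extinction_probability <- function(model, N0) {
  check_model(model)
  stopifnot(N0 >= 1)
  if (model$d == 0) return(0)
  b_eff <- if (model$family == "gompertz") model$b * log(model$K / N0) else model$b
  if (model$d >= b_eff) return(1)
  (model$d / b_eff)^N0
}

#' Serialize a growth model to a flat YAML block
#'
#' @param model A [growth_model()].
#' @param path Optional file path; if `NULL` the YAML text is returned.
#' @return `path` invisibly, or the YAML string.
#' @export
growth_model_to_yaml <- function(model, path = NULL) {
  check_model(model)
  lst <- unclass(model)
  lst$K <- if (is.finite(lst$K)) lst$K else ".inf"
  txt <- yaml::as.yaml(lst)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a growth model from a YAML block
#'
#' @param x A file path or a YAML string as produced by
#'   [growth_model_to_yaml()].
#' @return A [growth_model()].
#' @export
growth_model_from_yaml <- function(x) {
  lst <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  K <- if (identical(lst$K, ".inf") || is.null(lst$K)) Inf else lst$K
  null_if_na <- function(v) if (is.null(v)) NULL else v
  growth_model(family = lst$family, b = lst$b %||% 1, K = K,
               alpha = null_if_na(lst$alpha), beta = null_if_na(lst$beta),
               gamma = null_if_na(lst$gamma), d = lst$d %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
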