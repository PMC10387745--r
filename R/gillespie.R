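# Seeded exact stochastic simulation (Gillespie) of the growth processes.
# All simulators share one convention: a non-NULL `seed` makes the call
# bit-reproducible and leaves the caller's RNG state untouched.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

new_trajectory <- function(jump_times, sizes, N0, seed,
                           mutants = NULL, n0 = NULL) {
  structure(list(jump_times = jump_times, sizes = sizes, N0 = N0,
                 mutants = mutants, n0 = n0, seed = seed),
            class = "gillespie_trajectory")
}

#' @export
print.gillespie_trajectory <- function(x, ...) {
  cat(sprintf("<gillespie_trajectory> %d jumps, N: %d -> %d%s\n",
              length(x$jump_times), x$N0,
              if (length(x$sizes)) x$sizes[length(x$sizes)] else x$N0,
              if (!is.null(x$mutants))
                sprintf(" (mutants: %d -> %d)", x$n0,
                        if (length(x$mutants)) x$mutants[length(x$mutants)]
                        else x$n0)
              else ""))
  invisible(x)
}

# piecewise-constant state at arbitrary times
trajectory_at <- function(traj, times, what = "sizes") {
  vals <- c(if (what == "sizes") traj$N0 else traj$n0, traj[[what]])
  vals[findInterval(times, c(0, traj$jump_times))]
}

#' Simulate one pure-birth trajectory
#'
#' Exact (Gillespie) simulation of the pure-birth process with rates
#' \eqn{B(N)}: the waiting time in state `N` is exponential with rate `B(N)`,
#' and the trajectory ends at absorption (`N = K`) or at `t_max`.
#'
#' @param model A [growth_model()] with `d = 0`, `alpha = 1`. For the
#'   exponential family a finite `K` acts as a simulation cap.
#' @param N0 Initial size, `1 <= N0 <= K`.
#' @param t_max Simulation horizon.
#' @param seed Optional integer seed; identical seeds give identical
#'   trajectories.
#' @return A `gillespie_trajectory` with `jump_times` and the `sizes`
#'   reached after each jump.
#' @export
simulate_pure_birth <- function(model, N0, t_max, seed = NULL) {
  check_model(model)
  check_stochastic(model)
  K <- sim_cap(model)
  stopifnot(N0 >= 1, N0 <= K)
  B <- if (N0 == K) numeric(0) else birth_rate_capped(model, N0:(K - 1))
  jumps <- with_seed(seed, cpp_pure_birth_jumps(B, t_max))
  new_trajectory(jumps, N0 + seq_along(jumps), N0 = N0, seed = seed)
}

sim_cap <- function(model) {
  if (is.finite(model$K)) return(model$K)
  1000000L  # safety cap for unbounded exponential growth
}

birth_rate_capped <- function(model, N) {
  if (model$family == "exponential") model$b * N else birth_rate(model, N)
}

#' Simulate one birth-death trajectory
#'
#' Births occur at total rate \eqn{B(N)} and deaths at rate \eqn{dN}; size 0
#' is absorbing (extinction). At `N = K` the birth rate of a density-limited
#' model vanishes but deaths still occur, so `K` is not absorbing when
#' `d > 0`.
#'
#' @inheritParams simulate_pure_birth
#' @param model A [growth_model()] with `alpha = 1` and any `d >= 0`.
#' @return A `gillespie_trajectory`.
#' @export
simulate_birth_death <- function(model, N0, t_max, seed = NULL) {
  check_model(model)
  if (model$alpha != 1) stop("stochastic simulation requires alpha = 1")
  K <- sim_cap(model)
  stopifnot(N0 >= 0, N0 <= K)
  B <- birth_rate_capped(model, 0:K)
  if (model$family == "exponential") B[K + 1L] <- 0
  res <- with_seed(seed, cpp_birth_death_traj(B, model$d, N0, t_max))
  new_trajectory(res$times, res$sizes, N0 = N0, seed = seed)
}

#' Simulate one two-strain community trajectory
#'
#' Wild-type and mutant individuals reproduce at rates
#' \eqn{b_W g(N) (N - n)} and \eqn{b_M g(N) n}, sharing the density factor
#' \eqn{g(N)} of the growth family. Given that a birth occurs, it is a mutant
#' birth with probability \eqn{\Gamma(N, n) = r n / ((r-1) n + N)}, where
#' \eqn{r = b_M/b_W}.
#'
#' @inheritParams simulate_pure_birth
#' @param b_w,b_m Intrinsic birth rates of the wild-type and mutant strains.
#' @param n0 Initial number of mutants, `0 <= n0 <= N0`.
#' @return A `gillespie_trajectory` with a `mutants` component.
#' @export
simulate_community <- function(model, b_w, b_m, N0, n0, t_max, seed = NULL) {
  check_model(model)
  check_stochastic(model)
  K <- model$K
  stopifnot(is.finite(K), N0 >= 1, N0 <= K, n0 >= 0, n0 <= N0,
            b_w > 0, b_m > 0)
  g <- density_factor_vector(model)
  res <- with_seed(seed, cpp_community_traj(g, b_w, b_m, N0, n0, t_max))
  new_trajectory(res$times, res$sizes, N0 = N0, seed = seed,
                 mutants = res$mutants, n0 = n0)
}

density_factor_vector <- function(model) {
  # g(N) for N = 0..K (g(0) unused; set 0)
  c(0, per_capita_factor(model, 1:model$K))
}

#' Simulate a serial-passage experiment to fixation or loss
#'
#' Alternates community growth for a time `tau` with a bottleneck that
#' binomially resamples `N0 = D * K` individuals (sampling with replacement,
#' success probability `n/N`), until the mutant strain fixes (`n = N0`) or is
#' lost (`n = 0`).
#'
#' @inheritParams simulate_community
#' @param dilution Dilution ratio `D = N0 / K`; `D * K` must be a whole
#'   number at least 2.
#' @param tau Growth time between bottlenecks.
#' @param max_cycles Safety bound on the number of growth-dilution cycles.
#' @return A list with `fixed` (logical) and `cycles` (bottlenecks applied
#'   before absorption).
#' @export
simulate_serial_passage <- function(model, b_w, b_m, dilution, tau, n0,
                                    seed = NULL, max_cycles = 100000L) {
  res <- serial_passage_ensemble(model, b_w, b_m, dilution, tau, n0,
                                 reps = 1L, seed = seed,
                                 max_cycles = max_cycles)
  list(fixed = res$fixed[1], cycles = res$cycles[1])
}

#' Ensembles of replicate simulations
#'
#' Vectorized replicate simulation on a common time grid, for comparing
#' ensemble statistics with the exact solutions. All replicates are drawn
#' sequentially from the stream determined by `seed`.
#'
#' @inheritParams simulate_community
#' @param times Sorted grid at which the piecewise-constant state is read.
#' @param reps Number of replicates.
#' @return `pure_birth_ensemble` and `birth_death_ensemble` return an
#'   integer matrix `reps x length(times)` of sizes (`birth_death_ensemble`
#'   additionally carries an `"extinct"` attribute flagging absorption at 0
#'   within the horizon); `community_ensemble` returns a list of matrices
#'   `sizes` and `mutants`; `serial_passage_ensemble` returns a list with
#'   logical `fixed` and integer `cycles`.
#' @export
pure_birth_ensemble <- function(model, N0, times, reps, seed = NULL) {
  check_model(model)
  check_stochastic(model)
  K <- sim_cap(model)
  stopifnot(N0 >= 1, N0 <= K, !is.unsorted(times), reps >= 1)
  B <- if (N0 == K) numeric(0) else birth_rate_capped(model, N0:(K - 1))
  counts <- with_seed(seed, cpp_pure_birth_ensemble(B, times, as.integer(reps)))
  counts + N0
}

#' @rdname pure_birth_ensemble
#' @export
birth_death_ensemble <- function(model, N0, times, reps, seed = NULL) {
  check_model(model)
  if (model$alpha != 1) stop("stochastic simulation requires alpha = 1")
  K <- sim_cap(model)
  stopifnot(N0 >= 0, N0 <= K, !is.unsorted(times), reps >= 1)
  B <- birth_rate_capped(model, 0:K)
  if (model$family == "exponential") B[K + 1L] <- 0
  res <- with_seed(seed,
                   cpp_birth_death_ensemble(B, model$d, N0, times,
                                            as.integer(reps)))
  structure(res$sizes, extinct = res$extinct)
}

#' @rdname pure_birth_ensemble
#' @export
community_ensemble <- function(model, b_w, b_m, N0, n0, times, reps,
                               seed = NULL) {
  check_model(model)
  check_stochastic(model)
  stopifnot(is.finite(model$K), N0 >= 1, N0 <= model$K, n0 >= 0, n0 <= N0,
            !is.unsorted(times), reps >= 1)
  g <- density_factor_vector(model)
  with_seed(seed, cpp_community_ensemble(g, b_w, b_m, N0, n0, times,
                                         as.integer(reps)))
}

#' @rdname pure_birth_ensemble
#' @inheritParams simulate_serial_passage
#' @export
serial_passage_ensemble <- function(model, b_w, b_m, dilution, tau, n0, reps,
                                    seed = NULL, max_cycles = 100000L) {
  check_model(model)
  check_stochastic(model)
  K <- model$K
  stopifnot(is.finite(K), b_w > 0, b_m > 0, tau > 0)
  N0 <- dilution * K
  if (abs(N0 - round(N0)) > 1e-9 || round(N0) < 2)
    stop("'dilution' must give an integer post-bottleneck size D * K >= 2")
  N0 <- as.integer(round(N0))
  stopifnot(n0 >= 0, n0 <= N0)
  g <- density_factor_vector(model)
  raw <- with_seed(seed, cpp_serial_passage(g, b_w, b_m, N0, as.integer(n0),
                                            tau, as.integer(reps),
                                            as.integer(max_cycles)))
  if (anyNA(raw))
    warning(sum(is.na(raw)), " replicate(s) hit max_cycles before absorption")
  list(fixed = raw > 0, cycles = abs(raw) - 1L)
}

#' Ensemble mean trajectory with standard errors
#'
#' Averages replicate trajectories at the given grid times (piecewise-
#' constant interpolation for trajectory lists) and reports the per-time mean
#' and standard error of the mean.
#'
#' @param x A `reps x times` matrix as returned by the ensemble simulators,
#'   or a list of `gillespie_trajectory` objects.
#' @param times Time grid. Required for trajectory lists; for matrices it is
#'   only used to label the output.
#' @return A data frame with columns `time`, `mean`, `se`.
#' @export
ensemble_mean <- function(x, times) {
  if (is.list(x) && !is.matrix(x)) {
    stopifnot(all(vapply(x, inherits, logical(1), "gillespie_trajectory")))
    x <- do.call(rbind, lapply(x, trajectory_at, times = times))
  }
  stopifnot(is.matrix(x), ncol(x) == length(times))
  mean_ <- colMeans(x)
  se <- if (nrow(x) == 1L) rep(0, ncol(x))
        else apply(x, 2, stats::sd) / sqrt(nrow(x))
  data.frame(time = times, mean = mean_, se = se)
}
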