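test_that("fixed seeds make every simulator bit-reproducible", {
  m <- growth_model("logistic", K = 50)
  expect_identical(simulate_pure_birth(m, 1, 10, seed = 7),
                   simulate_pure_birth(m, 1, 10, seed = 7))
  md <- growth_model("logistic", K = 50, d = 0.3)
  expect_identical(simulate_birth_death(md, 5, 10, seed = 7),
                   simulate_birth_death(md, 5, 10, seed = 7))
  expect_identical(simulate_community(m, 1, 1.2, 2, 1, 5, seed = 7),
                   simulate_community(m, 1, 1.2, 2, 1, 5, seed = 7))
  expect_identical(
    serial_passage_ensemble(m, 1, 1.1, 0.04, 2, 1, 50, seed = 7),
    serial_passage_ensemble(m, 1, 1.1, 0.04, 2, 1, 50, seed = 7))
  # simulators restore the caller's RNG state
  set.seed(99); before <- .Random.seed
  invisible(simulate_pure_birth(m, 1, 5, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("pure-birth trajectories climb one individual at a time to K", {
  m <- growth_model("logistic", K = 20)
  tr <- simulate_pure_birth(m, 1, 1e6, seed = 2)
  expect_equal(tr$sizes, 2:20)                    # +1 per jump, absorbed at K
  expect_true(all(diff(tr$jump_times) > 0))
  # absorbing start: no jumps at all
  expect_length(simulate_pure_birth(m, 20, 10, seed = 1)$jump_times, 0)
})

test_that("ensemble means match the exact solution (exponential and logistic)", {
  e <- growth_model("exponential", K = 500)
  sizes <- pure_birth_ensemble(e, 1, c(0, 1), 10000, seed = 5)
  em <- ensemble_mean(sizes, c(0, 1))
  expect_lt(abs(em$mean[2] - exp(1)), 3 * em$se[2])
  m <- growth_model("logistic", K = 50)
  tms <- seq(0, 10, 1)
  em2 <- ensemble_mean(pure_birth_ensemble(m, 1, tms, 10000, seed = 6), tms)
  exact <- distribution_moments(exact_distribution(m, 1, tms), 1)$values[, 1]
  expect_true(all(abs(em2$mean - exact) <= 3 * pmax(em2$se, 1e-12)))
})

test_that("simulated size histogram agrees with the exact distribution", {
  m <- growth_model("logistic", K = 30)
  tm <- 3
  sizes <- pure_birth_ensemble(m, 1, c(0, tm), 10000, seed = 8)[, 2]
  p <- exact_distribution(m, 1, tm)$probs[1, ]
  obs <- tabulate(sizes, nbins = 30)
  keep <- p * 10000 >= 5
  chi <- sum((obs[keep] - 10000 * p[keep])^2 / (10000 * p[keep]))
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("birth-death dynamics: absorbing zero, extinction frequency, d = 0 law", {
  md <- growth_model("logistic", K = 30, d = 0.4)
  expect_length(simulate_birth_death(md, 0, 10, seed = 1)$jump_times, 0)
  # d = 0 reduces to the pure-birth law (distributional check on the mean)
  m0 <- growth_model("logistic", K = 30)
  tms <- c(0, 2, 5)
  bd <- birth_death_ensemble(m0, 1, tms, 5000, seed = 9)
  em <- ensemble_mean(bd, tms)
  exact <- distribution_moments(exact_distribution(m0, 1, tms), 1)$values[, 1]
  expect_true(all(abs(em$mean - exact) <= 3.5 * pmax(em$se, 1e-12)))
  # linear birth-death: extinction by t = 20 is essentially d/b
  lin <- growth_model("exponential", K = 300, d = 0.5)
  bd2 <- birth_death_ensemble(lin, 1, c(0, 20), 10000, seed = 10)
  freq <- mean(attr(bd2, "extinct"))
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("density dependence raises early extinction above the linear law", {
  # at K comparable to the quasi-equilibrium, crowding depresses per-capita
  # births and the rapid-extinction formula (d/b)^N0 underestimates the true
  # transient extinction probability, here computed exactly
  K <- 60; d <- 0.5
  Bv <- c(0, 1 * (1:K) * (1 - (1:K) / K))
  Dv <- d * (0:K)
  rhs <- function(t, p, parms) {
    gain_b <- c(0, Bv[1:K] * p[1:K])
    gain_d <- c(Dv[2:(K + 1)] * p[2:(K + 1)], 0)
    list(gain_b + gain_d - (Bv + Dv) * p)
  }
  p0 <- c(0, 1, rep(0, K - 1))
  sol <- deSolve::ode(p0, c(0, 50), rhs, NULL, rtol = 1e-10, atol = 1e-12)
  p_ext_exact <- sol[2, 2]
  expect_gt(p_ext_exact, 0.5)          # above (d/b)^N0
  expect_lt(p_ext_exact, 0.55)
  mk <- growth_model("logistic", K = K, d = d)
  bd <- birth_death_ensemble(mk, 1, c(0, 50), 4000, seed = 12)
  freq <- mean(attr(bd, "extinct"))
  expect_lt(abs(freq - p_ext_exact), 3 * sqrt(p_ext_exact * 0.5 / 4000))
})

test_that("community simulation respects strain structure", {
  m <- growth_model("logistic", K = 40)
  tr <- simulate_community(m, 1, 1.5, 5, 0, 20, seed = 3)
  expect_true(all(tr$mutants == 0))               # no mutants ever appear
  tr2 <- simulate_community(m, 1, 1.5, 5, 2, 20, seed = 4)
  expect_true(all(diff(tr2$sizes) == 1))
  expect_true(all(tr2$mutants <= tr2$sizes))
  expect_true(all(diff(tr2$mutants) %in% c(0L, 1L)))
})

test_that("neutral serial passage fixes half the time from half the bottleneck", {
  m <- growth_model("logistic", K = 100)
  res <- serial_passage_ensemble(m, 1, 1, 0.04, 3, 2, reps = 4000, seed = 21)
  expect_lt(abs(mean(res$fixed) - 0.5), 3 * sqrt(0.25 / 4000))
  # absorbing starts
  expect_false(simulate_serial_passage(m, 1, 1.1, 0.04, 3, 0, seed = 1)$fixed)
  expect_true(simulate_serial_passage(m, 1, 1.1, 0.04, 3, 4, seed = 1)$fixed)
})

test_that("ensemble_mean interpolates piecewise-constant trajectories", {
  tr <- structure(list(jump_times = c(1, 2), sizes = c(3L, 4L), N0 = 2L,
                       mutants = NULL, n0 = NULL, seed = NULL),
                  class = "gillespie_trajectory")
  em <- ensemble_mean(list(tr), times = c(0, 0.5, 1.5, 3))
  expect_equal(em$mean, c(2, 2, 3, 4))
  expect_equal(em$se, rep(0, 4))
  em2 <- ensemble_mean(list(tr, tr), times = c(0, 3))
  expect_equal(em2$mean, c(2, 4))
})
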