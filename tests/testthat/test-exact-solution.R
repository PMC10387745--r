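grid <- seq(0, 12, 0.25)

test_that("distributions start as a point mass and stay normalized", {
  for (fam in bounded_families) {
    for (K in c(10, 30)) {
      d <- exact_distribution(family_model(fam, K), 1, grid)
      expect_equal(unname(d$probs[1, ]), c(1, rep(0, K - 1)))
      expect_lt(max(abs(rowSums(d$probs) - 1)), 1e-9)
      expect_true(all(d$probs >= 0 & d$probs <= 1))
      # absorbing mass is non-decreasing
      expect_true(all(diff(d$probs[, K]) >= -1e-12))
    }
  }
})

test_that("the three solution routes agree to 1e-6 (small K, all families)", {
  for (fam in bounded_families) {
    for (K in c(10, 20, 30)) {
      m <- family_model(fam, K)
      ex <- exact_distribution(m, 1, grid)
      or <- master_equation_oracle(m, 1, grid)
      expect_lt(max(abs(ex$probs - or$probs)), 1e-6,
                label = sprintf("%s K=%d exact vs oracle", fam, K))
      distinct <- rate_sequence(m, 1)$groups$case == 2L
      if (distinct) {
        sp <- spectral_distribution(m, 1, grid)
        expect_lt(max(abs(sp$probs - or$probs)), 1e-6,
                  label = sprintf("%s K=%d spectral vs oracle", fam, K))
      }
    }
  }
})

test_that("the spectral route refuses degenerate rates, naming states", {
  err <- expect_error(
    spectral_distribution(growth_model("logistic", K = 100), 1, c(0, 1)),
    "degenerate")
  expect_match(conditionMessage(err), "states")
  # gompertz has the exact coincidence B(K/4) = B(K/2) when 4 divides K
  expect_error(spectral_distribution(growth_model("gompertz", K = 20),
                                     1, c(0, 1)), "degenerate")
})

test_that("the exponential model reproduces the Yule distribution", {
  m <- growth_model("exponential", K = 50)
  tms <- c(log(2), 1, 2)
  for (method in c("hypoexp", "uniformization", "ode")) {
    d <- exact_distribution(m, 1, tms, method = method)
    yule <- sapply(1:49, function(N) exp(-tms) * (1 - exp(-tms))^(N - 1))
    expect_lt(max(abs(d$probs[, 1:49] - yule)), 1e-8)
  }
  # P_{1,2} at e^-t = 1/2 is exactly 1/4
  d2 <- exact_distribution(m, 1, log(2))
  expect_equal(d2$probs[1, 2], 0.25)
})

test_that("constant-rate chains give Poisson occupation probabilities", {
  lambda <- 1.7
  d <- birth_chain_distribution(rep(lambda, 20), c(0.5, 2, 5), N0 = 3)
  for (i in seq_len(3)) {
    pois <- stats::dpois(0:18, lambda * c(0.5, 2, 5)[i])
    expect_equal(unname(d$probs[i, 1:19]), pois, tolerance = 1e-9)
  }
})

test_that("P_N * B_N is the hitting-time density of size N + 1", {
  # numerical differentiation of the hitting-time CDF from the ODE oracle
  m <- family_model("gompertz", 25)
  h <- 1e-4
  for (tm in c(1, 3)) {
    o <- master_equation_oracle(m, 1, c(tm - h, tm, tm + h))
    for (N in c(3, 10, 20)) {
      cdf <- rowSums(o$probs[, (N + 1):25, drop = FALSE])  # P(size > N)
      dens_fd <- (cdf[3] - cdf[1]) / (2 * h)
      dens <- birth_rate(m, N) * o$probs[2, N]
      expect_equal(dens, dens_fd, tolerance = 1e-5)
    }
  }
})

test_that("moments obey their defining identities", {
  d0 <- birth_chain_distribution(c(1, 2), 0, N0 = 4)   # t = 0: point mass
  mom0 <- distribution_moments(d0, 1:3)
  expect_equal(unname(mom0$values[1, ]), c(4, 16, 64))
  # exponential model: <N>(t) = e^t
  tms <- seq(0, 1, 0.1)
  dy <- exact_distribution(growth_model("exponential", K = 60), 1, tms)
  expect_equal(distribution_moments(dy, 1)$values[, 1], exp(tms),
               tolerance = 1e-8)
  # d<N>/dt = <B(N)> on the grid (central finite differences)
  m <- family_model("richards", 30)
  tf <- seq(0, 8, 0.01)
  dd <- exact_distribution(m, 1, tf)
  mean_t <- distribution_moments(dd, 1)$values[, 1]
  rhs <- as.numeric(dd$probs %*% birth_rate(m, 1:30))
  fd <- (mean_t[-(1:2)] - mean_t[1:(length(tf) - 2)]) / (2 * 0.01)
  expect_lt(max(abs(fd - rhs[-c(1, length(tf))])), 5e-3)
  # variance is non-negative
  mom <- distribution_moments(dd, 1:2)
  expect_true(all(mom$values[, 2] - mom$values[, 1]^2 >= -1e-9))
})

test_that("the deterministic curve bounds the exact mean from above", {
  # at the default study conditions (K = 100, N0 = 1) the mean-field curve
  # overestimates the exact mean throughout the growth window
  tms <- seq(0, 15, 0.25)
  for (fam in bounded_families) {
    m <- family_model(fam, 100)
    mean_t <- distribution_moments(exact_distribution(m, 1, tms), 1)$values[, 1]
    det <- deterministic_trajectory(m, 1, tms)
    expect_true(all(det - mean_t >= -1e-8), label = fam)
  }
})

test_that("relative error is elementwise and guards the denominator", {
  expect_equal(relative_error(c(1, 1.3), c(1, 1)), c(0, 0.3))
  expect_error(relative_error(1, 0), "positive")
  expect_error(relative_error(c(1, 2), 1), "length")
})

test_that("absorbing-state mass converges to one at long times", {
  d <- exact_distribution(growth_model("logistic", K = 100), 1, c(0, 60))
  expect_gt(d$probs[2, 100], 1 - 1e-6)
})
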