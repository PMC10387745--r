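test_that("birth rates follow the family rate laws", {
  m <- growth_model("logistic", K = 100)
  expect_equal(birth_rate(m, 50), 25)                 # symmetric midpoint
  g <- growth_model("gompertz", K = 100)
  expect_equal(birth_rate(g, 10), 10 * log(10))
  expect_equal(birth_rate(growth_model("exponential"), 7), 7)
  r <- growth_model("richards", K = 100, beta = 2)
  expect_equal(birth_rate(r, 50), 50 * (1 - 0.25))
  bl <- growth_model("blumberg", K = 100, gamma = 1.5)
  expect_equal(birth_rate(bl, 50), 50 * 0.5^1.5)
})

test_that("density-limited rates vanish at N = 0 and N = K", {
  for (fam in bounded_families) {
    m <- family_model(fam, K = 100)
    expect_identical(birth_rate(m, 0), 0)
    expect_identical(birth_rate(m, 100), 0)
    expect_true(all(birth_rate(m, 1:99) > 0))
  }
  expect_error(birth_rate(family_model("logistic", 100), 101), "capacity")
})

test_that("per-capita factor is strictly decreasing on (0, K)", {
  for (fam in bounded_families) {
    g <- per_capita_factor(family_model(fam, 100), 1:99)
    expect_true(all(diff(g) < 0), label = fam)
  }
})

test_that("family exponent constraints are enforced", {
  expect_error(growth_model("logistic", K = 50, beta = 2), "beta")
  expect_error(growth_model("richards", K = 50, alpha = 2), "alpha")
  expect_error(growth_model("gompertz", K = 50, beta = 1), "beta")
  expect_error(growth_model("exponential", gamma = 2), "gamma")
  expect_error(growth_model("logistic", K = Inf), "finite")
  # Blumberg admits free alpha and gamma
  expect_s3_class(growth_model("blumberg", K = 50, alpha = 2, gamma = 0.5),
                  "growth_model")
})

test_that("inflection sizes match the closed form and maximize B", {
  expect_equal(inflection_size(growth_model("logistic", K = 100)), 50)
  expect_equal(inflection_size(growth_model("richards", K = 100, beta = 2)),
               100 * 3^(-1 / 2))
  expect_equal(inflection_size(growth_model("blumberg", K = 100, gamma = 1.5)),
               40)
  expect_equal(inflection_size(growth_model("gompertz", K = 100)),
               100 * exp(-1))
  expect_error(inflection_size(growth_model("exponential")), "inflection")
  # discrete consistency: the best integer neighbour of N* maximizes B
  for (fam in bounded_families) {
    m <- family_model(fam, 100)
    ns <- inflection_size(m)
    bmax <- max(birth_rate(m, 0:100))
    expect_gte(max(birth_rate(m, floor(ns)), birth_rate(m, ceiling(ns))),
               bmax - 1e-12)
  }
})

test_that("deterministic trajectories honour closed forms and limits", {
  times <- seq(0, 25, 0.25)
  for (fam in bounded_families) {
    m <- family_model(fam, 100)
    tr <- deterministic_trajectory(m, 1, times)
    expect_equal(tr[1], 1)
    expect_true(all(diff(tr) >= -1e-9))
    expect_true(all(tr <= 100 + 1e-9))
    expect_equal(tr[length(tr)], 100, tolerance = 1e-2)  # t -> infinity: K
    # (Blumberg approaches K algebraically, so the window limit is loose)
  }
  g <- growth_model("gompertz", K = 100)
  expect_equal(deterministic_trajectory(g, 1, log(2)), 10)  # 100 * 0.01^0.5
  e <- growth_model("exponential")
  expect_equal(deterministic_trajectory(e, 2, 1), 2 * exp(1))
})

test_that("Richards with beta = 1 is exactly logistic; Blumberg gamma = 1 agrees", {
  times <- seq(0, 12, 0.1)
  l <- deterministic_trajectory(growth_model("logistic", K = 80), 3, times)
  r <- deterministic_trajectory(growth_model("richards", K = 80, beta = 1),
                                3, times)
  expect_identical(r, l)
  b <- deterministic_trajectory(growth_model("blumberg", K = 80, gamma = 1),
                                3, times)
  expect_equal(b, l, tolerance = 1e-8)
})

test_that("birth-death trajectory reduces, equilibrates, and saturates", {
  times <- seq(0, 10, 0.5)
  m <- family_model("richards", 100)
  expect_equal(deterministic_bd_trajectory(m, 1, times),
               deterministic_trajectory(m, 1, times), tolerance = 1e-8)
  # logistic fixed point: b(1 - N/K) = d at N = K(1 - d/b)
  md <- growth_model("logistic", K = 100, d = 0.1)
  eq <- deterministic_bd_trajectory(md, 90, times)
  expect_equal(eq, rep(90, length(times)), tolerance = 1e-7)
  lt <- deterministic_bd_trajectory(md, 1, seq(0, 200, 50))
  expect_equal(lt[length(lt)], 90, tolerance = 1e-5)
})

test_that("rapid-extinction probability follows the supercritical branching law", {
  expect_identical(rapid_extinction_probability(growth_model("logistic",
                                                             K = 100), 1), 0)
  m <- growth_model("logistic", K = 100, d = 0.5)
  expect_equal(rapid_extinction_probability(m, 1), 0.5)
  expect_equal(rapid_extinction_probability(m, 3), 0.125)
  g <- growth_model("gompertz", K = 100, d = 0.5)
  expect_equal(rapid_extinction_probability(g, 1), 0.5 / log(100))
  sub <- growth_model("logistic", K = 100, d = 2)
  expect_identical(rapid_extinction_probability(sub, 5), 1)
})

test_that("models round-trip through YAML", {
  m <- growth_model("blumberg", b = 0.7, K = 42, alpha = 1.2, gamma = 2.5,
                    d = 0.1)
  m2 <- growth_model_from_yaml(growth_model_to_yaml(m))
  expect_equal(m2, m)
  e2 <- growth_model_from_yaml(growth_model_to_yaml(growth_model("exponential")))
  expect_identical(e2$K, Inf)
})
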