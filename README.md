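# stochgrowth

Exact, approximate, and simulated solutions for the stochastic dynamics of
density-limited population growth.

Sigmoid growth curves — logistic, Richards, Blumberg, Gompertz — are
everywhere in microbiology, ecology, and epidemiology, and they are almost
always fitted and interpreted as deterministic ODEs. But growth is a
sequence of discrete, randomly timed birth events. When a population starts
from a few individuals, the deterministic curve is a *biased* predictor of
the mean stochastic trajectory: it can overestimate the average population
size by tens of percent, with the worst error near the inflection point.
This package is for modelers and experimentalists who need the stochastic
answer exactly: the full time-dependent population-size distribution, its
moments, the accuracy of moment-closure shortcuts, and downstream
applications to two-strain competition and fixation in serial-passage
(growth-dilution) experiments.

## The model and its exact solution

A growth model defines the total birth rate of a population of size `N`,

    B(N) = b N^alpha (1 - (N/K)^beta)^gamma        (Gompertz: b N log(K/N))

with intrinsic rate `b` and carrying capacity `K`. The stochastic version
is a pure-birth Markov jump process with master equation

    dP(N, t)/dt = B(N-1) P(N-1, t) - B(N) P(N, t),

absorbing at `K`. Because the population passes through every size in
order, the hitting time of size `N+1` is a sum of independent exponentials
with rates `B(N0), ..., B(N)` — hypoexponential — and the exact solution is

    P(N, t) = H_t(B(N0), ..., B(N)) / B(N),        N < K,

where `H_t` is the hypoexponential density (Erlang when all rates
coincide; an alternating exponential sum when all differ; an
Erlang-mixture with derivative coefficients under partial degeneracy, as
happens for the logistic model's mirror-symmetric rates). The package
evaluates these closed forms with extended-precision summation, checks them
against a spectral (transition-rate-matrix) expansion and an independent
stiff ODE integration of the master equation, and switches to
uniformization of the underlying Markov chain whenever a closed form would
lose precision — so results stay exact (to ~1e-9 or better) at any `K`.

On top of this sit the moment hierarchy of the logistic process with six
classical third-moment closures, seeded Gillespie simulators (C++ cores)
for pure-birth, birth-death, two-strain community, and serial-passage
dynamics, the exact two-strain composition/size/mutant-count laws, and
exact mutant fixation probabilities under repeated binomial bottlenecks.

## Worked example

How biased is the deterministic Gompertz curve, starting from a single
individual?

```r
library(stochgrowth)

m <- growth_model("gompertz", K = 100)
#> <growth_model> gompertz: B(N) = b N log(K/N)
#>   b = 1, K = 100, d = 0

times <- seq(0, 15, 0.05)
dist  <- exact_distribution(m, N0 = 1, times)   # full P(N, t)
mean_exact <- distribution_moments(dist, 1)$values[, 1]
det   <- deterministic_trajectory(m, N0 = 1, times)
eta   <- relative_error(det, mean_exact)
sprintf("max eta = %.1f%% at t = %.2f (inflection size N* = %.1f)",
        100 * max(eta), times[which.max(eta)], inflection_size(m))
#> "max eta = 11.5% at t = 1.15 (inflection size N* = 36.8)"
```

The deterministic curve overshoots the exact mean by up to 11.5%, peaking
close to the inflection point — and Gompertz is the *best-behaved* family;
Richards with `beta = 2` reaches ~31%. A seeded Gillespie ensemble confirms
the exact mean:

```r
grid <- seq(0, 15, 1)
sim  <- ensemble_mean(pure_birth_ensemble(m, 1, grid, 10000, seed = 1), grid)
head(cbind(sim, exact = mean_exact[times %in% grid]), 5)
#>   time   mean    se  exact
#> 1    0  1.000 0.000  1.000
#> 2    1 16.542 0.082 16.501
#> 3    2 49.454 0.123 49.457
#> 4    3 76.398 0.089 76.456
#> 5    4 90.377 0.049 90.421
```

The same bias propagates into experimental-evolution predictions. For a
mutant with 10% fitness advantage under growth-dilution cycles
(`K = 100`, dilution `D = 0.04`, `tau = 3`, starting from 2 mutants of 4):

```r
sp <- passage_spec(growth_model("logistic", K = 100), b_w = 1, b_m = 1.1,
                   dilution = 0.04, tau = 3, n0 = 2)
c(stochastic    = fixation_probability(bottleneck_matrix(sp), 2),
  deterministic = fixation_probability(bottleneck_matrix(sp, "deterministic"), 2))
#>    stochastic deterministic
#>     0.6227007     0.7228527
```

The mean-field treatment of the growth phase inflates the fixation
probability from 0.62 to 0.72; the exact chain matches direct simulation of
the experiment within Monte-Carlo error.

A command-line front end mirrors these computations
(`inst/cli/stochgrowth exact|closure|simulate|community|passage`), writing
CSV tables with a commented parameter echo; see `?run_cli`.

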