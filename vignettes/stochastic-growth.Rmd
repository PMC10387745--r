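---
title: "Exact stochastic dynamics of density-limited population growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact stochastic dynamics of density-limited population growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochgrowth)
```

## The model

Populations that grow toward a carrying capacity are classically described
by the generalized-logistic family of deterministic equations,

$$\frac{dN}{dt} = B(N) = b\,N^\alpha \left(1 - (N/K)^\beta\right)^\gamma,$$

which contains the logistic ($\alpha=\beta=\gamma=1$), Richards (free
$\beta$), Blumberg (free $\alpha$, $\gamma$), and — in the $\beta \to 0$
limit — Gompertz ($B(N) = bN\log(K/N)$) models, plus unbounded exponential
growth. `growth_model()` constructs these; exponents inconsistent with a
family are rejected at construction.

Real growth, however, is a sequence of discrete birth events. The honest
microscopic counterpart of the rate law is a continuous-time pure-birth
Markov process: a population of size $N$ waits an exponential time with
rate $B(N)$, then gains one individual. $K$ is an absorbing state. The
occupation probabilities obey the master equation

$$\frac{dP_{N_0,N}(t)}{dt} = B_{N-1}P_{N_0,N-1}(t) - B_N P_{N_0,N}(t),$$

and the central quantitative question is how far the deterministic sigmoid
strays from the exact mean $\langle N\rangle(t)$ of this process — the
relative error $\eta(t) = (N_d(t) - \langle N\rangle(t))/\langle
N\rangle(t)$. With $\alpha = 1$ the jump process has the rate law above as
its mean-field limit, which is why the stochastic machinery in this package
requires $\alpha = 1$ (and no deaths); general $\alpha$ remains available in
the deterministic operations.

## The exact solution

Because a pure-birth population passes through every size in order, the
hitting time of size $N+1$ is a sum of independent exponentials with rates
$B_{N_0},\dots,B_N$ — a hypoexponential random variable — and

$$P_{N_0,N}(t) = \frac{H_t(B_{N_0},\dots,B_N)}{B_N},\qquad N < K,$$

with the absorbing state taking the complementary mass. `hypoexp_pdf()`
implements the density in its three regimes: all rates equal (Erlang), all
distinct (the alternating exponential sum), and partially degenerate, where
the coefficients $C_{i,k} = \frac{d^k}{ds^k}\prod_{j\neq i}
(s+\lambda_j)^{-n_j}\big|_{s=-\lambda_i}$ are generated by a
logarithmic-derivative recursion (the derivatives of the logarithm are
elementary power sums). Degeneracy matters in practice: the logistic rates
have the mirror symmetry $B_k = B_{K-k}$, and the Gompertz rates collide
exactly at $B(K/4) = B(K/2)$ whenever $4 \mid K$.

An alternative spectral route (`spectral_distribution()`) diagonalizes the
bidiagonal transition-rate matrix; its eigenvalues are $-B_k$ and the
expansion reproduces the distinct-rate hypoexponential formula. It is
undefined for degenerate rate sets and refuses them with an error naming the
colliding states.

### Numerical choices

The closed forms are alternating sums whose largest term grows roughly
geometrically with the chain length; in binary64 they lose all accuracy
around $K \approx 20$–$30$. Three measures keep the package exact in
practice:

* **Round-off tracking.** Every closed-form evaluation carries an estimate
  of its absolute round-off (largest summand $\times$ machine epsilon).
* **Extended precision.** The distinct-rate sum and the spectral expansion
  are evaluated in compensated double-double arithmetic (about 31
  significant digits) in C++, pushing exact evaluation out to $K \approx
  40$–$50$.
* **Uniformization.** The production path for large chains
  (`method = "uniformization"`, and the automatic fallback whenever the
  estimated round-off exceeds $10^{-10}$ or a row-sum check fails at
  $10^{-9}$) computes transient probabilities through a Poisson-randomized
  discrete chain. All terms are non-negative — no cancellation — and the
  Poisson tail is truncated at mass $10^{-13}$, with the remainder assigned
  to the absorbing state.

An independent stiff ODE integration of the full master equation
(`master_equation_oracle()`, banded Jacobian, rtol $10^{-10}$/atol
$10^{-12}$) shares no code with the analytic routes and serves as ground
truth in the tests; the routes agree to better than $10^{-6}$ across all
families for $K \le 30$ and to $\sim 10^{-11}$ typically. Negative
round-off residues are clamped to zero and rows renormalized; the clamping
magnitude is recorded and stays below $10^{-9}$. Rates are grouped as equal
when they differ by at most $10^{-9}\max(B)$ — loose enough to catch exact
symmetries, tight enough never to merge genuinely distinct rates of these
families. The default time grid mirrors the growth window of the study
conditions, $t \in [0, 15]$ in steps of $0.05$ with $b = 1$ (time in units
of $1/b$; `b` rescales time throughout).

## Moment hierarchy and closures

For polynomial rate laws the master equation induces exact moment ODEs,
$d\langle f(N)\rangle/dt = \langle(f(N+1)-f(N))B(N)\rangle$. For
exponential growth the hierarchy closes order by order; for the logistic
model each order pulls in the next ($d\langle N\rangle/dt = \langle
N\rangle - \langle N^2\rangle/K$, and so on), and the non-polynomial
families admit no such expansion at all — `moment_ode_coefficients()`
rejects them. The classical remedy closes the first two equations with a
distributional ansatz for $\langle N^3\rangle$
(`third_moment_closure()`): binomial, lognormal, Nåsell-Poisson,
new-Poisson, normal, and separable derivative matching (identical to
lognormal), plus the mean-field closure $\langle N^2\rangle = \langle
N\rangle^2$, which collapses the system to the deterministic logistic
equation exactly. Closure systems are integrated adaptively at rtol
$10^{-10}$; if a closure ever drives the variance negative the first
violation time is recorded in a `"validity_breach"` attribute rather than
aborting, since the trajectory may still be of diagnostic interest.

At the study conditions ($K = 100$, $N_0 = 1$) the deterministic curve
overestimates the exact mean everywhere, maximally near the inflection
point: about 11.5% for Gompertz and up to about 31% for Richards with
$\beta = 2$. The binomial closure reduces the worst error to about 6.4%,
the normal closure worsens to about 26% (underestimating); binomial, SDM,
and mean-field closures overestimate while the Poisson-type and normal
closures underestimate. All of these numbers are recomputed, not quoted, by
`scripts/acceptance.R` and the test suite. The overestimation property is a
numerical observation at those conditions, not a theorem — at small $K$ the
Blumberg deterministic curve can dip marginally below the exact mean at late
times.

## Stochastic simulation

`simulate_pure_birth()`, `simulate_birth_death()`, `simulate_community()`,
and `simulate_serial_passage()` run exact Gillespie simulations with C++
cores, with matching `*_ensemble()` functions that evaluate replicates on a
shared time grid. Design choices:

* All replicates draw sequentially from R's RNG; a non-`NULL` `seed` makes
  any call bit-reproducible and restores the caller's RNG state. (Ensembles
  are cheap enough in compiled code that per-replicate streams for parallel
  execution were not worth their complexity.)
* In the birth-death process, size 0 is absorbing; at $N = K$ the birth rate
  of a density-limited model vanishes but deaths continue, so $K$ is *not*
  absorbing when $d > 0$.
* For the exponential family, a finite `K` acts as a truncation/cap rather
  than a carrying capacity; the final state of the exact distribution then
  aggregates all sizes $\ge K$.

The birth-death process also exposes the rapid-extinction probability
$p_0 = (d/b)^{N_0}$ — from the linear process, valid while the population
is small compared to $K$. For the Gompertz model the initial per-capita
rate is density dependent even at small sizes, and the package uses
$p_0 = (d/(b\log(K/N_0)))^{N_0}$; this variant is validated against the
package's own simulator only. The validity condition $N_0 \ll K$ is
quantitative: the exact transient solution shows extinction by $t = 50$ of
$0.511$ at $K = 100$ versus $0.501$ at $K = 1000$ for $d/b = 0.5$, so the
formula's consistency check is run in the latter regime, and the $K = 100$
density correction is itself asserted against the exact transient in the
unit tests.

## Two-strain communities

For a wild-type/mutant pair sharing the density factor $g(N) = B(N)/(bN)$,
a birth in state $(N, n)$ is a mutant birth with probability
$\Gamma(N,n) = rn/((r-1)n + N)$, $r = b_M/b_W$ — independent of the growth
family, which is what makes a family-independent composition law possible.
The conditional composition $P(N, n \mid N_0, n_0)$ follows a one-step
recursion in $N$; the total community size is then itself a pure-birth
chain with composition-averaged rates, so the exact single-population
machinery applies unchanged, and the mutant-count law is the marginal over
$N$. The same per-capita-factor generalization is used for the mean-field
community system $dn/dt = b_M n g(N)$, $dN/dt = (b_M n + b_W(N-n))g(N)$ —
the unique extension beyond the logistic family consistent with a
family-independent $\Gamma$. Neutral communities ($r = 1$) collapse to the
single-population law at machine precision, a property the tests assert
exactly. The composition recursion runs in doubles; its tests compare
against brute-force enumeration over birth sequences at small $K$ rather
than a rational-arithmetic mode, which no available dependency provides.

## Serial passage and fixation

A serial-passage experiment alternates growth for a time $\tau$ with a
binomial bottleneck down to $N_0 = DK$ individuals (sampling with
replacement at success probability $n/N$; hypergeometric bottlenecks are
out of scope). The post-bottleneck mutant count is a Markov chain on
$0..N_0$ whose transition matrix mixes binomial laws over the exact joint
$(N, n)$ distribution at $\tau$ — recomputed from scratch for every
starting count $k$ — or, in the mean-field variant, evaluates a single
binomial at the deterministic $(n(\tau), N(\tau))$. Fixation probabilities
come from the continuous-time embedding $R_{ij} = \Pi_{j\to i}$ with the
absorbing rows and columns removed,
$p_{\mathrm{fix}} = -\sum_i \Pi_{i\to N_0}(\tilde R^{-1})_{i,n_0}$,
which equals discrete-chain absorption (also asserted in tests via the
fundamental matrix). Neutral chains give $p_{\mathrm{fix}} = n_0/N_0$ to
$10^{-10}$; under selection the mean-field chain systematically
overestimates fixation, and the exact chain matches $10^5$-replicate
simulated experiments within Monte-Carlo error across dilution ratios.

## What the generator emulates — and what it does not

The simulators and exact solutions describe demographic stochasticity in a
homogeneous, well-mixed population in a constant environment: every
individual shares one intrinsic rate, the only noise is the exponential
waiting times between births (plus binomial sampling at bottlenecks), and
carrying capacity is hard. They do not emulate heterogeneous birth rates,
environmental fluctuations, explicit resource dynamics, spatial structure,
or measurement noise on abundances. Passing tests therefore certify the
mathematics of the jump process and its solutions, not the fidelity of any
particular biological dataset to that process.

## Problem sizes and defaults

The package defaults follow the study conditions: $b = 1$, $K = 100$,
$N_0 = 1$ ($N_0 = 2$, $n_0 = 1$ for communities), $b_M = 1.1$, $b_W = 1$,
$\tau = 3$, grids $t \in [0,15]$ by $0.05$. The test suite exercises
$K \le 30$ exhaustively against the ODE oracle, $K = 100$ through
uniformization, ensembles of $10^5$ replicates for the headline
simulation-consistency checks, and a reduced dilution sweep
$D \in \{0.02, 0.04, 0.1, 0.2\}$ for fixation; these sizes reproduce every
quantitative claim while keeping a full run in a few minutes on one core.

## Known limitations

* The exact machinery covers pure-birth processes; the birth-death process
  is available through simulation and its deterministic/mean-field and
  rapid-extinction summaries, not through an exact transient solution.
* Closed-form hypoexponential evaluation is precision-limited by design;
  beyond the double-double range the package switches to uniformization
  (exact to truncation $10^{-13}$) rather than attempting arbitrary
  precision.
* Moment hierarchies and closures apply to polynomial rate laws only —
  exponential and logistic.
* Communities are limited to two strains with one shared carrying capacity;
  parameter inference from data is out of scope.
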