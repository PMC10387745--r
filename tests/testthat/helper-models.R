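# Shared fixtures: the four density-limited families at the default
# exponents (beta = 2 for Richards, gamma = 1.5 for Blumberg) and a helper
# that builds them at any K.

family_model <- function(family, K, b = 1, d = 0) {
  growth_model(family, b = b, K = K,
               beta = if (family == "richards") 2 else NULL,
               gamma = if (family == "blumberg") 1.5 else NULL,
               d = d)
}

bounded_families <- c("logistic", "richards", "blumberg", "gompertz")

# brute-force composition law by enumerating all birth sequences:
# at community state (N, n) the next birth is a mutant w.p. Gamma(N, n)
enumerate_composition <- function(r, N0, n0, N_target) {
  probs <- numeric(N_target + 1L)  # index n + 1
  recurse <- function(N, n, p) {
    if (N == N_target) {
      probs[n + 1L] <<- probs[n + 1L] + p
      return(invisible())
    }
    gam <- r * n / ((r - 1) * n + N)
    if (gam > 0) recurse(N + 1L, n + 1L, p * gam)
    if (gam < 1) recurse(N + 1L, n, p * (1 - gam))
  }
  recurse(N0, n0, 1)
  probs
}
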