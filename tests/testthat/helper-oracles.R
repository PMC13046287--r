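# Shared oracles, independent of the package's series evaluations.

# total-variation distance between a pmf_vector and an empirical count vector
tv_to_counts <- function(pmf, counts) {
  emp <- tabulate(counts + 1L, nbins = pmf$n_max + 1L) / length(counts)
  0.5 * (sum(abs(emp - pmf$probs)) + mean(counts > pmf$n_max))
}

# brute-force Beta-Poisson mixture via adaptive quadrature
tele_pmf_oracle <- function(rho, son, soff, nmax) {
  vapply(0:nmax, function(n) {
    integrate(function(x) dbeta(x, son, soff) * dpois(n, rho * x),
              0, 1, rel.tol = 1e-11, stop.on.error = FALSE)$value
  }, numeric(1))
}

# 200-node Gauss-Legendre marginalization of a base pmf over a Beta capture
# density; base_pmf(pcap, nmax) returns the thinned pmf at fixed pcap
beta_mixture_oracle <- function(base_pmf, a, b, nmax, nodes = 200L) {
  gl <- pracma::gaussLegendre(nodes, 0, 1)
  acc <- numeric(nmax + 1)
  for (j in seq_along(gl$x))
    acc <- acc + gl$w[j] * dbeta(gl$x[j], a, b) * base_pmf(gl$x[j], nmax)
  acc
}

rand_tele_params <- function(n, seed) {
  set.seed(seed)
  data.frame(rho = runif(n, 2, 20),
             fon = runif(n, 0.05, 0.95),
             nsigma = 10^runif(n, -1, 2.5))
}
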