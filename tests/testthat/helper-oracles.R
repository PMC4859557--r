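# Shared fixtures: rate bundles and independent oracles built in code.

rate_list <- function(lam14, lam12, lam21, lam23, lam32, lam43, lam34, lam41) {
  list(lam14 = lam14, lam12 = lam12, lam21 = lam21, lam23 = lam23,
       lam32 = lam32, lam43 = lam43, lam34 = lam34, lam41 = lam41)
}

all_equal_rates <- function(lam) {
  rate_list(lam, lam, lam, lam, lam, lam, lam, lam)
}

# Stationary law of the two-state (telegraph) promoter, two independent
# routes that never touch the package's C++ evaluator:
#   (1) Kummer-transformed positive series in plain double arithmetic,
#       P(m) = e^{-mu} mu^m/m! (kon)_m/(kon+koff)_m
#              * sum_n (koff)_n mu^n / ((m+kon+koff)_n n!)
#       (all terms positive, so doubles suffice);
#   (2) Poisson-beta quadrature, P(m) = E_B[Pois(m; mu B)], B ~ Beta(kon,
#       koff), usable when the beta density has no endpoint singularity.
telegraph_series <- function(kon, koff, mu, M) {
  vapply(0:M, function(m) {
    lpref <- -mu + m * log(mu) - lgamma(m + 1) +
      lgamma(kon + m) - lgamma(kon) -
      (lgamma(kon + koff + m) - lgamma(kon + koff))
    s <- 1
    t <- 1
    n <- 1
    repeat {
      t <- t * (koff + n - 1) * mu / ((m + kon + koff + n - 1) * n)
      s <- s + t
      if (t < 1e-17 * s && n > mu) break
      n <- n + 1
    }
    exp(lpref) * s
  }, 1.0)
}

telegraph_quadrature <- function(kon, koff, mu, M) {
  stopifnot(kon >= 1, koff >= 1)  # endpoint-regular beta density
  vapply(0:M, function(m)
    stats::integrate(function(p) stats::dbeta(p, kon, koff) *
                       stats::dpois(m, mu * p),
                     0, 1, rel.tol = 1e-10)$value, 1.0)
}

# A small battery of moderate-rate configurations used across files.
random_rate_configs <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(rates = rate_list(runif(1, 0.2, 3), runif(1, 0.2, 3),
                           runif(1, 0.2, 3), runif(1, 0.2, 3),
                           runif(1, 0.2, 3), runif(1, 0.2, 3),
                           runif(1, 0.2, 3), runif(1, 0.2, 3)),
         mu1 = runif(1, 2, 15), mu2 = runif(1, 2, 15))
  })
}
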