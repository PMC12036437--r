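# Shared fixtures: tiny region tables and cohorts built in code.

# region table with s SN, f FPN, d DMN regions (TNM-restricted)
tiny_regions <- function(s = 2, f = 2, d = 2) {
  tnmpls:::synthetic_regions(c(SN = s, FPN = f, DMN = d))
}

# random symmetric correlation-like matrix with unit diagonal
random_symmetric <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  S <- (A + t(A)) / 2
  diag(S) <- 1
  S
}

# small centered two-domain dataset
random_domains <- function(n = 8, p = 5, q = 3, seed = 1) {
  set.seed(seed)
  list(X = scale(matrix(rnorm(n * p), n, p), scale = FALSE),
       Y = scale(matrix(rnorm(n * q), n, q), scale = FALSE))
}

# noiseless rank-1 two-domain dataset with given sparse loadings
rank1_domains <- function(n = 12, a, b, seed = 3) {
  set.seed(seed)
  t <- rnorm(n)
  t <- t - mean(t)
  list(X = t %*% t(a), Y = t %*% t(b), t = t, a = a, b = b)
}

# small synthetic cohort (cheap defaults for unit tests)
small_cohort <- function(seed = 1, K = 1, ...) {
  simulate_cohort(cohort_config(
    network_sizes = c(SN = 6, FPN = 8, DMN = 8),
    n_factors = K, seed = seed, ...))
}
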