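# Shared fixtures: small datasets built in code.

# a fast, small synthetic configuration for pipeline-level tests
small_sim_config <- function(seed = 1L, n = 15L) {
  synthetic_config(
    n_per_class = c(intact = n, internal_injury = n, scab = n, rotten = n),
    n_bands = 60L, seed = seed
  )
}

# a tiny GA budget for tests that only need the mechanism, not convergence
tiny_ga <- function(seed = 1L, gens = 4L, pop = 6L) {
  ga_config(population_size = pop, max_generations = gens,
            bits_per_parameter = 8L, seed = seed)
}

# a coarse LS-SVM grid for speed
tiny_ls <- function(seed = 1L) {
  ls_grid(gam = 2^c(0, 4, 8), sig2 = 2^c(0, 4, 8), cv_folds = 3L,
          seed = seed)
}

# random regression problem with known informative structure
random_xy <- function(n, p, seed = 1L, informative = 1L, noise = 0) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- numeric(p)
    beta[seq_len(informative)] <- seq_len(informative)
    y <- drop(X %*% beta) + rnorm(n, 0, noise)
    list(X = X, y = y, beta = beta)
  })
}
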