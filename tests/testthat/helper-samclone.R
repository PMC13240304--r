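# Shared test helpers: random parameter draws and a brute-force efficacy
# oracle independent of the package's kernel.

# Interior (x, y, z) draws bounded away from 0 and 1.
random_interior_params <- function(n, lo = 0.05, hi = 0.95) {
  data.frame(x = runif(n, lo, hi), y = runif(n, lo, hi), z = runif(n, lo, hi))
}

# Independent oracle: survival through two independent routes, written as
# the complement product rather than the expanded polynomial.
oracle_efficacy <- function(x, y, z, d = 0, alpha = 1) {
  p_arac <- (1 - (1 - d) * z) * x
  p_samhd1 <- (1 - alpha * d) * y
  1 - (1 - p_arac) * (1 - p_samhd1)
}

# Random small population with positive fractions.
random_population <- function(n_clones, lo = 0.05, hi = 0.95) {
  f <- runif(n_clones, 0.1, 1)
  f <- f / sum(f)
  pars <- random_interior_params(n_clones, lo, hi)
  clone_population(lapply(seq_len(n_clones), function(i) {
    clone(paste0("C", i), f[i], clone_params(pars$x[i], pars$y[i], pars$z[i]))
  }))
}

# Noise-free dose-response generating profiles shared by estimation tests.
dr_profiles <- function() {
  list(conc = c(0, 0.4, 1.7, 7, 16, 46),
       x = c(0, 0.2, 0.4, 0.6, 0.8, 0.9),
       z = c(1, 1, 1, 0.7, 0.4, 0.11),
       y = 0.0982)
}
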