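# Independent oracles used across the suite.

# Brute-force 1-D maximizer: dense grid scan then golden-section refinement.
# Deliberately independent of mean_mode()'s internals.
oracle_argmax <- function(f, lower, upper, grid_n = 4001L) {
  grid <- seq(lower, upper, length.out = grid_n)
  v <- f(grid)
  i <- which.max(v)
  lo <- grid[max(1L, i - 2L)]
  hi <- grid[min(grid_n, i + 2L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)
  if (opt$objective >= v[i]) {
    list(argmax = opt$maximum, max = opt$objective)
  } else {
    list(argmax = grid[i], max = v[i])
  }
}

# random valid sech parameter draws over wide ranges
random_sech_params <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(H = exp(runif(n, log(0.1), log(200))),
             m = runif(n, -100, 100),
             s = exp(runif(n, log(0.2), log(40))),
             r = runif(n, -0.95, 0.95),
             p = exp(runif(n, log(0.15), log(6))))
}

# total mass of a discrete family by truncated summation (tail-bounded)
discrete_total_mass <- function(fam, mu, theta, upper = 4000L) {
  y <- 0:upper
  sum(exp(err_log_density(fam, y, rep(mu, length(y)), theta)))
}

# atom + quadrature total mass for a mixed/continuous family on [0, upper]
continuous_total_mass <- function(fam, mu, theta, upper, atom_zero = TRUE) {
  dens <- function(y) exp(err_log_density(fam, y, rep(mu, length(y)), theta))
  at0 <- if (atom_zero) dens(0) else 0
  at0 + stats::integrate(dens, 1e-12, upper, rel.tol = 1e-9,
                         subdivisions = 400L)$value
}

# quick scenario constructors used in several files
sech_nb_scenario <- function(n = 500L, r = 0, pi0 = NULL, err = "nb") {
  theta_err <- if (err == "zinb") c(phi = 2, pi = pi0) else c(phi = 2)
  sim_scenario("sech", c(H = 50, m = 100, s = 20, r = r, p = 1),
               err, theta_err, n = n, xlim = c(0, 200))
}
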