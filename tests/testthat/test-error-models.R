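test_that("zero-inflated mixtures have the closed-form zero mass", {
  # P(0) = pi + (1 - pi) * exp(-mu) for ZIP
  expect_equal(err_log_density("zip", 0, 2, c(pi = 0.3)),
               log(0.3 + 0.7 * exp(-2)))
  expect_equal(err_log_density("zip", 0, 2, c(pi = 0.3)), log(0.3947347),
               tolerance = 1e-7)
  # positive observations: log(1 - pi) + base log-mass
  expect_equal(err_log_density("zip", 3, 2, c(pi = 0.3)),
               log(0.7) + dpois(3, 2, log = TRUE))
})

test_that("the zero-inflation degeneracy ladder holds exactly", {
  y <- 0:20
  mu <- 4
  # pi = 0: ZI family equals its base family
  expect_identical(err_log_density("zinb", y, mu, c(phi = 2, pi = 0)),
                   err_log_density("nb", y, mu, c(phi = 2)))
  expect_identical(err_log_density("zip", y, mu, c(pi = 0)),
                   err_log_density("poisson", y, mu))
  # linked ZI with g1 = 0 equals constant-pi ZI at pi = plogis(g0)
  g0 <- 0.4
  expect_equal(err_log_density("zinbl", y, mu, c(phi = 2, g0 = g0, g1 = 0)),
               err_log_density("zinb", y, mu, c(phi = 2, pi = plogis(g0))))
  expect_equal(err_log_density("zipl.mu", y, mu, c(g0 = g0, g1 = 0)),
               err_log_density("zip", y, mu, c(pi = plogis(g0))))
  yc <- c(0, 0.5, 1.3, 4)
  expect_equal(err_log_density("zigl", yc, 2, c(alpha = 2, g0 = g0, g1 = 0)),
               err_log_density("zig", yc, 2, c(alpha = 2, pi = plogis(g0))))
  expect_equal(err_log_density("zitab", c(0, 0.3, 0.8), 0.4,
                               c(psi = 8, pi = 0)),
               err_log_density("tab", c(0, 0.3, 0.8), 0.4, c(psi = 8)))
})

test_that("linked zero-inflation follows the logit-linear occupancy link", {
  expect_equal(linked_pi(0, 0, c(0.5, 2, 7)), rep(0.5, 3))
  expect_equal(linked_pi(0, -1, 1, mode = "log"), 0.5)
  expect_equal(linked_pi(0, -1, exp(1), mode = "log"), plogis(-1))
  expect_equal(plogis(-1), 0.2689414, tolerance = 1e-7)
  # negative slope: pi strictly decreasing in mu, both link modes
  mu <- seq(0.2, 30, length.out = 50)
  expect_true(all(diff(linked_pi(1, -0.8, mu, "log")) < 0))
  expect_true(all(diff(linked_pi(1, -0.8, mu, "mu")) < 0))
  expect_true(all(diff(linked_pi(1, 0.8, mu, "log")) > 0))
})

test_that("expected response is (1 - pi) * mu for zero-inflated families", {
  expect_equal(err_mean("zinb", 8, c(phi = 2, pi = 0.25)), 6)
  expect_equal(err_mean("zip", 8, c(pi = 0)), 8)
  expect_equal(err_mean("nb", 8, c(phi = 2)), 8)
  # linked ZI: E[Y] varies with mu only through pi(mu)
  mu <- c(1, 2, 4)
  ey <- err_mean("zipl", mu, c(g0 = 0, g1 = -1))
  expect_equal(ey, (1 - plogis(-log(mu))) * mu)
})

test_that("discrete families normalise to total mass one", {
  expect_equal(discrete_total_mass("poisson", 3, numeric()), 1, tolerance = 1e-10)
  expect_equal(discrete_total_mass("nb", 5, c(phi = 0.5)), 1, tolerance = 1e-10)
  expect_equal(discrete_total_mass("zip", 2, c(pi = 0.4)), 1, tolerance = 1e-10)
  expect_equal(discrete_total_mass("zinb", 4, c(phi = 1.5, pi = 0.2)), 1,
               tolerance = 1e-10)
  expect_equal(discrete_total_mass("zinbl", 4, c(phi = 2, g0 = 1, g1 = -1)), 1,
               tolerance = 1e-10)
  expect_equal(discrete_total_mass("bernoulli", 0.3, numeric(), upper = 1L), 1)
  yb <- (0:20) / 20
  expect_equal(sum(exp(err_log_density("binomial", yb, rep(0.3, 21), numeric(),
                                       size = 20))), 1, tolerance = 1e-12)
})

test_that("continuous families (with zero atoms) integrate to one", {
  expect_equal(continuous_total_mass("gamma", 3, c(alpha = 2), upper = 200,
                                     atom_zero = FALSE), 1, tolerance = 1e-6)
  expect_equal(continuous_total_mass("zig", 3, c(alpha = 2, pi = 0.3), upper = 200),
               1, tolerance = 1e-6)
  expect_equal(continuous_total_mass("ziig", 2, c(lambda = 3, pi = 0.25), upper = 400),
               1, tolerance = 1e-6)
  expect_equal(continuous_total_mass("zigl", 3, c(alpha = 2, g0 = 0, g1 = -1),
                                     upper = 200), 1, tolerance = 1e-6)
})

test_that("NB parameterisation has Var = mu + mu^2/phi (Monte-Carlo oracle)", {
  set.seed(31)
  n <- 1e6
  y <- err_sample("nb", rep(4, n), c(phi = 2))
  v_true <- 4 + 16 / 2
  expect_lt(abs(mean(y) - 4), 3 * sqrt(v_true / n))
  # SE of the sample variance ~ sqrt((kurtosis-ish)/n); generous 4-SE bound
  expect_lt(abs(var(y) - v_true), 4 * sqrt(2 * v_true^2 / n) * 3)
  # Poisson limit: phi -> infinity
  expect_equal(err_log_density("nb", 0:15, 3, c(phi = 1e8)),
               err_log_density("poisson", 0:15, 3), tolerance = 1e-6)
})

test_that("sampler matches the analytic zero mass and is seed-deterministic", {
  set.seed(7)
  y <- err_sample("zip", rep(2, 1e5), c(pi = 0.3))
  p0 <- 0.3 + 0.7 * exp(-2)
  expect_lt(abs(mean(y == 0) - p0), 3 * sqrt(p0 * (1 - p0) / 1e5))
  # near-total gating
  set.seed(8)
  y2 <- err_sample("zip", rep(5, 1e4), c(pi = 0.999))
  expect_gte(mean(y2 == 0), 0.98)
  # determinism contract
  set.seed(99); a <- err_sample("zinbl", runif(500, 1, 10), c(phi = 2, g0 = 1, g1 = -1))
  set.seed(99); b <- err_sample("zinbl", runif(500, 1, 10), c(phi = 2, g0 = 1, g1 = -1))
  expect_identical(a, b)
})

test_that("sampler and density agree for every family (moment identity)", {
  set.seed(55)
  n <- 2e5
  cases <- list(
    list("poisson", numeric(), 3), list("nb", c(phi = 0.7), 4),
    list("zip", c(pi = 0.3), 2), list("zinb", c(phi = 2, pi = 0.3), 4),
    list("zipl", c(g0 = 0.5, g1 = -1), 2),
    list("zinbl", c(phi = 2, g0 = 0.5, g1 = -1), 4),
    list("zipl.mu", c(g0 = 0.5, g1 = -0.5), 2),
    list("zinbl.mu", c(phi = 2, g0 = 0.5, g1 = -0.5), 4),
    list("gamma", c(alpha = 2), 3), list("zig", c(alpha = 2, pi = 0.3), 3),
    list("zigl", c(alpha = 2, g0 = 0, g1 = -1), 3),
    list("zigl.mu", c(alpha = 2, g0 = 0, g1 = -0.5), 3),
    list("ziig", c(lambda = 3, pi = 0.3), 2),
    list("ziigl", c(lambda = 3, g0 = 0, g1 = -1), 2),
    list("ziigl.mu", c(lambda = 3, g0 = 0, g1 = -0.5), 2),
    list("tweedie", c(rho = 1.5, phi = 1), 2),
    list("tab", c(psi = 10), 0.4), list("zitab", c(psi = 10, pi = 0.3), 0.4),
    list("bernoulli", numeric(), 0.3))
  for (cs in cases) {
    fam <- cs[[1]]; th <- cs[[2]]; mu <- cs[[3]]
    y <- err_sample(fam, rep(mu, n), th, size = 20)
    tm <- err_mean(fam, mu, th, size = 20)
    se <- sd(y) / sqrt(n)
    expect_lt(abs(mean(y) - tm), 4 * se)
  }
  # binomial separately (size required)
  yb <- err_sample("binomial", rep(0.4, n), numeric(), size = 20)
  expect_lt(abs(mean(yb) - 0.4), 4 * sd(yb) / sqrt(n))
})

test_that("support violations are rejected with the observation index", {
  expect_error(err_log_density("poisson", c(1, 2.5), 3), "observation 2")
  expect_error(err_log_density("poisson", -1, 3), "observation 1")
  expect_error(err_log_density("gamma", 0, 3, c(alpha = 1)), "observation 1")
  expect_error(err_log_density("tab", 1.2, 0.4, c(psi = 5)), "observation 1")
  expect_error(err_log_density("bernoulli", 2, 0.4), "observation 1")
  expect_error(err_log_density("zip", 1, 2, c(pi = 1.2)), "'pi' must lie")
  expect_error(err_log_density("unknown", 1, 2), "unknown error family")
})

test_that("infeasible means signal -Inf instead of erroring", {
  ll <- err_log_density("poisson", c(0, 1), c(-1, -1))
  expect_identical(ll, c(-Inf, -Inf))
  # mu = 0 is the degenerate limit: all mass at zero
  ll0 <- err_log_density("poisson", c(0, 1), c(0, 0))
  expect_identical(ll0, c(0, -Inf))
  expect_identical(err_log_density("tab", 0.4, 1.5, c(psi = 5)), -Inf)
})
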