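test_that("initial values recover the mode of a noiseless curve", {
  x <- seq(0, 100, length.out = 201)
  y <- round(mean_response("gaussian", c(H = 30, m = 42, s = 9), x))
  d <- gradient_data(x, y, "count")
  iv <- initial_values(d, "gaussian", "poisson")
  expect_lt(abs(iv$mean[["m"]] - 42), 1.0)   # within ~2 grid steps
  expect_gt(iv$mean[["H"]], 15)
  ivs <- initial_values(d, "sech", "nb")
  expect_equal(ivs$mean[["r"]], 0)
  expect_equal(ivs$mean[["p"]], 1)
})

test_that("initial pi reflects the structural zero fraction", {
  set.seed(71)
  x <- runif(800, 0, 100)
  mu <- rep(5, 800)
  y <- err_sample("zip", mu, c(pi = 0.5))
  d <- gradient_data(x, y, "count")
  iv <- initial_values(d, "constant", "zip")
  expect_gte(iv$err[["pi"]], 0.3)
  expect_lte(iv$err[["pi"]], 0.7)
  expect_error(initial_values(gradient_data(1:5, rep(0, 5), "count"),
                              "sech", "nb"),
               "insufficient non-zero observations")
})

test_that("negative log-likelihood matches closed forms and is additive", {
  set.seed(72)
  x <- runif(100, 0, 10)
  y <- rpois(100, 4)
  d <- gradient_data(x, y, "count")
  tr <- param_transform("constant", "poisson")
  nll_at <- function(cc) negative_log_likelihood(d, "constant", "poisson",
                                                 tr$to_u(c(c = cc), numeric()))
  # Poisson MLE optimality at c = ybar, with the closed-form value
  closed <- -sum(dpois(y, mean(y), log = TRUE))
  expect_equal(nll_at(mean(y)), closed, tolerance = 1e-10)
  expect_lt(nll_at(mean(y)), nll_at(mean(y) * 1.1))
  # additivity: appending a duplicate adds exactly its own contribution
  d2 <- gradient_data(c(x, x[1]), c(y, y[1]), "count")
  extra <- -dpois(y[1], mean(y), log = TRUE)
  expect_equal(negative_log_likelihood(d2, "constant", "poisson",
                                       tr$to_u(c(c = mean(y)), numeric())),
               nll_at(mean(y)) + extra, tolerance = 1e-10)
  # ZINB at the pi -> 0 boundary equals the NB objective
  trz <- param_transform("constant", "zinb")
  trn <- param_transform("constant", "nb")
  vz <- c(trn$to_u(c(c = 4), c(phi = 2))[1:2], E.pi = stats::qlogis(1e-12))
  expect_equal(negative_log_likelihood(d, "constant", "zinb", vz),
               negative_log_likelihood(d, "constant", "nb",
                                       trn$to_u(c(c = 4), c(phi = 2))),
               tolerance = 1e-6)
  # non-finite parameters penalised, never a crash
  expect_equal(negative_log_likelihood(d, "constant", "poisson", NaN), 1e10)
})

test_that("two-stage fit refines the annealing solution and is stable", {
  sc <- sech_nb_scenario(n = 500)
  d <- generate_dataset(sc, seed = 81)
  f1 <- suppressWarnings(fit_response(d, "sech", "nb", control = fit_control(seed = 1)))
  f2 <- suppressWarnings(fit_response(d, "sech", "nb", control = fit_control(seed = 2)))
  expect_true(f1$converged)
  # stage-2 contract: refined objective never above the annealing objective
  expect_lte(f1$nll, f1$nll_sann + 1e-8)
  # optimizer-seed stability of the refined optimum
  expect_lt(abs(f1$logLik - f2$logLik), 0.01)
  # fixed point: restarting from the estimates reproduces the optimum
  f3 <- suppressWarnings(fit_response(d, "sech", "nb",
                                      control = fit_control(seed = 3),
                                      init = list(mean = f1$theta_mean,
                                                  err = f1$theta_err)))
  expect_lt(abs(f3$logLik - f1$logLik), 1e-6 + 1e-8 * abs(f1$logLik))
})

test_that("a flexible curve never fits worse than its flat special case", {
  set.seed(82)
  x <- runif(400, 0, 100)
  y <- rpois(400, 6)
  d <- gradient_data(x, y, "count")
  fc <- suppressWarnings(fit_response(d, "constant", "poisson",
                                      control = fit_control(seed = 1)))
  fs <- suppressWarnings(fit_response(d, "sech", "poisson",
                                      control = fit_control(seed = 1)))
  # the constant curve is the s -> infinity limit of the sech family, so the
  # flexible fit can only approach it; allow the optimizer's own tolerance
  expect_gte(fs$logLik, fc$logLik - 0.01)
})

test_that("rare-species gate follows the presence-fraction rule of thumb", {
  d1 <- gradient_data(seq_len(1280), c(rep(1, 7), rep(0, 1273)), "count")
  expect_true(rare_species_gate(d1, 0.005, warn = FALSE))     # 7/1280 = 0.547%
  expect_warning(ok <- rare_species_gate(d1, 0.01), "rare species")
  expect_false(ok)
  d2 <- gradient_data(seq_len(1000), c(1, rep(0, 999)), "count")
  expect_false(rare_species_gate(d2, warn = FALSE))           # default 1%
  expect_true(rare_species_gate(d2, 0, warn = FALSE))
})

test_that("tiny samples give far more variable mode estimates", {
  sc <- sim_scenario("sech_p1_r0", c(H = 50, m = 100, s = 20), "nb",
                     c(phi = 2), xlim = c(0, 200))
  est_m <- function(n, reps, seed0) {
    vapply(seq_len(reps), function(r) {
      sc$n <- as.integer(n)
      d <- generate_dataset(sc, seed = seed0 + r)
      f <- tryCatch(suppressWarnings(
        fit_response(d, "sech_p1_r0", "nb",
                     control = fit_control(seed = seed0 + r, sann_budget = 150),
                     gate = FALSE)),
        error = function(e) NULL)
      if (is.null(f)) NA_real_ else f$m
    }, numeric(1))
  }
  m10 <- est_m(10, 80, 9000)
  m200 <- est_m(200, 80, 19000)
  expect_gte(sd(m10, na.rm = TRUE) / sd(m200, na.rm = TRUE), 3)
})

test_that("estimator bias and spread shrink with sample size", {
  sc <- sech_nb_scenario()
  res <- lapply(c(50, 200, 1000), function(n) {
    sc$n <- as.integer(n)
    m_hat <- vapply(1:60, function(r) {
      d <- generate_dataset(sc, seed = 300 * n + r)
      f <- tryCatch(suppressWarnings(
        fit_response(d, "sech", "nb", control = fit_control(seed = 300 * n + r),
                     gate = FALSE)),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) NA_real_ else f$m
    }, numeric(1))
    m_hat[is.finite(m_hat)]
  })
  rmse <- vapply(res, function(m) sqrt(mean((m - 100)^2)), numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_lt(abs(mean(res[[3]]) - 100), 3 * sd(res[[3]]) / sqrt(length(res[[3]])))
})

test_that("mixture components are reported ordered by location", {
  sc <- sim_scenario("mixgaussian",
                     c(H1 = 20, m1 = 30, s1 = 8, H2 = 10, m2 = 70, s2 = 8),
                     "poisson", n = 600, xlim = c(0, 100))
  d <- generate_dataset(sc, seed = 91)
  f <- suppressWarnings(fit_response(d, "mixgaussian", "poisson",
                                     control = fit_control(seed = 91)))
  expect_lt(f$theta_mean[["m1"]], f$theta_mean[["m2"]])
  expect_lt(abs(f$theta_mean[["m1"]] - 30), 3)
  expect_lt(abs(f$theta_mean[["m2"]] - 70), 3)
})

test_that("incompatible family/data-type pairs are refused", {
  d <- gradient_data(1:10, rpois(10, 2), "count")
  expect_error(fit_response(d, "gaussian", "tab"), "serves cover data")
})
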