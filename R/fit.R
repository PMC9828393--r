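#' Fitting options
#'
#' @param seed integer seed driving the stochastic global search (and any
#'   restart jitter); all randomness in a fit flows from it.
#' @param sann_budget number of simulated-annealing objective evaluations
#'   (stage 1 of the optimisation).
#' @param qn_tol relative convergence tolerance of the quasi-Newton stage.
#' @param restarts number of annealing starts; restarts beyond the first
#'   begin from jittered initial values.
#' @param min_presence_fraction rare-species gate threshold (see
#'   [rare_species_gate()]).
#' @param delta tail-adjusted beta rounding constant in (0, 1/2); fixed, not
#'   estimated (it models instrument rounding).
#' @param size binomial trials per observation (binomial error family).
#' @return List of options for [fit_response()].
#' @export
fit_control <- function(seed = 1L, sann_budget = 300L, qn_tol = 1e-8,
                        restarts = 1L, min_presence_fraction = 0.01,
                        delta = 0.01, size = NULL) {
  list(seed = as.integer(seed), sann_budget = as.integer(sann_budget),
       qn_tol = qn_tol, restarts = as.integer(restarts),
       min_presence_fraction = min_presence_fraction,
       delta = delta, size = size)
}

#' Negative log-likelihood of a mean-by-error model
#'
#' Objective function on the unconstrained parameter scale:
#' \eqn{-\sum_i \log P(y_i \mid \mu_i = f(x_i \mid \theta_M), \theta_E)}
#' with the identity link between the mean curve and the distribution mean.
#' Parameter vectors yielding infeasible means or non-finite contributions
#' return a large penalty value (1e10) rather than erroring, so stochastic
#' optimizers can traverse them.
#'
#' @param data a [gradient_data()] object.
#' @param mean_fun,err_dist family names.
#' @param vec unconstrained parameter vector (see [param_transform()]).
#' @param delta,size fixed error-family constants (see [fit_control()]).
#' @param xrange gradient range used to normalise the HOF curve.
#' @return Scalar objective value.
#' @export
negative_log_likelihood <- function(data, mean_fun, err_dist, vec,
                                    delta = 0.01, size = NULL,
                                    xrange = range(data$x)) {
  if (any(!is.finite(vec))) return(1e10)
  tr <- param_transform(mean_fun, err_dist)
  th <- tr$to_n(vec)
  mu <- tryCatch(mean_response(mean_fun, th$mean, data$x, xrange = xrange),
                 error = function(e) NULL)
  if (is.null(mu) || any(!is.finite(mu))) return(1e10)
  ll <- tryCatch(err_log_density(err_dist, data$y, mu, th$err,
                                 size = size, delta = delta),
                 error = function(e) NULL)
  if (is.null(ll)) return(1e10)
  nll <- -sum(ll)
  if (!is.finite(nll)) 1e10 else nll
}

#' Fit one mean-by-error model by maximum likelihood
#'
#' Two-stage optimisation on the unconstrained parameter scale: simulated
#' annealing from method-of-moments initial values (global search), followed
#' by quasi-Newton (BFGS) refinement, with a bounded Newton-variant fallback
#' (`nlminb`) if refinement fails.  The refined solution never has higher
#' negative log-likelihood than the annealing solution.  All stages and the
#' convergence outcome are recorded; total failure returns the best point
#' seen with `converged = FALSE`, never an error.
#'
#' @param data a [gradient_data()] object (or data frame plus
#'   `xvar`/`yvar`/`data_type`).
#' @param mean_fun mean family (see [mean_families()]).
#' @param err_dist error family (see [err_families()]); must be compatible
#'   with the data type.
#' @param control options from [fit_control()].
#' @param init optional list with `mean`/`err` starting values overriding
#'   [initial_values()].
#' @param xvar,yvar,data_type used only when `data` is a data frame.
#' @param gate apply the rare-species gate (warning only) before fitting.
#' @return Object of class `gradresp_fit`: estimates on natural
#'   (`theta_mean`, `theta_err`) and unconstrained (`par_u`) scales, `logLik`,
#'   parameter count `k`, information criteria, modal summary (`m`, `H`),
#'   convergence diagnostics and the seed used.
#' @examples
#' set.seed(1)
#' x <- runif(200, 0, 100)
#' mu <- mean_response("gaussian", c(H = 20, m = 50, s = 12), x)
#' d <- gradient_data(x, err_sample("poisson", mu), "count")
#' fit <- fit_response(d, "gaussian", "poisson")
#' coef(fit)
#' @export
fit_response <- function(data, mean_fun, err_dist, control = fit_control(),
                         init = NULL, xvar = NULL, yvar = NULL,
                         data_type = NULL, gate = TRUE) {
  if (is.data.frame(data)) {
    if (is.null(xvar) || is.null(yvar) || is.null(data_type))
      stop("supply 'xvar', 'yvar' and 'data_type' with a data frame", call. = FALSE)
    data <- gradient_data(data[[xvar]], data[[yvar]], data_type)
  }
  stopifnot(inherits(data, "gradient_data"))
  mean_fun <- match_mean_family(mean_fun)
  err_dist <- match_err_family(err_dist)
  if (err_data_type(err_dist) != data$data_type)
    stop("error family '", err_dist, "' serves ", err_data_type(err_dist),
         " data, not ", data$data_type, call. = FALSE)
  if (gate) rare_species_gate(data, control$min_presence_fraction)

  if (is.null(init)) init <- initial_values(data, mean_fun, err_dist,
                                            delta = control$delta)
  tr <- param_transform(mean_fun, err_dist)
  v0 <- tr$to_u(init$mean, init$err)
  xrange <- range(data$x)
  obj <- function(v) negative_log_likelihood(data, mean_fun, err_dist, v,
                                             delta = control$delta,
                                             size = control$size,
                                             xrange = xrange)

  set.seed(control$seed)
  best <- list(par = v0, value = obj(v0))
  stages <- character()
  converged <- FALSE
  nll_sann <- Inf
  for (rs in seq_len(max(1L, control$restarts))) {
    start <- if (rs == 1L) v0 else v0 + stats::rnorm(length(v0), 0, 0.3)
    parscale <- pmax(abs(start), 0.5)
    # stage 1: simulated annealing (global stochastic search)
    sa <- tryCatch(
      stats::optim(start, obj, method = "SANN",
                   control = list(maxit = control$sann_budget,
                                  parscale = parscale, temp = 2)),
      error = function(e) NULL)
    stages <- c(stages, sprintf("SANN[%d]", rs))
    cand <- if (!is.null(sa) && is.finite(sa$value)) sa else list(par = start, value = obj(start))
    nll_sann <- min(nll_sann, cand$value)
    # stage 2: quasi-Newton refinement
    qn <- tryCatch(
      stats::optim(cand$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = control$qn_tol,
                                  parscale = pmax(abs(cand$par), 0.5))),
      error = function(e) NULL)
    ok_qn <- !is.null(qn) && is.finite(qn$value) && qn$value <= cand$value + 1e-8
    if (ok_qn) {
      stages <- c(stages, sprintf("BFGS[%d]", rs))
      if (qn$value < best$value) best <- qn
      if (qn$convergence == 0) converged <- TRUE
    }
    if (!ok_qn || qn$convergence != 0) {
      # fallback / additional refinement: bounded Newton-variant
      nb <- tryCatch(
        stats::nlminb(cand$par, obj, control = list(rel.tol = control$qn_tol)),
        error = function(e) NULL)
      if (!is.null(nb) && is.finite(nb$objective)) {
        stages <- c(stages, sprintf("nlminb[%d]", rs))
        if (nb$objective < best$value) best <- list(par = nb$par, value = nb$objective)
        if (nb$convergence == 0) converged <- TRUE
      }
    }
    if (!is.null(sa) && is.finite(sa$value) && sa$value < best$value) best <- sa
  }

  th <- tr$to_n(best$par)
  # mixture label-switching: report components ordered by location
  if (mean_fun == "mixgaussian" && th$mean[["m1"]] > th$mean[["m2"]]) {
    th$mean <- th$mean[c("H2", "m2", "s2", "H1", "m1", "s1")]
    names(th$mean) <- c("H1", "m1", "s1", "H2", "m2", "s2")
    best$par <- tr$to_u(th$mean, th$err)
  }
  k <- length(best$par)
  ll <- -best$value
  ic <- information_criteria(ll, k, data$n)
  mode <- mean_mode(mean_fun, th$mean, xrange)
  structure(list(
    mean_fun = mean_fun, err_dist = err_dist, data = data,
    theta_mean = th$mean, theta_err = th$err,
    par_u = stats::setNames(best$par, tr$names),
    logLik = ll, k = k, n = data$n,
    AIC = ic[["AIC"]], AICc = ic[["AICc"]], BIC = ic[["BIC"]],
    m = mode$m, H = mode$H,
    nll = best$value, nll_sann = nll_sann,
    converged = converged && is.finite(ll) && best$value < 1e9,
    stages = stages, seed = control$seed, control = control,
    xrange = xrange, init = init
  ), class = "gradresp_fit")
}

#' @export
coef.gradresp_fit <- function(object, ...) {
  c(object$theta_mean,
    if (length(object$theta_err))
      stats::setNames(object$theta_err, names(object$theta_err)))
}

#' @export
logLik.gradresp_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
print.gradresp_fit <- function(x, ...) {
  cat(sprintf("<gradresp_fit> %s + %s  (n = %d, k = %d)\n",
              x$mean_fun, x$err_dist, x$n, x$k))
  cat(sprintf("  logLik = %.4f  AICc = %.4f  converged = %s\n",
              x$logLik, x$AICc, x$converged))
  cat(sprintf("  mode: m = %.6g  H = %.6g\n", x$m, x$H))
  est <- coef(x)
  cat("  estimates:", paste(sprintf("%s = %.6g", names(est), est), collapse = ", "), "\n")
  invisible(x)
}

#' Predicted mean curve from a fit
#'
#' @param object a `gradresp_fit`.
#' @param x gradient positions (defaults to a 200-point grid over the data
#'   range).
#' @param type `"mu"` for the mean of the non-excess-zero component,
#'   `"response"` for E[Y] including zero-inflation.
#' @param ... unused.
#' @return Data frame with columns `x` and `mu` (or `ey`).
#' @export
predict.gradresp_fit <- function(object, x = NULL,
                                 type = c("mu", "response"), ...) {
  type <- match.arg(type)
  if (is.null(x)) x <- seq(object$xrange[1], object$xrange[2], length.out = 200L)
  mu <- mean_response(object$mean_fun, object$theta_mean, x,
                      xrange = object$xrange)
  if (type == "mu") return(data.frame(x = x, mu = mu))
  ey <- rep(NA_real_, length(mu))
  pos <- mu > 0
  ey[pos] <- err_mean(object$err_dist, mu[pos], object$theta_err,
                      size = object$control$size, delta = object$control$delta)
  ey[!pos] <- 0
  data.frame(x = x, ey = ey)
}
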