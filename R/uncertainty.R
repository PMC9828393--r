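# Uncertainty quantification: observed-information Wald intervals,
# stratified fractional jackknife, and nonparametric bootstrap.

# numeric jacobian of the unconstrained -> natural map at vec
.natural_jacobian <- function(tr, vec, eps = 1e-6) {
  f <- function(v) {
    th <- tr$to_n(v)
    c(th$mean, th$err)
  }
  f0 <- f(vec)
  J <- matrix(0, nrow = length(f0), ncol = length(vec),
              dimnames = list(names(f0), tr$names))
  for (j in seq_along(vec)) {
    h <- eps * max(abs(vec[j]), 1)
    vp <- vec; vp[j] <- vp[j] + h
    vm <- vec; vm[j] <- vm[j] - h
    J[, j] <- (f(vp) - f(vm)) / (2 * h)
  }
  J
}

#' Standard errors and Wald intervals from the observed information matrix
#'
#' Computes the numerical Hessian of the negative log-likelihood at the
#' optimum on the unconstrained scale; its inverse is the estimated
#' covariance.  Natural-scale standard errors follow by the delta method,
#' while 95% (or `level`) confidence intervals are formed on the
#' unconstrained scale and each endpoint is mapped back (endpoint
#' transformation), keeping interval bounds inside the parameter domains.
#'
#' @param fit a converged `gradresp_fit`.
#' @param level confidence level (default 0.95).
#' @return Object of class `gradresp_uncertainty`: data frame `table` with
#'   per-parameter estimate, SE, lower and upper (natural scale), plus
#'   `method = "information"`, `usable` flag and diagnostic message.
#' @export
information_se <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "gradresp_fit"))
  tr <- param_transform(fit$mean_fun, fit$err_dist)
  obj <- function(v) negative_log_likelihood(fit$data, fit$mean_fun,
                                             fit$err_dist, v,
                                             delta = fit$control$delta,
                                             size = fit$control$size,
                                             xrange = fit$xrange)
  vec <- fit$par_u
  H <- tryCatch(stats::optimHess(vec, obj,
                                 control = list(parscale = pmax(abs(vec), 0.5))),
                error = function(e) NULL)
  est <- c(fit$theta_mean, fit$theta_err)
  bad <- function(msg) {
    structure(list(table = data.frame(parameter = names(est), estimate = est,
                                      se = NA_real_, lower = NA_real_,
                                      upper = NA_real_),
                   method = "information", level = level, usable = FALSE,
                   message = msg, vcov_u = NULL),
              class = "gradresp_uncertainty")
  }
  if (is.null(H) || any(!is.finite(H))) return(bad("Hessian evaluation failed"))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0))
    return(bad("information matrix singular or not positive definite"))
  se_u <- sqrt(diag(V))
  z <- stats::qnorm(1 - (1 - level) / 2)
  J <- .natural_jacobian(tr, vec)
  V_nat <- J %*% V %*% t(J)
  se_nat <- sqrt(pmax(diag(V_nat), 0))
  lower <- upper <- numeric(length(vec))
  for (j in seq_along(vec)) {
    vl <- vec; vl[j] <- vl[j] - z * se_u[j]
    vu <- vec; vu[j] <- vu[j] + z * se_u[j]
    nl <- tr$to_n(vl); nu <- tr$to_n(vu)
    lo <- c(nl$mean, nl$err)[j]; up <- c(nu$mean, nu$err)[j]
    lower[j] <- min(lo, up); upper[j] <- max(lo, up)
  }
  structure(list(table = data.frame(parameter = names(est), estimate = est,
                                    se = se_nat, lower = lower, upper = upper),
                 method = "information", level = level, usable = TRUE,
                 message = "ok", vcov_u = V),
            class = "gradresp_uncertainty")
}

#' @export
print.gradresp_uncertainty <- function(x, ...) {
  cat(sprintf("<gradresp_uncertainty> method = %s, level = %.2f, usable = %s\n",
              x$method, x$level, x$usable))
  if (!is.null(x$n_rep)) cat("  effective replicates:", x$n_rep, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# refit on a row subset, seeded from the full fit's estimates
.refit_subset <- function(fit, idx, seed) {
  d <- gradient_data(fit$data$x[idx], fit$data$y[idx], fit$data$data_type)
  ctl <- fit$control
  ctl$seed <- seed
  ctl$sann_budget <- max(50L, ctl$sann_budget %/% 4L)
  tryCatch(
    suppressWarnings(fit_response(d, fit$mean_fun, fit$err_dist, control = ctl,
                                  init = list(mean = fit$theta_mean,
                                              err = fit$theta_err),
                                  gate = FALSE)),
    error = function(e) NULL)
}

.resample_table <- function(fit, est_mat, method, level, scale_factor, n_rep) {
  est <- c(fit$theta_mean, fit$theta_err)
  se <- apply(est_mat, 2, stats::sd) * scale_factor
  if (method == "bootstrap") {
    qs <- apply(est_mat, 2, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2))
    lower <- qs[1, ]; upper <- qs[2, ]
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    lower <- est - z * se; upper <- est + z * se
  }
  structure(list(table = data.frame(parameter = names(est), estimate = est,
                                    se = se, lower = lower, upper = upper),
                 method = method, level = level, usable = nrow(est_mat) >= 2,
                 message = sprintf("%d of %d replicates usable",
                                   nrow(est_mat), n_rep),
                 n_rep = nrow(est_mat), replicates = est_mat),
            class = "gradresp_uncertainty")
}

#' Jackknife standard errors by stratified fractional subsampling
#'
#' Repeatedly refits the model on random subsamples containing a fixed
#' fraction of the data (default one quarter), drawn proportionally within
#' equal-width strata along the gradient so every subsample covers the full
#' range.  The delete-d jackknife standard error is the replicate standard
#' deviation rescaled by sqrt(fraction / (1 - fraction)).  Defaults follow
#' the workflow of 50 replicates of one-quarter proportional
#' gradient-stratified subsamples.  Subsamples failing the rare-species gate
#' or the refit are dropped and counted.
#'
#' @param fit a `gradresp_fit`.
#' @param n_rep number of jackknife replicates (default 50).
#' @param fraction subsample fraction in (0, 1) (default 0.25).
#' @param strata_bins number of equal-width gradient strata (default 4).
#' @param seed integer seed for the subsampling.
#' @param level confidence level for the reported Wald-style bounds.
#' @return A `gradresp_uncertainty` with the replicate estimates attached.
#' @export
jackknife_se <- function(fit, n_rep = 50L, fraction = 0.25, strata_bins = 4L,
                         seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "gradresp_fit"), fraction > 0, fraction < 1)
  x <- fit$data$x
  br <- seq(min(x), max(x), length.out = strata_bins + 1L)
  stratum <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), strata_bins)
  set.seed(seed)
  gate_thr <- fit$control$min_presence_fraction
  ests <- list()
  for (r in seq_len(n_rep)) {
    idx <- unlist(lapply(split(seq_along(x), stratum), function(ii) {
      m <- max(1L, round(fraction * length(ii)))
      if (length(ii) == 1L) ii else sample(ii, m)
    }), use.names = FALSE)
    d <- gradient_data(fit$data$x[idx], fit$data$y[idx], fit$data$data_type)
    if (d$presence_fraction < gate_thr) next
    f <- .refit_subset(fit, idx, seed = seed + r)
    if (is.null(f) || !f$converged) next
    ests[[length(ests) + 1L]] <- c(f$theta_mean, f$theta_err, m = f$m, H = f$H)
  }
  if (length(ests) < 2L)
    stop("fewer than 2 usable jackknife replicates", call. = FALSE)
  est_mat <- do.call(rbind, ests)
  out <- .resample_table(fit, est_mat[, seq_len(fit$k), drop = FALSE],
                         "jackknife", level,
                         scale_factor = sqrt(fraction / (1 - fraction)),
                         n_rep = n_rep)
  out$mode_replicates <- est_mat[, c("m", "H"), drop = FALSE]
  out
}

#' Bootstrap confidence intervals
#'
#' Nonparametric bootstrap: resamples (x, y) pairs with replacement, refits,
#' and reports percentile confidence intervals and the replicate standard
#' deviation as the SE.
#'
#' @inheritParams jackknife_se
#' @param n_rep number of bootstrap replicates (>= 100 recommended).
#' @return A `gradresp_uncertainty` with the replicate estimates attached.
#' @export
bootstrap_ci <- function(fit, n_rep = 200L, seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "gradresp_fit"))
  n <- fit$data$n
  set.seed(seed)
  ests <- list()
  for (r in seq_len(n_rep)) {
    idx <- sample.int(n, n, replace = TRUE)
    f <- .refit_subset(fit, idx, seed = seed + r)
    if (is.null(f) || !f$converged) next
    ests[[length(ests) + 1L]] <- c(f$theta_mean, f$theta_err)
  }
  if (length(ests) < 2L)
    stop("fewer than 2 usable bootstrap replicates", call. = FALSE)
  .resample_table(fit, do.call(rbind, ests), "bootstrap", level,
                  scale_factor = 1, n_rep = n_rep)
}
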