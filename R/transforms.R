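# Mapping between natural-scale parameters and the unconstrained scale the
# optimizer works on.  Each parameter name has a fixed transform type:
#   log      : strictly positive (heights, spreads, shapes, dispersions)
#   identity : unbounded (mode locations, logit-link coefficients)
#   atanh    : (-1, 1)  (sech asymmetry r)
#   logit    : (0, 1)   (excess-zero probability pi)
#   rho      : (1, 2)   (Tweedie power, via logit(rho - 1))
#   span     : interval upper bound b, stored as log(b - a) so a < b always
.par_type <- c(
  H = "log", s = "log", p = "log", c = "log", psi = "log",
  H1 = "log", s1 = "log", H2 = "log", s2 = "log",
  alpha = "log", gamma = "log", phi = "log", lambda = "log",
  b1 = "log", b2 = "log",
  m = "identity", m1 = "identity", m2 = "identity",
  a = "identity", a1 = "identity", a2 = "identity",
  g0 = "identity", g1 = "identity",
  r = "atanh", pi = "logit", rho = "rho", b = "span"
)

.to_u1 <- function(type, value, a = NULL) {
  switch(type,
    log = log(value),
    identity = value,
    atanh = atanh(value),
    logit = stats::qlogis(value),
    rho = stats::qlogis(value - 1),
    span = log(value - a))
}

.to_n1 <- function(type, value, a = NULL) {
  switch(type,
    log = exp(value),
    identity = value,
    atanh = tanh(value),
    logit = stats::plogis(value),
    rho = 1 + stats::plogis(value),
    span = a + exp(value))
}

#' Parameter transformation for a mean-by-error model
#'
#' Builds the pair of maps between natural-scale parameters and the
#' unconstrained scale used by the optimizer.  Strictly positive parameters
#' use log, the sech asymmetry uses artanh, probabilities use logit, the
#' Tweedie power uses logit(rho - 1), and interval bounds (a, b) are encoded
#' as (a, log(b - a)) so the ordering constraint always holds.  The round
#' trip is the identity to floating-point accuracy.
#'
#' @param mean_fun mean family name.
#' @param err_dist error family name.
#' @return List with `names` (unconstrained vector names, prefixed `M.` /
#'   `E.`), `to_u(theta_mean, theta_err)` returning the unconstrained vector
#'   and `to_n(vec)` returning `list(mean = ..., err = ...)`.
#' @export
param_transform <- function(mean_fun, err_dist) {
  mnames <- mean_par_names(mean_fun)
  enames <- err_par_names(err_dist)
  unames <- c(paste0("M.", mnames),
              if (length(enames)) paste0("E.", enames) else character(0))

  boundary_check <- function(nm, val) {
    ty <- .par_type[[nm]]
    bad <- switch(ty,
      log = val <= 0,
      atanh = abs(val) >= 1,
      logit = val <= 0 || val >= 1,
      rho = val <= 1 || val >= 2,
      FALSE)
    if (is.na(bad) || bad)
      stop("parameter '", nm, "' = ", val,
           " is at or beyond its domain boundary", call. = FALSE)
  }

  to_u <- function(theta_mean, theta_err = numeric()) {
    u <- numeric(length(unames))
    a_val <- if ("a" %in% mnames) theta_mean[["a"]] else NULL
    vals <- c(theta_mean[mnames], if (length(enames)) theta_err[enames])
    nms <- c(mnames, enames)
    for (i in seq_along(nms)) {
      boundary_check(nms[i], vals[[i]])
      if (.par_type[[nms[i]]] == "span" && vals[[i]] <= a_val)
        stop("'b' must exceed 'a'", call. = FALSE)
      u[i] <- .to_u1(.par_type[[nms[i]]], vals[[i]], a_val)
    }
    stats::setNames(u, unames)
  }

  to_n <- function(vec) {
    nms <- c(mnames, enames)
    a_val <- if ("a" %in% mnames) vec[[match("M.a", unames)]] else NULL
    out <- numeric(length(nms))
    for (i in seq_along(nms)) {
      out[i] <- .to_n1(.par_type[[nms[i]]], vec[[i]], a_val)
    }
    nm_mean <- stats::setNames(out[seq_along(mnames)], mnames)
    nm_err <- if (length(enames))
      stats::setNames(out[length(mnames) + seq_along(enames)], enames)
    else numeric()
    list(mean = nm_mean, err = nm_err)
  }

  list(names = unames, to_u = to_u, to_n = to_n,
       mean_names = mnames, err_names = enames)
}
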