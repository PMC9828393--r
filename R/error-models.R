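# Error-distribution families.  Each family couples a base distribution with
# a zero-inflation flavour:
#   none     : no excess zeros
#   constant : excess-zero probability pi, constant along the gradient
#   loglink  : logit(pi_i) = g0 + g1 * log(mu_i)   (linked; 'L' families)
#   mulink   : logit(pi_i) = g0 + g1 * mu_i        ('L.mu' families)
# mu_i always denotes the mean of the non-excess-zero component.
.err_registry <- list(
  poisson   = list(base = "poisson",  zi = "none",     type = "count",      pars = character()),
  nb        = list(base = "nb",       zi = "none",     type = "count",      pars = "phi"),
  zip       = list(base = "poisson",  zi = "constant", type = "count",      pars = "pi"),
  zinb      = list(base = "nb",       zi = "constant", type = "count",      pars = c("phi", "pi")),
  zipl      = list(base = "poisson",  zi = "loglink",  type = "count",      pars = c("g0", "g1")),
  zinbl     = list(base = "nb",       zi = "loglink",  type = "count",      pars = c("phi", "g0", "g1")),
  zipl.mu   = list(base = "poisson",  zi = "mulink",   type = "count",      pars = c("g0", "g1")),
  zinbl.mu  = list(base = "nb",       zi = "mulink",   type = "count",      pars = c("phi", "g0", "g1")),
  gamma     = list(base = "gamma",    zi = "none",     type = "continuous", pars = "alpha"),
  zig       = list(base = "gamma",    zi = "constant", type = "continuous", pars = c("alpha", "pi")),
  zigl      = list(base = "gamma",    zi = "loglink",  type = "continuous", pars = c("alpha", "g0", "g1")),
  zigl.mu   = list(base = "gamma",    zi = "mulink",   type = "continuous", pars = c("alpha", "g0", "g1")),
  ziig      = list(base = "ig",       zi = "constant", type = "continuous", pars = c("lambda", "pi")),
  ziigl     = list(base = "ig",       zi = "loglink",  type = "continuous", pars = c("lambda", "g0", "g1")),
  ziigl.mu  = list(base = "ig",       zi = "mulink",   type = "continuous", pars = c("lambda", "g0", "g1")),
  tweedie   = list(base = "tweedie",  zi = "none",     type = "continuous", pars = c("rho", "phi")),
  binomial  = list(base = "binomial", zi = "none",     type = "cover",      pars = character()),
  tab       = list(base = "tab",      zi = "none",     type = "cover",      pars = "psi"),
  zitab     = list(base = "tab",      zi = "constant", type = "cover",      pars = c("psi", "pi")),
  bernoulli = list(base = "bernoulli", zi = "none",    type = "binary",     pars = character())
)

#' Names of the available error-distribution families
#'
#' Families follow the usual acronyms: `zip`/`zinb` are zero-inflated Poisson
#' / negative binomial with constant excess-zero probability `pi`; an `l`
#' suffix links logit(pi) to log(mu) and `.mu` links it to mu directly;
#' `zig`/`ziig` are zero-inflated gamma / inverse Gaussian; `tab`/`zitab` the
#' (zero-inflated) tail-adjusted beta for cover data.
#'
#' @param data_type optionally restrict to families compatible with one of
#'   `"count"`, `"continuous"`, `"cover"`, `"binary"`.
#' @return Character vector of family names (lower case).
#' @export
err_families <- function(data_type = NULL) {
  nm <- names(.err_registry)
  if (!is.null(data_type)) {
    data_type <- match.arg(data_type, c("count", "continuous", "cover", "binary"))
    nm <- nm[vapply(.err_registry, function(e) e$type == data_type, logical(1))]
  }
  nm
}

match_err_family <- function(err_dist) {
  err_dist <- tolower(err_dist)
  if (!err_dist %in% names(.err_registry)) {
    stop("unknown error family '", err_dist, "'; available: ",
         paste(names(.err_registry), collapse = ", "), call. = FALSE)
  }
  err_dist
}

#' Parameter names of an error family
#'
#' Non-mean parameters (theta_E) in canonical order: `phi` NB dispersion
#' (Var = mu + mu^2/phi), `alpha` gamma shape, `lambda` inverse-Gaussian
#' shape, `rho`/`phi` Tweedie power and dispersion, `psi` beta precision,
#' `pi` excess-zero probability, `g0`/`g1` logit-scale link coefficients.
#'
#' @param err_dist family name (see [err_families()]).
#' @export
err_par_names <- function(err_dist) .err_registry[[match_err_family(err_dist)]]$pars

#' Data type served by an error family
#' @inheritParams err_par_names
#' @return One of `"count"`, `"continuous"`, `"cover"`, `"binary"`.
#' @export
err_data_type <- function(err_dist) .err_registry[[match_err_family(err_dist)]]$type

err_zi_type <- function(err_dist) .err_registry[[match_err_family(err_dist)]]$zi

is_zi_family <- function(err_dist) err_zi_type(err_dist) != "none"

validate_err_params <- function(err_dist, theta) {
  err_dist <- match_err_family(err_dist)
  need <- .err_registry[[err_dist]]$pars
  miss <- setdiff(need, names(theta))
  if (length(miss)) {
    stop("missing parameter(s) for '", err_dist, "': ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  th <- as.list(theta[need])
  for (k in intersect(c("phi", "alpha", "lambda", "psi"), need)) {
    if (!is.finite(th[[k]]) || th[[k]] <= 0)
      stop("parameter '", k, "' must be > 0", call. = FALSE)
  }
  if ("pi" %in% need && (th$pi < 0 || th$pi >= 1))
    stop("parameter 'pi' must lie in [0, 1)", call. = FALSE)
  if ("rho" %in% need && (th$rho <= 1 || th$rho >= 2))
    stop("parameter 'rho' must lie strictly in (1, 2)", call. = FALSE)
  invisible(theta[need])
}

#' Excess-zero probability linked to the mean
#'
#' Computes per-observation zero-inflation probabilities
#' \eqn{\pi_i = \mathrm{logit}^{-1}(\gamma_0 + \gamma_1 \log \mu_i)} (log
#' link) or \eqn{\mathrm{logit}^{-1}(\gamma_0 + \gamma_1 \mu_i)} (direct
#' link).  Reflecting the occupancy--abundance relationship, `g1` is
#' typically negative so zero-inflation rises where the mean falls.
#'
#' @param g0,g1 logit-scale intercept and slope.
#' @param mu positive mean vector.
#' @param mode `"log"` (link to log mean) or `"mu"` (link to mean).
#' @return Vector of probabilities in (0, 1).
#' @export
linked_pi <- function(g0, g1, mu, mode = c("log", "mu")) {
  mode <- match.arg(mode)
  stats::plogis(g0 + g1 * (if (mode == "log") log(mu) else mu))
}

# per-observation pi for any family (0 where no zero-inflation)
err_pi <- function(err_dist, mu, theta) {
  switch(err_zi_type(err_dist),
    none     = rep(0, length(mu)),
    constant = rep(theta[["pi"]], length(mu)),
    loglink  = linked_pi(theta[["g0"]], theta[["g1"]], mu, "log"),
    mulink   = linked_pi(theta[["g0"]], theta[["g1"]], mu, "mu"))
}

## ---- tail-adjusted beta (TAB) ----------------------------------------------

#' Tail-adjusted beta density
#'
#' Beta distribution with mean `mu` and precision `psi` (shapes
#' `mu * psi`, `(1 - mu) * psi`) whose tail mass below `delta` (and above
#' `1 - delta`) is spread uniformly over `[0, delta]` (`[1 - delta, 1]`), so
#' cover recorded as exactly 0 or 1 has positive density while total mass
#' stays 1.  `delta` models instrument rounding and is fixed, not estimated.
#'
#' @param y values in `[0, 1]`.
#' @param mu mean in (0, 1).
#' @param psi precision (> 0).
#' @param delta rounding half-width in (0, 1/2).
#' @param log return the log-density.
#' @return Density (or log-density) values.
#' @export
tab_density <- function(y, mu, psi, delta, log = FALSE) {
  a <- mu * psi; b <- (1 - mu) * psi
  lo <- stats::pbeta(delta, a, b) / delta
  hi <- (1 - stats::pbeta(1 - delta, a, b)) / delta
  d <- ifelse(y <= delta, lo,
       ifelse(y >= 1 - delta, hi, stats::dbeta(y, a, b)))
  if (log) log(d) else d
}

# exact mean of the TAB distribution (central part + two uniform bands)
tab_mean <- function(mu, psi, delta) {
  a <- mu * psi; b <- (1 - mu) * psi
  central <- mu * (stats::pbeta(1 - delta, a + 1, b) - stats::pbeta(delta, a + 1, b))
  central + stats::pbeta(delta, a, b) * delta / 2 +
    (1 - stats::pbeta(1 - delta, a, b)) * (2 - delta) / 2
}

tab_sample <- function(mu, psi, delta) {
  z <- stats::rbeta(length(mu), mu * psi, (1 - mu) * psi)
  lo <- z <= delta; hi <- z >= 1 - delta
  z[lo] <- stats::runif(sum(lo), 0, delta)
  z[hi] <- stats::runif(sum(hi), 1 - delta, 1)
  z
}

## ---- Tweedie (compound Poisson-gamma), power rho in (1,2) ------------------

tweedie_pars <- function(mu, rho, phi) {
  list(lambda = mu^(2 - rho) / (phi * (2 - rho)),      # Poisson rate
       shape  = (2 - rho) / (rho - 1),                 # gamma shape per event
       scale  = phi * (rho - 1) * mu^(rho - 1))        # gamma scale
}

#' Tweedie log-density (compound Poisson-gamma)
#'
#' Evaluates the log-density of the Tweedie distribution with mean `mu`,
#' power `rho` in (1, 2) and dispersion `phi` (variance `phi * mu^rho`).
#' The distribution is a Poisson sum of gamma variates: it places mass
#' \eqn{\exp(-\mu^{2-\rho} / (\phi (2-\rho)))} at zero and is continuous on
#' y > 0, where the density is computed by series summation over the Poisson
#' event count with adaptive truncation around the dominant term.
#'
#' @param y non-negative observations.
#' @param mu positive mean(s).
#' @param rho power parameter, strictly inside (1, 2).
#' @param phi positive dispersion.
#' @return Log-density vector.
#' @export
tweedie_log_density <- function(y, mu, rho, phi) {
  if (rho <= 1 || rho >= 2) stop("'rho' must lie strictly in (1, 2)", call. = FALSE)
  if (any(y < 0)) stop("Tweedie support is y >= 0", call. = FALSE)
  n <- max(length(y), length(mu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  tp <- tweedie_pars(mu, rho, phi)
  out <- numeric(n)
  zero <- y == 0
  out[zero] <- -tp$lambda[zero]
  if (any(!zero)) {
    yi <- y[!zero]; lam <- tp$lambda[!zero]; sc <- tp$scale[!zero]
    a <- tp$shape[1]
    # dominant Poisson index: j* ~ y^(2-rho) / (phi (2-rho)); window wide
    # enough that dropped terms are below exp(-37) of the peak
    jstar <- pmax(1, yi^(2 - rho) / (phi * (2 - rho)))
    jmax <- ceiling(max(jstar + 12 * sqrt(jstar) + 40))
    j <- seq_len(jmax)
    lt <- matrix(-Inf, nrow = jmax, ncol = length(yi))
    for (k in j) {
      lt[k, ] <- -lam + k * log(lam) - lgamma(k + 1) +
        stats::dgamma(yi, shape = k * a, scale = sc, log = TRUE)
    }
    mx <- apply(lt, 2, max)
    out[!zero] <- mx + log(colSums(exp(sweep(lt, 2, mx))))
  }
  out
}

tweedie_sample <- function(mu, rho, phi) {
  tp <- tweedie_pars(mu, rho, phi)
  nev <- stats::rpois(length(mu), tp$lambda)
  y <- numeric(length(mu))
  pos <- nev > 0
  y[pos] <- stats::rgamma(sum(pos), shape = nev[pos] * tp$shape[1],
                          scale = rep_len(tp$scale, length(mu))[pos])
  y
}

## ---- inverse Gaussian (mean mu, shape lambda) ------------------------------

ig_log_density <- function(y, mu, lambda) {
  ifelse(y > 0,
         0.5 * (log(lambda) - log(2 * pi) - 3 * log(pmax(y, .Machine$double.xmin))) -
           lambda * (y - mu)^2 / (2 * mu^2 * pmax(y, .Machine$double.xmin)),
         -Inf)
}

ig_sample <- function(mu, lambda) {
  # Michael, Schucany & Haas transform-with-rejection sampler
  n <- length(mu)
  w <- stats::rnorm(n)^2
  x1 <- mu + mu^2 * w / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * w + mu^2 * w^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x1), x1, mu^2 / x1)
}

## ---- base log-densities ----------------------------------------------------

base_log_density <- function(base, y, mu, theta, size, delta) {
  switch(base,
    poisson  = stats::dpois(y, mu, log = TRUE),
    nb       = stats::dnbinom(y, size = theta[["phi"]], mu = mu, log = TRUE),
    gamma    = stats::dgamma(y, shape = theta[["alpha"]],
                             rate = theta[["alpha"]] / mu, log = TRUE),
    ig       = ig_log_density(y, mu, theta[["lambda"]]),
    tweedie  = tweedie_log_density(y, mu, theta[["rho"]], theta[["phi"]]),
    tab      = tab_density(y, mu, theta[["psi"]], delta, log = TRUE),
    binomial = stats::dbinom(round(y * size), size, mu, log = TRUE),
    bernoulli = stats::dbinom(y, 1, mu, log = TRUE))
}

# support validation; returns index of first violation or 0
check_support <- function(err_dist, y, size = NULL) {
  info <- .err_registry[[err_dist]]
  bad <- switch(info$type,
    count = which(y < 0 | y != floor(y)),
    continuous = if (info$zi == "none" && info$base != "tweedie")
                   which(y <= 0) else which(y < 0),
    cover = {
      w <- which(y < 0 | y > 1)
      if (info$base == "binomial" && !length(w))
        w <- which(abs(y * size - round(y * size)) > 1e-8)
      w
    },
    binary = which(!y %in% c(0, 1)))
  if (length(bad)) bad[1] else 0L
}

#' Per-observation log-likelihood contributions
#'
#' Evaluates the log mass/density of each observation `y[i]` under the chosen
#' error family with mean `mu[i]` and non-mean parameters `theta`.  For
#' zero-inflated families the zero mass is the mixture
#' \eqn{\pi_i + (1-\pi_i) P_{base}(0)} and positive observations contribute
#' \eqn{\log(1-\pi_i)} plus the base log-density.  Infeasible means (`mu <= 0`,
#' or outside (0,1) for cover/binary families) yield `-Inf` contributions
#' rather than an error, so an optimizer can treat them as infinitely bad.
#'
#' @inheritParams err_par_names
#' @param y observations, within the family's support.
#' @param mu per-observation means of the non-excess-zero component.
#' @param theta named numeric vector of non-mean parameters (see
#'   [err_par_names()]).
#' @param size binomial trials per observation (binomial family only).
#' @param delta rounding half-width of the tail-adjusted beta, in (0, 1/2).
#' @return Numeric vector of log-likelihood contributions.
#' @examples
#' err_log_density("zip", y = 0, mu = 2, theta = c(pi = 0.3))
#' # log(0.3 + 0.7 * exp(-2))
#' @export
err_log_density <- function(err_dist, y, mu, theta = numeric(),
                            size = NULL, delta = 0.01) {
  err_dist <- match_err_family(err_dist)
  info <- .err_registry[[err_dist]]
  validate_err_params(err_dist, theta)
  if (info$base == "tab" && (delta <= 0 || delta >= 0.5))
    stop("'delta' must lie in (0, 1/2)", call. = FALSE)
  if (info$base == "binomial" && is.null(size))
    stop("binomial family requires a trials count 'size'", call. = FALSE)
  bad <- check_support(err_dist, y, size)
  if (bad > 0)
    stop("observation ", bad, " (y = ", y[bad], ") outside the support of '",
         err_dist, "'", call. = FALSE)
  n <- max(length(y), length(mu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  mu_hi <- if (info$type %in% c("cover", "binary")) 1 else Inf
  ok <- is.finite(mu) & mu > 0 & mu < mu_hi
  ll <- rep(-Inf, n)
  # mu = 0 is the degenerate all-mass-at-zero limit of every family here
  # (needed so bounded mean curves, zero outside (a,b), stay fittable)
  ll[is.finite(mu) & mu == 0 & y == 0] <- 0
  if (!any(ok)) return(ll)
  yk <- y[ok]; muk <- mu[ok]
  if (info$zi == "none") {
    ll[ok] <- base_log_density(info$base, yk, muk, theta, size, delta)
    return(ll)
  }
  pik <- err_pi(err_dist, muk, theta)
  lb <- base_log_density(info$base, yk, muk, theta, size, delta)
  lz <- if (info$base %in% c("gamma", "ig")) {
    log(pik)                               # continuous base: no mass at 0
  } else {
    b0 <- base_log_density(info$base, rep(0, length(yk)), muk, theta, size, delta)
    log(pik + (1 - pik) * exp(b0))
  }
  ll[ok] <- ifelse(yk == 0, lz, log1p(-pik) + lb)
  ll
}

#' Expected response E[Y] under an error family
#'
#' For zero-inflated families \eqn{E[Y_i] = (1-\pi_i)\mu_i}; otherwise
#' \eqn{E[Y_i] = \mu_i}.  The tail-adjusted beta uses its exact tail-adjusted
#' mean (the uniform bands perturb the beta mean slightly).
#'
#' @inheritParams err_log_density
#' @return Vector of expected responses.
#' @export
err_mean <- function(err_dist, mu, theta = numeric(), size = NULL, delta = 0.01) {
  err_dist <- match_err_family(err_dist)
  info <- .err_registry[[err_dist]]
  pi_i <- err_pi(err_dist, mu, theta)
  base_mean <- if (info$base == "tab") tab_mean(mu, theta[["psi"]], delta) else mu
  (1 - pi_i) * base_mean
}

#' Draw random responses from an error family
#'
#' Generates independent draws with per-observation means `mu`.
#' Zero-inflated families are sampled by Bernoulli(pi_i) gating of the base
#' draw.  Use `set.seed()` for reproducibility.
#'
#' @inheritParams err_log_density
#' @return Numeric vector of draws, one per element of `mu`.
#' @export
err_sample <- function(err_dist, mu, theta = numeric(), size = NULL, delta = 0.01) {
  err_dist <- match_err_family(err_dist)
  info <- .err_registry[[err_dist]]
  validate_err_params(err_dist, theta)
  n <- length(mu)
  y <- switch(info$base,
    poisson  = stats::rpois(n, mu),
    nb       = stats::rnbinom(n, size = theta[["phi"]], mu = mu),
    gamma    = stats::rgamma(n, shape = theta[["alpha"]], rate = theta[["alpha"]] / mu),
    ig       = ig_sample(mu, theta[["lambda"]]),
    tweedie  = tweedie_sample(mu, theta[["rho"]], theta[["phi"]]),
    tab      = tab_sample(mu, theta[["psi"]], delta),
    binomial = stats::rbinom(n, size, mu) / size,
    bernoulli = stats::rbinom(n, 1, mu))
  if (info$zi != "none") {
    y[stats::runif(n) < err_pi(err_dist, mu, theta)] <- 0
  }
  y
}
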