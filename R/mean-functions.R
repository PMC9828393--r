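# Registry of mean-response families.  Each family maps a named parameter
# vector theta to a non-negative mean curve f(x | theta).  Parameter order
# here is the canonical order used throughout fitting and reporting.
.mean_registry <- list(
  constant    = c("c"),
  uniform     = c("c", "a", "b"),
  gaussian    = c("H", "m", "s"),
  mixgaussian = c("H1", "m1", "s1", "H2", "m2", "s2"),
  beta        = c("H", "a", "b", "alpha", "gamma"),
  sech        = c("H", "m", "s", "r", "p"),
  sech_p1     = c("H", "m", "s", "r"),
  sech_r0     = c("H", "m", "s", "p"),
  sech_p1_r0  = c("H", "m", "s"),
  hof         = c("H", "a1", "b1", "a2", "b2")
)

#' Names of the available mean-response families
#'
#' @return Character vector of family names.  The `sech_*` entries are the
#'   hyperbolic-secant curve with peakedness and/or symmetry fixed a priori
#'   (`p = 1`, `r = 0`), giving simpler nested sub-models.
#' @export
mean_families <- function() names(.mean_registry)

#' Parameter names of a mean family
#'
#' @param mean_fun family name (see [mean_families()]).
#' @return Character vector of free parameter names in canonical order.
#' @export
mean_par_names <- function(mean_fun) {
  mean_fun <- match_mean_family(mean_fun)
  .mean_registry[[mean_fun]]
}

match_mean_family <- function(mean_fun) {
  mean_fun <- tolower(mean_fun)
  if (!mean_fun %in% names(.mean_registry)) {
    stop("unknown mean family '", mean_fun, "'; available: ",
         paste(names(.mean_registry), collapse = ", "), call. = FALSE)
  }
  mean_fun
}

# Bound checks, reporting which bound failed by name.
.check_pos <- function(theta, nm) {
  for (k in nm) {
    if (!is.finite(theta[[k]])) stop("parameter '", k, "' must be finite", call. = FALSE)
    if (theta[[k]] <= 0) stop("parameter '", k, "' must be > 0", call. = FALSE)
  }
}

#' Validate mean-function parameters
#'
#' Checks that a named parameter vector satisfies the family's domain
#' constraints (positivity of heights/spreads/shapes, `-1 < r < 1`,
#' ordered interval bounds `a < b`).
#'
#' @inheritParams mean_par_names
#' @param theta named numeric vector of parameters.
#' @return `theta` (invisibly), reordered to canonical order.
#' @export
validate_mean_params <- function(mean_fun, theta) {
  mean_fun <- match_mean_family(mean_fun)
  need <- .mean_registry[[mean_fun]]
  miss <- setdiff(need, names(theta))
  if (length(miss)) {
    stop("missing parameter(s) for '", mean_fun, "': ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  theta <- theta[need]
  if (any(!is.finite(unlist(theta)))) stop("non-finite parameter value", call. = FALSE)
  switch(mean_fun,
    constant = {
      if (theta[["c"]] < 0) stop("parameter 'c' must be >= 0", call. = FALSE)
    },
    uniform = {
      if (theta[["c"]] < 0) stop("parameter 'c' must be >= 0", call. = FALSE)
      if (theta[["a"]] >= theta[["b"]]) stop("'a' must be < 'b'", call. = FALSE)
    },
    gaussian = .check_pos(theta, c("H", "s")),
    mixgaussian = .check_pos(theta, c("H1", "s1", "H2", "s2")),
    beta = {
      .check_pos(theta, c("H", "alpha", "gamma"))
      if (theta[["a"]] >= theta[["b"]]) stop("'a' must be < 'b'", call. = FALSE)
    },
    sech = {
      .check_pos(theta, c("H", "s", "p"))
      if (abs(theta[["r"]]) >= 1) stop("parameter 'r' must lie in (-1, 1)", call. = FALSE)
    },
    sech_p1 = {
      .check_pos(theta, c("H", "s"))
      if (abs(theta[["r"]]) >= 1) stop("parameter 'r' must lie in (-1, 1)", call. = FALSE)
    },
    sech_r0 = .check_pos(theta, c("H", "s", "p")),
    sech_p1_r0 = .check_pos(theta, c("H", "s")),
    hof = {
      .check_pos(theta, "H")
      if (any(!is.finite(unlist(theta)))) stop("non-finite HOF parameter", call. = FALSE)
    }
  )
  invisible(theta)
}

# Hyperbolic-secant response curve.
#
# f(x) = (H / H_m) * exp(r * p * u) * sech(u)^p,  u = (x - m)/s + artanh(r)
#
# The offset x_m = s * artanh(r) and normaliser
# H_m = exp(r * p * artanh(r)) * (1 - r^2)^(p/2) anchor the curve so that the
# mode sits exactly at m with height exactly H.  Derivation of the sign
# convention: d/dx log f = (p/s) * (r - tanh(u)) = 0  <=>  tanh(u) = r, i.e.
# u* = artanh(r).  Shifting the argument by +artanh(r) places that stationary
# point at x = m, and sech(artanh(r)) = sqrt(1 - r^2) gives f(m) = H.  The
# second derivative -(p/s^2) * sech(u)^2 < 0 confirms a maximum.  For r > 0
# the right tail decays at rate p(1 - r)/s versus p(1 + r)/s on the left,
# hence a broader right-hand tail.
sech_curve <- function(x, H, m, s, r, p) {
  u <- (x - m) / s + atanh(r)
  lHm <- r * p * atanh(r) + (p / 2) * log1p(-r^2)
  # log-scale evaluation: sech(u) = 2 / (e^u + e^-u); use -log(cosh) stably
  lsech <- -abs(u) - log1p(exp(-2 * abs(u))) + log(2)
  H * exp(r * p * u + p * lsech - lHm)
}

gaussian_curve <- function(x, H, m, s) H * exp(-0.5 * ((x - m) / s)^2)

beta_curve <- function(x, H, a, b, alpha, gamma) {
  m <- (alpha * b + gamma * a) / (alpha + gamma)
  f <- numeric(length(x))
  inside <- x > a & x < b
  xi <- x[inside]
  f[inside] <- H * ((xi - a) / (m - a))^alpha * ((b - xi) / (b - m))^gamma
  f
}

# HOF-style product of two logistic flanks, height-normalised numerically on
# the evaluation range so the reported H equals the curve maximum there.
hof_raw <- function(x, a1, b1, a2, b2) {
  stats::plogis(b1 * (x - a1)) * stats::plogis(-b2 * (x - a2))
}

hof_peak <- function(a1, b1, a2, b2, xrange) {
  # maximum of the raw flank product over the range: dense grid then local
  # refinement (the product is smooth; grid+optimize is robust to plateaus)
  grid <- seq(xrange[1], xrange[2], length.out = 513L)
  g <- hof_raw(grid, a1, b1, a2, b2)
  i <- which.max(g)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  if (lo < hi) {
    opt <- stats::optimize(function(z) hof_raw(z, a1, b1, a2, b2),
                           c(lo, hi), maximum = TRUE, tol = 1e-10)
    if (opt$objective >= g[i]) return(list(x = opt$maximum, g = opt$objective))
  }
  list(x = grid[i], g = g[i])
}

#' Evaluate a mean-response curve
#'
#' Computes the mean response \eqn{\mu = f(x \mid \theta_M) \ge 0} of the
#' chosen family at gradient positions `x`.
#'
#' For the hyperbolic-secant family the curve is anchored so that the free
#' parameter `m` is exactly the modal position and `H` exactly the maximum
#' height; `r` in (-1, 1) controls asymmetry (positive: broader right tail)
#' and `p > 0` peakedness.  The HOF family is a product of two logistic
#' flanks rescaled so its maximum over `xrange` equals `H`; monotone shapes
#' arise when one flank is flat within the range.
#'
#' @inheritParams validate_mean_params
#' @param x numeric vector of gradient positions.
#' @param xrange length-2 numeric range used to normalise the HOF curve
#'   (defaults to `range(x)`); ignored by other families.
#' @return Numeric vector of non-negative means, same length as `x`.
#' @examples
#' mean_response("sech", c(H = 10, m = 50, s = 10, r = 0, p = 1), x = 50)
#' mean_response("beta", c(H = 3, a = 0, b = 1, alpha = 1, gamma = 1), x = 0.5)
#' @export
mean_response <- function(mean_fun, theta, x, xrange = NULL) {
  mean_fun <- match_mean_family(mean_fun)
  validate_mean_params(mean_fun, theta)
  th <- as.list(theta[.mean_registry[[mean_fun]]])
  switch(mean_fun,
    constant = rep(th$c, length(x)),
    uniform  = ifelse(x >= th$a & x <= th$b, th$c, 0),
    gaussian = gaussian_curve(x, th$H, th$m, th$s),
    mixgaussian = gaussian_curve(x, th$H1, th$m1, th$s1) +
                  gaussian_curve(x, th$H2, th$m2, th$s2),
    beta = beta_curve(x, th$H, th$a, th$b, th$alpha, th$gamma),
    sech       = sech_curve(x, th$H, th$m, th$s, th$r, th$p),
    sech_p1    = sech_curve(x, th$H, th$m, th$s, th$r, 1),
    sech_r0    = sech_curve(x, th$H, th$m, th$s, 0, th$p),
    sech_p1_r0 = sech_curve(x, th$H, th$m, th$s, 0, 1),
    hof = {
      if (is.null(xrange)) xrange <- range(x)
      pk <- hof_peak(th$a1, th$b1, th$a2, th$b2, xrange)
      th$H * hof_raw(x, th$a1, th$b1, th$a2, th$b2) / pk$g
    }
  )
}

#' Modal position and height of a mean curve
#'
#' Returns the gradient position of the maximum (`m`) and the maximum mean
#' (`H`) for a fitted or specified mean curve.  For families where these are
#' free parameters they are read off directly; otherwise (HOF, mixtures,
#' uniform, constant) the maximum is located numerically on `xrange`.
#'
#' @inheritParams mean_response
#' @return List with elements `m` and `H`.
#' @export
mean_mode <- function(mean_fun, theta, xrange) {
  mean_fun <- match_mean_family(mean_fun)
  th <- as.list(theta)
  if (mean_fun %in% c("gaussian", "sech", "sech_p1", "sech_r0", "sech_p1_r0")) {
    return(list(m = th$m, H = th$H))
  }
  if (mean_fun == "beta") {
    m <- (th$alpha * th$b + th$gamma * th$a) / (th$alpha + th$gamma)
    return(list(m = m, H = th$H))
  }
  grid <- seq(xrange[1], xrange[2], length.out = 1025L)
  f <- mean_response(mean_fun, theta, grid, xrange = xrange)
  i <- which.max(f)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  if (lo < hi && !mean_fun %in% c("constant", "uniform")) {
    opt <- stats::optimize(function(z) mean_response(mean_fun, theta, z, xrange = xrange),
                           c(lo, hi), maximum = TRUE, tol = 1e-9)
    if (opt$objective >= f[i]) return(list(m = opt$maximum, H = opt$objective))
  }
  list(m = grid[i], H = f[i])
}
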