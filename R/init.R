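# Initial parameter values by the method of moments from a smoothed curve.
# A smoothing spline (or binned running mean when x has few distinct values)
# approximates the mean response; its maximum gives H0 and m0, the second
# moment of its normalised positive part gives the spread s0, and the zero
# pattern of y against the smoothed mean seeds the zero-inflation and
# dispersion parameters.

smooth_mean_curve <- function(x, y, grid_n = 201L) {
  ux <- sort(unique(x))
  grid <- seq(min(x), max(x), length.out = grid_n)
  fit <- NULL
  if (length(ux) >= 8L) {
    fit <- tryCatch(stats::smooth.spline(x, y, df = min(8, length(ux) - 1)),
                    error = function(e) NULL)
  }
  if (!is.null(fit)) {
    sm_grid <- stats::predict(fit, grid)$y
    sm_x <- stats::predict(fit, x)$y
  } else {
    # binned running mean fallback for sparse designs
    nb <- max(3L, min(12L, length(ux)))
    br <- seq(min(x), max(x), length.out = nb + 1L)
    bin <- pmin(findInterval(x, br, rightmost.closed = TRUE), nb)
    bm <- tapply(y, factor(bin, levels = seq_len(nb)), mean)
    mid <- (br[-1] + br[-length(br)]) / 2
    ok <- !is.na(bm)
    sm_grid <- stats::approx(mid[ok], bm[ok], xout = grid, rule = 2)$y
    sm_x <- stats::approx(mid[ok], bm[ok], xout = x, rule = 2)$y
  }
  list(grid = grid, f = pmax(sm_grid, 0), fx = pmax(sm_x, 0))
}

# curve moments: H0 = max, m0 = argmax, s0 = sd of the normalised curve
curve_moments <- function(grid, f) {
  H0 <- max(f)
  m0 <- grid[which.max(f)]
  w <- pmax(f, 0)
  if (sum(w) <= 0) w <- rep(1, length(grid))
  w <- w / sum(w)
  mbar <- sum(w * grid)
  s0 <- sqrt(max(sum(w * (grid - mbar)^2), 1e-12))
  width <- diff(range(grid))
  list(H0 = max(H0, 1e-6), m0 = m0, s0 = max(min(s0, width), width / 100))
}

local_maxima <- function(f) {
  n <- length(f)
  which(f > c(-Inf, f[-n]) & f >= c(f[-1], -Inf))
}

init_mean_params <- function(mean_fun, x, y, sm) {
  cm <- curve_moments(sm$grid, sm$f)
  H0 <- cm$H0; m0 <- cm$m0; s0 <- cm$s0
  width <- diff(range(x))
  if (width <= 0) width <- max(abs(x[1]), 1)
  switch(mean_fun,
    constant = c(c = max(mean(y), 1e-6)),
    uniform = {
      xs <- if (any(y > 0)) range(x[y > 0]) else range(x)
      pad <- 0.02 * width
      a0 <- max(min(x) - pad, xs[1] - pad)
      b0 <- min(max(x) + pad, xs[2] + pad)
      if (b0 <= a0) { a0 <- min(x) - pad; b0 <- max(x) + pad }
      inside <- x >= a0 & x <= b0
      c0 <- if (any(inside)) max(mean(y[inside]), 1e-6) else max(mean(y), 1e-6)
      c(c = c0, a = a0, b = b0)
    },
    gaussian = c(H = H0, m = m0, s = s0),
    mixgaussian = {
      pk <- local_maxima(sm$f)
      pk <- pk[order(sm$f[pk], decreasing = TRUE)]
      if (length(pk) >= 2L) {
        p2 <- sort(pk[1:2])
        c(H1 = max(sm$f[p2[1]], 1e-6), m1 = sm$grid[p2[1]], s1 = s0 / 2,
          H2 = max(sm$f[p2[2]], 1e-6), m2 = sm$grid[p2[2]], s2 = s0 / 2)
      } else {
        c(H1 = H0 / 2, m1 = m0 - s0, s1 = s0 / 2,
          H2 = H0 / 2, m2 = m0 + s0, s2 = s0 / 2)
      }
    },
    beta = c(H = H0, a = min(x) - 0.05 * width, b = max(x) + 0.05 * width,
             alpha = 2, gamma = 2),
    sech = c(H = H0, m = m0, s = s0, r = 0, p = 1),
    sech_p1 = c(H = H0, m = m0, s = s0, r = 0),
    sech_r0 = c(H = H0, m = m0, s = s0, p = 1),
    sech_p1_r0 = c(H = H0, m = m0, s = s0),
    hof = c(H = H0, a1 = m0 - s0, b1 = 2 / s0, a2 = m0 + s0, b2 = 2 / s0)
  )
}

init_err_params <- function(err_dist, x, y, sm, delta = 0.01) {
  info <- .err_registry[[err_dist]]
  muhat <- pmax(sm$fx, 1e-6)
  if (info$type %in% c("cover", "binary")) muhat <- pmin(muhat, 1 - 1e-6)
  vres <- max(stats::var(y - muhat), 1e-8)
  out <- numeric()
  if ("phi" %in% info$pars && info$base == "nb") {
    # moment match Var = mu + mu^2/phi on average
    excess <- max(vres - mean(muhat), mean(muhat)^2 / 100)
    out["phi"] <- min(max(mean(muhat^2) / excess, 0.05), 100)
  }
  if ("alpha" %in% info$pars)
    out["alpha"] <- min(max(mean(muhat^2) / vres, 0.05), 100)
  if ("lambda" %in% info$pars)
    out["lambda"] <- min(max(mean(muhat^3) / vres, 0.05), 1000)
  if ("rho" %in% info$pars) out["rho"] <- 1.5
  if (info$base == "tweedie")
    out["phi"] <- min(max(vres / mean(muhat^1.5), 0.05), 100)
  if ("psi" %in% info$pars) {
    mbar <- mean(pmin(pmax(y, 1e-3), 1 - 1e-3))
    out["psi"] <- min(max(mbar * (1 - mbar) / vres - 1, 0.5), 200)
  }
  if (info$zi == "constant") {
    low <- muhat <= stats::median(muhat)
    if (!any(low)) low <- rep(TRUE, length(y))
    out["pi"] <- min(max(mean(y[low] == 0), 0.05), 0.9)
  }
  if (info$zi %in% c("loglink", "mulink")) {
    z <- as.numeric(y == 0)
    pred <- if (info$zi == "loglink") log(muhat) else muhat
    co <- tryCatch(
      stats::coef(suppressWarnings(
        stats::glm(z ~ pred, family = stats::binomial()))),
      error = function(e) NULL)
    if (is.null(co) || any(!is.finite(co))) {
      co <- c(stats::qlogis(min(max(mean(z), 0.05), 0.95)), -0.5)
    }
    out["g0"] <- min(max(co[1], -10), 10)
    out["g1"] <- min(max(co[2], -10), 10)
  }
  out[info$pars]
}

#' Initial parameter values for a mean-by-error model
#'
#' Method-of-moments starting values from a smoothed mean curve: the curve
#' maximum seeds `H` and `m`, its normalised second moment seeds `s`;
#' asymmetry and peakedness start at their neutral values (r = 0, p = 1);
#' the zero-inflation probability comes from the zero fraction where the
#' smoothed mean is low, NB dispersion from variance--mean moment matching,
#' and link coefficients from a logistic regression of the zero indicator on
#' the (log) smoothed mean.
#'
#' @param data a [gradient_data()] object with at least two distinct `x`
#'   among positive responses for modal families.
#' @param mean_fun,err_dist family names.
#' @param delta tail-adjusted beta rounding constant (cover families).
#' @return List with `mean` and `err` named parameter vectors.
#' @export
initial_values <- function(data, mean_fun, err_dist, delta = 0.01) {
  mean_fun <- match_mean_family(mean_fun)
  err_dist <- match_err_family(err_dist)
  if (all(data$y == 0))
    stop("insufficient non-zero observations to initialise the fit", call. = FALSE)
  if (mean_fun != "constant" && length(unique(data$x[data$y > 0])) < 2)
    stop("insufficient non-zero observations to initialise the fit", call. = FALSE)
  sm <- smooth_mean_curve(data$x, data$y)
  if (err_data_type(err_dist) %in% c("cover", "binary")) {
    sm$f <- pmin(sm$f, 1 - 1e-4)
    sm$fx <- pmin(sm$fx, 1 - 1e-4)
  }
  list(mean = init_mean_params(mean_fun, data$x, data$y, sm),
       err = init_err_params(err_dist, data$x, data$y, sm, delta))
}
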