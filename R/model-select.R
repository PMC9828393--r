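#' Information criteria from a maximised log-likelihood
#'
#' AIC = -2 logLik + 2k; AICc = AIC + 2k(k+1)/(n-k-1) (small-sample
#' correction, undefined when n <= k + 1); BIC = -2 logLik + k log n.
#'
#' @param logLik maximised log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations.
#' @return Named numeric vector `c(AIC, AICc, BIC)`; `AICc` is `NA` (with a
#'   warning) when `n <= k + 1`.
#' @examples
#' information_criteria(-100, 3, 50)
#' @export
information_criteria <- function(logLik, k, n) {
  aic <- -2 * logLik + 2 * k
  bic <- -2 * logLik + k * log(n)
  if (n > k + 1) {
    aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
  } else {
    warning("AICc undefined: n <= k + 1 (n = ", n, ", k = ", k, ")", call. = FALSE)
    aicc <- NA_real_
  }
  c(AIC = aic, AICc = aicc, BIC = bic)
}

#' Fit a grid of mean-by-error model combinations
#'
#' Fits every combination of the requested mean and error families to one
#' dataset and ranks the converged fits by AICc (ties broken by smaller
#' parameter count, then lexicographic family names, for determinism).
#' Error families incompatible with the data type are skipped with a logged
#' reason rather than aborting; non-converged fits are kept in the table but
#' excluded from the ranking.
#'
#' @param data a [gradient_data()] object.
#' @param mean_funs character vector of mean families.
#' @param err_dists character vector of error families.
#' @param control options from [fit_control()].
#' @return Object of class `gradresp_grid`: `table` (one row per attempted
#'   combination with k, logLik, AIC/AICc/BIC, converged, delta_AICc),
#'   `fits` (list of `gradresp_fit`), `best` (row index of the AICc-best
#'   converged fit), `skipped` (data frame of skipped combinations).
#' @export
fit_grid <- function(data, mean_funs, err_dists, control = fit_control()) {
  stopifnot(inherits(data, "gradient_data"))
  mean_funs <- vapply(mean_funs, match_mean_family, character(1))
  err_dists <- vapply(err_dists, match_err_family, character(1))
  combos <- expand.grid(mean_fun = mean_funs, err_dist = err_dists,
                        stringsAsFactors = FALSE)
  keep <- vapply(combos$err_dist, function(e) err_data_type(e) == data$data_type,
                 logical(1))
  skipped <- combos[!keep, , drop = FALSE]
  if (nrow(skipped)) {
    skipped$reason <- paste0("error family serves ",
                             vapply(skipped$err_dist, err_data_type, character(1)),
                             " data, dataset is ", data$data_type)
  } else skipped$reason <- character(0)
  combos <- combos[keep, , drop = FALSE]

  fits <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    f <- tryCatch(
      suppressWarnings(fit_response(data, combos$mean_fun[i], combos$err_dist[i],
                                    control = control, gate = FALSE)),
      error = function(e) NULL)
    fits[[i]] <- f
    rows[[i]] <- if (is.null(f)) {
      data.frame(mean_fun = combos$mean_fun[i], err_dist = combos$err_dist[i],
                 k = NA_integer_, logLik = NA_real_, AIC = NA_real_,
                 AICc = NA_real_, BIC = NA_real_, converged = FALSE)
    } else {
      data.frame(mean_fun = f$mean_fun, err_dist = f$err_dist, k = f$k,
                 logLik = f$logLik, AIC = f$AIC, AICc = f$AICc, BIC = f$BIC,
                 converged = f$converged)
    }
  }
  tab <- do.call(rbind, rows)
  conv <- which(tab$converged & is.finite(tab$AICc))
  tab$delta_AICc <- NA_real_
  best <- NA_integer_
  if (length(conv)) {
    ord <- conv[order(tab$AICc[conv], tab$k[conv],
                      tab$mean_fun[conv], tab$err_dist[conv])]
    best <- ord[1]
    tab$delta_AICc[conv] <- tab$AICc[conv] - tab$AICc[best]
  }
  structure(list(table = tab, fits = fits, best = best, skipped = skipped,
                 data = data, attempted = nrow(combos)),
            class = "gradresp_grid")
}

#' @export
print.gradresp_grid <- function(x, ...) {
  cat(sprintf("<gradresp_grid> %d attempted fits, %d skipped\n",
              x$attempted, nrow(x$skipped)))
  tab <- x$table[order(x$table$delta_AICc, na.last = TRUE), ]
  print(utils::head(tab, 10), row.names = FALSE)
  if (!is.na(x$best))
    cat(sprintf("best (AICc): %s + %s\n",
                x$table$mean_fun[x$best], x$table$err_dist[x$best]))
  invisible(x)
}

#' Best fit of a model grid
#' @param grid a `gradresp_grid`.
#' @return The AICc-best converged `gradresp_fit`, or `NULL` when none
#'   converged.
#' @export
best_fit <- function(grid) {
  if (is.na(grid$best)) return(NULL)
  grid$fits[[grid$best]]
}

#' Delta-AICc profile across mean families at the best error family
#'
#' Holds the error distribution fixed at that of the AICc-best model and
#' tabulates delta AICc for each mean family, a plot-ready summary of how
#' much each mean shape loses relative to the best.
#'
#' @param grid a `gradresp_grid` with at least two converged rows.
#' @return Data frame with columns `mean_fun`, `err_dist`, `AICc`,
#'   `delta_AICc`, sorted by `delta_AICc`.
#' @export
delta_aicc_profile <- function(grid) {
  tab <- grid$table
  conv <- tab[tab$converged & is.finite(tab$AICc), , drop = FALSE]
  if (nrow(conv) < 2) stop("need at least two converged fits", call. = FALSE)
  if (is.na(grid$best)) stop("no best model identified", call. = FALSE)
  be <- tab$err_dist[grid$best]
  sub <- conv[conv$err_dist == be, c("mean_fun", "err_dist", "AICc")]
  sub$delta_AICc <- sub$AICc - min(sub$AICc)
  sub[order(sub$delta_AICc), ]
}

#' Tally best models across many datasets
#'
#' Cross-tabulates the AICc-best (mean family, error family) pair over a
#' list of fitted grids — the multi-species summary view with error
#' distributions as rows and mean functions as columns.
#'
#' @param grids list of `gradresp_grid` objects.
#' @return Contingency table (rows = error family, columns = mean family).
#' @export
grid_tally <- function(grids) {
  pairs <- lapply(grids, function(g) {
    if (is.na(g$best)) return(NULL)
    data.frame(mean_fun = g$table$mean_fun[g$best],
               err_dist = g$table$err_dist[g$best])
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) stop("no grids with a best model", call. = FALSE)
  table(err_dist = pairs$err_dist, mean_fun = pairs$mean_fun)
}
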