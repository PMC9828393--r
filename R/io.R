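# Data ingestion, result serialisation and plot-ready exports.

#' Read a gradient dataset from a delimited text file
#'
#' Reads a CSV (header required), extracts the gradient and response
#' columns, drops rows with missing values (with a message), and validates
#' against the declared data type.  Cover data supplied in percent (values
#' above 1) are divided by 100, with a message.
#'
#' @param path file path to a delimited text file.
#' @param xvar,yvar column names of the gradient and the response.
#' @param data_type one of `"count"`, `"continuous"`, `"cover"`, `"binary"`.
#' @param sep field separator (default comma).
#' @return A [gradient_data()] object.
#' @export
read_gradient_data <- function(path, xvar, yvar,
                               data_type = c("count", "continuous", "cover", "binary"),
                               sep = ",") {
  data_type <- match.arg(data_type)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (v in c(xvar, yvar)) {
    if (!v %in% names(df))
      stop("column '", v, "' not found in ", path, call. = FALSE)
  }
  x <- as.numeric(df[[xvar]]); y <- as.numeric(df[[yvar]])
  drop <- !is.finite(x) | !is.finite(y)
  if (any(drop)) {
    message("dropping ", sum(drop), " row(s) with missing x or y")
    x <- x[!drop]; y <- y[!drop]
  }
  if (data_type == "cover" && any(y > 1)) {
    message("cover values exceed 1; interpreting as percent and dividing by 100")
    y <- y / 100
  }
  if (data_type == "count" && any(y != floor(y))) {
    bad <- which(y != floor(y))
    stop("count data contains non-integer values at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  gradient_data(x, y, data_type)
}

#' Serialise a result object to JSON
#'
#' Writes fits, grids or experiment results as JSON at full double
#' precision, so a written-then-reread result reproduces all numeric fields
#' exactly.
#'
#' @param object a `gradresp_fit`, `gradresp_grid`, `gradresp_uncertainty`
#'   or `gradresp_experiment`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(object, path) {
  x <- if (inherits(object, "gradresp_fit")) {
    list(mean_fun = object$mean_fun, err_dist = object$err_dist,
         estimates = as.list(c(object$theta_mean, object$theta_err)),
         unconstrained = as.list(object$par_u),
         logLik = object$logLik, k = object$k, n = object$n,
         AIC = object$AIC, AICc = object$AICc, BIC = object$BIC,
         m = object$m, H = object$H, converged = object$converged,
         stages = object$stages, seed = object$seed)
  } else if (inherits(object, "gradresp_grid")) {
    list(table = object$table, skipped = object$skipped,
         best = if (is.na(object$best)) NULL else list(
           mean_fun = object$table$mean_fun[object$best],
           err_dist = object$table$err_dist[object$best]))
  } else if (inherits(object, "gradresp_uncertainty")) {
    list(method = object$method, level = object$level, usable = object$usable,
         message = object$message, table = object$table)
  } else if (inherits(object, "gradresp_experiment")) {
    list(summary = object$summary, truth = object$truth[c("m", "H")],
         seed = object$seed)
  } else {
    object
  }
  # 17 significant digits: enough for an exact double round trip
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Export fitted curves for several species as a long table
#'
#' Evaluates each fitted mean curve on a common gradient grid and stacks
#' them in long format for external plotting.  In `"absolute"` mode curves
#' are the fitted means and species are ordered by decreasing maximum height
#' H; in `"relative"` mode each curve is divided by its maximum over the
#' grid (so every species peaks at 1) and species are ordered by decreasing
#' modal position m.
#'
#' @param fits named list of `gradresp_fit` objects (names = species).
#' @param xgrid numeric vector of gradient positions common to all species.
#' @param mode `"absolute"` or `"relative"`.
#' @return Data frame with columns `species` (factor ordered per the mode),
#'   `x`, `mu`.
#' @export
export_multispecies_curves <- function(fits, xgrid,
                                       mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  stopifnot(length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("species_", seq_along(fits))
  rows <- lapply(names(fits), function(sp) {
    f <- fits[[sp]]
    mu <- mean_response(f$mean_fun, f$theta_mean, xgrid, xrange = f$xrange)
    if (mode == "relative") mu <- mu / max(mu)
    data.frame(species = sp, x = xgrid, mu = mu)
  })
  out <- do.call(rbind, rows)
  key <- vapply(fits, function(f) if (mode == "absolute") f$H else f$m, numeric(1))
  out$species <- factor(out$species, levels = names(sort(key, decreasing = TRUE)))
  out[order(out$species, out$x), ]
}

## ---- command-line interface ------------------------------------------------

#' Run the command-line interface
#'
#' Thin shell entry point over the package functions, used by the
#' `inst/cli/gradresp-cli.R` script.  Subcommands: `fit` (one model; also
#' writes the predicted-curve table), `grid` (all combinations of listed
#' families), `simulate` (write a synthetic dataset), `coverage` (CI
#' coverage experiment).  Multi-species curve export is available through
#' [export_multispecies_curves()].
#'
#' @param args character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
cli_run <- function(args) {
  usage <- paste(
    "usage: gradresp-cli.R <fit|grid|simulate|coverage> [options]",
    "common: --input PATH --xvar NAME --yvar NAME --type count|continuous|cover|binary",
    "        --mean FAMILY[,FAMILY...] --err FAMILY[,FAMILY...] --seed INT --out DIR",
    "simulate: --mean-params 'H=50,m=100,...' --err-params 'phi=2' --n INT --xlim 'a,b'",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list(seed = 1L, out = ".", type = "count", n = 500L,
               xlim = c(0, 200), mean = NULL, err = NULL)
  kv <- args[-1]
  i <- 1L
  while (i <= length(kv)) {
    key <- sub("^--", "", kv[i]); val <- if (i < length(kv)) kv[i + 1L] else NA
    opts[[key]] <- val
    i <- i + 2L
  }
  parse_params <- function(s) {
    if (is.null(s)) return(numeric())
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    kvs <- strsplit(parts, "=", fixed = TRUE)
    stats::setNames(vapply(kvs, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(kvs, `[`, character(1), 1))
  }
  seed <- as.integer(opts$seed)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  status <- tryCatch({
    switch(cmd,
      fit = {
        d <- read_gradient_data(opts$input, opts$xvar, opts$yvar, opts$type)
        f <- fit_response(d, opts$mean, opts$err,
                          control = fit_control(seed = seed))
        write_result_json(f, file.path(opts$out, "fit.json"))
        utils::write.csv(predict(f), file.path(opts$out, "curve.csv"),
                         row.names = FALSE)
        print(f)
        0L
      },
      grid = {
        d <- read_gradient_data(opts$input, opts$xvar, opts$yvar, opts$type)
        g <- fit_grid(d, strsplit(opts$mean, ",")[[1]],
                      strsplit(opts$err, ",")[[1]],
                      control = fit_control(seed = seed))
        write_result_json(g, file.path(opts$out, "grid.json"))
        utils::write.csv(g$table, file.path(opts$out, "grid.csv"),
                         row.names = FALSE)
        print(g)
        0L
      },
      simulate = {
        sc <- sim_scenario(opts$mean, parse_params(opts[["mean-params"]]),
                           opts$err, parse_params(opts[["err-params"]]),
                           n = as.integer(opts$n),
                           xlim = as.numeric(strsplit(as.character(opts$xlim),
                                                      ",")[[1]]))
        d <- generate_dataset(sc, seed = seed)
        utils::write.csv(data.frame(x = d$x, y = d$y),
                         file.path(opts$out, "simulated.csv"),
                         row.names = FALSE)
        0L
      },
      coverage = {
        sc <- sim_scenario(opts$mean, parse_params(opts[["mean-params"]]),
                           opts$err, parse_params(opts[["err-params"]]),
                           n = as.integer(opts$n),
                           xlim = as.numeric(strsplit(as.character(opts$xlim),
                                                      ",")[[1]]))
        ex <- coverage_experiment(sc, reps = as.integer(opts$reps %||% 200L),
                                  seed = seed)
        write_result_json(ex, file.path(opts$out, "coverage.json"))
        print(ex)
        0L
      },
      { message("unknown subcommand '", cmd, "'\n", usage); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
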