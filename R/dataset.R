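#' Construct a gradient dataset
#'
#' Bundles paired observations (gradient value `x`, response `y`) for one
#' species with a declared data type and validates them: `count` responses
#' must be non-negative integers, `continuous` non-negative reals, `cover`
#' values in [0, 1] (percent cover should be divided by 100 first; see
#' [read_gradient_data()]), and `binary` values in {0, 1}.
#'
#' @param x numeric gradient positions (finite).
#' @param y responses, same length as `x`.
#' @param data_type one of `"count"`, `"continuous"`, `"cover"`, `"binary"`.
#' @return An object of class `gradient_data`: list with `x`, `y`,
#'   `data_type`, `n` and `presence_fraction` (share of y > 0).
#' @export
gradient_data <- function(x, y, data_type = c("count", "continuous", "cover", "binary")) {
  data_type <- match.arg(data_type)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 1L) stop("need at least one observation", call. = FALSE)
  if (any(!is.finite(x))) stop("'x' contains missing or non-finite values", call. = FALSE)
  if (any(!is.finite(y))) stop("'y' contains missing or non-finite values", call. = FALSE)
  bad <- switch(data_type,
    count = which(y < 0 | y != floor(y)),
    continuous = which(y < 0),
    cover = which(y < 0 | y > 1),
    binary = which(!y %in% c(0, 1)))
  if (length(bad)) {
    stop("response values incompatible with data type '", data_type,
         "' at row(s): ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  structure(list(x = x, y = y, data_type = data_type, n = length(x),
                 presence_fraction = mean(y > 0)),
            class = "gradient_data")
}

#' @export
print.gradient_data <- function(x, ...) {
  cat("<gradient_data> n =", x$n, " type =", x$data_type,
      sprintf(" presence = %.1f%%", 100 * x$presence_fraction),
      sprintf(" x range = [%g, %g]\n", min(x$x), max(x$x)))
  invisible(x)
}

#' Rare-species presence gate
#'
#' Modelling a species with very few non-zero responses gives unstable
#' estimates.  This gate compares the presence fraction (share of y > 0)
#' against a threshold; a practical rule of thumb lies between 1% and 5%,
#' and the default is 1%.  Failure is reported as a value (and optionally a
#' warning), never an error: the decision is left to the experimenter.
#'
#' @param data a [gradient_data()] object.
#' @param min_presence_fraction threshold in [0, 1]; default 0.01.
#' @param warn emit a warning on failure (default TRUE).
#' @return Logical scalar (TRUE = passes) with attribute `message`.
#' @export
rare_species_gate <- function(data, min_presence_fraction = 0.01, warn = TRUE) {
  pass <- data$presence_fraction >= min_presence_fraction
  msg <- sprintf("presence fraction %.4f %s threshold %.4f",
                 data$presence_fraction, if (pass) ">=" else "<",
                 min_presence_fraction)
  if (!pass && warn) {
    warning("rare species: ", msg, "; estimates may be highly unstable",
            call. = FALSE)
  }
  structure(pass, message = msg)
}
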