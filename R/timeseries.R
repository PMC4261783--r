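#' Discrete time-course trajectory
#'
#' A `timeseries` stores concentrations of `n` components at `N + 1` strictly
#' increasing time points: one row per component, one column per time point.
#' It is the common container for both observation data and model
#' simulations.
#'
#' @param times numeric vector of strictly increasing time points.
#' @param values numeric matrix of concentrations, one row per component and
#'   one column per time point.
#' @param component_names character vector of row labels; defaults to the
#'   rownames of `values` or `X1 ... Xn`.
#'
#' @return An object of class `timeseries` with fields `times`, `values`
#'   and `component_names`.
#' @export
#' @examples
#' ts <- timeseries(0:3, rbind(a = c(1, 2, 4, 8)))
#' ts$values["a", 3]
timeseries <- function(times, values, component_names = NULL) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times))
    abort_validation("'times' must be a numeric vector without missing values")
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  if (!is.numeric(values) || !is.matrix(values))
    abort_validation("'values' must be a numeric matrix")
  if (anyNA(values) || any(!is.finite(values)))
    abort_validation("'values' must not contain missing or non-finite entries")
  if (ncol(values) != length(times))
    abort_validation("'values' must have one column per time point")
  if (length(times) > 1L && any(diff(times) <= 0))
    abort_validation("'times' must be strictly increasing")
  component_names <- component_names %||% rownames(values) %||%
    paste0("X", seq_len(nrow(values)))
  if (length(component_names) != nrow(values))
    abort_validation("number of component names must equal the number of rows")
  rownames(values) <- component_names
  structure(list(times = as.numeric(times), values = values,
                 component_names = component_names),
            class = "timeseries")
}

#' @export
print.timeseries <- function(x, ...) {
  cat(sprintf("<timeseries> %d component(s) x %d time point(s), t in [%g, %g]\n",
              nrow(x$values), length(x$times), min(x$times), max(x$times)))
  df <- as.data.frame(x)
  print(utils::head(df, 8L))
  if (nrow(df) > 8L) cat(sprintf("... %d more rows\n", nrow(df) - 8L))
  invisible(x)
}

#' @export
as.data.frame.timeseries <- function(x, ...) {
  data.frame(time = x$times, t(x$values), check.names = FALSE)
}

#' Read and write time-course data as delimited text
#'
#' The on-disk format is CSV with a leading `time` column and one column per
#' component; values are written with 17 significant digits so that the
#' write/read round trip is bit-lossless at double precision.
#'
#' @param path file path.
#' @return `read_timeseries()` returns a [timeseries()].
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path))
    abort_odeinfer(sprintf("file not found: %s", path), "odeinfer_io_error")
  df <- tryCatch(read.csv(path, check.names = FALSE),
                 error = function(e) abort_parse(
                   sprintf("cannot parse '%s': %s", path, conditionMessage(e))))
  if (ncol(df) < 2L || names(df)[1L] != "time")
    abort_parse(sprintf(
      "'%s': expected a header starting with 'time' and >= 1 component column",
      path))
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[j]])))))[1L]
      abort_parse(sprintf("'%s': non-numeric value in column '%s' near line %d",
                          path, names(df)[j], bad + 1L))
    }
  }
  if (anyNA(df))
    abort_parse(sprintf("'%s': missing values are not allowed", path))
  if (any(diff(df$time) <= 0))
    abort_validation(sprintf("'%s': time column must be strictly increasing",
                             path))
  timeseries(df$time, t(as.matrix(df[-1L])),
             component_names = names(df)[-1L])
}

#' @param series a [timeseries()].
#' @rdname read_timeseries
#' @export
write_timeseries <- function(series, path) {
  stopifnot(inherits(series, "timeseries"))
  df <- as.data.frame(series)
  txt <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  if (nrow(df) == 1L) txt <- matrix(txt, nrow = 1L)
  lines <- c(paste(names(df), collapse = ","),
             apply(txt, 1L, paste, collapse = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    abort_odeinfer(sprintf("cannot write '%s'", path), "odeinfer_io_error")
  invisible(path)
}
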