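#' Construct a Phanerozoic time series
#'
#' The basic data container of the package: a named, unit-bearing sequence of
#' (age, value) samples on a geological time axis. Ages are in millions of
#' years before present (Ma), stored strictly ascending, so index 1 is the
#' youngest sample (0 Ma = today) and the last index the oldest. Dynamical
#' operations (embedding, cross mapping) internally reverse this order so that
#' the state evolves forward in time, oldest to youngest.
#'
#' @param ages numeric vector of ages in Ma before present; non-negative,
#'   no duplicates. Any input order is accepted; storage is ascending.
#' @param values numeric vector of measurements, same length as `ages`; must
#'   be finite.
#' @param name short label for the series (used in cross-map direction labels).
#' @param units unit label for `values` (free text, e.g. `"10^18 mol C/Myr"`).
#' @return An object of class `"paleo_ts"`: a list with elements `name`,
#'   `units`, `ages`, `values`.
#' @examples
#' ts <- paleo_ts(c(0, 11, 22), c(1.2, 1.0, 0.8), name = "SQS", units = "rel")
#' ts
#' @export
paleo_ts <- function(ages, values, name = "series", units = "") {
  if (!is.numeric(ages) || !is.numeric(values))
    stop("'ages' and 'values' must be numeric", call. = FALSE)
  if (length(ages) != length(values))
    stop("'ages' and 'values' must have the same length", call. = FALSE)
  if (length(ages) < 1L)
    stop("a time series needs at least one sample", call. = FALSE)
  if (anyNA(ages) || any(!is.finite(ages)))
    stop("ages must be finite and non-missing", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite and non-missing", call. = FALSE)
  if (any(ages < 0))
    stop("ages are Myr before present and must be non-negative", call. = FALSE)
  o <- order(ages)
  ages <- ages[o]
  values <- values[o]
  if (anyDuplicated(ages))
    stop("duplicate ages: ", paste(unique(ages[duplicated(ages)]), collapse = ", "),
         call. = FALSE)
  structure(list(name = as.character(name)[1L], units = as.character(units)[1L],
                 ages = ages, values = values),
            class = "paleo_ts")
}

#' @export
print.paleo_ts <- function(x, ...) {
  cat(sprintf("<paleo_ts> %s%s: %d samples, %.6g-%.6g Ma\n",
              x$name, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              length(x$ages), min(x$ages), max(x$ages)))
  df <- as.data.frame(x)
  if (nrow(df) > 6L) {
    print(utils::head(df, 3L))
    cat(sprintf("  ... %d more rows\n", nrow(df) - 3L))
  } else {
    print(df)
  }
  invisible(x)
}

#' @export
as.data.frame.paleo_ts <- function(x, ...) {
  data.frame(age_Ma = x$ages, value = x$values)
}

#' @export
length.paleo_ts <- function(x) length(x$ages)

#' @export
plot.paleo_ts <- function(x, ..., type = "l") {
  graphics::plot(x$ages, x$values, type = type,
                 xlim = rev(range(x$ages)),
                 xlab = "Age (Ma)", ylab = x$units, main = x$name, ...)
  invisible(x)
}

#' Read a time series from a two-column delimited text file
#'
#' The on-disk format is two numeric columns, `age_Ma` and `value`, comma- or
#' whitespace-separated (autodetected). A header line is optional; lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path path to the file.
#' @param name,units labels attached to the returned series; `name` defaults
#'   to the file name without extension.
#' @return A validated [paleo_ts] sorted ascending in age.
#' @seealso [write_series()] for the inverse.
#' @export
read_series <- function(path, name = NULL,  units = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("no data rows in ", path, call. = FALSE)
  sep_split <- function(s) {
    if (grepl(",", s)) strsplit(s, "\\s*,\\s*")[[1]]
    else strsplit(trimws(s), "\\s+")[[1]]
  }
  parse_row <- function(s) suppressWarnings(as.numeric(sep_split(s)[1:2]))
  first <- parse_row(lines[1L])
  if (anyNA(first)) {  # header line
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (length(lines) < 2L)
    stop("need at least 2 data rows in ", path, call. = FALSE)
  mat <- vapply(lines, parse_row, numeric(2L), USE.NAMES = FALSE)
  bad <- which(colSums(is.na(mat)) > 0L)
  if (length(bad))
    stop(sprintf("non-numeric data at line %d of %s: '%s'",
                 lineno[bad[1L]], path, lines[bad[1L]]), call. = FALSE)
  ages <- mat[1L, ]
  if (anyDuplicated(ages)) {
    d <- ages[duplicated(ages)][1L]
    stop(sprintf("duplicate age %.6g in %s (line %d)",
                 d, path, lineno[which(ages == d)[2L]]), call. = FALSE)
  }
  paleo_ts(ages, mat[2L, ], name = name, units = units)
}

#' Write a time series to a two-column delimited text file
#'
#' Writes `age_Ma,value` rows at full double precision, so a
#' [read_series()]/[write_series()] round trip is lossless.
#'
#' @param x a [paleo_ts].
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_series <- function(x, path) {
  stopifnot(inherits(x, "paleo_ts"))
  lines <- c("age_Ma,value",
             sprintf("%.17g,%.17g", x$ages, x$values))
  writeLines(lines, path)
  invisible(x)
}

#' Interpolate a time series onto a new age grid
#'
#' Resamples a series at the requested ages, either piecewise linearly or with
#' a cubic spline (Forsythe-Malcolm-Moler end conditions, which reproduce
#' cubic polynomials exactly). Both methods pass exactly through the source
#' samples; extrapolation is never performed.
#'
#' @param series a [paleo_ts].
#' @param grid numeric vector of target ages (Ma), each inside the span of
#'   `series`; duplicates are an error.
#' @param method `"linear"` (default) or `"cubic"`.
#' @return A [paleo_ts] sampled exactly at `grid`.
#' @examples
#' s <- paleo_ts(c(0, 10), c(0, 10))
#' interpolate_series(s, 5)$values  # 5
#' @export
interpolate_series <- function(series, grid, method = c("linear", "cubic")) {
  stopifnot(inherits(series, "paleo_ts"))
  method <- match.arg(method)
  if (!is.numeric(grid) || length(grid) < 1L || anyNA(grid))
    stop("'grid' must be a non-empty numeric vector of ages", call. = FALSE)
  grid <- sort(grid)
  if (anyDuplicated(grid)) stop("duplicate ages in 'grid'", call. = FALSE)
  lo <- min(series$ages); hi <- max(series$ages)
  out <- grid < lo | grid > hi
  if (any(out))
    stop(sprintf("no extrapolation: grid ages outside [%.6g, %.6g] Ma of '%s': %s",
                 lo, hi, series$name,
                 paste(format(grid[out]), collapse = ", ")), call. = FALSE)
  vals <- if (method == "linear") {
    stats::approx(series$ages, series$values, xout = grid, ties = "ordered")$y
  } else {
    if (length(series$ages) < 4L)
      stats::spline(series$ages, series$values, xout = grid, method = "natural")$y
    else
      stats::spline(series$ages, series$values, xout = grid, method = "fmm")$y
  }
  paleo_ts(grid, vals, name = series$name, units = series$units)
}

#' Project a set of time series onto a common base grid
#'
#' Resamples every series in `series_list` onto the age grid of `base`
#' (typically the shortest, most coarsely sampled series — the diversity
#' curve). The base grid can first be trimmed to the intersection of all
#' series' spans (`trim = TRUE`, the default, with a warning listing dropped
#' ages), or a series failing to cover the base span can be a hard error
#' (`trim = FALSE`). Extrapolation never happens either way.
#'
#' @param series_list a (optionally named) list of [paleo_ts] objects.
#' @param base a [paleo_ts] supplying the target grid.
#' @param method interpolation method passed to [interpolate_series()];
#'   default linear.
#' @param trim logical; trim the base grid to the common span (default) or
#'   error on non-covering series.
#' @return A list of [paleo_ts], same names/order as `series_list`, all on
#'   the (possibly trimmed) base grid, with the grid attached as attribute
#'   `"grid"`.
#' @export
align_series <- function(series_list, base, method = c("linear", "cubic"),
                         trim = TRUE) {
  stopifnot(inherits(base, "paleo_ts"))
  if (inherits(series_list, "paleo_ts")) series_list <- list(series_list)
  stopifnot(all(vapply(series_list, inherits, logical(1), "paleo_ts")))
  method <- match.arg(method)
  grid <- base$ages
  lo <- max(vapply(series_list, function(s) min(s$ages), numeric(1)))
  hi <- min(vapply(series_list, function(s) max(s$ages), numeric(1)))
  covered <- grid >= lo & grid <= hi
  if (!all(covered)) {
    if (!trim) {
      for (s in series_list) {
        if (min(s$ages) > min(grid) || max(s$ages) < max(grid))
          stop(sprintf("series '%s' [%.6g, %.6g] Ma does not cover the base span [%.6g, %.6g] Ma",
                       s$name, min(s$ages), max(s$ages), min(grid), max(grid)),
               call. = FALSE)
      }
    }
    warning(sprintf("base grid trimmed to common span [%.6g, %.6g] Ma; dropped ages: %s",
                    lo, hi, paste(format(grid[!covered]), collapse = ", ")),
            call. = FALSE)
    grid <- grid[covered]
    if (length(grid) < 2L)
      stop("fewer than 2 base grid points remain inside the common span",
           call. = FALSE)
  }
  out <- lapply(series_list, interpolate_series, grid = grid, method = method)
  names(out) <- names(series_list)
  attr(out, "grid") <- grid
  out
}

#' Normalize a time series by its mean or maximum
#'
#' Divides the values by the series mean (`mode = "mean"`, so the output has
#' mean exactly 1) or by the series maximum (`mode = "max"`, so all values are
#' at most 1 with at least one equal to 1). Normalization is idempotent.
#'
#' @param series a [paleo_ts].
#' @param mode `"mean"` (default, used in the causal analysis) or `"max"`
#'   (a display convention).
#' @return The normalized [paleo_ts] (units become dimensionless).
#' @export
normalize_series <- function(series, mode = c("mean", "max")) {
  stopifnot(inherits(series, "paleo_ts"))
  mode <- match.arg(mode)
  div <- if (mode == "mean") mean(series$values) else max(series$values)
  if (div == 0)
    stop("cannot normalize '", series$name, "': ", mode, " of values is zero",
         call. = FALSE)
  paleo_ts(series$ages, series$values / div,
           name = series$name, units = "dimensionless")
}

# Values in dynamical (oldest -> youngest) order: the order in which the
# system actually evolved, required by delay embedding.
dyn_values <- function(x) {
  if (inherits(x, "paleo_ts")) rev(x$values) else as.numeric(x)
}

# Check two series share an identical age grid.
same_grid <- function(a, b) {
  length(a$ages) == length(b$ages) && all(a$ages == b$ages)
}
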