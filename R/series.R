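#' Serum concentration time series
#'
#' Container for one hormone's simulated or observed serum trajectory:
#' strictly increasing time points (h), non-negative concentrations, and
#' the concentration unit the values are expressed in. All arithmetic in
#' the package checks units before mixing series.
#'
#' @param times time points (h), strictly increasing.
#' @param values concentrations at `times`, same length, all `>= 0`.
#' @param unit concentration unit label, e.g. `"ng/mL"` or `"pg/mL"`.
#' @param hormone optional hormone label carried along for reporting.
#' @return An object of class `conc_series`.
#' @examples
#' s <- conc_series(0:5, exp(-0.1 * 0:5), unit = "ng/mL")
#' as.data.frame(s)
#' @export
conc_series <- function(times, values, unit, hormone = NULL) {
  if (!is.numeric(times) || !is.numeric(values) ||
      length(times) != length(values) || length(times) == 0L) {
    stop("`times` and `values` must be numeric vectors of equal, ",
         "positive length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  if (!is.character(unit) || length(unit) != 1L) {
    stop("`unit` must be a single string", call. = FALSE)
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 unit = unit, hormone = hormone),
            class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat("<conc_series>", if (!is.null(x$hormone)) x$hormone else "",
      length(x$times), "points over [", min(x$times), ",", max(x$times),
      "] h, unit", x$unit, "\n")
  cat("  range [", format(min(x$values), digits = 4), ",",
      format(max(x$values), digits = 4), "]", x$unit, "\n")
  invisible(x)
}

#' @export
as.data.frame.conc_series <- function(x, ...) {
  data.frame(time_h = x$times, concentration = x$values)
}

#' @export
length.conc_series <- function(x) length(x$times)

#' @export
plot.conc_series <- function(x, ...) {
  plot(x$times, x$values, type = "l",
       xlab = "time (h)",
       ylab = paste0("concentration (", x$unit, ")"), ...)
}

# error unless two series share a unit
check_same_unit <- function(a, b) {
  if (!identical(a$unit, b$unit)) {
    stop("concentration unit mismatch: ", a$unit, " vs ", b$unit,
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write concentration series as CSV
#'
#' The on-disk dialect is a two-column CSV with header
#' `time_h,concentration`, preceded by a comment line `# unit: <unit>`
#' (and optionally `# hormone: <label>`). Values are written with 6
#' significant digits so repeated runs are byte-identical.
#'
#' @param x a [conc_series()].
#' @param path file path.
#' @return `write_series_csv()` returns `path` invisibly;
#'   `read_series_csv()` returns a [conc_series()].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_series_csv(conc_series(0:3, c(0, 1, 2, 1.5), "ng/mL"), f)
#' read_series_csv(f)
#' @export
write_series_csv <- function(x, path) {
  stopifnot(inherits(x, "conc_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", x$unit), con)
  if (!is.null(x$hormone)) writeLines(paste0("# hormone: ", x$hormone), con)
  writeLines("time_h,concentration", con)
  writeLines(paste(format(signif(x$times, 6), trim = TRUE, scientific = FALSE),
                   format(signif(x$values, 6), trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  unit <- sub("^# unit:\\s*", "", grep("^# unit:", meta, value = TRUE))
  if (length(unit) != 1L) {
    stop("missing `# unit:` comment line in ", path, call. = FALSE)
  }
  hormone <- sub("^# hormone:\\s*", "",
                 grep("^# hormone:", meta, value = TRUE))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  if (!all(c("time_h", "concentration") %in% names(df))) {
    stop("expected columns `time_h,concentration` in ", path, call. = FALSE)
  }
  conc_series(df$time_h, df$concentration, unit = unit,
              hormone = if (length(hormone) == 1L) hormone else NULL)
}
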