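#' Annual time series with provenance flags
#'
#' The basic container moved between pipeline stages: one year-indexed
#' variable together with its units, a missing-value mask, and provenance
#' flags recording which transformations have been applied. The flags are
#' monotone -- once a series is marked `detrended` it stays so -- which lets
#' downstream stages enforce the required processing order (aggregate ->
#' adjust -> interpolate -> zscore -> detrend).
#'
#' @param years integer vector of calendar years, strictly increasing.
#' @param values numeric vector, same length as `years`; `NA` marks a
#'   missing year retained in the grid.
#' @param variable variable name (single string).
#' @param units unit string carried as metadata (never converted).
#' @param interpolated logical vector flagging values filled by
#'   interpolation (default: none).
#' @param adjusted,zscored,detrended scalar provenance flags.
#' @return An object of class `annual_series`.
#' @examples
#' s <- annual_series(2000:2005, rnorm(6), "cb153", "ug/g lw")
#' s$values
#' @export
annual_series <- function(years, values, variable = "x", units = "",
                          interpolated = rep(FALSE, length(years)),
                          adjusted = FALSE, zscored = FALSE,
                          detrended = FALSE) {
  years <- as.integer(years)
  if (length(years) != length(values))
    stop("years and values must have equal length")
  if (length(years) > 1L && any(diff(years) <= 0L))
    stop("years must be strictly increasing")
  if (length(interpolated) != length(years))
    stop("interpolated mask must match years")
  structure(
    list(years = years, values = as.numeric(values),
         variable = as.character(variable)[1L], units = as.character(units)[1L],
         interpolated = as.logical(interpolated),
         adjusted = isTRUE(adjusted), zscored = isTRUE(zscored),
         detrended = isTRUE(detrended)),
    class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  flags <- c(adjusted = x$adjusted, zscored = x$zscored,
             detrended = x$detrended)
  cat(sprintf("<annual_series> %s [%s], %d years (%d-%d)%s\n",
              x$variable, x$units, length(x$years),
              min(x$years), max(x$years),
              if (any(flags)) paste0(" | ", paste(names(flags)[flags],
                                                  collapse = ", ")) else ""))
  if (any(x$interpolated))
    cat("  interpolated years:",
        paste(x$years[x$interpolated], collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = x$years, value = x$values,
             interpolated = x$interpolated, stringsAsFactors = FALSE)
}

#' @rdname annual_series
#' @param x object to test.
#' @export
is_annual_series <- function(x) inherits(x, "annual_series")

# Internal: assert an annual_series argument, with a helpful caller name.
assert_series <- function(x, what = "series") {
  if (!is_annual_series(x))
    stop(sprintf("%s must be an annual_series object", what))
  invisible(x)
}
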