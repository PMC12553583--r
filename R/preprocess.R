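#' Lipid-normalize a wet-weight concentration
#'
#' Converts a concentration expressed per gram fresh (wet) tissue to a
#' concentration per gram extracted lipid, the standard reporting basis for
#' lipophilic organochlorines (PCBs, PCDD/Fs) in fish-monitoring programmes.
#'
#' @param conc_wet concentration per g wet weight (any mass unit).
#' @param lipid_fraction lipid content as a fraction in (0, 1].
#' @return concentration per g lipid weight, `conc_wet / lipid_fraction`.
#' @examples
#' lipid_normalize(2.0, 0.04)  # 50
#' @export
lipid_normalize <- function(conc_wet, lipid_fraction) {
  if (any(!is.finite(lipid_fraction)) || any(lipid_fraction <= 0))
    stop("lipid_fraction must be > 0")
  conc_wet / lipid_fraction
}

#' WHO 2005 toxic equivalency factors for the 17 PCDD/F congeners
#'
#' Returns the packaged TEF table (Van den Berg et al. 2006 re-evaluation)
#' for the seventeen 2,3,7,8-substituted dioxin and furan congeners.
#'
#' @return data.frame with columns `congener` and `tef`.
#' @export
default_tefs <- function() {
  path <- system.file("extdata", "tef_who2005.csv",
                      package = "herringdrivers", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 17L, all(tab$tef > 0), all(tab$tef <= 1))
  tab
}

#' Lower-bound TEQ of a dioxin/furan congener panel
#'
#' Computes the toxic equivalent (TEQ) of a set of congener concentrations
#' using the lower-bound convention: any concentration below its limit of
#' detection contributes zero. Every congener present must have a TEF.
#'
#' @param congeners named numeric vector of congener concentrations (pg/g).
#' @param lods named numeric vector of limits of detection, matched by name;
#'   a congener absent from `lods` is treated as detected (LOD 0).
#' @param tefs TEF table as returned by [default_tefs()], or a named numeric
#'   vector of factors.
#' @return TEQ in pg TEQ/g (same mass basis as the input concentrations).
#' @examples
#' compute_teq(c(tcdd_2378 = 1, ocdd = 100),
#'             lods = c(tcdd_2378 = 0.01, ocdd = 0.01))
#' @export
compute_teq <- function(congeners, lods = NULL, tefs = default_tefs()) {
  if (is.data.frame(tefs)) tefs <- stats::setNames(tefs$tef, tefs$congener)
  ids <- names(congeners)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("congeners must be a named vector")
  unknown <- setdiff(ids, names(tefs))
  if (length(unknown))
    stop("no TEF for congener(s): ", paste(unknown, collapse = ", "))
  lod <- rep(0, length(ids))
  if (!is.null(lods)) {
    hit <- ids %in% names(lods)
    lod[hit] <- lods[ids[hit]]
  }
  use <- ifelse(congeners >= lod, congeners, 0)
  sum(tefs[ids] * use)
}

#' Aggregate individual records to one annual value
#'
#' Collapses per-individual measurements to a single value per sampled year,
#' by geometric mean (the convention for log-normal-like contaminant data;
#' requires strictly positive values) or arithmetic mean (for delta-scale
#' isotope values, which can be negative).
#'
#' @param records data.frame with a `year` column and the measurement column.
#' @param variable name of the measurement column.
#' @param method `"geometric"` or `"arithmetic"`.
#' @param units unit string stored on the result.
#' @return an [annual_series] with one value per sampled year.
#' @export
annual_aggregate <- function(records, variable,
                             method = c("geometric", "arithmetic"),
                             units = "") {
  method <- match.arg(method)
  if (!all(c("year", variable) %in% names(records)))
    stop("records must contain columns 'year' and '", variable, "'")
  vals <- records[[variable]]
  yrs <- records$year
  keep <- !is.na(vals)
  vals <- vals[keep]; yrs <- yrs[keep]
  if (!length(vals)) stop("no non-missing values for ", variable)
  uy <- sort(unique(yrs))
  out <- vapply(uy, function(y) {
    v <- vals[yrs == y]
    if (method == "geometric") {
      if (any(v <= 0))
        stop(sprintf("geometric mean undefined for non-positive value(s) of %s in year %d",
                     variable, y))
      exp(mean(log(v)))
    } else mean(v)
  }, numeric(1))
  annual_series(uy, out, variable = variable, units = units)
}

#' Fit a covariate (body-length) confounding adjustment model
#'
#' Ordinary least-squares regression of a variable against a covariate
#' (typically total length, TL), following the monitoring-programme practice
#' of testing each biological variable for a length confounder. The
#' adjustment is applied downstream only when the regression is significant
#' at `alpha`.
#'
#' @param values numeric response (e.g. per-fish age).
#' @param covariate numeric covariate (e.g. per-fish TL, cm).
#' @param alpha significance level gating application (default 0.05).
#' @return object of class `adjustment_model`: slope `A` (response units per
#'   covariate unit), `covariate_mean`, `r2`, `p_value`, `applied`.
#' @export
fit_covariate_adjustment <- function(values, covariate, alpha = 0.05) {
  ok <- stats::complete.cases(values, covariate)
  values <- values[ok]; covariate <- covariate[ok]
  if (length(values) < 2L) stop("need at least 2 paired observations")
  if (stats::var(covariate) == 0) stop("covariate has zero variance")
  fit <- stats::lm(values ~ covariate)
  sm <- suppressWarnings(summary(fit))  # saturated/exact fits handled below
  A <- unname(stats::coef(fit)[2L])
  # with n = 2 the fit is saturated; p is undefined -> never applied
  p <- if (nrow(sm$coefficients) == 2L && ncol(sm$coefficients) == 4L &&
           sm$df[2L] > 0L) sm$coefficients[2L, 4L] else NA_real_
  if (stats::var(values) == 0) { A <- 0; p <- 1 }
  structure(list(A = A, covariate_mean = mean(covariate),
                 r2 = sm$r.squared, p_value = p,
                 applied = is.finite(p) && p < alpha, alpha = alpha,
                 n = length(values)),
            class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat(sprintf("<adjustment_model> A = %.4g, r2 = %.3f, p = %.3g, %s (n = %d)\n",
              x$A, x$r2, x$p_value,
              if (x$applied) "applied" else "not applied", x$n))
  invisible(x)
}

#' Adjust values to the covariate mean
#'
#' Standardizes measurements to a common covariate value:
#' `adjusted = measured + A * (mean(covariate) - covariate)`, i.e. each value
#' is re-expressed as if its fish had the series-average length. When `A` is
#' the OLS slope and the stored mean is the covariate mean of the same data,
#' the adjustment preserves the mean of `values` exactly.
#'
#' @param values measured values.
#' @param covariate the per-observation covariate (same length).
#' @param model an `adjustment_model` from [fit_covariate_adjustment()].
#' @param force apply even when `model$applied` is `FALSE` (default errors).
#' @return adjusted values.
#' @export
adjust_values <- function(values, covariate, model, force = FALSE) {
  if (!inherits(model, "adjustment_model")) stop("model must be an adjustment_model")
  if (!model$applied && !force)
    stop("adjustment model not significant at alpha = ", model$alpha,
         "; pass force = TRUE to apply anyway")
  values + model$A * (model$covariate_mean - covariate)
}

# ---- Stineman (1980) interpolation -----------------------------------------

# Stineman slope estimates: interior slopes weight adjacent secant slopes by
# the squared chord length of the *other* interval; end slopes extrapolate
# from the two nearest secants. Reproduces straight lines exactly.
stineman_slopes <- function(x, y) {
  m <- length(x)
  dx <- diff(x); dy <- diff(y)
  s <- dy / dx
  if (m == 2L) return(rep(s, 2L))
  yp <- numeric(m)
  dx2dy2 <- dx^2 + dy^2
  i <- 2:(m - 1L)
  yp[i] <- (s[i - 1L] * dx2dy2[i] + s[i] * dx2dy2[i - 1L]) /
    (dx2dy2[i - 1L] + dx2dy2[i])
  yp[1L] <- s[1L] * (1 + dx[1L] / (dx[1L] + dx[2L])) -
    s[2L] * dx[1L] / (dx[1L] + dx[2L])
  yp[m] <- s[m - 1L] * (1 + dx[m - 1L] / (dx[m - 1L] + dx[m - 2L])) -
    s[m - 2L] * dx[m - 1L] / (dx[m - 1L] + dx[m - 2L])
  # sign-consistency clamp: the rational interpolant is shape-preserving
  # only when each slope agrees in sign with its adjoining secants; at
  # local extrema (or when the endpoint extrapolation flips sign) the
  # slope is set to zero, per Stineman's consistency requirement
  yp[i][s[i - 1L] * s[i] <= 0] <- 0
  if (yp[1L] * s[1L] < 0) yp[1L] <- 0
  if (yp[m] * s[m - 1L] < 0) yp[m] <- 0
  yp
}

# Rational interpolant between knots given slope estimates; shape-preserving
# (no overshoot between monotone knots).
stineman_eval <- function(x, y, yp, xout) {
  idx <- findInterval(xout, x, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx >= length(x)] <- length(x) - 1L
  x1 <- x[idx]; x2 <- x[idx + 1L]
  y1 <- y[idx]; y2 <- y[idx + 1L]
  s <- (y2 - y1) / (x2 - x1)
  yo <- y1 + s * (xout - x1)
  dy1 <- (yp[idx] - s) * (xout - x1)       # tangent-at-left minus secant
  dy2 <- (yp[idx + 1L] - s) * (xout - x2)  # tangent-at-right minus secant
  out <- yo
  prod12 <- dy1 * dy2
  same <- is.finite(prod12) & prod12 > 0
  opp <- is.finite(prod12) & prod12 < 0
  out[same] <- yo[same] + prod12[same] / (dy1[same] + dy2[same])
  if (any(opp)) {
    dxi <- (xout - x1) + (xout - x2)
    out[opp] <- yo[opp] + prod12[opp] * dxi[opp] /
      ((dy1[opp] - dy2[opp]) * (x2[opp] - x1[opp]))
  }
  exact <- xout %in% x
  out[exact] <- y[match(xout[exact], x)]
  out
}

#' Fill interior gaps of an annual series by Stineman interpolation
#'
#' Missing interior years are filled with the shape-preserving rational
#' interpolation of Stineman (1980), the method used by common time-series
#' imputation packages. Observed values are never modified and no
#' extrapolation is performed: leading or trailing missing values are an
#' error.
#'
#' @param series an [annual_series] possibly containing `NA` values.
#' @return the series with gaps filled and `interpolated` flags set.
#' @export
stineman_interpolate <- function(series) {
  assert_series(series)
  miss <- is.na(series$values)
  if (!any(miss)) return(series)
  if (miss[1L] || miss[length(miss)])
    stop("leading/trailing missing values in '", series$variable,
         "': interpolation does not extrapolate")
  x <- as.numeric(series$years[!miss])
  y <- series$values[!miss]
  if (length(x) < 3L) stop("need >= 3 observed points to interpolate")
  yp <- stineman_slopes(x, y)
  filled <- series
  filled$values[miss] <- stineman_eval(x, y, yp,
                                       as.numeric(series$years[miss]))
  filled$interpolated <- series$interpolated | miss
  filled
}

#' Z-score normalize an annual series
#'
#' Mean-centers and variance-standardizes (sample SD, n-1 denominator) so
#' trend and regression stages compare relative rather than absolute change.
#'
#' @param series an [annual_series] with no missing values.
#' @return the standardized series with the `zscored` flag set.
#' @export
zscore <- function(series) {
  assert_series(series)
  v <- series$values
  if (any(is.na(v))) stop("interpolate before z-scoring: series has NA")
  if (length(v) < 2L) stop("need >= 2 values")
  s <- stats::sd(v)
  if (s == 0) stop("zero variance in '", series$variable, "'")
  out <- series
  out$values <- (v - mean(v)) / s
  out$zscored <- TRUE
  out$units <- "z"
  out
}

#' Linearly detrend an annual series against year
#'
#' Removes the shared-time-trend component before regression, applying the
#' length-adjustment identity with year as the covariate:
#' `value + A_year * (mean(year) - year)` with `A_year` the OLS slope of
#' value on year. Equivalent to OLS residuals plus the series mean; the mean
#' is preserved exactly and the output regressed on year has slope 0.
#'
#' @param series an [annual_series] with no missing values.
#' @return the detrended series with the `detrended` flag set.
#' @export
detrend <- function(series) {
  assert_series(series)
  v <- series$values
  if (any(is.na(v))) stop("interpolate before detrending: series has NA")
  if (length(v) < 3L) stop("need >= 3 values")
  yr <- as.numeric(series$years)
  A <- stats::cov(v, yr) / stats::var(yr)
  out <- series
  out$values <- v + A * (mean(yr) - yr)
  out$detrended <- TRUE
  out
}
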