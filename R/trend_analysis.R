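#' Single-breakpoint segmented trend classification
#'
#' Scans all admissible single-break partitions of an annual series, chooses
#' the break minimizing the total residual sum of squares of the two
#' segment-wise linear fits, and compares that model against the no-break
#' linear fit by BIC. Each retained segment gets an OLS fit whose slope is
#' tested two-sided at `alpha` and classified as increasing, decreasing or
#' no trend.
#'
#' The breakpoint year reported is the first year of the second segment.
#' RSS ties are broken toward the earlier break year. The BIC of the break
#' model counts 6 parameters (two intercepts, two slopes, the break
#' position, the error variance) against 3 for the null, which is
#' conservative toward the no-break model.
#'
#' @param series an [annual_series], z-scored upstream (flag warned on, not
#'   enforced, so the routine is usable on raw series too).
#' @param min_segment minimum observations per segment; default
#'   `max(3, ceiling(0.15 * n))`, mirroring common structural-change
#'   trimming.
#' @param alpha two-sided significance level for segment slopes.
#' @return object of class `trend_result`: `breakpoint_year` (NA when the
#'   null is selected), `segments` (data.frame of start/end year, slope,
#'   p-value, direction, df flag), `bic_null`, `bic_break`,
#'   `selected_model`, `rss_null`, `rss_break`.
#' @export
fit_segmented <- function(series, min_segment = NULL, alpha = 0.05) {
  assert_series(series)
  yr <- as.numeric(series$years)
  v <- series$values
  if (any(is.na(v))) stop("series has missing values; interpolate first")
  n <- length(v)
  if (is.null(min_segment)) min_segment <- max(3L, ceiling(0.15 * n))
  if (n < 2L * min_segment)
    stop(sprintf("series too short (n = %d) for min_segment = %d", n,
                 min_segment))

  seg_rss <- function(idx) {
    f <- stats::lm.fit(cbind(1, yr[idx]), v[idx])
    sum(f$residuals^2)
  }
  # candidate split j: segment 1 = 1..j, segment 2 = (j+1)..n
  cand <- seq.int(min_segment, n - min_segment)
  rss <- vapply(cand, function(j) {
    seg_rss(seq_len(j)) + seg_rss(seq.int(j + 1L, n))
  }, numeric(1))
  # earliest split within numerical tolerance of the minimum RSS: ties
  # (e.g. a continuous noiseless kink, where either adjacent split is
  # exact) resolve toward the earlier break year
  rss_tol <- 1e-9 * sum(v^2) + 1e-12
  j_best <- cand[which(rss <= min(rss) + rss_tol)[1L]]
  rss_break <- min(rss)
  rss_null <- seg_rss(seq_len(n))

  gauss_bic <- function(rss, k) {
    # profile log-likelihood of the Gaussian linear model
    rss <- max(rss, .Machine$double.eps)
    n * log(rss / n) + k * log(n)
  }
  bic_null <- gauss_bic(rss_null, 3L)
  bic_break <- gauss_bic(rss_break, 6L)
  use_break <- bic_break < bic_null

  seg_fit <- function(idx) {
    yy <- v[idx]; xx <- yr[idx]
    fit <- stats::lm(yy ~ xx)
    sm <- summary(fit)
    slope <- unname(stats::coef(fit)[2L])
    df <- fit$df.residual
    p <- if (df > 0L && stats::var(yy) > 0)
      sm$coefficients[2L, 4L] else NA_real_
    direction <- if (is.finite(p) && p < alpha) {
      if (slope > 0) "increasing" else "decreasing"
    } else "no trend"
    data.frame(start_year = min(xx), end_year = max(xx), n = length(idx),
               slope = slope, p_value = p, direction = direction,
               short_segment = df < 2L, stringsAsFactors = FALSE)
  }
  segments <- if (use_break) {
    rbind(seg_fit(seq_len(j_best)), seg_fit(seq.int(j_best + 1L, n)))
  } else seg_fit(seq_len(n))

  structure(list(
    variable = series$variable,
    breakpoint_year = if (use_break) series$years[j_best + 1L] else NA_integer_,
    segments = segments,
    bic_null = bic_null, bic_break = bic_break,
    rss_null = rss_null, rss_break = rss_break,
    selected_model = if (use_break) "break" else "null",
    min_segment = min_segment, alpha = alpha),
    class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> %s: %s model", x$variable, x$selected_model))
  if (x$selected_model == "break")
    cat(sprintf(" (breakpoint %d)", x$breakpoint_year))
  cat(sprintf("; BIC null %.2f vs break %.2f\n", x$bic_null, x$bic_break))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Trend table for a list of series
#'
#' Applies [fit_segmented()] to each series and stacks a flat results table
#' (one row per segment) suitable for CSV export.
#'
#' @param series_list list of [annual_series] objects.
#' @param ... passed to [fit_segmented()].
#' @return data.frame with variable, breakpoint, segment ranges, slopes,
#'   p-values, directions and BICs.
#' @export
trend_table <- function(series_list, ...) {
  do.call(rbind, lapply(series_list, function(s) {
    tr <- fit_segmented(s, ...)
    cbind(data.frame(variable = tr$variable,
                     breakpoint_year = tr$breakpoint_year,
                     selected_model = tr$selected_model,
                     bic_null = tr$bic_null, bic_break = tr$bic_break,
                     stringsAsFactors = FALSE),
          tr$segments, row.names = NULL)
  }))
}
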