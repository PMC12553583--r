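#' Cross-correlation screen for lagged predictor effects
#'
#' Computes the lagged Pearson correlation between a predictor leading the
#' response by k = 0..`max_lag` years: `ccf(k) = cor(x[t-k], y[t])` over the
#' overlapping window. A lag is flagged significant when |ccf| exceeds the
#' conventional white-noise bound `1.96 / sqrt(n)` (n the full aligned
#' length, as drawn on standard ccf plots). Both series should be detrended
#' and z-scored upstream so shared trends do not masquerade as lagged
#' effects. Lags whose overlap drops below 4 points are omitted with a
#' warning.
#'
#' @param x predictor [annual_series].
#' @param y response [annual_series] on the same year grid.
#' @param max_lag maximum predictor lead in years (default 5, the life span
#'   of the fish sampled).
#' @return data.frame of class `lag_screen` with columns predictor, lag,
#'   ccf, bound, significant, n_overlap.
#' @export
cross_correlation <- function(x, y, max_lag = 5L) {
  assert_series(x, "x"); assert_series(y, "y")
  if (!identical(x$years, y$years))
    stop("x and y must share an identical year grid")
  n <- length(x$years)
  if (n < 8L) stop("need >= 8 aligned years")
  bound <- 1.96 / sqrt(n)
  rows <- lapply(0:max_lag, function(k) {
    xs <- x$values[seq_len(n - k)]          # x at t - k
    ys <- y$values[seq.int(k + 1L, n)]      # y at t
    if (length(xs) < 4L) {
      warning(sprintf("lag %d omitted: overlap %d < 4", k, length(xs)))
      return(NULL)
    }
    r <- stats::cor(xs, ys)
    data.frame(predictor = x$variable, lag = k, ccf = r, bound = bound,
               significant = is.finite(r) && abs(r) > bound,
               n_overlap = length(xs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lag_screen", class(out))
  out
}

#' Screen many predictors against one response
#'
#' @param predictors named list of predictor [annual_series].
#' @param response response [annual_series].
#' @param max_lag maximum lag tested.
#' @return combined lag-screen table over all predictors.
#' @export
lag_screen_table <- function(predictors, response, max_lag = 5L) {
  out <- do.call(rbind, lapply(predictors, cross_correlation, y = response,
                               max_lag = max_lag))
  rownames(out) <- NULL
  out
}

#' Augment a predictor matrix with significant lagged copies
#'
#' Adds one column per significant lag spec, named `<predictor>_lag<k>`,
#' holding the source series shifted forward by k years. Rows (years) for
#' which any lagged value would reach before the start of the data are
#' dropped from the analysis window; the drop is recorded in the
#' `dropped_years` attribute. Lag-0 specs are never added (they would
#' duplicate the source column).
#'
#' @param X data.frame predictor matrix with a `year` column.
#' @param specs lag-screen table (rows with `significant = TRUE` are used;
#'   pre-filtered tables work too).
#' @return data.frame with the added columns and reduced analysis window;
#'   attributes `dropped_years` and `added_columns`.
#' @export
build_lagged_matrix <- function(X, specs) {
  if (!"year" %in% names(X)) stop("X must contain a 'year' column")
  use <- specs[specs$significant & specs$lag > 0L, , drop = FALSE]
  key <- paste(use$predictor, use$lag)
  if (anyDuplicated(key)) stop("duplicate lag spec: ",
                               key[duplicated(key)][1L])
  if (!nrow(use)) {
    attr(X, "dropped_years") <- integer()
    attr(X, "added_columns") <- character()
    return(X)
  }
  out <- X
  added <- character()
  for (i in seq_len(nrow(use))) {
    pn <- use$predictor[i]; k <- use$lag[i]
    if (!pn %in% names(X)) stop("unknown predictor in spec: ", pn)
    col <- paste0(pn, "_lag", k)
    idx <- match(X$year - k, X$year)   # value k years earlier
    out[[col]] <- X[[pn]][idx]
    added <- c(added, col)
  }
  keep <- stats::complete.cases(out[, added, drop = FALSE])
  dropped <- X$year[!keep]
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_years") <- dropped
  attr(out, "added_columns") <- added
  out
}
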