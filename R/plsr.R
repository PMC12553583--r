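#' PLS1 regression by NIPALS
#'
#' Classical single-response partial least squares (PLS1) fitted by the
#' NIPALS algorithm. Both blocks are column-standardized internally
#' (centering and unit sample SD; parameters stored for prediction). For
#' each component a: `w_a = X'y / ||X'y||`, `t_a = X w_a`,
#' `p_a = X't_a / (t_a't_a)`, `q_a = y't_a / (t_a't_a)`, then X and y are
#' deflated. Regression coefficients on the standardized scale are
#' `b = W (P'W)^-1 q`. Weight columns have unit norm and score columns are
#' mutually orthogonal; with as many components as (full-rank) predictors
#' the coefficients coincide with OLS.
#'
#' @param X numeric matrix or data.frame, n x p, no missing values.
#' @param y numeric response of length n.
#' @param ncomp number of latent components A (1 <= A <= rank limit).
#' @return object of class `plsr_model`: `weights` W (p x A), `x_loadings`
#'   P, `scores` T (n x A), `y_loadings` q, `coef` (standardized scale),
#'   `r2y` (cumulative per component), `fitted`, `residuals` (original y
#'   scale), `x_center`, `x_scale`, `y_center`, `y_scale`, `ssy` (explained
#'   y-variance per component, standardized), `predictors`.
#' @export
nipals_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y")
  if (n < ncomp + 2L) stop("need n >= ncomp + 2")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  xc <- colMeans(X); xs <- apply(X, 2L, stats::sd)
  bad <- which(xs == 0)
  if (length(bad))
    stop("zero-variance predictor column(s): ",
         paste(colnames(X)[bad], collapse = ", "))
  if (ncomp > qr(scale(X))$rank)
    stop("ncomp exceeds the rank of X")
  yc <- mean(y); ys <- stats::sd(y)
  if (ys == 0) stop("response has zero variance")
  Xs <- scale(X, center = xc, scale = xs)
  ysd <- (y - yc) / ys

  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  ssy <- numeric(ncomp)
  Xd <- Xs; yd <- ysd
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) stop("degenerate component ", a,
                                       ": X'y is zero")
    w <- w / nw
    t_ <- Xd %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xd, t_) / tt
    q_ <- sum(yd * t_) / tt
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
    ssy[a] <- q_^2 * tt                      # y-variance captured by comp a
    Xd <- Xd - t_ %*% t(p_)
    yd <- yd - q_ * t_
  }
  B <- drop(W %*% solve(crossprod(P, W), q)) # standardized-scale coefficients
  names(B) <- colnames(X)
  fitted_std <- Xs %*% B
  tss <- sum(ysd^2)
  r2y <- vapply(seq_len(ncomp), function(a) {
    res <- ysd - Xs %*% (W[, seq_len(a), drop = FALSE] %*%
      solve(crossprod(P[, seq_len(a), drop = FALSE],
                      W[, seq_len(a), drop = FALSE]), q[seq_len(a)]))
    1 - sum(res^2) / tss
  }, numeric(1))
  rownames(W) <- rownames(P) <- colnames(X)
  structure(list(ncomp = ncomp, weights = W, x_loadings = P, scores = Tm,
                 y_loadings = q, coef = B, r2y = r2y, ssy = ssy,
                 fitted = drop(fitted_std) * ys + yc,
                 residuals = y - (drop(fitted_std) * ys + yc),
                 x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
                 predictors = colnames(X), n = n, p = p),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d component(s), %d predictors, n = %d\n",
              x$ncomp, x$p, x$n))
  cat("R2Y (cumulative):", paste(sprintf("%.3f", x$r2y), collapse = " "),
      "\n")
  invisible(x)
}

#' Predict from a fitted PLS1 model
#'
#' @param object a `plsr_model`.
#' @param newdata matrix/data.frame with the model's predictor columns.
#' @param ... unused.
#' @return predictions on the original response scale.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)[, object$predictors, drop = FALSE]
  Xs <- scale(Xn, center = object$x_center, scale = object$x_scale)
  drop(Xs %*% object$coef) * object$y_scale + object$y_center
}

#' Leave-one-out cross-validation of PLS1
#'
#' For each held-out observation the model (including column
#' standardization) is refitted on the remaining n-1 rows and the held-out
#' response predicted, for 1..`ncomp_max` components.
#' `Q2_A = 1 - PRESS_A / TSS` where `PRESS_A` accumulates squared held-out
#' errors and TSS accumulates squared deviations of each held-out value
#' from its training-fold mean (no leakage of the left-out point into
#' centering or scaling).
#'
#' @param X predictor matrix (n x p), `y` response, n >= 6.
#' @param y numeric response.
#' @param ncomp_max maximum components assessed.
#' @return list with vectors `q2` and `press` (per component count) and
#'   `tss`.
#' @export
loo_q2 <- function(X, y, ncomp_max) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 6L) stop("need n >= 6 for leave-one-out validation")
  ncomp_max <- min(ncomp_max, ncol(X), n - 3L)
  press <- numeric(ncomp_max)
  tss <- 0
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    fit <- nipals_fit(Xi, yi, ncomp_max)
    xs <- (X[i, , drop = TRUE] - fit$x_center) / fit$x_scale
    for (a in seq_len(ncomp_max)) {
      Wa <- fit$weights[, seq_len(a), drop = FALSE]
      Pa <- fit$x_loadings[, seq_len(a), drop = FALSE]
      Ba <- Wa %*% solve(crossprod(Pa, Wa), fit$y_loadings[seq_len(a)])
      pred <- sum(xs * Ba) * fit$y_scale + fit$y_center
      press[a] <- press[a] + (y[i] - pred)^2
    }
    tss <- tss + (y[i] - mean(yi))^2
  }
  list(q2 = 1 - press / tss, press = press, tss = tss)
}

#' Select the number of PLS components
#'
#' Chooses the smallest component count whose leave-one-out PRESS is within
#' `tol` (default 5%) of the minimum PRESS over 1..`ncomp_max` -- the
#' parsimony reading of "minimum number of components" under LOO
#' validation.
#'
#' @param X,y data as in [nipals_fit()].
#' @param ncomp_max maximum components considered (capped at p and n-3).
#' @param tol relative PRESS slack.
#' @return list with `ncomp` (selected A), `q2`, `press`.
#' @export
select_components <- function(X, y, ncomp_max = 5L, tol = 0.05) {
  cv <- loo_q2(X, y, ncomp_max)
  a <- which(cv$press <= min(cv$press) * (1 + tol))[1L]
  list(ncomp = a, q2 = cv$q2, press = cv$press)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with `SSY_a` the
#' response variance explained by component a (cumulative over all fitted
#' components). Satisfies `sum_j VIP_j^2 = p`.
#'
#' @param model a fitted `plsr_model`.
#' @return named vector of VIP scores.
#' @export
vip <- function(model) {
  W2 <- model$weights^2
  s <- drop(W2 %*% model$ssy) / sum(model$ssy)
  out <- sqrt(model$p * s)
  names(out) <- model$predictors
  out
}

#' Weighted regression coefficients (WRC)
#'
#' The driver-importance statistic: each standardized regression
#' coefficient multiplied by the predictor's summed squared component
#' weights, `WRC_j = b_j * sum_a w_ja^2`. Predictors are ranked by |WRC|;
#' the sign gives the effect direction.
#'
#' @param model a fitted `plsr_model`.
#' @return named vector of signed WRC values.
#' @export
wrc <- function(model) {
  out <- model$coef * rowSums(model$weights^2)
  names(out) <- model$predictors
  out
}

#' Rank predictors by absolute WRC
#'
#' @param model a fitted `plsr_model`.
#' @return data.frame sorted by decreasing |WRC| with coefficient, VIP, WRC
#'   and effect direction.
#' @export
wrc_ranking <- function(model) {
  w <- wrc(model)
  out <- data.frame(predictor = model$predictors, coef = model$coef,
                    vip = vip(model), wrc = w,
                    direction = ifelse(w >= 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$wrc)), ]
  rownames(out) <- NULL
  out
}

#' Backward variable selection by VIP
#'
#' Iteratively fits a PLS1 model (component count re-selected each round by
#' [select_components()]), computes VIP scores and, while any predictor
#' falls below `vip_threshold`, drops the single lowest-VIP predictor
#' (alphabetical tie-break) and refits. Stops when all survivors have
#' VIP >= threshold or only two predictors remain. Lagged predictors
#' (columns named via `_lag<k>`, or listed in `lagged`) must additionally
#' improve the cross-validated fit: after VIP selection each surviving
#' lagged column is kept only if removing it decreases Q2 (retained iff
#' delta-Q2 > 0).
#'
#' @param X predictor matrix or data.frame (>= 2 columns, no year column).
#' @param y response vector.
#' @param vip_threshold retention threshold (default 0.7).
#' @param ncomp_max maximum components per fit.
#' @param lagged character vector naming lagged columns; defaults to those
#'   matching `_lag[0-9]+$`.
#' @return list with `model` (final `plsr_model`), `ncomp`, `q2` (final
#'   selected-component Q2), `trace` (data.frame of drops: predictor, vip
#'   at drop, q2 after refit, reason), `kept`.
#' @export
backward_select <- function(X, y, vip_threshold = 0.7, ncomp_max = 5L,
                            lagged = NULL) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stop("need >= 2 predictors")
  if (is.null(lagged)) lagged <- grep("_lag[0-9]+$", names(X), value = TRUE)

  fit_current <- function(Xc) {
    sel <- select_components(Xc, y, ncomp_max = ncomp_max)
    list(model = nipals_fit(Xc, y, sel$ncomp), ncomp = sel$ncomp,
         q2 = sel$q2[sel$ncomp])
  }

  trace <- list()
  cur <- fit_current(X)
  repeat {
    v <- vip(cur$model)
    if (min(v) >= vip_threshold || ncol(X) <= 2L) break
    low <- names(v)[v == min(v)]
    drop_name <- sort(low)[1L]               # deterministic tie-break
    X[[drop_name]] <- NULL
    cur <- fit_current(X)
    trace[[length(trace) + 1L]] <-
      data.frame(predictor = drop_name, vip_at_drop = min(v),
                 q2_after = cur$q2, reason = "vip",
                 stringsAsFactors = FALSE)
  }

  # lag-retention rule: a surviving lagged column must improve Q2
  for (lg in intersect(lagged, names(X))) {
    if (ncol(X) <= 2L) break
    without <- fit_current(X[, setdiff(names(X), lg), drop = FALSE])
    if (cur$q2 - without$q2 <= 0) {
      v <- vip(cur$model)
      X[[lg]] <- NULL
      cur <- without
      trace[[length(trace) + 1L]] <-
        data.frame(predictor = lg, vip_at_drop = unname(v[lg]),
                   q2_after = cur$q2, reason = "lag_no_q2_gain",
                   stringsAsFactors = FALSE)
    }
  }

  list(model = cur$model, ncomp = cur$ncomp, q2 = cur$q2,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(predictor = character(), vip_at_drop = numeric(),
                    q2_after = numeric(), reason = character(),
                    stringsAsFactors = FALSE),
       kept = names(X))
}

#' Permutation (y-scrambling) validation
#'
#' Refits the model `n_perm` times on row-permuted responses (fixed
#' predictor set; component count re-selected each time) and compares the
#' observed cross-validated Q2 with the permutation null. The p-value uses
#' the add-one rule `p = (1 + #(null >= observed)) / (1 + n_perm)`, so it
#' is never zero. R2Y is collected alongside.
#'
#' @param X predictor matrix, `y` response.
#' @param y numeric response.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed (local RNG; global state untouched).
#' @param ncomp_max maximum components per fit.
#' @return list of class `permutation_result`: `observed` (q2, r2y),
#'   `null_q2`, `null_r2y`, `p_value` (for Q2), `p_value_r2y`, `n_perm`,
#'   `seed`.
#' @export
permutation_test <- function(X, y, n_perm = 199L, seed = 1L,
                             ncomp_max = 5L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  X <- as.matrix(X)
  obs_sel <- select_components(X, y, ncomp_max = ncomp_max)
  obs_q2 <- obs_sel$q2[obs_sel$ncomp]
  obs_r2y <- nipals_fit(X, y, obs_sel$ncomp)$r2y[obs_sel$ncomp]
  perms <- with_local_seed(seed, replicate(n_perm, sample.int(length(y)),
                                           simplify = FALSE))
  null_q2 <- null_r2y <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- y[perms[[b]]]
    sel <- select_components(X, yp, ncomp_max = ncomp_max)
    null_q2[b] <- sel$q2[sel$ncomp]
    null_r2y[b] <- nipals_fit(X, yp, sel$ncomp)$r2y[sel$ncomp]
  }
  structure(list(observed = c(q2 = obs_q2, r2y = obs_r2y),
                 null_q2 = null_q2, null_r2y = null_r2y,
                 p_value = (1 + sum(null_q2 >= obs_q2)) / (1 + n_perm),
                 p_value_r2y = (1 + sum(null_r2y >= obs_r2y)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> observed Q2 = %.3f ",
                     "(R2Y = %.3f); p = %.4f over %d permutations\n"),
              x$observed["q2"], x$observed["r2y"], x$p_value, x$n_perm))
  invisible(x)
}

#' Residual autocorrelation diagnostics
#'
#' Autocorrelation function of the model residuals at lags 1..`max_lag`
#' plus the Ljung-Box portmanteau test with `max_lag` degrees of freedom.
#' Used as the independence check on the regression residuals of annual
#' series (a full ARIMA fit on ~20 residuals is unstable; the portmanteau
#' test answers the same question).
#'
#' @param model a fitted `plsr_model` (its `residuals` are used), or a
#'   numeric vector of residuals.
#' @param max_lag highest lag tested (default 5).
#' @return list with `acf` (named, lags 1..max_lag), `statistic`, `df`,
#'   `p_value`.
#' @export
residual_autocorrelation <- function(model, max_lag = 5L) {
  res <- if (inherits(model, "plsr_model")) model$residuals else
    as.numeric(model)
  n <- length(res)
  if (n <= max_lag + 2L) stop("too few residuals for max_lag = ", max_lag)
  ac <- stats::acf(res, lag.max = max_lag, plot = FALSE)$acf[-1L]
  lb <- stats::Box.test(res, lag = max_lag, type = "Ljung-Box")
  list(acf = stats::setNames(ac, paste0("lag", seq_len(max_lag))),
       statistic = unname(lb$statistic), df = max_lag,
       p_value = lb$p.value)
}

#' Pairwise collinearity screen
#'
#' Flags all unordered predictor pairs whose absolute Pearson correlation
#' meets or exceeds `threshold` (default 0.8, the conventional cut below
#' which PLSR predictor sets are accepted).
#'
#' @param X predictor matrix or data.frame (>= 2 columns).
#' @param threshold absolute-correlation flag level.
#' @return data.frame with columns var1, var2, r for flagged pairs (zero
#'   rows when none); the full correlation matrix as attribute `cor`.
#' @export
collinearity_screen <- function(X, threshold = 0.8) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need >= 2 columns")
  C <- stats::cor(X)
  idx <- which(upper.tri(C) & abs(C) >= threshold, arr.ind = TRUE)
  out <- data.frame(var1 = colnames(C)[idx[, 1L]],
                    var2 = colnames(C)[idx[, 2L]],
                    r = C[idx], stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cor") <- C
  out
}

#' Model quality gate
#'
#' The reporting rule for explanatory and predictive adequacy: a model is
#' "good" iff R2Y > 0.7 and Q2 > 0.4.
#'
#' @param r2y explanatory capacity of the final model.
#' @param q2 leave-one-out predictive capacity.
#' @return "good" or "poor".
#' @export
model_quality <- function(r2y, q2) {
  if (r2y > 0.7 && q2 > 0.4) "good" else "poor"
}
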