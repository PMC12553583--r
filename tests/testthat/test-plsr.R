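random_problem <- function(n = 30, p = 5, seed = 1, noise = 0.2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y, beta = beta)
}

test_that("first NIPALS weight is normalized X'y", {
  for (seed in 1:5) {
    pr <- random_problem(seed = seed)
    m <- nipals_fit(pr$X, pr$y, 1)
    Xs <- scale(pr$X)
    ys <- scale(pr$y)[, 1]
    w_ref <- crossprod(Xs, ys)
    w_ref <- w_ref / sqrt(sum(w_ref^2))
    expect_lt(max(abs(m$weights[, 1] - w_ref)), 1e-10)
  }
})

test_that("full-component PLS1 equals OLS; orthonormal-X case too", {
  for (seed in 1:5) {
    pr <- random_problem(seed = seed)
    m <- nipals_fit(pr$X, pr$y, 5)
    ols <- lm(scale(pr$y)[, 1] ~ scale(pr$X) - 1)
    expect_lt(max(abs(m$coef - coef(ols))), 1e-8)
  }
  # orthonormal columns
  set.seed(77)
  Q <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))
  colnames(Q) <- paste0("q", 1:4)
  y <- drop(Q %*% c(1, -2, 0.5, 3)) + rnorm(30, 0, 0.1)
  m <- nipals_fit(Q, y, 4)
  expect_lt(max(abs(m$coef - coef(lm(scale(y)[, 1] ~ scale(Q) - 1)))), 1e-8)
})

test_that("model structure invariants hold for every fit", {
  for (seed in 1:6) {
    pr <- random_problem(n = 24, p = 6, seed = seed, noise = 1)
    m <- nipals_fit(pr$X, pr$y, 4)
    # unit-norm weights
    expect_equal(colSums(m$weights^2), rep(1, 4), tolerance = 1e-12)
    # score orthogonality
    G <- crossprod(m$scores)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
    # R2Y nondecreasing
    expect_true(all(diff(m$r2y) >= -1e-12))
    # VIP identity
    expect_equal(sum(vip(m)^2), 6, tolerance = 1e-8)
  }
})

test_that("no-signal responses give near-zero R2Y at one component", {
  set.seed(123)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("x", 1:3)))
  Xs <- scale(X)
  y0 <- scale(rnorm(40))[, 1]
  y_perp <- y0 - Xs %*% qr.solve(crossprod(Xs), crossprod(Xs, y0))
  # tiny perturbation keeps X'y nonzero so NIPALS is defined; the
  # in-span energy of y is O(1e-12) of its variance
  y <- drop(y_perp) + 1e-6 * rnorm(40)
  m <- nipals_fit(X, y, 1)
  expect_lt(m$r2y[1], 1e-8)
})

test_that("degenerate inputs raise named errors", {
  pr <- random_problem()
  Xz <- pr$X
  Xz[, 2] <- 5
  expect_error(nipals_fit(Xz, pr$y, 2), "x2")
  Xr <- cbind(pr$X, x6 = pr$X[, 1] + pr$X[, 2])
  expect_error(nipals_fit(Xr, pr$y, 6), "rank")
})

test_that("LOO Q2 is near 1 on noiseless data and <= 1 always", {
  set.seed(6)
  x <- matrix(rnorm(24), 24, 1, dimnames = list(NULL, "x1"))
  y <- drop(2 * x)
  cv <- loo_q2(x, y, 1)
  expect_gte(cv$q2[1], 0.999)
  expect_true(all(cv$q2 <= 1))
  # multi-predictor fits never exceed 1 either
  X <- matrix(rnorm(24 * 3), 24, 3, dimnames = list(NULL, paste0("x", 1:3)))
  expect_true(all(loo_q2(X, rnorm(24), 3)$q2 <= 1))
})

test_that("pure-noise responses give negative mean Q2 (overfit penalty)", {
  set.seed(31)
  nsim <- 60  # full 500-run calibration lives in the acceptance suite
  q2 <- replicate(nsim, {
    X <- matrix(rnorm(24 * 5), 24, 5)
    colnames(X) <- paste0("x", 1:5)
    y <- rnorm(24)
    max(loo_q2(X, y, 3)$q2)
  })
  expect_lt(mean(q2), 0)
})

test_that("component selection takes the smallest PRESS-competitive A", {
  # one-factor data -> A* = 1
  set.seed(17)
  t1 <- rnorm(30)
  X <- outer(t1, c(1, -1, 0.5, 2)) + matrix(rnorm(120, 0, 0.05), 30)
  colnames(X) <- paste0("x", 1:4)
  y <- 3 * t1 + rnorm(30, 0, 0.2)
  expect_equal(select_components(X, y, ncomp_max = 4)$ncomp, 1L)
  expect_equal(select_components(X, y, ncomp_max = 1)$ncomp, 1L)
})

test_that("VIP and WRC formulas and symmetries", {
  # duplicated predictor pair gets equal VIP and equal WRC
  set.seed(21)
  base <- rnorm(24)
  X <- cbind(a = base + rnorm(24, 0, 1e-8), b = base + rnorm(24, 0, 1e-8),
             c = rnorm(24))
  y <- base + rnorm(24, 0.3)
  m <- nipals_fit(X, y, 1)
  v <- vip(m)
  w <- wrc(m)
  expect_equal(unname(v["a"]), unname(v["b"]), tolerance = 1e-4)
  expect_equal(unname(w["a"]), unname(w["b"]), tolerance = 1e-4)
  # A = 1: WRC_j = b_j * w_j1^2, sign matches the coefficient
  expect_equal(unname(w), unname(m$coef * m$weights[, 1]^2))
  expect_equal(sign(w), sign(m$coef))

  # p = 1 has VIP exactly 1 (single-column edge case)
  m1 <- nipals_fit(cbind(only = rnorm(20)), rnorm(20), 1)
  expect_equal(unname(vip(m1)), 1)
})

test_that("backward selection stops at threshold and is deterministic", {
  # all-strong predictors: nothing dropped
  set.seed(41)
  t1 <- rnorm(24); t2 <- rnorm(24)
  X <- cbind(a = t1, b = t2)
  y <- t1 + t2 + rnorm(24, 0, 0.1)
  sel <- backward_select(X, y)
  expect_equal(nrow(sel$trace), 0L)
  expect_setequal(sel$kept, c("a", "b"))

  # deterministic given inputs
  pr <- random_problem(n = 24, p = 6, seed = 5, noise = 2)
  s1 <- backward_select(pr$X, pr$y)
  s2 <- backward_select(pr$X, pr$y)
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$kept, s2$kept)
  # survivors all meet the threshold
  expect_true(all(vip(s1$model)[s1$kept] >= 0.7 | length(s1$kept) == 2))
})

test_that("a pure-noise column among strong drivers is eliminated", {
  # n = 60 keeps chance correlations of the noise column well below the
  # VIP threshold; at n ~ 24 the false-retention rate is inherently ~15%
  drops <- vapply(1:200, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(60 * 4), 60, 4,
                dimnames = list(NULL, c("s1", "s2", "s3", "noise")))
    y <- drop(X[, 1:3] %*% c(1, 1, 1)) + rnorm(60, 0, 0.1)
    sel <- backward_select(X, y)
    !("noise" %in% sel$kept)
  }, logical(1))
  expect_gte(mean(drops), 0.95)
})

test_that("permutation test is seeded, bounded, and detects signal", {
  pr <- random_problem(n = 24, p = 4, seed = 2, noise = 0.3)
  p1 <- permutation_test(pr$X, pr$y, n_perm = 99, seed = 7)
  p2 <- permutation_test(pr$X, pr$y, n_perm = 99, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
  expect_gte(p1$p_value, 1 / 100)
  expect_lte(p1$p_value, 1)
  expect_lte(p1$p_value, 0.05)  # strong signal
  expect_error(permutation_test(pr$X, pr$y, n_perm = 50), "99")
})

test_that("residual autocorrelation flags AR(1) and passes white noise", {
  set.seed(55)
  white <- rnorm(100)
  r <- residual_autocorrelation(white, max_lag = 5)
  expect_equal(length(r$acf), 5L)
  expect_equal(r$df, 5L)
  expect_gt(r$p_value, 0.01)

  ar <- as.numeric(arima.sim(list(ar = 0.8), 100))
  expect_lt(residual_autocorrelation(ar, max_lag = 5)$p_value, 0.05)
  expect_error(residual_autocorrelation(rnorm(6), max_lag = 5), "too few")
})

test_that("collinearity screen flags constructed pairs only", {
  # duplicated column -> r = 1
  set.seed(61)
  X <- cbind(a = rnorm(24), b = rnorm(24))
  X <- cbind(X, c = X[, "a"])
  fl <- collinearity_screen(X)
  expect_true(any(fl$var1 == "a" & fl$var2 == "c" |
                    fl$var1 == "c" & fl$var2 == "a"))
  expect_equal(max(abs(fl$r)), 1)

  # engineered r = 0.9 pair flagged, independent columns usually not
  z <- rnorm(200)
  u <- 0.9 * scale(z)[, 1] + sqrt(1 - 0.81) * scale(rnorm(200))[, 1]
  Y <- cbind(p = scale(z)[, 1], q = u, r = rnorm(200))
  fl2 <- collinearity_screen(Y, threshold = 0.8)
  expect_equal(nrow(fl2), 1L)
  expect_setequal(c(fl2$var1, fl2$var2), c("p", "q"))
})

test_that("model quality gate applies the R2Y/Q2 rule", {
  expect_equal(model_quality(0.84, 0.65), "good")
  expect_equal(model_quality(0.58, 0.26), "poor")
  expect_equal(model_quality(0.9, 0.3), "poor")
})
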