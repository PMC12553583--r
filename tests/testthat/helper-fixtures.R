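# Shared fixture builders (all data generated in code).

# Small, fast synthetic world for structural tests.
tiny_config <- function(seed = 1L, ...) {
  synthetic_config(year_start = 2000L, year_end = 2011L,
                   n_fish_per_year = 6L, seed = seed, ...)
}

# n x 2 matrix whose *sample* covariance equals `target` exactly.
matrix_with_cov <- function(n, target, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * 2L), n, 2L)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / (n - 1)
  Y <- Xc %*% solve(chol(S)) %*% chol(target)
  stopifnot(max(abs(cov(Y) - target)) < 1e-10)
  Y
}

# Annual series with a continuous slope change starting at `break_year`.
piecewise_series <- function(years, break_year, slope1, slope2,
                             noise_sd = 0, seed = 1L) {
  v <- slope1 * (years - years[1L])
  after <- years >= break_year
  v[after] <- v[years == break_year] + slope2 * (years[after] - break_year)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + rnorm(length(years), 0, noise_sd)
  }
  annual_series(years, v, variable = "pw")
}

# Independent brute-force RSS scan over all single-break partitions
# (two lm() fits per split), used as the oracle for fit_segmented.
brute_force_break <- function(years, values, min_segment) {
  n <- length(values)
  cand <- seq.int(min_segment, n - min_segment)
  rss <- vapply(cand, function(j) {
    i1 <- 1:j; i2 <- (j + 1L):n
    sum(resid(lm(values[i1] ~ years[i1]))^2) +
      sum(resid(lm(values[i2] ~ years[i2]))^2)
  }, numeric(1))
  tol <- 1e-9 * sum(values^2) + 1e-12   # earliest split on numerical ties
  j <- cand[which(rss <= min(rss) + tol)[1L]]
  list(split = j, rss = min(rss), break_year = years[j + 1L])
}
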