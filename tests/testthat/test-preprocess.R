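test_that("lipid normalization is division by lipid fraction", {
  expect_equal(lipid_normalize(2.0, 0.04), 50.0)
  expect_equal(lipid_normalize(3.7, 1.0), 3.7)
  expect_equal(lipid_normalize(0, 0.05), 0)
  expect_error(lipid_normalize(1, 0), "lipid_fraction")
  expect_error(lipid_normalize(1, -0.1), "lipid_fraction")
})

test_that("TEQ uses the lower-bound convention with WHO2005 factors", {
  tefs <- default_tefs()
  expect_equal(nrow(tefs), 17L)
  expect_equal(sum(tefs$tef == 1), 2L)  # TCDD and 1,2,3,7,8-PeCDD

  conc <- c(tcdd_2378 = 1.0, ocdd = 100)
  # hand sum: 1*1.0 + 0.0003*100 = 1.03
  expect_equal(compute_teq(conc, lods = c(tcdd_2378 = 0.1, ocdd = 1)), 1.03)
  expect_equal(compute_teq(2 * conc), 2 * compute_teq(conc))

  # all below LOD -> 0
  expect_equal(compute_teq(conc, lods = c(tcdd_2378 = 5, ocdd = 500)), 0)
  expect_error(compute_teq(c(not_a_congener = 1)), "no TEF")

  # monotone nondecreasing in every congener concentration
  set.seed(42)
  for (i in 1:20) {
    base <- setNames(runif(17, 0, 10), tefs$congener)
    lods <- setNames(runif(17, 0, 5), tefs$congener)
    j <- sample(17, 1)
    bumped <- base
    bumped[j] <- bumped[j] + runif(1, 0, 5)
    expect_gte(compute_teq(bumped, lods), compute_teq(base, lods))
  }
})

test_that("annual aggregation computes geometric/arithmetic means per year", {
  rec <- data.frame(year = c(2000, 2000, 2001, 2001, 2001),
                    conc = c(4, 9, 5, 5, 5))
  g <- annual_aggregate(rec, "conc", "geometric")
  expect_equal(g$values, c(6, 5))
  expect_equal(g$years, c(2000L, 2001L))

  a <- annual_aggregate(data.frame(year = 2000, conc = c(1, 100)),
                        "conc", "arithmetic")
  g2 <- annual_aggregate(data.frame(year = 2000, conc = c(1, 100)),
                         "conc", "geometric")
  expect_lte(g2$values, a$values)  # AM-GM

  bad <- data.frame(year = c(2000, 2001), conc = c(1, -2))
  expect_error(annual_aggregate(bad, "conc", "geometric"), "2001")
})

test_that("covariate adjustment matches hand OLS and preserves the mean", {
  m <- fit_covariate_adjustment(c(2, 4), c(16, 18))
  expect_equal(m$A, 1)
  expect_equal(m$covariate_mean, 17)
  expect_equal(adjust_values(c(2, 4), c(16, 18), m, force = TRUE), c(3, 3))

  # exact fit: values = 3 * covariate
  cv <- 1:10
  m3 <- fit_covariate_adjustment(3 * cv, cv)
  expect_equal(m3$A, 3)
  expect_lt(m3$p_value, 1e-10)
  expect_true(m3$applied)

  # constant values -> A = 0, not applied
  m0 <- fit_covariate_adjustment(rep(5, 8), cv[1:8])
  expect_equal(m0$A, 0)
  expect_false(m0$applied)
  expect_error(fit_covariate_adjustment(1:5, rep(2, 5)), "zero")

  # identity when TL_measured == TL_average, or when A = 0
  set.seed(1)
  v <- rnorm(10); cvr <- rnorm(10)
  mm <- fit_covariate_adjustment(v, cvr)
  expect_equal(adjust_values(v, rep(mm$covariate_mean, 10), mm,
                             force = TRUE), v)
  # mean preservation: A is the OLS slope, mean at the covariate mean
  expect_equal(mean(adjust_values(v, cvr, mm, force = TRUE)), mean(v))
  expect_error(adjust_values(v, cvr,
                             fit_covariate_adjustment(rnorm(10), rnorm(10))),
               "not significant")
})

test_that("Stineman interpolation is exact on lines and shape-preserving", {
  s <- annual_series(c(2000L, 2001L, 2002L, 2003L), c(1, 2, NA, 4))
  out <- stineman_interpolate(s)
  expect_equal(out$values[3], 3)
  expect_equal(out$interpolated, c(FALSE, FALSE, TRUE, FALSE))

  # observed values untouched; no gaps -> identity
  s2 <- annual_series(2000:2004, c(5, 1, 4, 1, 5))
  expect_identical(stineman_interpolate(s2), s2)

  # no extrapolation
  expect_error(stineman_interpolate(
    annual_series(2000:2003, c(NA, 1, 2, 3))), "leading/trailing")

  # monotone input -> monotone output, bounded by neighbours (no overshoot)
  set.seed(7)
  for (rep in 1:25) {
    v <- cumsum(runif(12, 0.1, 2))
    gap <- sample(2:11, 3)
    vv <- v; vv[gap] <- NA
    out <- stineman_interpolate(annual_series(2000:2011, vv))
    expect_false(is.unsorted(out$values))
    expect_true(all(out$values >= min(v) & out$values <= max(v)))
  }
})

test_that("z-scoring gives mean 0, sd 1, and affine invariance", {
  s <- annual_series(2000:2002, c(1, 2, 3))
  z <- zscore(s)
  expect_equal(z$values, c(-1, 0, 1))
  expect_true(z$zscored)

  set.seed(3)
  v <- rnorm(15)
  z1 <- zscore(annual_series(2000:2014, v))$values
  z2 <- zscore(annual_series(2000:2014, 5 + 2.5 * v))$values
  expect_equal(z1, z2)
  expect_lt(abs(mean(z1)), 1e-12)
  expect_equal(sd(z1), 1)
  expect_error(zscore(annual_series(2000:2003, rep(2, 4))), "variance")
})

test_that("detrending equals residuals plus mean, slope 0, idempotent", {
  # hand OLS: values (0,1,4) at years 1..3 -> slope 2, residuals+mean (2,1,2)
  s <- annual_series(1:3, c(0, 1, 4))
  d <- detrend(s)
  expect_equal(d$values, c(2, 1, 2))
  expect_equal(mean(d$values), mean(s$values))
  expect_lt(abs(coef(lm(d$values ~ s$years))[2]), 1e-10)
  expect_true(d$detrended)

  # perfectly linear -> constant at the mean; zero slope -> unchanged
  lin <- annual_series(2000:2009, 3 + 0.5 * (0:9))
  expect_equal(detrend(lin)$values, rep(mean(lin$values), 10))
  flat <- annual_series(2000:2009, rep(0, 10) + rnorm(10) * 0)
  flat$values <- c(1, -1, 2, -2, 0, 1, -1, 2, -2, 0)
  flat$values <- flat$values - mean(flat$values)
  # construct an exactly slope-free series by detrending first
  f0 <- detrend(flat)
  expect_equal(detrend(f0)$values, f0$values, tolerance = 1e-10)

  # idempotence on random series
  set.seed(11)
  r <- annual_series(1990:2009, rnorm(20))
  expect_equal(detrend(detrend(r))$values, detrend(r)$values,
               tolerance = 1e-10)
})

test_that("annual_series enforces its invariants", {
  expect_error(annual_series(c(2000, 2000), 1:2), "strictly increasing")
  expect_error(annual_series(2000:2001, 1:3), "equal length")
  expect_true(is_annual_series(annual_series(2000:2001, 1:2)))
})
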