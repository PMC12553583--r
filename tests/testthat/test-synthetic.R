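test_that("generator is deterministic and respects degenerate configs", {
  cfg <- tiny_config(seed = 5)
  p1 <- generate_predictors(cfg)
  p2 <- generate_predictors(cfg)
  expect_identical(p1$table, p2$table)
  f1 <- generate_fish(cfg, p1)
  f2 <- generate_fish(cfg, p2)
  expect_identical(f1, f2)

  # zero slopes, zero noise -> constant series
  cfg0 <- tiny_config(trend_slopes = setNames(
    numeric(14), synthetic_config()$predictor_names),
    predictor_noise_sd = 0)
  p0 <- generate_predictors(cfg0)
  expect_true(all(vapply(p0$predictors, function(s)
    all(s$values == s$values[1]), logical(1))))

  expect_error(synthetic_config(year_start = 2000, year_end = 2008),
               "10 years")
  expect_error(synthetic_config(n_fish_per_year = 2), "n_fish_per_year")
  expect_error(synthetic_config(true_lags = c(biovolume = 6L)), "0..5")
  expect_error(synthetic_config(
    breakpoints = list(fca = list(year = 1990, slope_change = 1))),
    "breakpoint year")
})

test_that("a configured noiseless breakpoint has zero RSS at its year", {
  cfg <- synthetic_config(
    predictor_noise_sd = 0,
    breakpoints = list(fca = list(year = 2007, slope_change = -2)),
    trend_slopes = c(fca = 1))
  p <- generate_predictors(cfg)
  s <- p$predictors$fca
  bf <- brute_force_break(s$years, s$values, 4)
  expect_lt(bf$rss, 1e-18)
  expect_equal(bf$break_year, 2007)
  expect_equal(p$truth$breakpoint_map$fca$year, 2007)
})

test_that("fish table honors missing years, flags, and the response model", {
  cfg <- synthetic_config(missing_years = 2015L)
  fish <- generate_fish(cfg)
  expect_false(2015 %in% fish$year)
  expect_equal(sort(unique(fish$year)),
               setdiff(1995:2018, 2015))
  expect_equal(nrow(fish), 23 * 12)

  # lag-truncated first year flagged (default has a lag-1 driver)
  expect_true(all(fish$lag_truncated[fish$year == 1995]))
  expect_false(any(fish$lag_truncated[fish$year > 1995]))

  # noise 0, no drivers, flat trend, no age effect -> one value per year
  cfg0 <- tiny_config(noise_sd = 0, true_coefficients = numeric(),
                      true_lags = integer(), response_trend = 0,
                      age_effect = 0)
  f0 <- generate_fish(cfg0)
  expect_equal(length(unique(round(f0$conc_cb153, 12))), 1L)

  # positive coefficient -> positive correlation with the detrended driver
  cfgp <- tiny_config(noise_sd = 0,
                      true_coefficients = c(fca = 1), true_lags = integer())
  pp <- generate_predictors(cfgp)
  fp <- generate_fish(cfgp, pp)
  ylog <- log(annual_aggregate(fp, "conc_cb153", "geometric")$values)
  dzfca <- detrend(zscore(pp$predictors$fca))$values
  expect_gt(cor(ylog, dzfca), 0)
})

test_that("TL distribution and age-length coupling match the design", {
  cfg <- synthetic_config(n_fish_per_year = 50, seed = 2)
  fish <- generate_fish(cfg)
  expect_true(all(fish$total_length >= 15 & fish$total_length <= 19))
  # compare against the theoretical truncated-normal mean: the 15-19 cm
  # window is asymmetric around 17.7, so truncation shifts the mean down
  a <- (15 - 17.7) / 1; b <- (19 - 17.7) / 1
  mu_trunc <- 17.7 + (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  se <- sd(fish$total_length) / sqrt(nrow(fish))
  expect_lt(abs(mean(fish$total_length) - mu_trunc), 3 * se)
  expect_true(all(fish$age %in% 3:5))
  # age ~ TL regression must be significant (the adjustment pathway)
  fit <- summary(lm(age ~ total_length, fish))
  expect_lt(fit$coefficients[2, 4], 1e-6)
  expect_gt(fit$coefficients[2, 1], 0)
})

test_that("noiseless annual log geometric mean is exactly linear in drivers", {
  cfg <- synthetic_config(noise_sd = 0, age_effect = 0,
                          true_lags = integer())
  pred <- generate_predictors(cfg)
  fish <- generate_fish(cfg, pred)
  years <- sort(unique(fish$year))
  ylog <- log(annual_aggregate(fish, "conc_cb153", "geometric")$values)
  tr <- pred$truth
  expect_setequal(tr$driver_ranking, c("d15n_range", "biovolume", "fca"))
  signal <- cfg$response_baseline +
    cfg$response_trend * (years - mean(years))
  for (nm in names(tr$true_coefficients)) {
    b <- tr$true_coefficients[[nm]]
    if (b == 0) next
    signal <- signal + b * detrend(zscore(pred$predictors[[nm]]))$values
  }
  expect_lt(max(abs(ylog - signal)) / max(abs(signal)), 1e-10)
})

test_that("congener panel has 17 columns and honors the LOD fraction", {
  cfg <- tiny_config()
  pan <- generate_congener_panel(cfg, below_lod_fraction = 1)
  expect_equal(ncol(pan$conc), 18L)  # year + 17 congeners
  expect_true(all(as.matrix(pan$below_lod[, -1])))
  pan0 <- generate_congener_panel(cfg, below_lod_fraction = 0)
  expect_false(any(as.matrix(pan0$below_lod[, -1])))
  expect_identical(generate_congener_panel(cfg, 0.3),
                   generate_congener_panel(cfg, 0.3))
  # all-below-LOD panel aggregates to TEQ 0
  teqs <- vapply(seq_len(nrow(pan$conc)), function(i) {
    compute_teq(unlist(pan$conc[i, -1]), unlist(pan$lod[i, -1]))
  }, numeric(1))
  expect_true(all(teqs == 0))
})

test_that("bundle writer produces readable CSV/JSON round-trips", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config()
  paths <- write_synthetic_bundle(cfg, dir)
  expect_true(all(file.exists(paths)))
  fish <- read.csv(paths["fish"])
  expect_equal(nrow(fish), 12 * 6)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(sort(truth$driver_ranking),
               sort(generate_predictors(cfg)$truth$driver_ranking))
})
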