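#' Configuration for the synthetic monitoring-data generator
#'
#' Describes the simulated world: a fish-monitoring time series in the
#' style of the Baltic national programmes (annual cohorts of similar-sized
#' herring), a panel of annual ecosystem predictors with linear trends and
#' optional single breakpoints, and a log-scale contaminant response driven
#' by a known subset of the (detrended) predictors, possibly with lags.
#' The defaults emulate the stated monitoring design: 24 annual cohorts
#' (1995-2018), 12 fish per year, total length averaging 17.7 cm within
#' 15-19 cm, ages 3-5 correlated with length, 14 candidate predictors of
#' which three are true drivers (one acting at lag 1).
#'
#' @param year_start,year_end calendar years (span >= 10).
#' @param n_fish_per_year fish sampled per year (>= 3).
#' @param tl_mean,tl_sd,tl_range total-length distribution (cm); lengths
#'   are drawn truncated-normal within `tl_range`.
#' @param age_levels integer ages present (years).
#' @param age_tl_slope target slope of the age~TL relationship (yr/cm),
#'   realized by assigning ages from TL quantile bins with jitter.
#' @param predictor_names names of the candidate predictors.
#' @param trend_slopes named per-predictor linear slope (raw units/yr).
#' @param breakpoints named list: `list(pred = list(year =, slope_change =))`
#'   adds a slope change starting at the given year.
#' @param true_coefficients named effects (z-units of detrended predictor
#'   per log-concentration unit); predictors absent from the name set have
#'   coefficient 0.
#' @param true_lags named integer lags in 0..5 for the true drivers.
#' @param response_trend log-concentration change per year (default -0.03,
#'   a declining contaminant).
#' @param response_baseline log of the mean concentration.
#' @param age_effect log-concentration per year of age (slow growers
#'   accumulate more; default 0.02).
#' @param noise_sd SD of the annual process noise on the log response
#'   (z-units); individual fish add noise with SD
#'   `noise_sd * fish_noise_frac`, so `noise_sd = 0` silences both.
#' @param fish_noise_frac individual-to-annual noise ratio.
#' @param predictor_noise_sd white-noise SD added to each predictor series.
#' @param predictor_noise `"white"` or `"ar1"` (AR(1) with coefficient
#'   `ar1_phi`); the true noise structure of monitoring series is unknown,
#'   so both are available.
#' @param ar1_phi AR(1) coefficient when `predictor_noise = "ar1"`.
#' @param isotope_mean,isotope_cov mean vector (d13C, d15N, permil) and 2x2
#'   covariance of the per-fish bulk isotope scatter (drives SEA).
#' @param missing_years years with no fish sampled.
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(year_start = 1995L, year_end = 2018L,
                             n_fish_per_year = 12L,
                             tl_mean = 17.7, tl_sd = 1.0,
                             tl_range = c(15, 19),
                             age_levels = 3:5, age_tl_slope = 0.5,
                             predictor_names = c(
                               "deposition", "age", "tp", "d13c_range",
                               "d15n_range", "sea_b", "temperature",
                               "salinity", "monoporeia", "zoopl_biomass",
                               "zoopl_size", "cyano_n", "biovolume", "fca"),
                             trend_slopes = NULL,
                             breakpoints = list(),
                             true_coefficients = c(d15n_range = 0.2,
                                                   fca = -0.2,
                                                   biovolume = 0.2),
                             true_lags = c(biovolume = 1L),
                             response_trend = -0.03,
                             response_baseline = log(0.1),
                             age_effect = 0.02,
                             noise_sd = 0.05, fish_noise_frac = 4,
                             predictor_noise_sd = 1.0,
                             predictor_noise = c("white", "ar1"),
                             ar1_phi = 0.5,
                             isotope_mean = c(-21.5, 12.0),
                             isotope_cov = matrix(c(0.6, 0.15, 0.15, 0.35),
                                                  2L, 2L),
                             missing_years = integer(),
                             seed = 1L) {
  predictor_noise <- match.arg(predictor_noise)
  if (year_end - year_start < 9L) stop("need a span of at least 10 years")
  if (n_fish_per_year < 3L) stop("n_fish_per_year must be >= 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(trend_slopes)) {
    trend_slopes <- stats::setNames(
      rep_len(c(-0.05, 0.04, -0.03, 0.05), length(predictor_names)),
      predictor_names)
  }
  if (!all(names(trend_slopes) %in% predictor_names))
    stop("trend_slopes names must be predictor names")
  slopes <- stats::setNames(numeric(length(predictor_names)),
                            predictor_names)
  slopes[names(trend_slopes)] <- trend_slopes
  unknown <- setdiff(names(true_coefficients), predictor_names)
  if (length(unknown)) stop("unknown predictor in true_coefficients: ",
                            paste(unknown, collapse = ", "))
  if (length(true_lags)) {
    if (!all(names(true_lags) %in% predictor_names))
      stop("true_lags names must be predictor names")
    if (any(true_lags < 0L | true_lags > 5L))
      stop("every true lag must be in 0..5")
  }
  for (bn in names(breakpoints)) {
    by <- breakpoints[[bn]]$year
    if (is.null(by) || by <= year_start || by >= year_end)
      stop("breakpoint year for '", bn,
           "' must lie strictly inside the year range")
  }
  structure(list(year_start = as.integer(year_start),
                 year_end = as.integer(year_end),
                 n_fish_per_year = as.integer(n_fish_per_year),
                 tl_mean = tl_mean, tl_sd = tl_sd, tl_range = tl_range,
                 age_levels = as.integer(age_levels),
                 age_tl_slope = age_tl_slope,
                 predictor_names = predictor_names,
                 trend_slopes = slopes, breakpoints = breakpoints,
                 true_coefficients = true_coefficients,
                 true_lags = true_lags,
                 response_trend = response_trend,
                 response_baseline = response_baseline,
                 age_effect = age_effect,
                 noise_sd = noise_sd, fish_noise_frac = fish_noise_frac,
                 predictor_noise_sd = predictor_noise_sd,
                 predictor_noise = predictor_noise, ar1_phi = ar1_phi,
                 isotope_mean = isotope_mean, isotope_cov = isotope_cov,
                 missing_years = as.integer(missing_years),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate the annual predictor panel with known ground truth
#'
#' Each predictor series is a linear trend, plus an optional single slope
#' change starting at its configured breakpoint year (the series stays
#' continuous), plus white or AR(1) noise. Deterministic given the config
#' seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `predictors` (named list of raw [annual_series]
#'   covering every year), `table` (wide data.frame with `year` column) and
#'   `truth` (class `synthetic_truth`: `true_coefficients`, `true_lags`,
#'   `breakpoint_map`, `driver_ranking` by decreasing |coefficient|).
#' @export
generate_predictors <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  years <- seq.int(config$year_start, config$year_end)
  nt <- length(years)
  series <- with_local_seed(derive_seed(config$seed, "predictors"), {
    lapply(config$predictor_names, function(pn) {
      slope <- config$trend_slopes[[pn]]
      base <- slope * (years - config$year_start)
      bp <- config$breakpoints[[pn]]
      if (!is.null(bp)) {
        after <- years >= bp$year
        base[after] <- base[years == bp$year] +
          (slope + bp$slope_change) * (years[after] - bp$year)
      }
      noise <- if (config$predictor_noise_sd == 0) numeric(nt) else {
        eps <- stats::rnorm(nt, 0, config$predictor_noise_sd)
        if (config$predictor_noise == "ar1") {
          out <- numeric(nt)
          out[1L] <- eps[1L] / sqrt(1 - config$ar1_phi^2)
          for (t in 2:nt) out[t] <- config$ar1_phi * out[t - 1L] + eps[t]
          out
        } else eps
      }
      annual_series(years, base + noise, variable = pn, units = "raw")
    })
  })
  names(series) <- config$predictor_names
  tab <- data.frame(year = years)
  for (pn in config$predictor_names) tab[[pn]] <- series[[pn]]$values
  coefs <- stats::setNames(numeric(length(config$predictor_names)),
                           config$predictor_names)
  coefs[names(config$true_coefficients)] <- config$true_coefficients
  lags <- stats::setNames(integer(length(config$predictor_names)),
                          config$predictor_names)
  if (length(config$true_lags)) lags[names(config$true_lags)] <-
    config$true_lags
  drivers <- names(coefs)[coefs != 0]
  truth <- structure(list(
    true_coefficients = coefs, true_lags = lags,
    breakpoint_map = config$breakpoints,
    driver_ranking = drivers[order(-abs(coefs[drivers]))]),
    class = "synthetic_truth")
  list(predictors = series, table = tab, truth = truth)
}

# Detrended, z-scored version of a raw predictor series (the scale on which
# the true coefficients act, matching the analysis pipeline).
detrended_z <- function(series) detrend(zscore(series))

#' Generate the individual-fish table
#'
#' Per fish: total length from a truncated normal within `tl_range`; age
#' from TL quantile bins over `age_levels` with jitter (so an age~TL
#' regression is significant without simulating growth); bulk isotopes from
#' a bivariate normal; and log contaminant concentrations built as
#' year trend + sum of true coefficients times the detrended z-scored
#' predictor at the configured lag + age effect + annual and individual
#' noise, then exponentiated (so geometric-mean aggregation is the natural
#' annual estimator). Years listed in `missing_years` produce no rows.
#' Years whose lagged driver would reach before `year_start` use zero for
#' that term and are flagged in `lag_truncated`.
#'
#' @param config a [synthetic_config()].
#' @param predictors output of [generate_predictors()] (regenerated from
#'   the config when omitted).
#' @return data.frame with columns year, total_length, age, lipid,
#'   conc_cb153, conc_hg, d13c, d15n, lag_truncated; attribute `truth`.
#' @export
generate_fish <- function(config, predictors = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(predictors)) predictors <- generate_predictors(config)
  years_all <- seq.int(config$year_start, config$year_end)
  if (!identical(predictors$predictors[[1L]]$years, years_all))
    stop("predictors must cover every year of the config range")
  years <- setdiff(years_all, config$missing_years)
  truth <- predictors$truth
  drivers <- names(truth$true_coefficients)[truth$true_coefficients != 0]
  dz <- lapply(predictors$predictors[drivers], detrended_z)

  # annual driver signal (log scale)
  driver_term <- vapply(years, function(t) {
    tot <- 0
    trunc_flag <- FALSE
    for (pn in names(truth$true_coefficients)) {
      b <- truth$true_coefficients[[pn]]
      if (b == 0) next
      k <- truth$true_lags[[pn]]
      ty <- t - k
      if (ty < config$year_start) { trunc_flag <- TRUE; next }
      tot <- tot + b * dz[[pn]]$values[match(ty, years_all)]
    }
    c(tot, as.numeric(trunc_flag))
  }, numeric(2))

  with_local_seed(derive_seed(config$seed, "fish"), {
    eps_year <- stats::rnorm(length(years), 0, config$noise_sd)
    rows <- lapply(seq_along(years), function(i) {
      t <- years[i]
      nf <- config$n_fish_per_year
      tl <- rtruncnorm(nf, config$tl_mean, config$tl_sd, config$tl_range)
      age <- age_from_tl(tl, config)
      iso <- MASS::mvrnorm(nf, mu = config$isotope_mean,
                           Sigma = config$isotope_cov)
      lipid <- pmin(pmax(stats::rnorm(nf, 0.03, 0.005), 0.01), 0.08)
      base <- config$response_baseline +
        config$response_trend * (t - mean(years_all)) +
        driver_term[1L, i] + eps_year[i]
      mk_logc <- function(offset) {
        base + offset + config$age_effect * (age - mean(config$age_levels)) +
          stats::rnorm(nf, 0, config$noise_sd * config$fish_noise_frac)
      }
      data.frame(year = t, total_length = tl, age = age, lipid = lipid,
                 conc_cb153 = exp(mk_logc(0)),
                 conc_hg = exp(mk_logc(log(30 / 0.1))),
                 d13c = iso[, 1L], d15n = iso[, 2L],
                 lag_truncated = driver_term[2L, i] > 0)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

# Truncated-normal draws by inverse CDF (exact, no rejection loop).
rtruncnorm <- function(n, mean, sd, range) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(range[1L], mean, sd)
  hi <- stats::pnorm(range[2L], mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

# Age from TL quantile bins with jitter: longer fish get older ages at a
# rate consistent with age_tl_slope, without a growth model.
age_from_tl <- function(tl, config) {
  lev <- sort(config$age_levels)
  k <- length(lev)
  if (k == 1L) return(rep(lev, length(tl)))
  qs <- stats::quantile(tl, probs = seq_len(k - 1L) / k, names = FALSE)
  idx <- findInterval(tl, qs) + 1L
  # jitter: move a fish one bin with probability shrinking in age_tl_slope
  p_move <- max(0, min(0.45, 0.45 - 0.3 * config$age_tl_slope))
  move <- stats::runif(length(tl)) < p_move
  dir <- sample(c(-1L, 1L), length(tl), replace = TRUE)
  idx[move] <- pmin(pmax(idx[move] + dir[move], 1L), k)
  lev[idx]
}

#' Generate a synthetic dioxin/furan congener panel
#'
#' One pooled sample per year with the 17 laterally substituted PCDD/F
#' congeners, lognormal concentrations scaled per congener, and a
#' configurable fraction of entries flagged below the limit of detection.
#' Deterministic given the seed.
#'
#' @param config a [synthetic_config()] (years and seed are used).
#' @param below_lod_fraction fraction of concentration cells flagged below
#'   LOD (0..1).
#' @param seed optional seed override (defaults to the config seed).
#' @return list with `conc` (data.frame year + 17 congener columns, pg/g),
#'   `lod` (same shape, the detection limits), `below_lod` (logical, same
#'   shape).
#' @export
generate_congener_panel <- function(config, below_lod_fraction = 0.2,
                                    seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (below_lod_fraction < 0 || below_lod_fraction > 1)
    stop("below_lod_fraction must be in [0, 1]")
  if (is.null(seed)) seed <- config$seed
  tefs <- default_tefs()
  years <- seq.int(config$year_start, config$year_end)
  ny <- length(years)
  with_local_seed(derive_seed(seed, "congeners"), {
    conc <- lod <- flag <- data.frame(year = years)
    for (i in seq_len(nrow(tefs))) {
      cg <- tefs$congener[i]
      scale_i <- 0.5 / max(tefs$tef[i], 0.01)  # rarer toxics lower conc
      cc <- stats::rlnorm(ny, meanlog = log(scale_i), sdlog = 0.4)
      below <- stats::runif(ny) < below_lod_fraction
      ld <- ifelse(below, cc * 1.5, cc * 0.05)
      conc[[cg]] <- cc; lod[[cg]] <- ld; flag[[cg]] <- below
    }
    list(conc = conc, lod = lod, below_lod = flag)
  })
}

#' Write a synthetic data bundle to CSV/JSON
#'
#' Writes the fish table, predictor table, congener panel (concentrations
#' and LODs) as RFC 4180 CSV (UTF-8, ISO year column) and the ground truth
#' as JSON.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @param below_lod_fraction passed to [generate_congener_panel()].
#' @return invisibly, the named list of written paths.
#' @export
write_synthetic_bundle <- function(config, dir,
                                   below_lod_fraction = 0.2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pred <- generate_predictors(config)
  fish <- generate_fish(config, pred)
  panel <- generate_congener_panel(config, below_lod_fraction)
  paths <- c(fish = file.path(dir, "fish.csv"),
             predictors = file.path(dir, "predictors.csv"),
             congener_conc = file.path(dir, "congener_conc.csv"),
             congener_lod = file.path(dir, "congener_lod.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(fish, paths["fish"], row.names = FALSE)
  utils::write.csv(pred$table, paths["predictors"], row.names = FALSE)
  utils::write.csv(panel$conc, paths["congener_conc"], row.names = FALSE)
  utils::write.csv(panel$lod, paths["congener_lod"], row.names = FALSE)
  tr <- attr(fish, "truth")
  jsonlite::write_json(
    list(true_coefficients = as.list(tr$true_coefficients),
         true_lags = as.list(tr$true_lags),
         breakpoint_map = tr$breakpoint_map,
         driver_ranking = tr$driver_ranking),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
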