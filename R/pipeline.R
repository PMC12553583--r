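#' Analysis configuration
#'
#' Bundles every tunable of the full pipeline. Can be built directly or
#' loaded from YAML with [read_analysis_config()].
#'
#' @param response which contaminant to model: `"cb153"` (geometric annual
#'   mean of `conc_cb153`), `"hg"`, or `"pcddf_teq"`.
#' @param year_range optional `c(first, last)` restriction.
#' @param alpha significance level for the covariate adjustment and for
#'   segment slope classification.
#' @param vip_threshold VIP retention threshold in backward selection.
#' @param max_lag maximum predictor lead tested (years).
#' @param n_perm permutations for the validation test.
#' @param ncomp_max maximum PLS components considered.
#' @param beta,tdf CSIA trophic-position constants (permil), echoed into
#'   the report.
#' @param add_isotope_metrics compute annual NR/CR/SEA-B from the fish bulk
#'   isotopes and append them as predictors.
#' @param log_response model the log of the annual geometric-mean
#'   concentration (default `TRUE`). Concentrations are log-normal-like --
#'   that is why the geometric mean is the annual estimator -- and the log
#'   of the geometric mean is exactly the mean log-concentration, the scale
#'   on which additive driver effects are coherent. For series with modest
#'   interannual amplitude the two scales give near-identical z-scores.
#' @param seed master seed; per-stage child seeds derive from it.
#' @param output_dir optional directory for intermediate CSVs and the
#'   report.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(response = c("cb153", "hg", "pcddf_teq"),
                            year_range = NULL, alpha = 0.05,
                            vip_threshold = 0.7, max_lag = 5L,
                            n_perm = 199L, ncomp_max = 5L,
                            beta = 3.4, tdf = 7.6,
                            add_isotope_metrics = TRUE,
                            log_response = TRUE,
                            seed = 1L, output_dir = NULL) {
  response <- match.arg(response)
  stopifnot(alpha > 0, vip_threshold > 0, max_lag >= 0, n_perm >= 99)
  structure(list(response = response, year_range = year_range,
                 alpha = alpha, vip_threshold = vip_threshold,
                 max_lag = as.integer(max_lag), n_perm = as.integer(n_perm),
                 ncomp_max = as.integer(ncomp_max),
                 beta = beta, tdf = tdf,
                 add_isotope_metrics = isTRUE(add_isotope_metrics),
                 log_response = isTRUE(log_response),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "analysis_config")
}

#' Load an analysis configuration from YAML
#'
#' @param path YAML file whose keys match [analysis_config()] arguments.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

response_column <- function(response) {
  switch(response, cb153 = "conc_cb153", hg = "conc_hg",
         pcddf_teq = "teq_pcddf")
}

# Stage-order guard: the regression stages only accept series whose flags
# prove prior z-scoring and detrending.
assert_detrended <- function(series_list) {
  bad <- names(series_list)[!vapply(series_list, function(s)
    s$zscored && s$detrended, logical(1))]
  if (length(bad))
    stop("stage-order violation: series not z-scored+detrended: ",
         paste(bad, collapse = ", "))
  invisible(series_list)
}

# aggregate -> adjust -> interpolate on the full year grid
annualize <- function(values, years, variable, method, year_grid,
                      units = "") {
  s <- annual_aggregate(data.frame(year = years, v = values), "v",
                        method = method, units = units)
  s$variable <- variable
  full <- annual_series(year_grid,
                        s$values[match(year_grid, s$years)],
                        variable = variable, units = units)
  stineman_interpolate(full)
}

#' Run the full driver-attribution analysis
#'
#' Executes the complete workflow on an individual-fish table and an annual
#' predictor table: annual (geometric-mean) aggregation of the response and
#' of age; length-confounder adjustment of individual-level variables when
#' significant; Stineman interpolation of missing years; z-scoring;
#' single-breakpoint trend classification of every series; linear
#' detrending; cross-correlation lag screening (predictor leading response
#' up to `max_lag` years); collinearity screen; NIPALS PLS1 with VIP-based
#' backward selection and WRC importance ranking; permutation validation;
#' and a residual-autocorrelation check. Deterministic given config + data.
#'
#' @param fish data.frame with columns `year`, `total_length`, `age`,
#'   `lipid`, the response concentration column, and optionally `d13c`,
#'   `d15n`.
#' @param predictors data.frame with a `year` column plus one column per
#'   annual predictor (raw scale; missing years as `NA` rows are allowed).
#' @param config an [analysis_config()].
#' @return list of class `analysis_report`: `trend_table`, `lag_table`,
#'   `collinearity`, `adjustment`, `selection`, `model_summary`,
#'   `wrc_ranking`, `permutation`, `residual_diagnostics`, `gates`,
#'   `provenance`.
#' @export
run_full_analysis <- function(fish, predictors, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  rc <- response_column(config$response)
  need <- c("year", "total_length", "age", rc)
  miss <- setdiff(need, names(fish))
  if (length(miss))
    stop("stage input-validation: fish table lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!"year" %in% names(predictors))
    stop("stage input-validation: predictor table lacks 'year'")

  if (!is.null(config$year_range)) {
    fish <- fish[fish$year >= config$year_range[1L] &
                   fish$year <= config$year_range[2L], , drop = FALSE]
    predictors <- predictors[predictors$year >= config$year_range[1L] &
                               predictors$year <= config$year_range[2L], ,
                             drop = FALSE]
  }
  year_grid <- seq.int(min(predictors$year), max(predictors$year))
  log_line <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))

  # --- stage 1: length-confounder adjustment (individual level) ----------
  adj <- fit_covariate_adjustment(fish$age, fish$total_length,
                                  alpha = config$alpha)
  age_vals <- if (adj$applied)
    adjust_values(fish$age, fish$total_length, adj) else fish$age
  log_line("adjust", sprintf("age~TL r2 = %.2f, p = %.3g -> %s",
                             adj$r2, adj$p_value,
                             if (adj$applied) "adjusted" else "unadjusted"))

  # --- stage 2: annual aggregation + interpolation -----------------------
  resp_series <- annualize(fish[[rc]], fish$year, config$response,
                           "geometric", year_grid)
  if (config$log_response) {
    resp_series$values <- log(resp_series$values)
    resp_series$units <- "log"
  }
  age_series <- annualize(age_vals, fish$year, "age", "geometric",
                          year_grid)
  pred_series <- list(age = age_series)
  for (pn in setdiff(names(predictors), "year")) {
    full <- annual_series(year_grid,
                          predictors[[pn]][match(year_grid,
                                                 predictors$year)],
                          variable = pn)
    pred_series[[pn]] <- stineman_interpolate(full)
  }
  if (config$add_isotope_metrics &&
      all(c("d13c", "d15n") %in% names(fish))) {
    iso <- isotope_metric_series(fish, year_grid,
                                 seed = derive_seed(config$seed, "sea"))
    iso <- iso[setdiff(names(iso), names(pred_series))]  # no collisions
    pred_series <- c(pred_series, iso)
  }
  log_line("aggregate",
           sprintf("%d predictor series on %d-year grid",
                   length(pred_series), length(year_grid)))

  # --- stage 3: z-score + trend classification ---------------------------
  z_all <- lapply(c(list(response = resp_series), pred_series), zscore)
  trends <- trend_table(z_all, alpha = config$alpha)
  log_line("trends", sprintf("%d series classified, %d with breakpoint",
                             length(z_all),
                             sum(!is.na(unique(
                               trends[c("variable", "breakpoint_year")]
                             )$breakpoint_year))))

  # --- stage 4: detrend --------------------------------------------------
  d_all <- lapply(z_all, detrend)
  assert_detrended(d_all)
  resp_d <- d_all$response
  pred_d <- d_all[setdiff(names(d_all), "response")]

  # --- stage 5: lag screen -----------------------------------------------
  lag_tab <- lag_screen_table(pred_d, resp_d, max_lag = config$max_lag)
  X <- data.frame(year = year_grid)
  for (pn in names(pred_d)) X[[pn]] <- pred_d[[pn]]$values
  Xlag <- build_lagged_matrix(X, lag_tab)
  log_line("lags", sprintf("%d significant lag column(s) added; %d year(s) dropped",
                           length(attr(Xlag, "added_columns")),
                           length(attr(Xlag, "dropped_years"))))

  # --- stage 6: collinearity screen --------------------------------------
  Xm <- Xlag[, setdiff(names(Xlag), "year"), drop = FALSE]
  coll <- collinearity_screen(Xm, threshold = 0.8)

  # --- stage 7: PLSR with VIP backward selection -------------------------
  yv <- resp_d$values[match(Xlag$year, year_grid)]
  sel <- backward_select(Xm, yv, vip_threshold = config$vip_threshold,
                         ncomp_max = config$ncomp_max)
  r2y <- sel$model$r2y[sel$ncomp]
  gate <- model_quality(r2y, sel$q2)
  log_line("plsr", sprintf("%d predictors kept, A = %d, R2Y = %.2f, Q2 = %.2f (%s)",
                           length(sel$kept), sel$ncomp, r2y, sel$q2, gate))

  # --- stage 8: permutation + residual diagnostics -----------------------
  Xfinal <- Xm[, sel$kept, drop = FALSE]
  perm <- permutation_test(Xfinal, yv, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, "perm"),
                           ncomp_max = config$ncomp_max)
  diag <- residual_autocorrelation(sel$model,
                                   max_lag = min(config$max_lag,
                                                 length(yv) - 3L))

  report <- structure(list(
    trend_table = trends, lag_table = lag_tab, collinearity = coll,
    adjustment = adj,
    selection = list(trace = sel$trace, kept = sel$kept,
                     ncomp = sel$ncomp),
    model_summary = list(r2y = r2y, q2 = sel$q2, ncomp = sel$ncomp,
                         coefficients = sel$model$coef,
                         vip = vip(sel$model)),
    wrc_ranking = wrc_ranking(sel$model),
    permutation = perm, residual_diagnostics = diag,
    gates = list(quality = gate, r2y = r2y, q2 = sel$q2),
    provenance = list(response = config$response,
                      year_range = range(Xlag$year),
                      n_years = length(yv),
                      csia = c(beta = config$beta, tdf = config$tdf),
                      seed = config$seed,
                      config_hash = config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("herringdrivers")),
                      stages = c("aggregate", "adjust", "interpolate",
                                 "zscore", "trend", "detrend", "lag_screen",
                                 "collinearity", "plsr", "permutation",
                                 "residual_check"))),
    class = "analysis_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

config_hash <- function(config) {
  x <- unlist(config[setdiff(names(config), "output_dir")])
  sum(utf8ToInt(paste(names(x), x, collapse = "|", sep = "="))) %% 1e9
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> response %s, %d years (%d-%d)\n",
              x$provenance$response, x$provenance$n_years,
              x$provenance$year_range[1L], x$provenance$year_range[2L]))
  cat(sprintf("  model: %d component(s), R2Y = %.3f, Q2 = %.3f [%s]\n",
              x$model_summary$ncomp, x$gates$r2y, x$gates$q2,
              x$gates$quality))
  cat(sprintf("  permutation p = %.4f (%d perms); Ljung-Box p = %.3f\n",
              x$permutation$p_value, x$permutation$n_perm,
              x$residual_diagnostics$p_value))
  cat("  top drivers by |WRC|:\n")
  print(utils::head(x$wrc_ranking, 5L), row.names = FALSE)
  invisible(x)
}

#' Write an analysis report (and intermediates) to disk
#'
#' Writes the stage tables as CSV and the full report as JSON plus a short
#' markdown summary.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the report path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$trend_table, file.path(dir, "trends.csv"),
                   row.names = FALSE)
  utils::write.csv(report$lag_table, file.path(dir, "lag_screen.csv"),
                   row.names = FALSE)
  utils::write.csv(report$collinearity,
                   file.path(dir, "collinearity.csv"), row.names = FALSE)
  utils::write.csv(report$wrc_ranking,
                   file.path(dir, "importance.csv"), row.names = FALSE)
  json <- list(
    model_summary = lapply(report$model_summary, function(z)
      if (is.numeric(z) && !is.null(names(z))) as.list(z) else z),
    gates = report$gates,
    permutation = list(p_value = report$permutation$p_value,
                       observed = as.list(report$permutation$observed),
                       n_perm = report$permutation$n_perm,
                       seed = report$permutation$seed),
    residual_diagnostics = list(
      acf = as.list(report$residual_diagnostics$acf),
      ljung_box_p = report$residual_diagnostics$p_value),
    selection = list(kept = report$selection$kept,
                     ncomp = report$selection$ncomp),
    provenance = report$provenance)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA)
  md <- c(sprintf("# Driver-attribution report: %s",
                  report$provenance$response),
          "",
          sprintf("- Years: %d-%d (n = %d)",
                  report$provenance$year_range[1L],
                  report$provenance$year_range[2L],
                  report$provenance$n_years),
          sprintf("- Model: %d component(s), R2Y = %.3f, Q2 = %.3f (%s)",
                  report$model_summary$ncomp, report$gates$r2y,
                  report$gates$q2, report$gates$quality),
          sprintf("- Permutation p = %.4f; Ljung-Box p = %.3f",
                  report$permutation$p_value,
                  report$residual_diagnostics$p_value),
          "", "## Predictors ranked by |WRC|", "",
          knit_table(report$wrc_ranking))
  writeLines(md, file.path(dir, "report.md"))
  invisible(path)
}

knit_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(z) sprintf("%.4f", z))
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1L, function(r) paste("|", paste(r, collapse = " | "),
                                          "|"))
  c(header, sep, rows)
}

# Annual isotope-niche predictor series from per-fish bulk isotopes:
# delta15N range, delta13C range, and the Bayesian standard ellipse area
# posterior mode, each then interpolated onto the full year grid.
isotope_metric_series <- function(fish, year_grid, seed = 1L,
                                  n_draws = 1000L) {
  yrs <- sort(unique(fish$year))
  nr <- cr <- seab <- rep(NA_real_, length(yrs))
  for (i in seq_along(yrs)) {
    sub <- fish[fish$year == yrs[i], ]
    if (nrow(sub) < 3L) next
    rng <- layman_ranges(sub$d13c, sub$d15n)
    nr[i] <- rng$nr; cr[i] <- rng$cr
    seab[i] <- sea_bayesian(sub$d13c, sub$d15n, n_draws = n_draws,
                            seed = derive_seed(seed, paste0("y", yrs[i]))
    )$mode
  }
  mk <- function(v, nm) {
    full <- annual_series(year_grid, v[match(year_grid, yrs)],
                          variable = nm, units = "permil")
    stineman_interpolate(full)
  }
  list(nr = mk(nr, "nr"), cr = mk(cr, "cr"), sea_b = mk(seab, "sea_b"))
}

#' Re-run the analysis on constrained year ranges
#'
#' Fits one full analysis per year range (each at least 10 years) and
#' tabulates WRC signs across ranges -- the sensitivity design used to ask
#' whether driver directions hold within sub-periods (e.g. low sprat
#' density).
#'
#' @param fish,predictors as in [run_full_analysis()].
#' @param config base [analysis_config()].
#' @param year_ranges list of `c(first, last)` pairs.
#' @return list with `reports` (one per range) and `sign_comparison`
#'   (data.frame predictor x range of WRC signs).
#' @export
run_period_constrained <- function(fish, predictors, config, year_ranges) {
  for (r in year_ranges)
    if (diff(range(r)) + 1L < 10L)
      stop("each year range must span at least 10 years")
  reports <- lapply(year_ranges, function(r) {
    cfg <- config
    cfg$year_range <- r
    cfg$output_dir <- NULL
    run_full_analysis(fish, predictors, cfg)
  })
  names(reports) <- vapply(year_ranges, function(r)
    sprintf("%d-%d", r[1L], r[2L]), character(1))
  preds <- sort(unique(unlist(lapply(reports, function(rep)
    rep$wrc_ranking$predictor))))
  signs <- data.frame(predictor = preds, stringsAsFactors = FALSE)
  for (nm in names(reports)) {
    w <- reports[[nm]]$wrc_ranking
    signs[[nm]] <- ifelse(
      preds %in% w$predictor,
      ifelse(w$wrc[match(preds, w$predictor)] >= 0, "+", "-"),
      NA_character_)
  }
  list(reports = reports, sign_comparison = signs)
}
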