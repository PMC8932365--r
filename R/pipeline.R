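# End-to-end orchestration: simulate | fit | project | equity | determinants
# | diagnose, driven by a config list (or YAML file), with reproducible
# seeding, manifests and plain-text artifacts. The companion command-line
# wrapper lives in inst/cli/anc-pipeline.

#' Persist a fitted trend model as plain-text artifacts
#'
#' Writes the retained draws in long format
#' (`chain,iteration,parameter,value`), the observation/covariate tables and
#' a JSON sidecar with the layout, options and standardization constants, so
#' the fit can be reloaded without resampling.
#'
#' @param fit an [anc_trend()] fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- fit$draws$draws
  d <- dim(arr)
  long <- data.frame(
    chain = rep(seq_len(d[1]), times = d[2] * d[3]),
    iteration = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    parameter = rep(dimnames(arr)[[3]], each = d[1] * d[2]),
    value = as.vector(arr), stringsAsFactors = FALSE)
  utils::write.csv(long, file.path(dir, "draws_long.csv"), row.names = FALSE,
                   quote = 3L)  # parameter labels contain commas
  write_observations(fit$model_frame$data[, c(
    "obs_id", "region_id", "country_id", "year", "age_group", "indicator",
    "stratum", "proportion", "logit_value", "ess")],
    file.path(dir, "observations.csv"))
  write_covariates(fit$covariates, file.path(dir, "covariates.csv"))
  meta <- list(
    indicator = fit$indicator, age_group = fit$age_group,
    stratum = fit$stratum, use_covariates = fit$use_covariates,
    scale = fit$model_frame$scale,
    priors = unclass(fit$priors), control = unclass(fit$control),
    acceptance = as.list(fit$draws$acceptance),
    parameter_names = fit$draws$parameter_names)
  jsonlite::write_json(meta, file.path(dir, "fit_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Reload a persisted trend fit
#'
#' @param dir directory written by [write_fit()].
#' @return an `anc_trend` object equivalent to the one persisted.
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "fit_meta.json"),
                              simplifyVector = TRUE)
  obs <- read_observations(file.path(dir, "observations.csv"))
  cov <- read_covariates(file.path(dir, "covariates.csv"))
  md <- build_model_frame(obs, cov, use_covariates = meta$use_covariates,
                          scale = as.list(meta$scale))
  long <- utils::read.csv(file.path(dir, "draws_long.csv"),
                          stringsAsFactors = FALSE)
  nm <- meta$parameter_names
  chains <- max(long$chain); iters <- max(long$iteration)
  arr <- array(NA_real_, c(chains, iters, length(nm)),
               dimnames = list(NULL, NULL, nm))
  arr[cbind(long$chain, long$iteration, match(long$parameter, nm))] <- long$value
  control <- do.call(sampler_config, as.list(meta$control)[
    c("iterations", "chains", "thin", "burn_in", "seed", "adapt", "step_init")])
  priors <- do.call(anc_priors, as.list(meta$priors))
  draws <- structure(list(draws = arr, parameter_names = nm,
                          acceptance = unlist(meta$acceptance),
                          config = control, layout = make_layout(md)),
                     class = "anc_draws")
  structure(list(draws = draws, model_frame = md, covariates = cov,
                 priors = priors, control = control,
                 indicator = meta$indicator, age_group = meta$age_group,
                 stratum = meta$stratum, use_covariates = meta$use_covariates,
                 call = quote(read_fit(dir))),
            class = "anc_trend")
}

default_run_config <- function() {
  list(
    out = "anctrend-output",
    seed = 1L,
    scenario = list(),
    simulate = list(n_individuals = 0L, horizon = 2030L),
    paths = list(),
    model = list(indicator = "ANC1", age_group = "15-19",
                 stratum = "national", use_covariates = TRUE),
    sampler = list(),
    priors = list(),
    equity = list(threshold = 80, target_year = 2030,
                  shares = rep(0.2, 5), from = 2000, to = 2030),
    determinants = list(indicator = "anc1"),
    sensitivity = list(variants = c("drop_covariates", "alternate_priors"),
                       years = c(2000, 2018, 2030))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

manifest_write <- function(dir, command, config, outputs) {
  inputs <- unlist(config$paths, use.names = TRUE)
  inputs <- inputs[file.exists(inputs)]
  man <- list(
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = config,
    input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)) else list(),
    outputs = outputs,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("anctrend")))
  jsonlite::write_json(man, file.path(dir, paste0("manifest_", command, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

load_fit_inputs <- function(config) {
  obs <- read_observations(config$paths$observations)
  cov <- read_covariates(config$paths$covariates)
  list(obs = obs, cov = cov)
}

config_sampler <- function(config) {
  do.call(sampler_config, merge_config(list(seed = config$seed),
                                       config$sampler))
}

#' Run one stage of the analysis pipeline
#'
#' Subcommands: `simulate` writes synthetic observation/covariate/individual
#' CSVs and the ground-truth bundle; `fit` samples the posterior and persists
#' it; `project` writes projection, target-flag and (when strata allow) gap
#' CSVs; `equity` writes SII and rate-of-change CSVs from a quintile fit;
#' `determinants` fits the individual-level model and writes the odds-ratio
#' table; `diagnose` writes Gelman-Rubin/DIC reports and, when configured,
#' the sensitivity comparison. Every stage writes a manifest (seed, config,
#' input checksums, outputs, versions) sufficient to re-run it. On failure,
#' files created by the stage are removed.
#'
#' @param command one of `simulate`, `fit`, `project`, `equity`,
#'   `determinants`, `diagnose`.
#' @param config a config list, or path to a YAML file with the same
#'   structure; see the package vignette. Unspecified entries fall back to
#'   defaults.
#' @return (invisibly) a named list of written artifact paths.
#' @export
run_pipeline <- function(command = c("simulate", "fit", "project", "equity",
                                     "determinants", "diagnose"),
                         config = list()) {
  command <- match.arg(command)
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_run_config(), config)
  config$seed <- as.integer(config$seed)
  out_dir <- config$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  reg <- function(path) { written <<- c(written, path); path }

  run <- function() {
    switch(command,
      simulate = {
        scen <- do.call(anc_scenario,
                        merge_config(list(seed = config$seed),
                                     config$scenario))
        sim <- simulate_anc_data(scen, horizon = config$simulate$horizon,
                                 n_individuals = config$simulate$n_individuals)
        write_observations(rbind(sim$observations, sim$strata),
                           reg(file.path(out_dir, "observations.csv")))
        write_covariates(sim$covariates,
                         reg(file.path(out_dir, "covariates.csv")))
        if (!is.null(sim$individuals)) {
          utils::write.csv(sim$individuals,
                           reg(file.path(out_dir, "individuals.csv")),
                           row.names = FALSE, quote = FALSE)
        }
        truth <- sim$truth
        utils::write.csv(
          data.frame(country_id = rownames(truth$country_beta),
                     region_id = unname(truth$region_of_country),
                     truth$country_beta),
          reg(file.path(out_dir, "truth_country.csv")), row.names = FALSE)
        utils::write.csv(
          data.frame(region_id = rownames(truth$region_beta),
                     truth$region_beta),
          reg(file.path(out_dir, "truth_region.csv")), row.names = FALSE)
        utils::write.csv(
          data.frame(level = c("global", "sd_region", "sd_country"),
                     rbind(truth$global_beta, truth$sigmas$region_sd,
                           truth$sigmas$country_sd),
                     obs_sd = truth$sigmas$obs_sd),
          reg(file.path(out_dir, "truth_global.csv")), row.names = FALSE)
      },
      fit = {
        inp <- load_fit_inputs(config)
        rep <- validate_dataset(inp$obs, inp$cov)
        if (nrow(rep)) {
          utils::write.csv(rep, reg(file.path(out_dir, "validation.csv")),
                           row.names = FALSE)
        }
        fit <- anc_trend(inp$obs, inp$cov,
                         indicator = config$model$indicator,
                         age_group = config$model$age_group,
                         stratum = config$model$stratum,
                         use_covariates = isTRUE(config$model$use_covariates),
                         priors = do.call(anc_priors, config$priors),
                         control = config_sampler(config))
        fit_dir <- file.path(out_dir, "fit")
        write_fit(fit, fit_dir)
        reg(file.path(fit_dir, c("draws_long.csv", "fit_meta.json",
                                 "observations.csv", "covariates.csv")))
        gr <- gelman_rubin(fit$draws)
        utils::write.csv(gr, reg(file.path(out_dir, "psrf.csv")),
                         row.names = FALSE)
        d <- dic(fit)
        utils::write.csv(data.frame(dic = d$dic, dbar = d$dbar, pd = d$pd),
                         reg(file.path(out_dir, "dic.csv")), row.names = FALSE)
      },
      project = {
        fit <- read_fit(file.path(out_dir, "fit"))
        proj <- project_coverage(fit, keep_draws = TRUE)
        utils::write.csv(
          proj[, c("country_id", "year", "age_group", "indicator", "stratum",
                   "mean_coverage", "cri_low", "cri_high")],
          reg(file.path(out_dir, "projection.csv")), row.names = FALSE)
        flags <- flag_threshold(proj, threshold = config$equity$threshold,
                                target_year = config$equity$target_year)
        utils::write.csv(flags, reg(file.path(out_dir, "flags.csv")),
                         row.names = FALSE)
        if (all(c("urban", "rural") %in% proj$stratum)) {
          utils::write.csv(urban_rural_gap(proj),
                           reg(file.path(out_dir, "urban_rural_gap.csv")),
                           row.names = FALSE)
        }
      },
      equity = {
        fit <- read_fit(file.path(out_dir, "fit"))
        proj <- project_coverage(fit, keep_draws = TRUE)
        if (fit$stratum == "quintile") {
          utils::write.csv(sii_table(proj, shares = config$equity$shares),
                           reg(file.path(out_dir, "sii.csv")),
                           row.names = FALSE)
        }
        utils::write.csv(rate_of_change(proj, from = config$equity$from,
                                        to = config$equity$to),
                         reg(file.path(out_dir, "rate_of_change.csv")),
                         row.names = FALSE)
      },
      determinants = {
        indiv <- utils::read.csv(config$paths$individuals,
                                 stringsAsFactors = FALSE)
        dfit <- anc_determinants(indiv,
                                 indicator = config$determinants$indicator,
                                 priors = do.call(anc_priors, config$priors),
                                 control = config_sampler(config))
        utils::write.csv(summarize_odds_ratios(dfit),
                         reg(file.path(out_dir, "odds_ratios.csv")),
                         row.names = FALSE)
      },
      diagnose = {
        fit <- read_fit(file.path(out_dir, "fit"))
        gr <- gelman_rubin(fit$draws)
        utils::write.csv(gr, reg(file.path(out_dir, "psrf.csv")),
                         row.names = FALSE)
        d <- dic(fit)
        utils::write.csv(data.frame(dic = d$dic, dbar = d$dbar, pd = d$pd),
                         reg(file.path(out_dir, "dic.csv")), row.names = FALSE)
        if (length(config$sensitivity$variants)) {
          sens <- sensitivity_compare(
            fit$model_frame$data, fit$covariates,
            variants = config$sensitivity$variants,
            indicator = fit$indicator, age_group = fit$age_group,
            stratum = fit$stratum, priors = fit$priors,
            control = fit$control, years = config$sensitivity$years)
          utils::write.csv(sens$comparison,
                           reg(file.path(out_dir, "sensitivity.csv")),
                           row.names = FALSE)
          utils::write.csv(sens$summary,
                           reg(file.path(out_dir, "sensitivity_summary.csv")),
                           row.names = FALSE)
        }
      })
  }

  ok <- FALSE
  tryCatch({
    run()
    ok <- TRUE
  }, finally = {
    if (!ok) unlink(written)
  })
  manifest_write(out_dir, command, config, as.list(written))
  invisible(stats::setNames(as.list(written), basename(written)))
}
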