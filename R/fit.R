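#' Fit the Bayesian hierarchical ANC coverage trend model
#'
#' The workhorse fitter. Selects one indicator, age group and stratum system
#' from the observation table, binds covariates, and samples the posterior of
#' the hierarchical logit-scale regression (countries nested in regions, with
#' year, SDI and HRH effects) by Metropolis-within-Gibbs. Each indicator, age
#' group and stratum system is fitted independently; the `"quintile"` system
#' fits the five wealth-quintile series jointly with country-by-quintile
#' offsets on intercept and year slope (sum-to-zero within country).
#'
#' @param observations validated observation table (see
#'   [read_observations()]).
#' @param covariates covariate table covering all observation years.
#' @param indicator `"ANC1"` or `"ANC4"`.
#' @param age_group one of `"15-19"`, `"20-35"`, `"36-49"`.
#' @param stratum `"national"`, `"urban"`, `"rural"` (each fitted on its own
#'   rows) or `"quintile"` (joint fit of Q1..Q5 rows).
#' @param use_covariates include the SDI/HRH columns (set `FALSE` for the
#'   covariate-exclusion sensitivity fit).
#' @param priors an [anc_priors()].
#' @param control an [sampler_config()].
#' @param fixed optional list fixing scale parameters at known values
#'   (validation use).
#' @return an object of class `anc_trend` with components `draws`
#'   (an `anc_draws`), the model frame, data, priors and control settings.
#'   Methods: [print()], [summary()], [coef()], [predict.anc_trend()],
#'   [plot.anc_trend()], [simulate.anc_trend()], [residuals.anc_trend()],
#'   [fitted()], [dic()].
#' @examples
#' \donttest{
#' sim <- simulate_anc_data(anc_scenario(n_regions = 2,
#'                                       countries_per_region = 3, seed = 7))
#' fit <- anc_trend(sim$observations, sim$covariates,
#'                  control = sampler_config(iterations = 600, burn_in = 200,
#'                                           thin = 2, chains = 2, seed = 7))
#' summary(fit)
#' }
#' @export
anc_trend <- function(observations, covariates,
                      indicator = "ANC1", age_group = "15-19",
                      stratum = c("national", "urban", "rural", "quintile"),
                      use_covariates = TRUE,
                      priors = anc_priors(),
                      control = sampler_config(),
                      fixed = list()) {
  stratum <- match.arg(stratum)
  strata_wanted <- if (stratum == "quintile") paste0("Q", 1:5) else stratum
  obs <- observations[observations$indicator == indicator &
                        observations$age_group == age_group &
                        observations$stratum %in% strata_wanted, , drop = FALSE]
  if (!nrow(obs)) {
    stop("no observations for indicator=", indicator, ", age_group=",
         age_group, ", stratum=", stratum)
  }
  md <- build_model_frame(obs, covariates, use_covariates = use_covariates)
  draws <- run_sampler(md, priors, control, fixed = fixed)
  structure(list(draws = draws, model_frame = md,
                 covariates = covariates, priors = priors, control = control,
                 indicator = indicator, age_group = age_group,
                 stratum = stratum, use_covariates = use_covariates,
                 call = match.call()),
            class = "anc_trend")
}

# posterior mean of every parameter, as a state object
posterior_mean_state <- function(fit) {
  unpack_state(colMeans(as.matrix(fit$draws)), fit$draws$layout)
}

#' @export
print.anc_trend <- function(x, ...) {
  md <- x$model_frame
  cat("Hierarchical ANC coverage trend model (", x$indicator, ", ages ",
      x$age_group, ", ", x$stratum, " stratum)\n", sep = "")
  cat(" ", md$n, "observations;", length(md$countries), "countries in",
      length(md$regions), "regions;",
      if (md$use_covariates) "covariates: year + SDI + HRH"
      else "covariates: year only", "\n")
  cfg <- x$control
  cat("  sampler:", cfg$chains, "chains x", cfg$iterations, "iterations",
      "(burn-in", paste0(cfg$burn_in, ","), "thin", paste0(cfg$thin, ")"),
      "->", cfg$n_retained * cfg$chains, "retained draws\n")
  gb <- posterior_mean_state(x)$global_beta
  cat("  posterior mean global coefficients:",
      paste(names(gb), signif(gb, 3), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Posterior summary of a trend fit
#'
#' Posterior mean, sd and 95% credible interval for the global coefficients
#' and the noise sd, plus the worst (largest) Gelman-Rubin statistics over all
#' parameters and the Metropolis acceptance rates.
#'
#' @param object an `anc_trend` fit.
#' @param level credible-interval mass.
#' @param ... unused.
#' @return a `summary.anc_trend` list.
#' @export
summary.anc_trend <- function(object, level = 0.95, ...) {
  mat <- as.matrix(object$draws)
  keep <- c(paste0("beta[", object$draws$layout$coefs, "]"), "tau")
  tab <- t(vapply(keep, function(nm) {
    ci <- credible_interval(mat[, nm], level)
    c(mean = mean(mat[, nm]), sd = stats::sd(mat[, nm]), ci)
  }, numeric(4)))
  gr <- if (object$control$chains >= 2) gelman_rubin(object$draws) else NULL
  out <- list(coefficients = tab, psrf = gr,
              acceptance = object$draws$acceptance,
              level = level, fit = object)
  class(out) <- "summary.anc_trend"
  out
}

#' @export
print.summary.anc_trend <- function(x, ...) {
  print(x$fit)
  cat("\nPosterior summaries (", round(100 * x$level),
      "% credible intervals):\n", sep = "")
  print(round(x$coefficients, 4))
  if (!is.null(x$psrf)) {
    worst <- x$psrf[which.max(x$psrf$point), ]
    cat("\nGelman-Rubin: max point estimate ", round(worst$point, 3),
        " (upper ", round(worst$upper, 3), ") at ", worst$parameter, "\n",
        sep = "")
  }
  cat("Metropolis acceptance:",
      paste(names(x$acceptance), signif(x$acceptance, 2), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Posterior mean coefficients
#'
#' @param object an `anc_trend` fit.
#' @param which `"global"`, `"region"` or `"country"` coefficients.
#' @param ... unused.
#' @return named vector (global) or matrix (region/country).
#' @export
coef.anc_trend <- function(object, which = c("global", "region", "country"),
                           ...) {
  which <- match.arg(which)
  st <- posterior_mean_state(object)
  switch(which, global = st$global_beta, region = st$region_beta,
         country = st$country_beta)
}

#' Residuals on the logit scale
#'
#' Observed logit coverage minus the posterior-mean linear predictor.
#'
#' @param object an `anc_trend` fit.
#' @param ... unused.
#' @return numeric vector, one element per observation row.
#' @export
residuals.anc_trend <- function(object, ...) {
  md <- object$model_frame
  md$y - state_eta(posterior_mean_state(object), md)
}

#' @export
fitted.anc_trend <- function(object, ...) {
  inverse_logit(state_eta(posterior_mean_state(object), object$model_frame))
}

#' Posterior-predictive simulation of observed survey points
#'
#' For each replicate, draws a retained posterior sample and simulates new
#' logit-scale observations with Normal noise `tau`, returned as proportions.
#'
#' @param object an `anc_trend` fit.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated proportions, one row
#'   per observation.
#' @export
simulate.anc_trend <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  md <- object$model_frame
  mat <- as.matrix(object$draws)
  lay <- object$draws$layout
  idx <- sample(nrow(mat), nsim, replace = nsim > nrow(mat))
  out <- vapply(idx, function(i) {
    st <- unpack_state(mat[i, ], lay)
    inverse_logit(state_eta(st, md) + stats::rnorm(md$n, 0, st$obs_sd))
  }, numeric(md$n))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @rdname dic
#' @export
dic.anc_trend <- function(object, ...) {
  ll <- draws_loglik(object$draws, object$model_frame)
  dbar <- mean(-2 * ll)
  dhat <- -2 * log_likelihood(posterior_mean_state(object),
                              object$model_frame)
  pd <- dbar - dhat
  list(dic = dbar + pd, dbar = dbar, pd = pd)
}

#' Project coverage from a fitted model
#'
#' Thin wrapper around [project_coverage()].
#'
#' @param object an `anc_trend` fit.
#' @param years projection years (default 2000:2030).
#' @param covariates optional covariate table covering `years`; by default the
#'   fit's covariates are extended by [extrapolate_covariates()].
#' @param ... passed to [project_coverage()].
#' @return a projection table (see [project_coverage()]).
#' @export
predict.anc_trend <- function(object, years = 2000:2030, covariates = NULL,
                              ...) {
  project_coverage(object, years = years, covariates = covariates, ...)
}

#' Plot a fitted trend model
#'
#' `type = "trend"` draws projected mean coverage with the 95% credible band
#' per country; `type = "trace"` draws per-chain trace plots of a parameter.
#'
#' @param x an `anc_trend` fit.
#' @param type `"trend"` or `"trace"`.
#' @param countries countries to draw (default: up to 6).
#' @param parameter parameter name for trace plots (default the global year
#'   slope).
#' @param years projection years for the trend panel.
#' @param ... further graphical arguments.
#' @return invisibly, the projection table (trend) or `NULL` (trace).
#' @export
plot.anc_trend <- function(x, type = c("trend", "trace"), countries = NULL,
                           parameter = NULL, years = 2000:2030, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    if (is.null(parameter)) parameter <- "beta[year]"
    arr <- x$draws$draws
    graphics::matplot(t(arr[, , parameter]), type = "l", lty = 1,
                      xlab = "retained iteration", ylab = parameter,
                      main = paste("Trace:", parameter), ...)
    return(invisible(NULL))
  }
  proj <- project_coverage(x, years = years)
  if (is.null(countries)) {
    countries <- utils::head(unique(proj$country_id), 6)
  }
  proj <- proj[proj$country_id %in% countries & proj$stratum %in%
                 c("national", "urban", "rural", "Q1", "Q5"), ]
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(countries)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (ctry in countries) {
    pc <- proj[proj$country_id == ctry, ]
    s1 <- pc[pc$stratum == pc$stratum[1], ]
    graphics::plot(s1$year, s1$mean_coverage, type = "l", ylim = c(0, 100),
                   xlab = "year", ylab = "coverage (%)", main = ctry, ...)
    graphics::polygon(c(s1$year, rev(s1$year)),
                      c(s1$cri_low, rev(s1$cri_high)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(s1$year, s1$mean_coverage, lwd = 2, col = "steelblue4")
    graphics::abline(h = 80, lty = 3)
  }
  invisible(proj)
}
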