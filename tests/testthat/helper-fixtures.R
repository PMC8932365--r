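# Shared fixtures. Heavier objects (a fitted model on the small default
# scenario) are built once per test session and reused across files.

.fixture_env <- new.env(parent = emptyenv())

tiny_scenario <- function(seed = 11, ...) {
  args <- list(n_regions = 2, countries_per_region = 3,
               points_per_country = c(4, 6), seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(anc_scenario, args)
}

# an observation/covariate pair small enough for fast fits
tiny_data <- function(seed = 11, ...) {
  simulate_anc_data(tiny_scenario(seed = seed, ...))
}

# short-chain fit on the tiny scenario, cached
cached_tiny_fit <- function() {
  if (is.null(.fixture_env$tiny_fit)) {
    sim <- tiny_data(seed = 11)
    .fixture_env$tiny_sim <- sim
    .fixture_env$tiny_fit <- anc_trend(
      sim$observations, sim$covariates,
      control = sampler_config(iterations = 1200, burn_in = 400, thin = 4,
                               chains = 2, seed = 5))
  }
  list(fit = .fixture_env$tiny_fit, sim = .fixture_env$tiny_sim)
}

# single-country model frame with directly controlled design values:
# `sdi`/`hrh` are passed through unstandardized (scale fixed to identity)
oracle_frame <- function(n = 30, seed = 2, beta = c(0.5, 0.08, 0.3, 0.1),
                         tau = 0.3) {
  set.seed(seed)
  years <- sample(2000:2019, n, replace = TRUE)
  uy <- sort(unique(years))
  sdi_y <- runif(length(uy))
  hrh_y <- runif(length(uy), 0, 4)
  sdi <- sdi_y[match(years, uy)]
  hrh <- hrh_y[match(years, uy)]
  eta <- beta[1] + beta[2] * (years - 2000) + beta[3] * sdi + beta[4] * hrh
  y <- eta + rnorm(n, 0, tau)
  obs <- as_observations(data.frame(
    region_id = "R1", country_id = "C1", year = years, age_group = "15-19",
    indicator = "ANC1", stratum = "national", proportion = plogis(y),
    stringsAsFactors = FALSE), eps = 1e-9)
  cov <- data.frame(country_id = "C1", year = uy, sdi = sdi_y, hrh = hrh_y,
                    stringsAsFactors = FALSE)
  md <- anctrend:::build_model_frame(obs, cov,
                                     scale = list(sdi_mean = 0, sdi_sd = 1,
                                                  hrh_mean = 0, hrh_sd = 1))
  md
}

# hand-built parameter state for predictor/likelihood tests
manual_state <- function(country_beta, regions = "R1",
                         countries = rownames(country_beta),
                         region_sd = 1, global_sd = 1, obs_sd = 1) {
  p <- ncol(country_beta)
  structure(list(
    global_beta = rep(0, p),
    region_beta = matrix(0, length(regions), p,
                         dimnames = list(regions, colnames(country_beta))),
    country_beta = country_beta,
    region_sd = matrix(region_sd, length(regions), p,
                       dimnames = list(regions, colnames(country_beta))),
    global_sd = rep(global_sd, p),
    obs_sd = obs_sd), class = "anc_state")
}

# minimal hand-built fit object: given draws of country coefficients, the
# projection machinery can be exercised without running the sampler
fake_fit <- function(draw_beta, countries = "C1", stratum = "national",
                     years_cov = 2000:2030, use_covariates = FALSE) {
  # draw_beta: n_draws x 2 (intercept, year) per country, or list per country
  if (!is.list(draw_beta)) draw_beta <- setNames(list(draw_beta), countries)
  nd <- nrow(draw_beta[[1]])
  coefs <- c("intercept", "year")
  nm <- c(paste0("beta[", coefs, "]"),
          anctrend:::mat_names("beta_region", "R1", coefs),
          anctrend:::mat_names("beta_country", countries, coefs),
          anctrend:::mat_names("sigma_region", "R1", coefs),
          paste0("sigma_global[", coefs, "]"), "tau")
  mat <- matrix(0.5, nd, length(nm), dimnames = list(NULL, nm))
  for (k in seq_along(countries)) {
    mat[, paste0("beta_country[", countries[k], ",intercept]")] <-
      draw_beta[[k]][, 1]
    mat[, paste0("beta_country[", countries[k], ",year]")] <-
      draw_beta[[k]][, 2]
  }
  mat[, "tau"] <- 0.2
  lay <- list(p = 2L, coefs = coefs, countries = countries, regions = "R1",
              region_of_country = rep(1L, length(countries)),
              quint = FALSE, use_covariates = FALSE, scale = NULL)
  draws <- structure(list(
    draws = array(mat, c(1, nd, length(nm)),
                  dimnames = list(NULL, NULL, nm)),
    parameter_names = nm, acceptance = c(tau = 0.4),
    config = sampler_config(iterations = 20, burn_in = 0, thin = 1,
                            chains = 1), layout = lay),
    class = "anc_draws")
  md <- list(countries = countries, regions = "R1",
             region_of_country = rep(1L, length(countries)),
             use_covariates = FALSE, scale = NULL, n = 1L)
  structure(list(draws = draws, model_frame = md, covariates = NULL,
                 indicator = "ANC1", age_group = "15-19", stratum = stratum,
                 use_covariates = FALSE),
            class = "anc_trend")
}

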