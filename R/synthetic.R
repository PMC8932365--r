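# Synthetic multi-country survey data with known ground truth.
#
# The generator mirrors the structure the hierarchical model assumes: country
# regression coefficients drawn around region means, region means around a
# global mean, sparse noisy survey points on the logit scale, monotone SDI/HRH
# covariate trajectories, stratified (urban/rural, wealth-quintile) offsets,
# and individual-level records with known log-odds effects.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so all
#' generator randomness flows from the configured seed without disturbing
#' global state.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

COEF_NAMES <- c("intercept", "year", "sdi", "hrh")

#' Reference log-odds effects for the determinant generator
#'
#' Named log-odds coefficient vectors (one per indicator) used as the default
#' ground truth for [generate_individuals()]. Magnitudes follow published
#' odds-ratio estimates for ANC determinants in LMICs (e.g. richest-vs-poorest
#' OR 1.42 for ANC1 and 1.76 for ANC4), giving the generator realistic effect
#' sizes.
#' @return list with elements `anc1` and `anc4`, each a named numeric vector.
#' @export
default_determinant_coefs <- function() {
  list(
    anc1 = log(c(
      "hh_head_age:30-45" = 1.02, "hh_head_age:46-60" = 1.42,
      "hh_head_age:>60" = 1.29, "hh_head_sex:female" = 1.14,
      "education:primary" = 1.52, "education:secondary" = 2.10,
      "education:higher" = 2.22, "parity:2" = 1.03, "parity:3+" = 0.98,
      "mass_media:<once/week" = 1.19, "mass_media:>=once/week" = 1.32,
      "wealth_quintile:Q2" = 1.15, "wealth_quintile:Q3" = 1.26,
      "wealth_quintile:Q4" = 1.27, "wealth_quintile:Q5" = 1.42,
      "residence:rural" = 0.88)),
    anc4 = log(c(
      "hh_head_age:30-45" = 1.00, "hh_head_age:46-60" = 1.20,
      "hh_head_age:>60" = 1.19, "hh_head_sex:female" = 1.05,
      "education:primary" = 1.66, "education:secondary" = 2.28,
      "education:higher" = 2.90, "parity:2" = 0.99, "parity:3+" = 0.89,
      "mass_media:<once/week" = 1.16, "mass_media:>=once/week" = 1.44,
      "wealth_quintile:Q2" = 1.29, "wealth_quintile:Q3" = 1.44,
      "wealth_quintile:Q4" = 1.59, "wealth_quintile:Q5" = 1.76,
      "residence:rural" = 0.83))
  )
}

#' Scenario configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: a desk-scale default
#' of 4 regions x 5 countries with 3-8 sparse survey points each over
#' 2000-2019, logit-scale Normal observation noise, rising SDI/HRH
#' trajectories, an ordered pro-rich quintile gradient and an urban > rural
#' offset. A 54-country configuration is available by raising `n_regions` /
#' `countries_per_region`.
#'
#' @param n_regions number of regions.
#' @param countries_per_region countries nested in each region.
#' @param year_range two-element observation window (calendar years).
#' @param points_per_country two-element range; each country receives a
#'   uniform draw of survey years (without replacement) in this range.
#' @param global_means global coefficient vector (intercept, per-year slope,
#'   SDI effect, HRH effect) on the logit scale.
#' @param region_sd between-region coefficient standard deviations (length 4).
#' @param country_sd within-region, between-country standard deviations
#'   (length 4).
#' @param obs_sd logit-scale observation noise standard deviation (tau).
#' @param quintile_gradient length-5 logit offsets for Q1..Q5 (non-decreasing
#'   for pro-rich inequality).
#' @param urban_offset,rural_offset logit offsets for the urban and rural
#'   strata.
#' @param indicator,age_group labels stamped on generated observation rows.
#' @param determinant_coefs list with `anc1`/`anc4` named log-odds vectors
#'   (defaults to [default_determinant_coefs()]).
#' @param determinant_intercept named vector, log-odds intercepts for the two
#'   individual-level outcomes.
#' @param determinant_sd standard deviation of country random intercepts in
#'   the individual-level model.
#' @param covariate_freqs optional named list of category probabilities for
#'   the individual-level covariates (default uniform within each covariate).
#' @param nest_anc4 if `TRUE`, enforce ANC4 => ANC1 on generated individuals;
#'   off by default to match the independent-models assumption.
#' @param seed integer seed from which all generator randomness flows.
#' @return an object of class `anc_scenario` (a validated list).
#' @export
anc_scenario <- function(n_regions = 4L,
                         countries_per_region = 5L,
                         year_range = c(2000L, 2019L),
                         points_per_country = c(3L, 8L),
                         global_means = c(intercept = 0.2, year = 0.06,
                                          sdi = 1.0, hrh = 0.05),
                         region_sd = c(0.4, 0.015, 0.2, 0.02),
                         country_sd = c(0.5, 0.02, 0.2, 0.02),
                         obs_sd = 0.25,
                         quintile_gradient = c(-0.6, -0.3, 0, 0.3, 0.6),
                         urban_offset = 0.5,
                         rural_offset = -0.5,
                         indicator = "ANC1",
                         age_group = "15-19",
                         determinant_coefs = default_determinant_coefs(),
                         determinant_intercept = c(anc1 = 0.3, anc4 = -0.8),
                         determinant_sd = 0.3,
                         covariate_freqs = NULL,
                         nest_anc4 = FALSE,
                         seed = 1L) {
  stopifnot(n_regions >= 1, countries_per_region >= 1,
            length(year_range) == 2, year_range[2] >= year_range[1],
            length(points_per_country) == 2,
            points_per_country[1] >= 1,
            length(global_means) == 4, length(region_sd) == 4,
            length(country_sd) == 4, length(quintile_gradient) == 5)
  if (any(region_sd < 0) || any(country_sd < 0) || obs_sd < 0 ||
      determinant_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  window <- year_range[2] - year_range[1] + 1L
  if (points_per_country[2] > window) {
    stop("points_per_country exceeds the observation window length")
  }
  cfg <- list(
    n_regions = as.integer(n_regions),
    countries_per_region = as.integer(countries_per_region),
    year_range = as.integer(year_range),
    points_per_country = as.integer(points_per_country),
    global_means = stats::setNames(as.numeric(global_means), COEF_NAMES),
    region_sd = stats::setNames(as.numeric(region_sd), COEF_NAMES),
    country_sd = stats::setNames(as.numeric(country_sd), COEF_NAMES),
    obs_sd = obs_sd,
    quintile_gradient = stats::setNames(quintile_gradient, paste0("Q", 1:5)),
    urban_offset = urban_offset, rural_offset = rural_offset,
    indicator = indicator, age_group = age_group,
    determinant_coefs = determinant_coefs,
    determinant_intercept = determinant_intercept,
    determinant_sd = determinant_sd,
    covariate_freqs = covariate_freqs,
    nest_anc4 = isTRUE(nest_anc4),
    seed = as.integer(seed)
  )
  class(cfg) <- "anc_scenario"
  cfg
}

#' Draw the ground-truth parameter bundle for a scenario
#'
#' Region coefficient vectors are drawn Normal around the global means with
#' the between-region sds; country vectors Normal around their region with the
#' between-country sds; determinant country intercepts Normal(0,
#' `determinant_sd`). Deterministic given the scenario seed.
#'
#' @param scenario an [anc_scenario()].
#' @return an object of class `anc_truth`: global/region/country coefficient
#'   arrays, the region map, stratum offsets and determinant coefficients.
#'   Every noiseless logit value in generated data is reproducible from this
#'   bundle plus the covariates.
#' @export
generate_truth <- function(scenario) {
  stopifnot(inherits(scenario, "anc_scenario"))
  J <- scenario$n_regions
  Kr <- scenario$countries_per_region
  K <- J * Kr
  regions <- sprintf("R%d", seq_len(J))
  countries <- sprintf("C%02d", seq_len(K))
  region_of <- rep(regions, each = Kr)
  with_seed(scenario$seed, {
    region_beta <- matrix(stats::rnorm(J * 4, rep(scenario$global_means, each = J),
                                       rep(scenario$region_sd, each = J)),
                          nrow = J, dimnames = list(regions, COEF_NAMES))
    country_beta <- matrix(0, K, 4, dimnames = list(countries, COEF_NAMES))
    for (k in seq_len(K)) {
      country_beta[k, ] <- stats::rnorm(4, region_beta[region_of[k], ],
                                        scenario$country_sd)
    }
    det_u <- matrix(stats::rnorm(K * 2, 0, scenario$determinant_sd), K, 2,
                    dimnames = list(countries, c("anc1", "anc4")))
    structure(list(
      global_beta = scenario$global_means,
      region_beta = region_beta,
      country_beta = country_beta,
      region_of_country = stats::setNames(region_of, countries),
      sigmas = list(region_sd = scenario$region_sd,
                    country_sd = scenario$country_sd,
                    obs_sd = scenario$obs_sd),
      quintile_gradient = scenario$quintile_gradient,
      urban_offset = scenario$urban_offset,
      rural_offset = scenario$rural_offset,
      determinant_coefs = scenario$determinant_coefs,
      determinant_intercept = scenario$determinant_intercept,
      determinant_country_effects = det_u,
      scenario = scenario
    ), class = "anc_truth")
  })
}

#' Generate SDI and HRH covariate trajectories
#'
#' SDI follows a per-country scaled logistic curve (monotone non-decreasing,
#' inside \[0, 1\]); HRH is linear-plus-noise, clipped at 0. Trajectories cover
#' the full projection horizon so truth-known tests need no extrapolation.
#'
#' @param scenario an [anc_scenario()].
#' @param years calendar years to cover (default 2000:2030).
#' @return a covariate table (see [read_covariates()]).
#' @export
generate_covariates <- function(scenario, years = 2000:2030) {
  stopifnot(inherits(scenario, "anc_scenario"))
  K <- scenario$n_regions * scenario$countries_per_region
  countries <- sprintf("C%02d", seq_len(K))
  with_seed(scenario$seed + 1L, {
    out <- lapply(countries, function(ctry) {
      base <- stats::runif(1, 0.20, 0.45)
      cap <- stats::runif(1, 0.60, 0.95)
      mid <- stats::runif(1, 2004, 2018)
      rate <- stats::runif(1, 0.08, 0.20)
      sdi <- base + (cap - base) * stats::plogis(rate * (years - mid))
      h0 <- stats::runif(1, 0.5, 2.0)
      hslope <- stats::runif(1, 0.02, 0.12)
      hrh <- pmax(0, h0 + hslope * (years - min(years)) +
                    stats::rnorm(length(years), 0, 0.03))
      data.frame(country_id = ctry, year = years, sdi = sdi, hrh = hrh,
                 stringsAsFactors = FALSE)
    })
    as_covariates(do.call(rbind, out))
  })
}

# noiseless logit value for given country rows of a covariate table
truth_linear_predictor <- function(truth, country_id, year, sdi, hrh) {
  b <- truth$country_beta[country_id, , drop = FALSE]
  b[, "intercept"] + b[, "year"] * (year - 2000) + b[, "sdi"] * sdi +
    b[, "hrh"] * hrh
}

sample_survey_years <- function(scenario) {
  yrs <- seq(scenario$year_range[1], scenario$year_range[2])
  n <- if (scenario$points_per_country[1] == scenario$points_per_country[2]) {
    scenario$points_per_country[1]
  } else {
    sample(seq(scenario$points_per_country[1],
               scenario$points_per_country[2]), 1L)
  }
  sort(sample(yrs, n))
}

#' Generate national-level survey observations
#'
#' Per country, draws a number of survey years (without replacement) from the
#' observation window, computes the noiseless logit value from the truth
#' bundle and covariates, and adds Normal(0, `obs_sd`) noise.
#'
#' @param truth an `anc_truth` from [generate_truth()].
#' @param cov covariate table covering all sampled years.
#' @param scenario the generating [anc_scenario()].
#' @return a validated observation table with `stratum = "national"`.
#' @export
generate_observations <- function(truth, cov, scenario) {
  stopifnot(inherits(truth, "anc_truth"), inherits(scenario, "anc_scenario"))
  with_seed(scenario$seed + 2L, {
    rows <- lapply(rownames(truth$country_beta), function(ctry) {
      yrs <- sample_survey_years(scenario)
      cc <- cov[cov$country_id == ctry & cov$year %in% yrs, ]
      if (nrow(cc) != length(yrs)) stop("covariates missing for ", ctry)
      cc <- cc[order(cc$year), ]
      eta <- truth_linear_predictor(truth, ctry, cc$year, cc$sdi, cc$hrh)
      y <- eta + stats::rnorm(length(eta), 0, scenario$obs_sd)
      data.frame(
        region_id = unname(truth$region_of_country[ctry]),
        country_id = ctry, year = cc$year,
        age_group = scenario$age_group, indicator = scenario$indicator,
        stratum = "national",
        proportion = inverse_logit(y),
        ess = round(stats::runif(length(y), 300, 3000)),
        stringsAsFactors = FALSE
      )
    })
    as_observations(do.call(rbind, rows))
  })
}

#' Generate stratified survey observations
#'
#' For each sampled country-year, emits a national row (offset-free), urban
#' and rural rows, and Q1..Q5 wealth-quintile rows, adding the configured
#' logit offsets to the national linear predictor before observation noise.
#'
#' @inheritParams generate_observations
#' @return a validated observation table with strata
#'   national/urban/rural/Q1..Q5.
#' @export
generate_strata <- function(truth, cov, scenario) {
  stopifnot(inherits(truth, "anc_truth"), inherits(scenario, "anc_scenario"))
  offsets <- c(national = 0,
               urban = scenario$urban_offset, rural = scenario$rural_offset,
               scenario$quintile_gradient)
  with_seed(scenario$seed + 3L, {
    rows <- lapply(rownames(truth$country_beta), function(ctry) {
      yrs <- sample_survey_years(scenario)
      cc <- cov[cov$country_id == ctry & cov$year %in% yrs, ]
      if (nrow(cc) != length(yrs)) stop("covariates missing for ", ctry)
      cc <- cc[order(cc$year), ]
      eta <- truth_linear_predictor(truth, ctry, cc$year, cc$sdi, cc$hrh)
      per_stratum <- lapply(names(offsets), function(s) {
        y <- eta + offsets[[s]] +
          stats::rnorm(length(eta), 0, scenario$obs_sd)
        data.frame(
          region_id = unname(truth$region_of_country[ctry]),
          country_id = ctry, year = cc$year,
          age_group = scenario$age_group, indicator = scenario$indicator,
          stratum = s, proportion = inverse_logit(y),
          ess = round(stats::runif(length(y), 150, 1500)),
          stringsAsFactors = FALSE
        )
      })
      do.call(rbind, per_stratum)
    })
    as_observations(do.call(rbind, rows))
  })
}

INDIVIDUAL_VOCAB <- list(
  hh_head_age = c("<30", "30-45", "46-60", ">60"),
  hh_head_sex = c("male", "female"),
  education = c("none", "primary", "secondary", "higher"),
  parity = c("1", "2", "3+"),
  mass_media = c("none", "<once/week", ">=once/week"),
  wealth_quintile = paste0("Q", 1:5),
  residence = c("urban", "rural")
)

#' Generate individual-level determinant records
#'
#' Draws categorical covariates from the configured frequencies (uniform by
#' default), assigns countries uniformly, computes the log-odds
#' `intercept + country effect + sum of category coefficients` and draws
#' Bernoulli ANC1 and ANC4 outcomes independently (unless `nest_anc4`).
#'
#' @param truth an `anc_truth`.
#' @param scenario the generating [anc_scenario()].
#' @param n number of records.
#' @return a data.frame with the categorical covariates, `country_id` and
#'   binary `anc1`, `anc4` columns.
#' @export
generate_individuals <- function(truth, scenario, n) {
  stopifnot(inherits(truth, "anc_truth"), inherits(scenario, "anc_scenario"))
  if (length(n) != 1L || n <= 0) stop("`n` must be a positive count")
  countries <- rownames(truth$country_beta)
  with_seed(scenario$seed + 4L, {
    df <- data.frame(country_id = sample(countries, n, replace = TRUE),
                     stringsAsFactors = FALSE)
    for (v in names(INDIVIDUAL_VOCAB)) {
      levs <- INDIVIDUAL_VOCAB[[v]]
      pr <- scenario$covariate_freqs[[v]]
      if (is.null(pr)) pr <- rep(1 / length(levs), length(levs))
      df[[v]] <- sample(levs, n, replace = TRUE, prob = pr)
    }
    for (ind in c("anc1", "anc4")) {
      eta <- rep(truth$determinant_intercept[[ind]], n) +
        truth$determinant_country_effects[df$country_id, ind]
      coefs <- truth$determinant_coefs[[ind]]
      for (v in names(INDIVIDUAL_VOCAB)) {
        keys <- paste0(v, ":", df[[v]])
        hit <- keys %in% names(coefs)
        eta[hit] <- eta[hit] + coefs[keys[hit]]
      }
      df[[ind]] <- stats::rbinom(n, 1L, stats::plogis(eta))
    }
    if (scenario$nest_anc4) df$anc4 <- df$anc4 * df$anc1
    df
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: truth bundle, covariates over the full horizon,
#' national observations, stratified observations, and (optionally)
#' individual-level records.
#'
#' @param scenario an [anc_scenario()].
#' @param horizon last covariate year (default 2030).
#' @param n_individuals number of individual records (0 to skip).
#' @return list with elements `truth`, `covariates`, `observations`,
#'   `strata`, and `individuals` (NULL when skipped).
#' @export
simulate_anc_data <- function(scenario = anc_scenario(), horizon = 2030,
                              n_individuals = 0) {
  truth <- generate_truth(scenario)
  cov <- generate_covariates(scenario, years = 2000:horizon)
  obs <- generate_observations(truth, cov, scenario)
  strata <- generate_strata(truth, cov, scenario)
  indiv <- if (n_individuals > 0) {
    generate_individuals(truth, scenario, n_individuals)
  }
  list(truth = truth, covariates = cov, observations = obs,
       strata = strata, individuals = indiv)
}
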