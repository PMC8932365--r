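# The hierarchical trend model on the logit scale:
#
#   y ~ Normal(eta, tau^2)
#   eta = b0[country] + b1[country] * (year - 2000)
#         + b2[country] * sdi_std + b3[country] * hrh_std
#   beta[country] ~ N(beta[region], sigma_region^2)   (per coefficient)
#   beta[region]  ~ N(beta_global,  sigma_global^2)   (per coefficient)
#   beta_global   ~ N(0, 10000)
#   sigma_region, sigma_global ~ Gamma(0.001, 0.001)  (on the sd, not precision)
#   tau ~ Uniform(0, 1000)
#
# The wealth-quintile extension adds country-by-quintile offsets on the
# intercept and year slope, each family shrunk by its own sd (the two live
# on different scales) and identified by a sum-to-zero constraint across
# quintiles within each country.

#' Prior specification for the hierarchical model
#'
#' Diffuse defaults: Normal(0, variance 10 000) on the global coefficients,
#' Gamma(shape 0.001, rate 0.001) on every hierarchical standard deviation,
#' and Uniform(0, 1000) on the observation noise sd. A half-Cauchy alternative
#' for the sd priors supports the prior-sensitivity analysis.
#'
#' @param beta_var prior variance of the global coefficients.
#' @param sd_shape,sd_rate Gamma hyperparameters for the sd priors.
#' @param tau_upper upper limit of the Uniform prior on the noise sd.
#' @param sd_prior `"gamma"` (default) or `"halfcauchy"`.
#' @param halfcauchy_scale scale of the half-Cauchy sd prior when selected.
#' @return an object of class `anc_priors`.
#' @export
anc_priors <- function(beta_var = 1e4, sd_shape = 0.001, sd_rate = 0.001,
                       tau_upper = 1000,
                       sd_prior = c("gamma", "halfcauchy"),
                       halfcauchy_scale = 1) {
  sd_prior <- match.arg(sd_prior)
  stopifnot(beta_var > 0, sd_shape > 0, sd_rate > 0, tau_upper > 0,
            halfcauchy_scale > 0)
  structure(list(beta_var = beta_var, sd_shape = sd_shape, sd_rate = sd_rate,
                 tau_upper = tau_upper, sd_prior = sd_prior,
                 halfcauchy_scale = halfcauchy_scale),
            class = "anc_priors")
}

# Numerical floor on hierarchical sds. The Gamma(0.001, 0.001) sd prior is
# nearly improper at 0 (unbounded spike); values below any data resolution
# are statistically equivalent, so the support is truncated where floating
# point would otherwise underflow.
SD_FLOOR <- 1e-9

# log-density of the sd prior at s (vectorized); -Inf outside support
log_sd_prior <- function(s, priors) {
  out <- rep(-Inf, length(s))
  ok <- s > SD_FLOOR
  if (priors$sd_prior == "gamma") {
    out[ok] <- stats::dgamma(s[ok], shape = priors$sd_shape,
                             rate = priors$sd_rate, log = TRUE)
  } else {
    g <- priors$halfcauchy_scale
    out[ok] <- log(2) - log(pi * g * (1 + (s[ok] / g)^2))
  }
  out
}

#' Assemble the internal model frame
#'
#' Joins observations to covariates, codes year as `(calendar year - 2000)`,
#' z-standardizes SDI and HRH with constants estimated once from the fitting
#' data (stored for projection), and indexes countries within regions. With
#' `use_covariates = FALSE` the design reduces to intercept + year, for the
#' covariate-exclusion sensitivity analysis.
#'
#' @param obs observation table (one stratum system).
#' @param cov covariate table.
#' @param use_covariates include SDI/HRH columns?
#' @param scale optional pre-computed standardization constants (reused when
#'   predicting for new years).
#' @return a list with the response, design matrix, index vectors and labels.
#' @keywords internal
build_model_frame <- function(obs, cov, use_covariates = TRUE, scale = NULL) {
  m <- merge(obs, cov, by = c("country_id", "year"), all.x = TRUE,
             sort = FALSE)
  if (use_covariates && anyNA(m$sdi)) {
    miss <- unique(paste0(m$country_id[is.na(m$sdi)], ":", m$year[is.na(m$sdi)]))
    stop("no covariates for observation country-year(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  m <- m[order(m$country_id, m$year, m$stratum, m$obs_id), ]
  countries <- sort(unique(m$country_id))
  reg_map <- unique(m[, c("country_id", "region_id")])
  reg_map <- reg_map[match(countries, reg_map$country_id), ]
  regions <- sort(unique(reg_map$region_id))
  if (use_covariates) {
    if (is.null(scale)) {
      scale <- list(sdi_mean = mean(m$sdi), sdi_sd = stats::sd(m$sdi),
                    hrh_mean = mean(m$hrh), hrh_sd = stats::sd(m$hrh))
      if (!isTRUE(scale$sdi_sd > 0)) scale$sdi_sd <- 1
      if (!isTRUE(scale$hrh_sd > 0)) scale$hrh_sd <- 1
    }
    X <- cbind(intercept = 1, year = m$year - 2000,
               sdi = (m$sdi - scale$sdi_mean) / scale$sdi_sd,
               hrh = (m$hrh - scale$hrh_mean) / scale$hrh_sd)
  } else {
    scale <- NULL
    X <- cbind(intercept = 1, year = m$year - 2000)
  }
  quintile <- if (all(m$stratum %in% paste0("Q", 1:5))) {
    match(m$stratum, paste0("Q", 1:5))
  }
  list(y = m$logit_value, X = X, p = ncol(X),
       country = match(m$country_id, countries),
       countries = countries, regions = regions,
       region_of_country = match(reg_map$region_id, regions),
       quintile = quintile, n = nrow(m), data = m, scale = scale,
       use_covariates = use_covariates)
}

#' Initialize a parameter state for a model frame
#'
#' Country coefficients start at per-country ordinary least squares where the
#' country has at least `p + 1` points, otherwise at the region-pooled OLS
#' fit; hierarchical sds at 0.5; the noise sd at the pooled residual sd.
#'
#' @param md model frame from [build_model_frame()].
#' @return a parameter state list (class `anc_state`).
#' @keywords internal
init_state <- function(md) {
  p <- md$p
  K <- length(md$countries)
  J <- length(md$regions)
  pooled <- tryCatch(stats::lm.fit(md$X, md$y)$coefficients,
                     error = function(e) rep(0, p))
  pooled[!is.finite(pooled)] <- 0
  country_beta <- matrix(rep(pooled, each = K), K, p,
                         dimnames = list(md$countries, colnames(md$X)))
  for (k in seq_len(K)) {
    rows <- which(md$country == k)
    if (length(rows) > p) {
      b <- tryCatch(stats::lm.fit(md$X[rows, , drop = FALSE],
                                  md$y[rows])$coefficients,
                    error = function(e) pooled)
      if (all(is.finite(b))) country_beta[k, ] <- b
    }
  }
  region_beta <- matrix(0, J, p, dimnames = list(md$regions, colnames(md$X)))
  for (j in seq_len(J)) {
    region_beta[j, ] <- colMeans(country_beta[md$region_of_country == j, ,
                                              drop = FALSE])
  }
  resid <- md$y - rowSums(md$X * country_beta[md$country, , drop = FALSE])
  state <- list(
    global_beta = colMeans(region_beta),
    region_beta = region_beta,
    country_beta = country_beta,
    region_sd = matrix(0.5, J, p, dimnames = dimnames(region_beta)),
    global_sd = rep(0.5, p),
    obs_sd = max(stats::sd(resid), 0.1)
  )
  if (!is.null(md$quintile)) {
    state$q_int <- matrix(0, K, 5, dimnames = list(md$countries, paste0("Q", 1:5)))
    state$q_slope <- matrix(0, K, 5, dimnames = list(md$countries, paste0("Q", 1:5)))
    state$q_sd_int <- 0.25
    state$q_sd_slope <- 0.05
  }
  class(state) <- "anc_state"
  state
}

#' Linear predictor for one country-year
#'
#' Computes `b0 + b1 * (year - 2000) + b2 * sdi_std + b3 * hrh_std` for a
#' country's coefficient vector. When `scale` is `NULL` the supplied `sdi` and
#' `hrh` are taken as already standardized; otherwise the stored fit-time
#' constants are applied.
#'
#' @param state parameter state (needs `country_beta`).
#' @param country_id country identifier (rowname of `country_beta`).
#' @param year calendar year (vectorized).
#' @param cov list or data.frame with `sdi` and `hrh` (ignored for a
#'   2-column, covariate-free state).
#' @param scale optional standardization constants
#'   (`sdi_mean`,`sdi_sd`,`hrh_mean`,`hrh_sd`).
#' @return the linear predictor on the logit scale.
#' @export
linear_predictor <- function(state, country_id, year, cov = NULL,
                             scale = NULL) {
  if (!country_id %in% rownames(state$country_beta)) {
    stop("unknown country: ", country_id)
  }
  b <- state$country_beta[country_id, ]
  eta <- b[1] + b[2] * (year - 2000)
  if (length(b) >= 4) {
    sdi <- cov$sdi
    hrh <- cov$hrh
    if (!is.null(scale)) {
      sdi <- (sdi - scale$sdi_mean) / scale$sdi_sd
      hrh <- (hrh - scale$hrh_mean) / scale$hrh_sd
    }
    eta <- eta + b[3] * sdi + b[4] * hrh
  }
  unname(eta)
}

#' Wealth-quintile linear predictor
#'
#' National linear predictor plus the country-by-quintile intercept offset and
#' year-slope offset times `(year - 2000)`.
#'
#' @inheritParams linear_predictor
#' @param quintile one of `"Q1"`..`"Q5"`.
#' @return logit-scale predictor for the quintile.
#' @export
quintile_predictor <- function(state, country_id, quintile, year, cov = NULL,
                               scale = NULL) {
  if (!quintile %in% paste0("Q", 1:5)) stop("unknown quintile: ", quintile)
  eta <- linear_predictor(state, country_id, year, cov, scale)
  eta + state$q_int[country_id, quintile] +
    state$q_slope[country_id, quintile] * (year - 2000)
}

# vectorized predictor over all rows of a model frame
state_eta <- function(state, md) {
  eta <- rowSums(md$X * state$country_beta[md$country, , drop = FALSE])
  if (!is.null(md$quintile)) {
    idx <- cbind(md$country, md$quintile)
    eta <- eta + state$q_int[idx] + state$q_slope[idx] * md$X[, "year"]
  }
  eta
}

#' Log-likelihood of a parameter state
#'
#' Sum over observations of the Normal log-density of the logit-scale outcome
#' at the linear predictor, with homoscedastic noise sd `obs_sd`.
#'
#' @param state parameter state.
#' @param md model frame from [build_model_frame()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(state, md) {
  if (!isTRUE(state$obs_sd > 0)) stop("obs_sd must be positive")
  sum(stats::dnorm(md$y, state_eta(state, md), state$obs_sd, log = TRUE))
}

#' Log-prior of a parameter state
#'
#' Sums the hierarchical Normal terms (country coefficients around region
#' means, region means around the global mean), the diffuse Normal on the
#' global mean, the sd priors, and the Uniform on the noise sd. States outside
#' the prior support return `-Inf` rather than erroring.
#'
#' @param state parameter state.
#' @param priors an [anc_priors()].
#' @param md model frame (for the region index).
#' @return scalar log-prior density (possibly `-Inf`).
#' @export
log_prior <- function(state, priors, md) {
  if (any(state$region_sd <= 0) || any(state$global_sd <= 0) ||
      !isTRUE(state$obs_sd > 0) || state$obs_sd >= priors$tau_upper) {
    return(-Inf)
  }
  if (!is.null(state$q_sd_int) &&
      (state$q_sd_int <= 0 || state$q_sd_slope <= 0)) {
    return(-Inf)
  }
  lp <- sum(stats::dnorm(state$country_beta,
                         state$region_beta[md$region_of_country, , drop = FALSE],
                         state$region_sd[md$region_of_country, , drop = FALSE],
                         log = TRUE))
  lp <- lp + sum(stats::dnorm(state$region_beta,
                              rep(state$global_beta, each = nrow(state$region_beta)),
                              rep(state$global_sd, each = nrow(state$region_beta)),
                              log = TRUE))
  lp <- lp + sum(stats::dnorm(state$global_beta, 0, sqrt(priors$beta_var),
                              log = TRUE))
  lp <- lp + sum(log_sd_prior(state$region_sd, priors)) +
    sum(log_sd_prior(state$global_sd, priors))
  lp <- lp - log(priors$tau_upper) # Uniform(0, tau_upper) on obs_sd
  if (!is.null(state$q_sd_int)) {
    lp <- lp +
      sum(stats::dnorm(state$q_int, 0, state$q_sd_int, log = TRUE)) +
      sum(stats::dnorm(state$q_slope, 0, state$q_sd_slope, log = TRUE)) +
      log_sd_prior(state$q_sd_int, priors) +
      log_sd_prior(state$q_sd_slope, priors)
  }
  lp
}

#' Log-posterior (up to a constant)
#'
#' `log_likelihood + log_prior`; `-Inf` propagates for out-of-support states.
#'
#' @inheritParams log_prior
#' @return scalar log-posterior.
#' @export
log_posterior <- function(state, md, priors) {
  lp <- log_prior(state, priors, md)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(state, md)
}
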