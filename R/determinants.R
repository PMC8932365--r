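# Hierarchical logistic regression for individual-level ANC determinants:
# Bernoulli-logit outcome on dummy-coded categorical covariates (Normal(0,
# 10 000) priors) with a country random intercept whose sd carries the
# model's sd prior. Conjugacy does not hold, so every block is updated by
# adaptive random-walk Metropolis on the log-posterior (compiled core in
# src/sampler.cpp): scalar updates per fixed effect and per country
# intercept, and a log-scale update for the random-intercept sd.

# dummy design: intercept + one column per non-reference category
build_determinant_design <- function(individuals) {
  for (v in names(INDIVIDUAL_VOCAB)) {
    if (is.null(individuals[[v]])) stop("missing covariate column: ", v)
    bad <- setdiff(unique(individuals[[v]]), INDIVIDUAL_VOCAB[[v]])
    if (length(bad)) {
      stop("unknown ", v, " category: ", paste(bad, collapse = ", "))
    }
  }
  cols <- list("(Intercept)" = rep(1, nrow(individuals)))
  for (v in names(INDIVIDUAL_VOCAB)) {
    for (lev in INDIVIDUAL_VOCAB[[v]][-1]) {
      cols[[paste0(v, ":", lev)]] <- as.numeric(individuals[[v]] == lev)
    }
  }
  do.call(cbind, cols)
}

#' Fit the hierarchical determinant model
#'
#' Bayesian hierarchical logistic regression of a binary ANC outcome on the
#' standard individual- and household-level determinants (household-head age
#' and sex, maternal education, parity, mass-media exposure, wealth quintile,
#' residence), with a random intercept per country. All parameter blocks are
#' sampled by adaptive random-walk Metropolis; the fixed effects move in one
#' joint step shaped by the Cholesky factor of the maximum-likelihood
#' covariance from an ordinary logistic fit.
#'
#' @param individuals data.frame of individual records (see
#'   [generate_individuals()] for the column vocabulary) with binary columns
#'   `anc1` and `anc4` and a `country_id`.
#' @param indicator `"anc1"` or `"anc4"`.
#' @param priors an [anc_priors()]; `beta_var` applies to fixed effects and
#'   the sd prior to the country-intercept sd.
#' @param control an [sampler_config()]; the default here is lighter than for
#'   the trend model (individual-level likelihoods are expensive and the
#'   near-Gaussian posterior at large n mixes quickly).
#' @return object of class `anc_determinants`: coefficient draws
#'   (chains x retained x parameters), acceptance rates, the design metadata.
#' @export
anc_determinants <- function(individuals, indicator = c("anc1", "anc4"),
                             priors = anc_priors(),
                             control = sampler_config(iterations = 3000L,
                                                      chains = 2L, thin = 1L,
                                                      burn_in = 1000L)) {
  indicator <- match.arg(indicator)
  if (is.null(individuals[[indicator]])) {
    stop("missing outcome column: ", indicator)
  }
  countries <- sort(unique(individuals$country_id))
  if (length(countries) < 2) {
    stop("the hierarchical determinant model needs at least 2 countries")
  }
  y <- as.numeric(individuals[[indicator]])
  X <- build_determinant_design(individuals)
  ctry <- match(individuals$country_id, countries)
  p <- ncol(X)
  # MLE fit for initialization and Metropolis step scaling
  ml <- stats::glm.fit(X, y, family = stats::binomial())
  beta0 <- ml$coefficients
  beta0[!is.finite(beta0)] <- 0
  vc <- tryCatch(chol2inv(chol(crossprod(X * ml$weights, X))),
                 error = function(e) diag(0.05^2, p))
  prop_chol <- tryCatch(t(chol(vc)), error = function(e) diag(0.05, p))
  nm <- c(colnames(X), paste0("u[", countries, "]"), "sigma_country")
  arr <- array(NA_real_, c(control$chains, control$n_retained, length(nm)),
               dimnames = list(NULL, NULL, nm))
  accept <- matrix(NA_real_, control$chains, 3,
                   dimnames = list(NULL, c("beta", "u", "sigma_country")))
  for (ch in seq_len(control$chains)) {
    set.seed(as.integer((control$seed + 77003L * ch) %% .Machine$integer.max))
    res <- .logistic_chain_cpp(
      y = y, X = X, country = as.integer(ctry), beta0 = unname(beta0),
      prop_chol = prop_chol,
      prior = list(beta_var = priors$beta_var, sd_shape = priors$sd_shape,
                   sd_rate = priors$sd_rate,
                   halfcauchy_scale = priors$halfcauchy_scale,
                   sd_type = if (priors$sd_prior == "gamma") 0L else 1L),
      cfg = list(iterations = control$iterations, burn_in = control$burn_in,
                 thin = control$thin, adapt = control$adapt))
    arr[ch, , ] <- res$draws
    accept[ch, ] <- res$acceptance
    if (control$burn_in > 0 && any(res$burn_accept == 0)) {
      warning("zero Metropolis acceptance during burn-in for block(s) ",
              paste(names(res$burn_accept)[res$burn_accept == 0],
                    collapse = ", "))
    }
  }

  structure(list(
    draws = structure(list(draws = arr, parameter_names = nm,
                           acceptance = colMeans(accept), config = control),
                      class = "anc_draws"),
    coef_names = colnames(X), countries = countries,
    indicator = indicator, n = length(y), priors = priors,
    control = control, call = match.call()),
    class = "anc_determinants")
}

#' @export
print.anc_determinants <- function(x, ...) {
  cat("Hierarchical determinant model (", x$indicator, "): ", x$n,
      " individuals, ", length(x$countries), " countries\n", sep = "")
  cat("  fixed effects:", length(x$coef_names) - 1,
      "dummy-coded categories + intercept; country random intercepts\n")
  print(utils::head(summarize_odds_ratios(x), 8))
  cat("  ...\n")
  invisible(x)
}

#' @export
coef.anc_determinants <- function(object, ...) {
  mat <- as.matrix(object$draws)
  colMeans(mat[, object$coef_names, drop = FALSE])
}

#' @export
summary.anc_determinants <- function(object, ...) {
  out <- list(or_table = summarize_odds_ratios(object, ...),
              psrf = if (object$control$chains >= 2) gelman_rubin(object$draws),
              acceptance = object$draws$acceptance, fit = object)
  class(out) <- "summary.anc_determinants"
  out
}

#' @export
print.summary.anc_determinants <- function(x, ...) {
  cat("Odds ratios (", x$fit$indicator, "), 95% credible intervals:\n",
      sep = "")
  print(x$or_table, digits = 3)
  if (!is.null(x$psrf)) {
    cat("\nGelman-Rubin: max point estimate",
        round(max(x$psrf$point), 3), "\n")
  }
  invisible(x)
}

#' Odds-ratio table from determinant coefficient draws
#'
#' The OR point estimate is the exponential of the posterior mean coefficient
#' (configurable to the median); the credible interval is the exponential of
#' the 2.5/97.5 coefficient percentiles. Reference categories are emitted as
#' exactly 1.00 with no interval.
#'
#' @param object an [anc_determinants()] fit, or a draws x coefficients
#'   matrix with `"covariate:category"` column names.
#' @param point `"mean"` (default) or `"median"` posterior point estimate.
#' @param level credible mass.
#' @param indicator indicator label for the output (taken from the fit when
#'   available).
#' @return data.frame with `covariate, category, reference, or_point,
#'   cri_low, cri_high, indicator`.
#' @export
summarize_odds_ratios <- function(object, point = c("mean", "median"),
                                  level = 0.95, indicator = NA_character_) {
  point <- match.arg(point)
  if (inherits(object, "anc_determinants")) {
    indicator <- object$indicator
    mat <- as.matrix(object$draws)[, object$coef_names, drop = FALSE]
  } else {
    mat <- as.matrix(object)
  }
  if (!nrow(mat)) stop("no draws")
  rows <- list()
  for (v in names(INDIVIDUAL_VOCAB)) {
    for (lev in INDIVIDUAL_VOCAB[[v]]) {
      key <- paste0(v, ":", lev)
      if (lev == INDIVIDUAL_VOCAB[[v]][1]) {
        rows[[key]] <- data.frame(
          covariate = v, category = lev, reference = TRUE, or_point = 1,
          cri_low = NA_real_, cri_high = NA_real_, indicator = indicator,
          stringsAsFactors = FALSE)
      } else if (key %in% colnames(mat)) {
        d <- mat[, key]
        ctr <- if (point == "mean") mean(d) else stats::median(d)
        ci <- credible_interval(d, level)
        rows[[key]] <- data.frame(
          covariate = v, category = lev, reference = FALSE,
          or_point = exp(ctr), cri_low = exp(ci[["lower"]]),
          cri_high = exp(ci[["upper"]]), indicator = indicator,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
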