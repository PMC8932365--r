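# Posterior projections to 2030 and equity summaries: 80%-target flags,
# urban-rural gaps, the slope index of inequality and rates of change.

#' Extend covariate series to a projection horizon
#'
#' Fits a linear trend per country on the observed years and extends it to
#' `horizon`. SDI is clipped to \[0, 1\] and HRH to non-negative values;
#' observed years pass through unchanged.
#'
#' @param cov covariate table.
#' @param horizon last projection year (default 2030).
#' @return covariate table covering `min(observed year) .. horizon`.
#' @export
extrapolate_covariates <- function(cov, horizon = 2030) {
  out <- lapply(split(cov, cov$country_id), function(cc) {
    if (nrow(cc) < 2) {
      stop("cannot extrapolate covariates for country with a single year: ",
           cc$country_id[1])
    }
    yrs <- seq(min(cc$year), horizon)
    new_yrs <- setdiff(yrs, cc$year)
    if (!length(new_yrs)) return(cc[cc$year <= horizon, ])
    fs <- stats::lm(sdi ~ year, data = cc)
    fh <- stats::lm(hrh ~ year, data = cc)
    nd <- data.frame(year = new_yrs)
    add <- data.frame(country_id = cc$country_id[1], year = new_yrs,
                      sdi = pmin(1, pmax(0, stats::predict(fs, nd))),
                      hrh = pmax(0, stats::predict(fh, nd)),
                      stringsAsFactors = FALSE)
    rbind(cc, add)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$country_id, res$year), ]
}

#' Posterior coverage projections
#'
#' For every retained posterior draw, country and year, evaluates the linear
#' predictor (using the standardization constants stored at fit time),
#' back-transforms to percent coverage, and summarizes across draws with the
#' posterior mean, median and equal-tailed 95% and 50% credible intervals.
#' Quintile fits emit one row per wealth quintile with the country-specific
#' offsets applied.
#'
#' @param fit an [anc_trend()] fit.
#' @param years projection years (default 2000:2030).
#' @param covariates optional covariate table covering `years`; defaults to
#'   [extrapolate_covariates()] of the fit's covariates.
#' @param keep_draws attach the per-draw coverage matrix
#'   (draws x projection rows) as attribute `"draws"`, for joint summaries
#'   such as gaps and the slope index of inequality.
#' @return data.frame with columns `country_id, year, age_group, indicator,
#'   stratum, mean_coverage, median_coverage, cri_low, cri_high, cri50_low,
#'   cri50_high` (all coverages in percent).
#' @export
project_coverage <- function(fit, years = 2000:2030, covariates = NULL,
                             keep_draws = FALSE) {
  stopifnot(inherits(fit, "anc_trend"))
  md <- fit$model_frame
  lay <- fit$draws$layout
  if (is.null(covariates)) {
    covariates <- if (md$use_covariates) {
      extrapolate_covariates(fit$covariates, horizon = max(years))
    } else {
      expand.grid(country_id = md$countries, year = years,
                  stringsAsFactors = FALSE)
    }
  }
  mat <- as.matrix(fit$draws)
  nd <- nrow(mat)
  quint <- lay$quint
  strata <- if (quint) paste0("Q", 1:5) else fit$stratum
  rows <- list()
  draw_cols <- list()
  for (ctry in md$countries) {
    cc <- covariates[covariates$country_id == ctry &
                       covariates$year %in% years, , drop = FALSE]
    if (length(setdiff(years, cc$year))) {
      stop("covariates missing for ", ctry, " year(s) ",
           paste(utils::head(setdiff(years, cc$year), 3), collapse = ", "))
    }
    cc <- cc[match(years, cc$year), ]
    Z <- cbind(intercept = 1, year = years - 2000)
    if (md$use_covariates) {
      Z <- cbind(Z,
                 sdi = (cc$sdi - md$scale$sdi_mean) / md$scale$sdi_sd,
                 hrh = (cc$hrh - md$scale$hrh_mean) / md$scale$hrh_sd)
    }
    B <- mat[, mat_names("beta_country", ctry, lay$coefs), drop = FALSE]
    eta0 <- B %*% t(Z)                       # draws x years
    for (s in strata) {
      eta <- eta0
      if (quint) {
        qi <- mat[, paste0("q_int[", ctry, ",", s, "]")]
        qs <- mat[, paste0("q_slope[", ctry, ",", s, "]")]
        eta <- eta + qi + outer(qs, years - 2000)
      }
      covg <- 100 * stats::plogis(eta)
      qs95 <- apply(covg, 2, stats::quantile, c(0.025, 0.25, 0.5, 0.75, 0.975),
                    names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        country_id = ctry, year = years, age_group = fit$age_group,
        indicator = fit$indicator, stratum = s,
        mean_coverage = colMeans(covg), median_coverage = qs95[3, ],
        cri_low = qs95[1, ], cri_high = qs95[5, ],
        cri50_low = qs95[2, ], cri50_high = qs95[4, ],
        stringsAsFactors = FALSE)
      if (keep_draws) draw_cols[[length(draw_cols) + 1L]] <- covg
    }
  }
  proj <- do.call(rbind, rows)
  rownames(proj) <- NULL
  if (keep_draws) attr(proj, "draws") <- do.call(cbind, draw_cols)
  proj
}

#' Combine projection tables, preserving per-draw matrices
#'
#' Row-binds projection tables (e.g. separate urban and rural fits) and
#' column-binds their `"draws"` attributes when all carry one with the same
#' number of draws.
#'
#' @param ... projection tables from [project_coverage()].
#' @return a combined projection table.
#' @export
combine_projections <- function(...) {
  parts <- list(...)
  out <- do.call(rbind, lapply(parts, function(x) {
    attr(x, "draws") <- NULL
    x
  }))
  rownames(out) <- NULL
  dm <- lapply(parts, attr, "draws")
  if (!any(vapply(dm, is.null, logical(1))) &&
      length(unique(vapply(dm, nrow, integer(1)))) == 1) {
    attr(out, "draws") <- do.call(cbind, dm)
  }
  out
}

#' Flag countries reaching a coverage target
#'
#' Per country, indicator and stratum: whether the posterior-mean coverage
#' reaches `threshold` (inclusive) in `target_year`, and the first projection
#' year at which it crosses.
#'
#' @param proj projection table.
#' @param threshold coverage target in percent (default 80).
#' @param target_year year the flag refers to (default 2030).
#' @return data.frame with `country_id, indicator, stratum, reaches_target,
#'   first_crossing_year` (NA when never crossed).
#' @export
flag_threshold <- function(proj, threshold = 80, target_year = 2030) {
  grp <- split(proj, proj[, c("country_id", "indicator", "stratum")],
               drop = TRUE)
  out <- lapply(grp, function(g) {
    g <- g[order(g$year), ]
    at <- g$mean_coverage[g$year == target_year]
    crossed <- g$year[g$mean_coverage >= threshold]
    data.frame(country_id = g$country_id[1], indicator = g$indicator[1],
               stratum = g$stratum[1],
               reaches_target = length(at) == 1 && at >= threshold,
               first_crossing_year = if (length(crossed)) min(crossed)
               else NA_integer_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Urban-rural coverage gap
#'
#' `urban mean - rural mean` in percentage points per country-year. When the
#' projection carries a per-draw matrix, the credible interval of the gap is
#' computed from the per-draw differences (not from the difference of
#' marginal intervals).
#'
#' @param proj projection table containing both `urban` and `rural` strata
#'   (see [combine_projections()] for separate fits).
#' @param level credible mass for the gap interval.
#' @return data.frame with `country_id, year, indicator, gap, cri_low,
#'   cri_high` (intervals NA without draws).
#' @export
urban_rural_gap <- function(proj, level = 0.95) {
  u <- proj[proj$stratum == "urban", ]
  r <- proj[proj$stratum == "rural", ]
  key_u <- paste(u$country_id, u$year, u$indicator)
  key_r <- paste(r$country_id, r$year, r$indicator)
  if (!nrow(u) || !nrow(r)) stop("projection must contain urban and rural strata")
  miss <- c(setdiff(key_u, key_r), setdiff(key_r, key_u))
  if (length(miss)) {
    stop("missing stratum for country-year(s): ",
         paste(utils::head(miss, 5), collapse = "; "))
  }
  r <- r[match(key_u, key_r), ]
  dm <- attr(proj, "draws")
  lo <- hi <- rep(NA_real_, nrow(u))
  if (!is.null(dm)) {
    iu <- which(proj$stratum == "urban")
    ir <- which(proj$stratum == "rural")[match(key_u, key_r)]
    diff <- dm[, iu, drop = FALSE] - dm[, ir, drop = FALSE]
    qs <- apply(diff, 2, stats::quantile,
                c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    lo <- qs[1, ]; hi <- qs[2, ]
  }
  data.frame(country_id = u$country_id, year = u$year,
             indicator = u$indicator,
             gap = u$mean_coverage - r$mean_coverage,
             cri_low = lo, cri_high = hi,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Slope index of inequality (SII)
#'
#' Weighted least-squares regression of quintile coverage (percent) on ridit
#' scores (cumulative-population-share midpoints: 0.1, 0.3, 0.5, 0.7, 0.9 at
#' equal shares). The SII is the fitted value at rank 1 minus the fitted
#' value at rank 0, i.e. the regression slope, in percentage points, positive
#' for pro-rich inequality. The index is defined on \[-100, 100\] (0 = no
#' inequality) and the returned value is clamped to that range.
#'
#' @param coverage numeric length-5 vector (Q1..Q5, poorest to richest, in
#'   percent), or a draws x 5 matrix for per-draw computation.
#' @param shares population shares of the quintiles, positive, summing to 1
#'   (default 0.2 each).
#' @return a single SII (vector input) or one SII per draw (matrix input).
#' @export
slope_index_of_inequality <- function(coverage, shares = rep(0.2, 5)) {
  if (is.null(dim(coverage))) coverage <- matrix(coverage, nrow = 1)
  if (ncol(coverage) != length(shares)) {
    stop("coverage and shares must have the same number of groups")
  }
  if (any(shares <= 0)) stop("shares must be positive")
  if (abs(sum(shares) - 1) > 1e-6) stop("shares must sum to 1")
  ridit <- cumsum(shares) - shares / 2
  rbar <- sum(shares * ridit)
  wdev <- shares * (ridit - rbar)
  denom <- sum(wdev * (ridit - rbar))
  if (denom <= 0) return(rep(0, nrow(coverage)))
  # project deviations from the row mean so a flat profile gives exactly 0
  centered <- coverage - rowMeans(coverage)
  sii <- as.vector(centered %*% wdev) / denom
  out <- pmin(100, pmax(-100, sii))
  if (length(out) == 1) out[[1]] else out
}

#' SII per country-year from a quintile projection
#'
#' Computes the slope index of inequality for every country-year of a
#' wealth-quintile projection. With a per-draw matrix attached, the SII is
#' computed per posterior draw and summarized with its mean and equal-tailed
#' credible interval; otherwise from the posterior-mean coverages.
#'
#' @param proj projection table from a `stratum = "quintile"` fit (strata
#'   Q1..Q5).
#' @param shares quintile population shares.
#' @param level credible mass.
#' @return data.frame `country_id, year, indicator, sii, cri_low, cri_high`.
#' @export
sii_table <- function(proj, shares = rep(0.2, 5), level = 0.95) {
  qlev <- paste0("Q", 1:5)
  if (!all(qlev %in% proj$stratum)) {
    stop("projection must contain strata Q1..Q5")
  }
  dm <- attr(proj, "draws")
  grp <- split(seq_len(nrow(proj)), list(proj$country_id, proj$year),
               drop = TRUE)
  out <- lapply(grp, function(ix) {
    sub <- proj[ix, ]
    ord <- ix[match(qlev, sub$stratum)]
    if (anyNA(ord)) return(NULL)
    if (!is.null(dm)) {
      per_draw <- slope_index_of_inequality(dm[, ord, drop = FALSE], shares)
      ci <- stats::quantile(per_draw, c((1 - level) / 2, 1 - (1 - level) / 2),
                            names = FALSE)
      sii <- mean(per_draw)
    } else {
      sii <- slope_index_of_inequality(proj$mean_coverage[ord], shares)
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(country_id = proj$country_id[ord[1]], year = proj$year[ord[1]],
               indicator = proj$indicator[ord[1]], sii = sii,
               cri_low = ci[1], cri_high = ci[2], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$country_id, res$year), ]
}

#' Rate of change in projected coverage
#'
#' Annualized change between two projection years, per country, indicator and
#' stratum: the absolute rate `(p_to - p_from) / (to - from)` in percentage
#' points per year, and the relative annualized rate
#' `(p_to / p_from)^(1 / (to - from)) - 1` (NA when the baseline is 0).
#'
#' @param proj projection table.
#' @param from,to calendar years (defaults 2000 and 2030), both present in
#'   `proj`.
#' @return data.frame with `country_id, indicator, stratum, from, to,
#'   abs_rate_pp_per_year, rel_rate_annualized`.
#' @export
rate_of_change <- function(proj, from = 2000, to = 2030) {
  if (!all(c(from, to) %in% proj$year)) {
    stop("both `from` and `to` years must be present in the projection")
  }
  grp <- split(proj, proj[, c("country_id", "indicator", "stratum")],
               drop = TRUE)
  out <- lapply(grp, function(g) {
    p0 <- g$mean_coverage[g$year == from]
    p1 <- g$mean_coverage[g$year == to]
    if (!length(p0) || !length(p1)) return(NULL)
    data.frame(country_id = g$country_id[1], indicator = g$indicator[1],
               stratum = g$stratum[1], from = from, to = to,
               abs_rate_pp_per_year = (p1 - p0) / abs(to - from),
               rel_rate_annualized = if (p0 == 0) NA_real_ else
                 (p1 / p0)^(1 / abs(to - from)) - 1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
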