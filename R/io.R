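# Readers, writers and validation for the two interchange tables:
#   observations: region_id,country_id,year,age_group,indicator,stratum,proportion[,ess]
#   covariates:   country_id,year,sdi,hrh

AGE_GROUPS <- c("15-19", "20-35", "36-49")
INDICATORS <- c("ANC1", "ANC4")
STRATA     <- c("national", "urban", "rural", paste0("Q", 1:5))

OBS_COLUMNS <- c("region_id", "country_id", "year", "age_group",
                 "indicator", "stratum", "proportion")

#' Read a coverage observation table
#'
#' Reads a CSV of survey coverage estimates (one row per country-year-stratum
#' data point), validates it and attaches the logit-scale outcome. Rows with a
#' missing proportion are rejected, with their row numbers reported.
#'
#' @param path path to a CSV file with columns
#'   `region_id,country_id,year,age_group,indicator,stratum,proportion` and an
#'   optional `ess` (effective sample size) column.
#' @param eps clamp bound passed to [logit_transform()].
#' @return a `data.frame` with the input columns plus `obs_id` and
#'   `logit_value`.
#' @export
read_observations <- function(path, eps = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_observations(x, eps = eps)
}

#' Validate a data frame of coverage observations
#'
#' @param x data.frame with the observation columns (see
#'   [read_observations()]).
#' @inheritParams read_observations
#' @return the validated table with `obs_id` and `logit_value` columns.
#' @export
as_observations <- function(x, eps = 1e-3) {
  missing_cols <- setdiff(OBS_COLUMNS, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(x$proportion)) {
    stop("missing proportion in row(s): ",
         paste(which(is.na(x$proportion)), collapse = ", "))
  }
  bad <- which(x$proportion < 0 | x$proportion > 1)
  if (length(bad)) {
    stop("proportion outside [0, 1] in row(s): ", paste(bad, collapse = ", "))
  }
  bad_age <- setdiff(unique(x$age_group), AGE_GROUPS)
  if (length(bad_age)) stop("unknown age_group: ", paste(bad_age, collapse = ", "))
  bad_ind <- setdiff(unique(x$indicator), INDICATORS)
  if (length(bad_ind)) stop("unknown indicator: ", paste(bad_ind, collapse = ", "))
  bad_str <- setdiff(unique(x$stratum), STRATA)
  if (length(bad_str)) stop("unknown stratum: ", paste(bad_str, collapse = ", "))
  # a country must sit in exactly one region
  reg <- unique(x[, c("country_id", "region_id")])
  dup <- reg$country_id[duplicated(reg$country_id)]
  if (length(dup)) {
    stop("country mapped to multiple regions: ", paste(unique(dup), collapse = ", "))
  }
  if (is.null(x$obs_id)) x$obs_id <- seq_len(nrow(x))
  x$logit_value <- logit_transform(x$proportion, eps = eps)
  if (is.null(x$ess)) x$ess <- NA_real_
  x[, c("obs_id", "region_id", "country_id", "year", "age_group",
        "indicator", "stratum", "proportion", "logit_value", "ess")]
}

#' Write a coverage observation table to CSV
#'
#' @param obs validated observation table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a country-year covariate table (SDI and HRH)
#'
#' Reads and validates the covariate CSV. Duplicate (country, year) keys are an
#' error; gaps in the per-country year sequence are reported as a warning with
#' the missing years, since downstream extrapolation assumes contiguous series.
#'
#' @param path path to a CSV with columns `country_id,year,sdi,hrh`.
#' @return a validated `data.frame`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as_covariates(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Validate a covariate data frame
#' @param x data.frame with columns `country_id,year,sdi,hrh`.
#' @return the validated table.
#' @export
as_covariates <- function(x) {
  need <- c("country_id", "year", "sdi", "hrh")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- paste(x$country_id, x$year)
  if (anyDuplicated(key)) {
    stop("duplicate (country_id, year): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  if (any(x$sdi < 0 | x$sdi > 1, na.rm = TRUE)) stop("sdi outside [0, 1]")
  if (any(x$hrh < 0, na.rm = TRUE)) stop("hrh negative")
  gaps <- covariate_year_gaps(x)
  if (nrow(gaps)) {
    warning("covariate year gaps: ",
            paste(paste0(gaps$country_id, ":", gaps$year), collapse = ", "))
  }
  x[order(x$country_id, x$year), need]
}

#' Missing years in per-country covariate series
#'
#' @param cov covariate table.
#' @return data.frame with columns `country_id`, `year`, one row per missing
#'   year inside a country's observed span.
#' @export
covariate_year_gaps <- function(cov) {
  out <- lapply(split(cov$year, cov$country_id), function(yrs) {
    setdiff(seq(min(yrs), max(yrs)), yrs)
  })
  data.frame(
    country_id = rep(names(out), lengths(out)),
    year = unlist(out, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Write a covariate table to CSV
#' @param cov covariate table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cov, path) {
  utils::write.csv(cov, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate observation and covariate tables
#'
#' Report-only consistency checks before fitting: countries that have
#' observations but no covariate series, observation years outside the
#' covariate span, and countries with a single data point (flagged but
#' retained, since the model keeps every country with at least one point).
#'
#' @param obs observation table.
#' @param cov covariate table.
#' @return a data.frame report with columns `code`, `key`, `message`; zero rows
#'   when the tables are fully consistent. Inputs are never modified.
#' @export
validate_dataset <- function(obs, cov) {
  issues <- list()
  add <- function(code, key, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      code = code, key = key, message = message, stringsAsFactors = FALSE)
  }
  no_cov <- setdiff(unique(obs$country_id), unique(cov$country_id))
  for (ctry in no_cov) add("no_covariates", ctry, "observations but no covariate series")
  span <- split(cov$year, cov$country_id)
  for (ctry in setdiff(unique(obs$country_id), no_cov)) {
    yrs <- obs$year[obs$country_id == ctry]
    out <- yrs[yrs < min(span[[ctry]]) | yrs > max(span[[ctry]])]
    for (y in unique(out)) {
      add("year_outside_covariates", paste0(ctry, ":", y),
          "observation year outside covariate range")
    }
  }
  pts <- table(obs$country_id[obs$stratum == "national"])
  if (!length(pts)) pts <- table(obs$country_id)
  for (ctry in names(pts)[pts == 1L]) {
    add("single_data_point", ctry, "country has a single data point (retained)")
  }
  if (!length(issues)) {
    return(data.frame(code = character(), key = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}
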