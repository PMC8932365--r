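test_that("truth generation honours the hierarchy and the seed", {
  # degenerate hierarchy: all country vectors collapse onto the global mean
  sc0 <- anc_scenario(region_sd = rep(0, 4), country_sd = rep(0, 4), seed = 2)
  tr0 <- generate_truth(sc0)
  expect_true(all(abs(sweep(tr0$country_beta, 2, sc0$global_means)) < 1e-12))

  sc <- anc_scenario(seed = 7)
  expect_identical(generate_truth(sc), generate_truth(sc))
  expect_false(identical(generate_truth(sc)$country_beta,
                         generate_truth(anc_scenario(seed = 8))$country_beta))
  expect_error(anc_scenario(country_sd = c(-1, 1, 1, 1)), "non-negative")
})

test_that("simulated country intercepts have the configured spread", {
  # Monte-Carlo check of the stated sd at sigma = 0.5: 2000 countries
  sc <- anc_scenario(n_regions = 1, countries_per_region = 10000,
                     region_sd = rep(0, 4),
                     country_sd = c(0.5, 0.5, 0.5, 0.5), seed = 31)
  tr <- generate_truth(sc)
  expect_equal(sd(tr$country_beta[, "intercept"]), 0.5, tolerance = 0.02 / 0.5)
})

test_that("covariate trajectories are monotone, bounded and reproducible", {
  sc <- tiny_scenario(seed = 5)
  cov <- generate_covariates(sc, years = 2000:2030)
  expect_true(all(cov$sdi >= 0 & cov$sdi <= 1))
  expect_true(all(cov$hrh >= 0))
  for (ctry in unique(cov$country_id)) {
    s <- cov$sdi[cov$country_id == ctry]
    expect_true(all(diff(s) >= 0))
  }
  expect_identical(cov, generate_covariates(sc, years = 2000:2030))
})

test_that("observation noise and counts follow the configuration", {
  sc <- tiny_scenario(seed = 9, points_per_country = c(3, 3))
  tr <- generate_truth(sc)
  cov <- generate_covariates(sc, 2000:2019)
  obs <- generate_observations(tr, cov, sc)
  expect_equal(nrow(obs), 6 * 3) # 6 countries x exactly 3 points

  # noiseless limit reproduces the truth bundle exactly
  sc0 <- tiny_scenario(seed = 9, points_per_country = c(3, 3), obs_sd = 0)
  tr0 <- generate_truth(sc0)
  obs0 <- generate_observations(tr0, cov, sc0)
  m <- merge(obs0, cov, by = c("country_id", "year"))
  eta <- anctrend:::truth_linear_predictor(tr0, m$country_id, m$year,
                                           m$sdi, m$hrh)
  expect_equal(m$logit_value, unname(eta), tolerance = 1e-9)

  # residual sd across many draws matches the configured tau
  scn <- anc_scenario(n_regions = 1, countries_per_region = 700,
                      points_per_country = c(8, 8), obs_sd = 0.3, seed = 12)
  trn <- generate_truth(scn)
  covn <- generate_covariates(scn, 2000:2019)
  obsn <- generate_observations(trn, covn, scn)
  mn <- merge(obsn, covn, by = c("country_id", "year"))
  res <- mn$logit_value -
    anctrend:::truth_linear_predictor(trn, mn$country_id, mn$year,
                                      mn$sdi, mn$hrh)
  expect_equal(sd(res), 0.3, tolerance = 0.01 / 0.3)
})

test_that("stratified generation applies offsets before noise", {
  sc <- tiny_scenario(seed = 21, obs_sd = 0,
                      quintile_gradient = c(-0.4, -0.2, 0, 0.2, 0.4),
                      urban_offset = 0.5, rural_offset = -0.5)
  tr <- generate_truth(sc)
  cov <- generate_covariates(sc, 2000:2019)
  strata <- generate_strata(tr, cov, sc)
  wide <- reshape(strata[, c("country_id", "year", "stratum", "logit_value")],
                  idvar = c("country_id", "year"), timevar = "stratum",
                  direction = "wide")
  lv <- function(s) wide[[paste0("logit_value.", s)]]
  # urban/rural offsets are exact at tau = 0
  expect_equal(lv("urban"), lv("national") + 0.5, tolerance = 1e-9)
  expect_equal(lv("rural"), lv("national") - 0.5, tolerance = 1e-9)
  # monotone quintile gradient preserved at every country-year
  for (q in 1:4) {
    expect_true(all(lv(paste0("Q", q)) <= lv(paste0("Q", q + 1)) + 1e-12))
  }
  # a national logit of 0 with +-0.5 offsets gives the textbook proportions
  expect_equal(inverse_logit(0.5), 0.6225, tolerance = 1e-3)
  expect_equal(inverse_logit(-0.5), 0.3775, tolerance = 1e-3)

  # zero offsets collapse all strata onto the national series
  sc0 <- tiny_scenario(seed = 21, obs_sd = 0,
                       quintile_gradient = rep(0, 5),
                       urban_offset = 0, rural_offset = 0)
  st0 <- generate_strata(generate_truth(sc0), cov, sc0)
  w0 <- reshape(st0[, c("country_id", "year", "stratum", "logit_value")],
                idvar = c("country_id", "year"), timevar = "stratum",
                direction = "wide")
  for (s in c("urban", "rural", paste0("Q", 1:5))) {
    expect_equal(w0[[paste0("logit_value.", s)]], w0$logit_value.national,
                 tolerance = 1e-9)
  }
})

test_that("generated tables validate cleanly against their covariates", {
  sim <- tiny_data(seed = 14)
  expect_equal(nrow(validate_dataset(sim$observations, sim$covariates)), 0)
  expect_equal(nrow(validate_dataset(sim$strata, sim$covariates)), 0)
})

test_that("individual records reproduce the configured log-odds effects", {
  sc <- tiny_scenario(seed = 17)
  tr <- generate_truth(sc)
  expect_identical(generate_individuals(tr, sc, 500),
                   generate_individuals(tr, sc, 500))
  expect_error(generate_individuals(tr, sc, 0), "positive")

  # null model: prevalence one half
  null_coefs <- lapply(default_determinant_coefs(), function(v) v * 0)
  sc0 <- tiny_scenario(seed = 18, determinant_coefs = null_coefs,
                       determinant_intercept = c(anc1 = 0, anc4 = 0),
                       determinant_sd = 0)
  ind0 <- generate_individuals(generate_truth(sc0), sc0, 20000)
  expect_equal(mean(ind0$anc1), 0.5, tolerance = 0.01 / 0.5)

  # a single ln(2) richest-quintile effect shows up as an empirical odds
  # ratio of ~2 in the richest-vs-poorest 2x2 table
  c2 <- lapply(default_determinant_coefs(), function(v) {
    v[] <- 0; v["wealth_quintile:Q5"] <- log(2); v })
  sc2 <- tiny_scenario(seed = 19, determinant_coefs = c2,
                       determinant_intercept = c(anc1 = 0, anc4 = 0),
                       determinant_sd = 0)
  ind2 <- generate_individuals(generate_truth(sc2), sc2, 50000)
  sub <- ind2[ind2$wealth_quintile %in% c("Q1", "Q5"), ]
  tab <- table(sub$wealth_quintile, sub$anc1)
  or <- (tab["Q5", "1"] / tab["Q5", "0"]) / (tab["Q1", "1"] / tab["Q1", "0"])
  expect_equal(or, 2, tolerance = 0.15 / 2)
})
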