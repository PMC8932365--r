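test_that("covariate extrapolation extends linear trends with clipping", {
  cov <- data.frame(country_id = "C1", year = c(2000, 2010),
                    sdi = c(0.40, 0.50), hrh = c(1, 1))
  ext <- extrapolate_covariates(cov, horizon = 2030)
  expect_equal(ext$sdi[ext$year == 2030], 0.70, tolerance = 1e-9)
  expect_equal(ext$hrh[ext$year == 2030], 1, tolerance = 1e-9) # constant
  expect_equal(ext$sdi[ext$year == 2000], 0.40) # observed pass through
  # a trend reaching past 1 is clipped
  cov2 <- data.frame(country_id = "C1", year = c(2000, 2010),
                     sdi = c(0.6, 0.9), hrh = c(1, 2))
  ext2 <- extrapolate_covariates(cov2, horizon = 2030)
  expect_equal(ext2$sdi[ext2$year == 2030], 1.0)
  expect_error(extrapolate_covariates(
    data.frame(country_id = "C9", year = 2000, sdi = 0.5, hrh = 1)), "C9")
})

test_that("projection obeys its numeric contracts", {
  # degenerate all-zero draws: exactly 50% with zero-width intervals
  f0 <- fake_fit(matrix(0, 40, 2))
  p0 <- project_coverage(f0, years = 2000:2030)
  expect_true(all(p0$mean_coverage == 50))
  expect_true(all(p0$cri_low == 50 & p0$cri_high == 50))

  # single draw with year slope 0.1: the 2030 value through the inverse
  # logit is 95.257%
  f1 <- fake_fit(matrix(c(0, 0.1), 1, 2, byrow = TRUE))
  p1 <- project_coverage(f1, years = c(2000, 2030))
  expect_equal(p1$mean_coverage[p1$year == 2030], 95.257, tolerance = 1e-4)
  expect_equal(p1$mean_coverage[p1$year == 2000], 50)

  # positive slopes give monotone mean trajectories; all outputs in [0,100]
  # and 50% intervals nested inside 95% intervals
  set.seed(3)
  fm <- fake_fit(cbind(rnorm(60, 0, 0.5), runif(60, 0.01, 0.2)))
  pm <- project_coverage(fm, years = 2000:2030)
  expect_true(all(diff(pm$mean_coverage) >= -1e-9))
  expect_true(all(pm$cri_low >= 0 & pm$cri_high <= 100))
  expect_true(all(pm$cri_low <= pm$cri50_low & pm$cri50_high <= pm$cri_high))
  expect_true(all(pm$cri_low <= pm$median_coverage &
                    pm$median_coverage <= pm$cri_high))
})

test_that("threshold flags are inclusive and report first crossing", {
  proj <- data.frame(country_id = "C1", year = 2024:2030,
                     indicator = "ANC1", stratum = "national",
                     mean_coverage = c(70, 74, 79.5, 80.0, 81, 83, 80.0))
  fl <- flag_threshold(proj, threshold = 80)
  expect_true(fl$reaches_target)          # 80.0 at 2030 counts (inclusive)
  expect_equal(fl$first_crossing_year, 2027)
  proj$mean_coverage[7] <- 79.99
  expect_false(flag_threshold(proj, 80)$reaches_target)
  proj2 <- transform(proj, mean_coverage = mean_coverage - 40)
  expect_true(is.na(flag_threshold(proj2, 80)$first_crossing_year))
})

test_that("urban-rural gap uses joint draws, not marginal intervals", {
  yrs <- c(2000, 2030)
  mk <- function(stratum, mean_cov) {
    data.frame(country_id = "C1", year = yrs, indicator = "ANC1",
               stratum = stratum, mean_coverage = mean_cov)
  }
  proj <- rbind(mk("urban", c(62.25, 62.25)), mk("rural", c(37.75, 37.75)))
  g <- urban_rural_gap(proj)
  expect_equal(g$gap, c(24.5, 24.5), tolerance = 1e-6)

  # correlated draws: the per-draw gap interval is much tighter than the
  # difference of the marginal interval bounds
  set.seed(8)
  base <- rnorm(500, 60, 8)
  dm <- cbind(base, base, base - 10 + rnorm(500, 0, 0.5),
              base - 10 + rnorm(500, 0, 0.5))
  proj2 <- rbind(mk("urban", rep(mean(base), 2)),
                 mk("rural", rep(mean(base) - 10, 2)))
  attr(proj2, "draws") <- dm
  g2 <- urban_rural_gap(proj2)
  marginal_width <- diff(quantile(base, c(0.025, 0.975))) * 2
  expect_true(all(g2$cri_high - g2$cri_low < marginal_width / 2))
  expect_true(all(g2$cri_low <= g2$gap & g2$gap <= g2$cri_high))

  expect_error(urban_rural_gap(mk("urban", c(60, 60))), "urban and rural")
})

test_that("slope index of inequality matches the WLS closed form", {
  expect_equal(slope_index_of_inequality(rep(60, 5)), 0)
  expect_equal(slope_index_of_inequality(c(20, 30, 40, 50, 60)), 50,
               tolerance = 1e-10)
  # invariance to level shifts; linear response to scaled deviations
  x <- c(31, 42, 55, 61, 70)
  expect_equal(slope_index_of_inequality(x + 10),
               slope_index_of_inequality(x), tolerance = 1e-9)
  centered <- x - mean(x)
  expect_equal(slope_index_of_inequality(mean(x) + 1.5 * centered),
               1.5 * slope_index_of_inequality(x), tolerance = 1e-9)
  expect_error(slope_index_of_inequality(x, shares = c(1, 1, 1, 1, 1)),
               "sum to 1")
  expect_error(slope_index_of_inequality(x, shares = c(-.2, .4, .2, .4, .2)),
               "positive")

  # range contract on arbitrary admissible coverages
  set.seed(5)
  r <- matrix(runif(5000, 0, 100), ncol = 5)
  s <- slope_index_of_inequality(r)
  expect_true(all(abs(s) <= 100))

  # per-draw evaluation equals a brute-force row-by-row WLS oracle
  wls_oracle <- function(yrow, w = rep(0.2, 5)) {
    ridit <- cumsum(w) - w / 2
    fit <- lm(yrow ~ ridit, weights = w)
    max(-100, min(100, unname(coef(fit)[2])))
  }
  draws <- matrix(runif(500, 0, 100), ncol = 5)
  expect_equal(slope_index_of_inequality(draws),
               apply(draws, 1, wls_oracle), tolerance = 1e-8)
  # and under unequal shares
  sh <- c(0.1, 0.15, 0.25, 0.3, 0.2)
  expect_equal(slope_index_of_inequality(draws, sh),
               apply(draws, 1, wls_oracle, w = sh), tolerance = 1e-8)
})

test_that("SII summarized per country-year from quintile projections", {
  yrs <- c(2000, 2030)
  rows <- expand.grid(stratum = paste0("Q", 1:5), year = yrs,
                      stringsAsFactors = FALSE)
  proj <- data.frame(country_id = "C1", year = rows$year, indicator = "ANC1",
                     stratum = rows$stratum,
                     mean_coverage = rep(c(20, 30, 40, 50, 60), 2))
  # without draws: point SII from posterior means
  tab <- sii_table(proj)
  expect_equal(tab$sii, c(50, 50), tolerance = 1e-9)
  # with draws: mean of per-draw SIIs plus a credible interval
  set.seed(2)
  dm <- matrix(rnorm(200 * 10, rep(proj$mean_coverage, each = 200), 2),
               nrow = 200)
  attr(proj, "draws") <- dm
  tab2 <- sii_table(proj)
  expect_equal(tab2$sii, c(50, 50), tolerance = 1)
  expect_true(all(tab2$cri_low < tab2$sii & tab2$sii < tab2$cri_high))
})

test_that("rates of change are annualized and antisymmetric", {
  proj <- data.frame(country_id = "NPL", year = c(2000, 2030),
                     indicator = "ANC4", stratum = "national",
                     mean_coverage = c(15.7, 87.6))
  rc <- rate_of_change(proj, 2000, 2030)
  expect_equal(rc$abs_rate_pp_per_year, 2.396667, tolerance = 1e-6)
  expect_equal(rc$rel_rate_annualized, (87.6 / 15.7)^(1 / 30) - 1,
               tolerance = 1e-9)
  # flat trajectory
  projf <- transform(proj, mean_coverage = 44)
  expect_equal(rate_of_change(projf, 2000, 2030)$abs_rate_pp_per_year, 0)
  # reversing the window negates the absolute rate
  rc_rev <- rate_of_change(proj, 2030, 2000)
  expect_equal(rc_rev$abs_rate_pp_per_year, -rc$abs_rate_pp_per_year)
  # zero baseline: relative rate undefined
  proj0 <- transform(proj, mean_coverage = c(0, 50))
  expect_true(is.na(rate_of_change(proj0, 2000, 2030)$rel_rate_annualized))
  expect_error(rate_of_change(proj, 2000, 2031), "present")
})

test_that("fitted-model projection respects stored standardization", {
  tf <- cached_tiny_fit()
  proj <- predict(tf$fit, years = 2000:2030)
  expect_equal(nrow(proj), 6 * 31)
  expect_true(all(proj$cri_low >= 0 & proj$cri_high <= 100))
  expect_true(all(proj$cri_low <= proj$cri50_low &
                    proj$cri50_high <= proj$cri_high))
  # keep_draws: summary columns recomputable from the attached matrix
  proj2 <- project_coverage(tf$fit, years = c(2000, 2030), keep_draws = TRUE)
  dm <- attr(proj2, "draws")
  expect_equal(ncol(dm), nrow(proj2))
  expect_equal(colMeans(dm), proj2$mean_coverage, tolerance = 1e-9)
})
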