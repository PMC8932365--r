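test_that("linear predictor applies the year-2000 coding and covariates", {
  cb <- matrix(0, 1, 4, dimnames = list("C1", c("intercept", "year",
                                                "sdi", "hrh")))
  st <- manual_state(cb)
  expect_equal(linear_predictor(st, "C1", 2013,
                                list(sdi = 0.7, hrh = 2)), 0)
  st$country_beta["C1", ] <- c(0, 0.1, 0, 0)
  expect_equal(linear_predictor(st, "C1", 2010, list(sdi = 0, hrh = 0)), 1.0)
  st$country_beta["C1", ] <- c(-1, 0, 2, 0)
  # with no stored scale, supplied covariates are taken as standardized
  expect_equal(linear_predictor(st, "C1", 2005, list(sdi = 0.5, hrh = 0)), 0)
  expect_error(linear_predictor(st, "C9", 2005, list(sdi = 0, hrh = 0)),
               "unknown country")
})

test_that("log-likelihood is a sum of Normal densities at the predictor", {
  md <- oracle_frame(n = 1, seed = 4)
  cb <- matrix(0, 1, 4, dimnames = list("C1", colnames(md$X)))
  st <- manual_state(cb, obs_sd = 1)
  # single observation sitting exactly on the predictor: -log(sqrt(2 pi))
  md1 <- md
  md1$y <- as.vector(md$X %*% rep(0, 4)) # y = eta = 0
  expect_equal(log_likelihood(st, md1), -0.9189385, tolerance = 1e-6)
  # shifting the observation by 2 subtracts 2 under unit noise
  md1$y <- md1$y + 2
  expect_equal(log_likelihood(st, md1), -2.9189385, tolerance = 1e-6)
  # additivity: duplicating the row exactly doubles the log-likelihood
  md2 <- md1
  md2$y <- rep(md1$y, 2)
  md2$X <- md1$X[c(1, 1), , drop = FALSE]
  md2$country <- rep(md1$country, 2)
  md2$n <- 2L
  expect_equal(log_likelihood(st, md2), 2 * log_likelihood(st, md1))
  st$obs_sd <- -1
  expect_error(log_likelihood(st, md1), "positive")
})

test_that("log-prior respects support and matches the Gamma oracle", {
  md <- oracle_frame(n = 5, seed = 6)
  pri <- anc_priors()
  st <- anctrend:::init_state(md)
  base <- log_prior(st, pri, md)
  expect_true(is.finite(base))

  # tau outside Uniform(0, 1000): out of support, -Inf not an error
  st_bad <- st; st_bad$obs_sd <- 1500
  expect_identical(log_prior(st_bad, pri, md), -Inf)
  st_bad$obs_sd <- -1
  expect_identical(log_prior(st_bad, pri, md), -Inf)
  st_bad <- st; st_bad$region_sd[1, 1] <- -0.1
  expect_identical(log_prior(st_bad, pri, md), -Inf)

  # Uniform flatness: moving tau inside (0,1000) leaves the prior unchanged
  st5 <- st; st5$obs_sd <- 5
  st500 <- st; st500$obs_sd <- 500
  expect_equal(log_prior(st5, pri, md), log_prior(st500, pri, md))

  # Gamma(0.001, 0.001) log-density at sd = 1, against the hand formula
  # 0.001 log(0.001) - log Gamma(0.001) + (0.001 - 1) log(1) - 0.001
  expect_equal(anctrend:::log_sd_prior(1, pri), -6.9150866, tolerance = 1e-6)
})

test_that("log-posterior decomposes into likelihood plus prior", {
  md <- oracle_frame(n = 8, seed = 7)
  pri <- anc_priors()
  st <- anctrend:::init_state(md)
  expect_equal(log_posterior(st, md, pri),
               log_likelihood(st, md) + log_prior(st, pri, md))
  st_bad <- st; st_bad$obs_sd <- 2000
  expect_identical(log_posterior(st_bad, md, pri), -Inf)

  # appending one observation with y = eta under tau = 1 shifts the
  # posterior by exactly -log(sqrt(2 pi))
  st$obs_sd <- 1
  md2 <- md
  eta_new <- sum(md$X[1, ] * st$country_beta[1, ])
  md2$y <- c(md$y, eta_new)
  md2$X <- rbind(md$X, md$X[1, ])
  md2$country <- c(md$country, md$country[1])
  md2$n <- md$n + 1L
  expect_equal(log_posterior(st, md2, pri) - log_posterior(st, md, pri),
               -0.9189385, tolerance = 1e-6)
})

test_that("quintile predictor reduces to the national model and stays ordered", {
  cb <- matrix(c(0, 0.1, 0, 0), 1, 4,
               dimnames = list("C1", c("intercept", "year", "sdi", "hrh")))
  st <- manual_state(cb)
  st$q_int <- matrix(0, 1, 5, dimnames = list("C1", paste0("Q", 1:5)))
  st$q_slope <- matrix(0, 1, 5, dimnames = list("C1", paste0("Q", 1:5)))
  st$q_sd <- 0.2
  cv <- list(sdi = 0, hrh = 0)
  expect_equal(quintile_predictor(st, "C1", "Q3", 2010, cv),
               linear_predictor(st, "C1", 2010, cv))
  st$q_int["C1", ] <- c(-0.2, -0.1, 0, 0.1, 0.2)
  preds <- vapply(paste0("Q", 1:5), function(q)
    quintile_predictor(st, "C1", q, 2007, cv), numeric(1))
  expect_true(all(diff(preds) > 0))
  # sum-to-zero identification at year 2000
  devs <- vapply(paste0("Q", 1:5), function(q)
    quintile_predictor(st, "C1", q, 2000, cv) -
      linear_predictor(st, "C1", 2000, cv), numeric(1))
  expect_equal(sum(devs), 0, tolerance = 1e-12)
  expect_error(quintile_predictor(st, "C1", "Q9", 2000, cv), "quintile")
})
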