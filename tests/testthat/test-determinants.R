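test_that("odds-ratio summaries transform coefficient draws correctly", {
  nm <- c("wealth_quintile:Q5", "residence:rural")
  zero <- matrix(0, 100, 2, dimnames = list(NULL, nm))
  tab <- summarize_odds_ratios(zero)
  q5 <- tab[tab$category == "Q5", ]
  expect_equal(q5$or_point, 1)
  expect_equal(q5$cri_low, 1)
  expect_equal(q5$cri_high, 1)

  ln2 <- matrix(log(2), 100, 2, dimnames = list(NULL, nm))
  tab2 <- summarize_odds_ratios(ln2)
  expect_equal(tab2$or_point[tab2$category == "Q5"], 2, tolerance = 1e-9)

  # functional equivariance: shifting all draws by delta multiplies the
  # point estimate and both interval bounds by exp(delta)
  set.seed(1)
  d <- matrix(rnorm(400, 0.3, 0.2), 200, 2, dimnames = list(NULL, nm))
  t1 <- summarize_odds_ratios(d)
  t2 <- summarize_odds_ratios(d + 0.7)
  sel <- !t1$reference
  expect_equal(t2$or_point[sel], exp(0.7) * t1$or_point[sel],
               tolerance = 1e-9)
  expect_equal(t2$cri_low[sel], exp(0.7) * t1$cri_low[sel], tolerance = 1e-9)

  # reference categories always reported as exactly 1 with no interval
  refs <- tab[tab$reference, ]
  expect_true(all(refs$or_point == 1))
  expect_true(all(is.na(refs$cri_low)))
  expect_setequal(refs$category,
                  c("<30", "male", "none", "1", "Q1", "urban"))

  # median point estimate option
  skewed <- matrix(c(rep(0, 150), rep(2, 50)), 200, 1,
                   dimnames = list(NULL, "residence:rural"))
  tm <- summarize_odds_ratios(skewed, point = "median")
  expect_equal(tm$or_point[tm$category == "rural"], 1, tolerance = 1e-9)
})

test_that("determinant fit validates inputs", {
  sc <- tiny_scenario(seed = 23)
  tr <- generate_truth(sc)
  ind <- generate_individuals(tr, sc, 400)
  bad <- ind
  bad$education[1] <- "postgraduate"
  expect_error(anc_determinants(bad), "education")
  one_country <- ind[ind$country_id == ind$country_id[1], ]
  expect_error(anc_determinants(one_country), "2 countries")
  expect_error(anc_determinants(ind[, -which(names(ind) == "anc4")],
                                indicator = "anc4"), "anc4")
})

test_that("determinant sampler is reproducible and recovers known effects", {
  sc <- tiny_scenario(seed = 24, determinant_sd = 0.2)
  tr <- generate_truth(sc)
  ind <- generate_individuals(tr, sc, 6000)
  ctl <- sampler_config(iterations = 900, burn_in = 400, thin = 1,
                        chains = 2, seed = 31)
  f1 <- anc_determinants(ind, "anc1", control = ctl)
  f2 <- anc_determinants(ind, "anc1", control = ctl)
  expect_identical(f1$draws$draws, f2$draws$draws)
  expect_equal(dim(f1$draws$draws), c(2, 500, length(f1$draws$parameter_names)))

  # point estimates land near the generating log-odds (large effects only;
  # modest n keeps this a smoke-level recovery check)
  est <- coef(f1)
  truth <- tr$determinant_coefs$anc1
  expect_lt(abs(est["education:secondary"] - truth["education:secondary"]),
            0.25)
  expect_lt(abs(est["wealth_quintile:Q5"] - truth["wealth_quintile:Q5"]),
            0.25)
  tab <- summarize_odds_ratios(f1)
  expect_true(all(tab$or_point > 0))
  expect_equal(tab$indicator[1], "anc1")
})

test_that("swapping the dummy reference flips an odds ratio to its reciprocal", {
  sc <- tiny_scenario(seed = 26, determinant_sd = 0.1)
  tr <- generate_truth(sc)
  ind <- generate_individuals(tr, sc, 5000)
  ctl <- sampler_config(iterations = 900, burn_in = 400, thin = 1,
                        chains = 2, seed = 33)
  f <- anc_determinants(ind, "anc1", control = ctl)
  or_rural <- summarize_odds_ratios(f)
  or_rural <- or_rural$or_point[or_rural$category == "rural"]
  # refit with residence recoded so that rural is the reference
  ind2 <- ind
  ind2$residence <- ifelse(ind2$residence == "rural", "urban", "rural")
  f2 <- anc_determinants(ind2, "anc1", control = ctl)
  or_swapped <- summarize_odds_ratios(f2)
  or_swapped <- or_swapped$or_point[or_swapped$category == "rural"]
  expect_equal(or_swapped, 1 / or_rural, tolerance = 0.1)
})
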