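test_that("logit transform matches closed form and clamps extremes", {
  expect_identical(logit_transform(0.5), 0)
  expect_equal(logit_transform(0.8), log(0.8 / 0.2), tolerance = 1e-12)
  expect_equal(logit_transform(0.8), 1.3862943611, tolerance = 1e-9)
  # proportions of exactly 0/1 are clamped, not infinite
  expect_equal(logit_transform(1, eps = 0.001), 6.9067547786, tolerance = 1e-9)
  expect_equal(logit_transform(0, eps = 0.001), -6.9067547786, tolerance = 1e-9)
  expect_error(logit_transform(1.2), "outside")
  expect_error(logit_transform(-0.1), "outside")
  expect_error(logit_transform(0.5, eps = 0.7), "eps")
})

test_that("inverse logit is the exact inverse on the clamped range", {
  expect_identical(inverse_logit(0), 0.5)
  expect_equal(inverse_logit(1.386294), 0.8, tolerance = 1e-6)
  expect_true(inverse_logit(-50) > 0 && inverse_logit(-50) <= 1e-20)
  expect_error(inverse_logit(Inf), "finite")
  expect_error(inverse_logit(NA_real_), "finite")
  # round trip across the whole working range, well inside machine precision
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(inverse_logit(logit_transform(p)), p, tolerance = 1e-10)
})
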