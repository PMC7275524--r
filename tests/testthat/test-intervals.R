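test_that("modified-Wilson interval reproduces the worked-example proportions", {
  expect_ci_equal(yu_interval(608, 871), 0.66681, 0.72768)
  expect_ci_equal(yu_interval(502, 608), 0.79363, 0.85389)
  expect_ci_equal(yu_interval(554, 608), 0.88610, 0.93148)
  expect_ci_equal(yu_interval(195, 263), 0.68557, 0.79087)
  expect_ci_equal(yu_interval(197, 263), 0.69358, 0.79787)
})

test_that("modified-Wilson interval is symmetric at one half and contains the estimate", {
  for (m in c(10, 50, 200)) {
    ci <- yu_interval(m / 2, m)
    expect_equal(ci$lower + ci$upper, 1, tolerance = 1e-12)
  }
  set.seed(1)
  for (i in 1:100) {
    m <- sample(5:500, 1); k <- sample(0:m, 1)
    ci <- yu_interval(k, m)
    expect_lte(ci$lower, k / m + 1e-12)
    expect_gte(ci$upper, k / m - 1e-12)
    expect_lte(ci$lower, ci$upper)
    expect_gte(ci$lower, 0); expect_lte(ci$upper, 1)
  }
})

test_that("modified-Wilson width shrinks as trials grow at fixed proportion", {
  widths <- vapply(c(20, 100, 500, 2500), function(m) {
    ci <- yu_interval(round(0.3 * m), m); ci$upper - ci$lower
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("modified-Wilson interval rejects invalid inputs", {
  expect_error(yu_interval(5, 0), "trials")
  expect_error(yu_interval(-1, 10), "\\[0, m\\]")
  expect_error(yu_interval(11, 10), "\\[0, m\\]")
  expect_error(yu_interval(3, 10, alpha = 1.2), "alpha")
})

test_that("adjusted Wald difference interval matches the worked example and closed forms", {
  # oriented Se2 - Se1 from discordant diseased cells
  expect_ci_equal(bonett_laplace_diff_interval(81, 29, 608), 0.05192, 0.11857)
  # equal discordants: centred at zero
  ci <- bonett_laplace_diff_interval(7, 7, 100)
  expect_equal(ci$lower, -ci$upper, tolerance = 1e-12)
  # no discordance: centre 0, half-width z sqrt(2) / 12
  ci0 <- bonett_laplace_diff_interval(0, 0, 10)
  expect_equal(ci0$upper, qnorm(0.975) * sqrt(2) / 12, tolerance = 1e-12)
  expect_equal(ci0$lower, -ci0$upper, tolerance = 1e-12)
})

test_that("score ratio interval reproduces the four worked-example LR intervals", {
  x <- weiner()
  expect_ci_equal(score_ratio_interval(x, "PLR1"), 2.610, 3.952)
  expect_ci_equal(score_ratio_interval(x, "PLR2"), 2.962, 4.505)
  expect_ci_equal(score_ratio_interval(x, "NLR1"), 0.195, 0.283)
  expect_ci_equal(score_ratio_interval(x, "NLR2"), 0.090, 0.153)
})

test_that("score ratio interval brackets its estimate and narrows with tenfold data", {
  x <- weiner()
  lr <- estimate_likelihood_ratios(x)
  x10 <- as_paired_counts(x$cells * 10)
  for (w in c("PLR1", "PLR2", "NLR1", "NLR2")) {
    ci <- score_ratio_interval(x, w)
    est <- lr$estimate[lr$parameter == w]
    expect_lte(ci$lower, est); expect_gte(ci$upper, est)
    ci10 <- score_ratio_interval(x10, w)
    expect_lt(ci10$upper - ci10$lower, ci$upper - ci$lower)
    expect_lte(ci10$lower, est); expect_gte(ci10$upper, est)
  }
})

test_that("score ratio interval stays positive and finite on sparse tables", {
  # zero discordant and zero concordant-negative diseased cells
  x <- paired_counts(12, 0, 0, 1, 2, 3, 4, 30)
  for (w in c("PLR1", "PLR2", "NLR1", "NLR2")) {
    ci <- score_ratio_interval(x, w)
    expect_gte(ci$lower, 0)
    expect_gt(ci$upper, ci$lower)
  }
})
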