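test_that("Wald accuracy statistics match the worked example and are additive", {
  w <- wald_accuracy_tests(weiner())
  expect_equal(w$se$statistic, 608 * (29 - 81)^2 / (4 * 29 * 81 + (473 + 25) * (29 + 81)),
               tolerance = 1e-12)
  expect_lt(abs(w$sp$statistic - 0.044), 5.1e-4)
  expect_lt(abs(w$global$statistic - 25.662), 5.1e-4)
  expect_equal(w$global$statistic, w$se$statistic + w$sp$statistic, tolerance = 1e-12)
})

test_that("likelihood-ratio accuracy statistics evaluate their deviance form", {
  l <- lrt_accuracy_tests(weiner())
  expect_equal(l$se$statistic,
               2 * (29 * log(2 * 29 / 110) + 81 * log(2 * 81 / 110)),
               tolerance = 1e-12)
  expect_lt(abs(l$se$statistic - 25.591), 5.1e-4)
  expect_equal(l$global$statistic, l$se$statistic + l$sp$statistic, tolerance = 1e-12)
  expect_equal(attr(l$se, "signed_root"), -sqrt(l$se$statistic))
  # balanced discordance nullifies the statistic
  lb <- lrt_accuracy_tests(paired_counts(10, 6, 6, 4, 3, 5, 5, 12))
  expect_equal(lb$se$statistic, 0, tolerance = 1e-12)
  # zero discordant cell: not computable
  lz <- lrt_accuracy_tests(paired_counts(10, 0, 6, 4, 3, 5, 5, 12))
  expect_true(is.na(lz$se$statistic))
})

test_that("McNemar with continuity correction matches the example and its null form", {
  expect_lt(abs(mcnemar_cc(29, 81)$statistic - 23.645), 5.1e-4)
  expect_lt(abs(mcnemar_cc(46, 44)$statistic - 0.011), 5.1e-4)
  for (k in c(0, 1, 5, 40)) expect_equal(mcnemar_cc(k, k + 1)$statistic, 0)
  expect_error(mcnemar_cc(0, 0), class = "compbdt_infeasible")
})

test_that("accuracy comparison follows the prevalence/sample-size decision rules", {
  # n = 871, prevalence 0.70: rule (b), McNemar branch, Holm rejects Se only
  a <- compare_accuracies(weiner())
  expect_equal(a$rule, "b")
  expect_equal(a$individual$method, "mcnemar_cc")
  expect_true(a$holm$reject[1])
  expect_false(a$holm$reject[2])
  expect_named(a$intervals, "se")
  expect_equal(a$intervals$se$larger, "Test 2")
  expect_ci_equal(a$intervals$se, 0.05192, 0.11857)

  # small sample, low prevalence: rule (a), individual Wald, no global statistic
  xa <- paired_counts(2, 1, 1, 0, 3, 2, 6, 65)
  expect_lte(xa$s / xa$n, 0.10)
  a2 <- compare_accuracies(xa)
  expect_equal(a2$rule, "a")
  expect_null(a2$global)
  expect_equal(a2$individual$method, "wald")

  # large n uses the individual Wald branch after a significant global test
  x3 <- as_paired_counts(weiner()$cells * 2) # n = 1742 >= 1000
  a3 <- compare_accuracies(x3)
  expect_equal(a3$rule, "b")
  expect_equal(a3$individual$method, "wald")
})

test_that("a symmetric table yields null statistics and no contrast intervals", {
  x <- paired_counts(200, 30, 30, 200, 50, 20, 20, 300)
  a <- compare_accuracies(x)
  expect_equal(a$global$wald$statistic, 0)
  expect_equal(a$global$wald$p_value, 1)
  expect_length(a$intervals, 0)
  expect_null(a$holm)
})

test_that("degenerate accuracy statistics are reported, not fatal", {
  # no discordant diseased pairs at n > 100
  x <- paired_counts(150, 0, 0, 30, 20, 18, 21, 120)
  a <- compare_accuracies(x)
  expect_true(length(a$notes) > 0)
  expect_true(is.na(a$global$wald$statistic))
})
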