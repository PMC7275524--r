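test_that("point estimates and standard errors match the worked example", {
  est <- estimate_parameters(weiner())
  g <- function(p, col) est[[col]][est$parameter == p]
  expect_lt(abs(g("prevalence", "estimate") - 0.69805), 5.1e-4)
  expect_lt(abs(g("prevalence", "se") - 0.016), 5.1e-4)
  expect_lt(abs(g("Se1", "estimate") - 0.82566), 5.1e-6 * 100)
  expect_lt(abs(g("Se2", "estimate") - 0.91118), 5.1e-4)
  expect_lt(abs(g("Sp1", "estimate") - 0.74144), 5.1e-4)
  expect_lt(abs(g("Sp2", "estimate") - 0.74905), 5.1e-4)
  expect_lt(abs(g("Se1", "se") - 0.015), 5.1e-4)
  expect_lt(abs(g("Sp1", "se") - 0.027), 5.1e-4)
  expect_lt(abs(g("PPV1", "estimate") - 0.88070), 5.1e-4)
  expect_lt(abs(g("PPV2", "estimate") - 0.89355), 5.1e-4)
  expect_lt(abs(g("NPV1", "estimate") - 0.64784), 5.1e-4)
  expect_lt(abs(g("NPV2", "estimate") - 0.78486), 5.1e-4)
  expect_lt(abs(g("PPV1", "se") - 0.014), 5.1e-4)
  expect_lt(abs(g("NPV1", "se") - 0.028), 5.1e-4)
  expect_lt(abs(g("NPV2", "se") - 0.026), 5.1e-4)
  expect_lt(abs(g("PLR1", "estimate") - 3.193), 5.1e-4)
  expect_lt(abs(g("PLR1", "se") - 0.339), 5.1e-4)
  expect_lt(abs(g("PLR2", "estimate") - 3.631), 5.1e-4)
  expect_lt(abs(g("NLR1", "estimate") - 0.235), 5.1e-4)
  expect_lt(abs(g("NLR1", "se") - 0.022), 5.1e-4)
  expect_lt(abs(g("NLR2", "estimate") - 0.119), 5.1e-4)
  expect_lt(abs(g("NLR2", "se") - 0.016), 5.1e-4)
})

test_that("likelihood-ratio estimators equal Se/(1-Sp) and (1-Se)/Sp exactly", {
  set.seed(7)
  for (i in 1:100) {
    x <- random_table()
    m <- x$margins
    if (m$r1. == 0 || m$r0. == 0 || m$r.1 == 0 || m$r.0 == 0) next
    lr <- estimate_likelihood_ratios(x)
    Se1 <- m$s1. / x$s; Se2 <- m$s.1 / x$s
    Sp1 <- m$r0. / x$r; Sp2 <- m$r.0 / x$r
    expect_equal(lr$estimate[lr$parameter == "PLR1"], Se1 / (1 - Sp1), tolerance = 1e-12)
    expect_equal(lr$estimate[lr$parameter == "PLR2"], Se2 / (1 - Sp2), tolerance = 1e-12)
    expect_equal(lr$estimate[lr$parameter == "NLR1"], (1 - Se1) / Sp1, tolerance = 1e-12)
    expect_equal(lr$estimate[lr$parameter == "NLR2"], (1 - Se2) / Sp2, tolerance = 1e-12)
  }
})

test_that("identical tests yield identical parameter estimates", {
  # no discordant pairs in either group: the two tests agree on every subject
  x <- paired_counts(14, 0, 0, 11, 3, 0, 0, 22)
  est <- estimate_parameters(x)
  g <- function(p) est$estimate[est$parameter == p]
  expect_equal(g("Se1"), g("Se2"))
  expect_equal(g("Sp1"), g("Sp2"))
  expect_equal(g("PPV1"), g("PPV2"))
  expect_equal(g("NPV1"), g("NPV2"))
  expect_equal(g("PLR1"), g("PLR2"))
})

test_that("undefined parameters are reported as NA, not errors", {
  # every non-diseased subject positive on both tests: Sp = 0, NLR denominators vanish
  x <- paired_counts(10, 2, 3, 5, 20, 0, 0, 0)
  est <- estimate_parameters(x)
  expect_equal(est$estimate[est$parameter == "Sp1"], 0)
  expect_true(is.na(est$estimate[est$parameter == "NLR1"]))
  # perfect diseased classification: NLR numerator 0, estimate 0
  x2 <- paired_counts(10, 0, 0, 0, 2, 3, 4, 20)
  lr <- estimate_likelihood_ratios(x2)
  expect_equal(lr$estimate[lr$parameter == "NLR1"], 0)
})

test_that("every reported interval contains its point estimate", {
  est <- estimate_parameters(weiner())
  ok <- !is.na(est$estimate)
  expect_true(all(est$lower[ok] <= est$estimate[ok] + 1e-12))
  expect_true(all(est$upper[ok] >= est$estimate[ok] - 1e-12))
})
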