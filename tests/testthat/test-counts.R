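test_that("margins of the paired table are derived correctly", {
  x <- weiner()
  expect_equal(x$s, 608)
  expect_equal(x$r, 263)
  expect_equal(x$n, 871)
  expect_equal(x$margins$n11, 495)
  expect_equal(x$margins$n10, 75)
  expect_equal(x$margins$n01, 125)
  expect_equal(x$margins$n00, 176)
  expect_equal(x$margins$s1., 502)
  expect_equal(x$margins$s.1, 554)
  expect_equal(x$margins$r0., 195)
  expect_equal(x$margins$r.0, 197)
})

test_that("invalid tables are rejected with informative errors", {
  expect_error(paired_counts(-1, 0, 0, 0, 0, 0, 0, 0), class = "compbdt_negative_cell")
  expect_error(paired_counts(1.5, 0, 0, 1, 1, 0, 0, 1), class = "compbdt_noninteger_cell")
  expect_error(paired_counts(0, 0, 0, 0, 1, 0, 0, 1), class = "compbdt_empty_group")
  expect_error(paired_counts(1, 0, 0, 1, 0, 0, 0, 0), class = "compbdt_empty_group")
  expect_error(paired_counts(NA, 0, 0, 1, 1, 0, 0, 1), class = "compbdt_invalid_cell")
  # error message names the offending cell
  expect_error(paired_counts(1, 0, -2, 1, 1, 0, 0, 1), "s01")
  # minimal balanced table is valid
  x <- paired_counts(1, 0, 0, 1, 1, 0, 0, 1)
  expect_equal(c(x$s, x$r, x$n), c(2, 2, 4))
})

test_that("validate-then-serialize is the identity and margins match brute force", {
  set.seed(42)
  for (i in 1:200) {
    x <- random_table()
    cl <- x$cells
    expect_identical(as_paired_counts(cl)$cells, cl)
    expect_equal(x$s, sum(cl[1:4]))
    expect_equal(x$r, sum(cl[5:8]))
    expect_equal(x$margins$s1., cl[["s11"]] + cl[["s10"]])
    expect_equal(x$margins$s.0, cl[["s10"]] + cl[["s00"]])
    expect_equal(x$margins$r.1, cl[["r11"]] + cl[["r01"]])
    expect_equal(x$margins$n0., cl[["s01"]] + cl[["s00"]] + cl[["r01"]] + cl[["r00"]])
  }
})

test_that("Youden indices are Se + Sp - 1 and non-informative tests are caught", {
  y <- youden_indices(weiner())
  expect_equal(unname(y[1]), 502 / 608 + 195 / 263 - 1, tolerance = 1e-12)
  expect_lt(abs(y[["test1"]] - 0.567), 5e-4)
  expect_lt(abs(y[["test2"]] - 0.660), 5e-4)
  # Se1 = Sp1 = 0.5 puts test 1 exactly at chance
  expect_error(compbdt:::check_youden(paired_counts(5, 0, 0, 5, 5, 0, 0, 5)),
               class = "compbdt_noninformative_test")
  # errors exceed successes: negative index
  expect_error(compbdt:::check_youden(paired_counts(1, 0, 0, 9, 9, 0, 0, 1)),
               class = "compbdt_noninformative_test")
})

test_that("feasibility report tracks the zero pattern per statistic", {
  f <- feasibility(weiner())
  expect_true(all(f$feasible))

  # no discordant diseased pairs: Se comparisons collapse
  f2 <- feasibility(paired_counts(30, 0, 0, 10, 5, 8, 9, 40))
  get <- function(f, st) f$feasible[f$statistic == st]
  expect_false(get(f2, "wald_se"))
  expect_false(get(f2, "lrt_se"))
  expect_false(get(f2, "mcnemar_se"))
  expect_true(get(f2, "wald_sp"))
  expect_true(get(f2, "lr_contrast")) # every Se/Sp margin still interior

  # a zero Se/Sp margin puts a likelihood ratio on the boundary
  f4 <- feasibility(paired_counts(30, 5, 0, 0, 5, 8, 9, 40))
  expect_false(get(f4, "lr_contrast"))

  # a single zero discordant non-diseased cell only blocks the Sp LRT
  f3 <- feasibility(paired_counts(30, 6, 7, 10, 5, 8, 0, 40))
  expect_false(get(f3, "lrt_sp"))
  expect_true(get(f3, "wald_sp"))
  expect_true(get(f3, "mcnemar_sp"))
  expect_true(get(f3, "wald_se"))
})
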