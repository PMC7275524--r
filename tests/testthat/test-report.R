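weiner_report <- function(...) {
  compbdt(473, 29, 81, 25, 22, 46, 44, 151, reps = 200, seed = 42, ...)
}

test_that("the full report carries every headline number of the worked example", {
  res <- weiner_report()
  txt <- paste(capture.output(print(res)), collapse = "\n")
  for (needle in c("69.805%", "(66.681%; 72.768%)",
                   "82.566%", "91.118%", "74.144%", "74.905%",
                   "25.662", "23.645", "0.011",
                   "(5.192%; 11.857%)",
                   "3.193", "3.631", "0.235", "0.119",
                   "(2.610; 3.952)", "(0.090; 0.153)",
                   "23.438", "-0.898", "4.663", "(1.412; 2.554)",
                   "88.070%", "89.355%", "64.784%", "78.486%",
                   "25.944", "0.807", "22.502", "(8.041%; 19.363%)"))
    expect_match(txt, needle, fixed = TRUE)
  expect_match(txt, "reject the hypothesis H0: Se1 = Se2")
  expect_match(txt, "do not reject the hypothesis H0: Sp1 = Sp2")
  expect_match(txt, "greater than the negative PV of Test 1")
})

test_that("tiny p-values render below display resolution instead of as zero", {
  res <- weiner_report()
  txt <- paste(capture.output(print(res)), collapse = "\n")
  expect_match(txt, "< 0.001", fixed = TRUE)
})

test_that("report files are written and are reproducible byte for byte", {
  res <- weiner_report()
  d1 <- withr::local_tempdir()
  paths <- write_reports(res, d1)
  expect_true(all(file.exists(paths)))
  expect_identical(basename(paths),
                   c("Results_Comparison_Accuracies.txt",
                     "Results_Comparison_LRs.txt",
                     "Results_Comparison_PVs.txt"))
  expect_match(paste(readLines(paths[1]), collapse = "\n"),
               "reject the hypothesis H0: Se1 = Se2")
  res2 <- weiner_report()
  d2 <- withr::local_tempdir()
  paths2 <- write_reports(res2, d2)
  for (i in 1:3)
    expect_identical(readLines(paths[i]), readLines(paths2[i]))
})

test_that("case-control design suppresses prevalence and predictive values", {
  res <- weiner_report(design = "case_control")
  expect_null(res$predictive_values)
  txt <- paste(capture.output(print(res)), collapse = "\n")
  expect_match(txt, "case-control")
  expect_no_match(txt, "Estimated prevalence")
  expect_no_match(txt, "negative PV of Test 1 is 64.784%")
  # accuracy and LR blocks are unaffected
  expect_match(txt, "25.662", fixed = TRUE)
  expect_match(txt, "23.438", fixed = TRUE)
})

test_that("a stricter alpha widens intervals without moving the estimates", {
  r5 <- weiner_report()
  r1 <- compbdt(473, 29, 81, 25, 22, 46, 44, 151, alpha = 0.01, reps = 200, seed = 42)
  expect_equal(r1$estimates$estimate, r5$estimates$estimate)
  ok <- !is.na(r5$estimates$lower)
  expect_true(all(r1$estimates$lower[ok] <= r5$estimates$lower[ok] + 1e-12))
  expect_true(all(r1$estimates$upper[ok] >= r5$estimates$upper[ok] - 1e-12))
})

test_that("validation failures surface with their original condition class", {
  expect_error(compbdt(-1, 0, 0, 0, 1, 0, 0, 1, reps = 10),
               class = "compbdt_negative_cell")
  expect_error(compbdt(5, 0, 0, 5, 5, 0, 0, 5, reps = 10),
               class = "compbdt_noninformative_test")
})
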