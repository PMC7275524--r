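# shared fixtures, built in code

# coronary-artery-disease study: exercise test (Test 1) vs chest-pain history
# (Test 2) against angiography in 871 subjects; the canonical worked example
weiner <- function() paired_counts(473, 29, 81, 25, 22, 46, 44, 151)

# random valid paired table; guarantees both disease groups non-empty
random_table <- function(min_n = 40, max_n = 400) {
  repeat {
    n <- sample(min_n:max_n, 1)
    probs <- as.vector(stats::rgamma(8, shape = 0.8)) # ragged cell masses
    cells <- drop(stats::rmultinom(1, n, probs / sum(probs)))
    if (sum(cells[1:4]) >= 1 && sum(cells[5:8]) >= 1)
      return(as_paired_counts(cells))
  }
}

# null configuration with equal Se and Sp and within-group correlation rho
null_probs <- function(prev, Se, Sp, rho) {
  d <- c(Se^2 + rho * Se * (1 - Se), Se * (1 - Se) * (1 - rho),
         Se * (1 - Se) * (1 - rho), (1 - Se)^2 + rho * Se * (1 - Se))
  h <- c((1 - Sp)^2 + rho * Sp * (1 - Sp), Sp * (1 - Sp) * (1 - rho),
         Sp * (1 - Sp) * (1 - rho), Sp^2 + rho * Sp * (1 - Sp))
  c(prev * d, (1 - prev) * h)
}

# swap the roles of Test 1 and Test 2
relabel_tests <- function(x) {
  cl <- x$cells
  paired_counts(cl[["s11"]], cl[["s01"]], cl[["s10"]], cl[["s00"]],
                cl[["r11"]], cl[["r01"]], cl[["r10"]], cl[["r00"]])
}

expect_ci_equal <- function(ci, lower, upper, tol = 5.1e-4) {
  expect_lt(abs(ci$lower - lower), tol)
  expect_lt(abs(ci$upper - upper), tol)
}
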