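# Comparison of the sensitivities and specificities (the accuracies).

#' Wald statistics for the paired comparison of sensitivities and specificities
#'
#' Individual Wald statistics for `H0: Se1 = Se2` and `H0: Sp1 = Sp2`,
#' `chi2_Se = s (s10 - s01)^2 / (4 s10 s01 + (s11 + s00)(s10 + s01))` (and the
#' `r`-cell analogue), each referred to a chi-square with 1 df; the global
#' statistic for the simultaneous null is their sum, referred to a chi-square
#' with 2 df.
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @return A list of `bdt_test` objects `se`, `sp`, `global`; an element is
#'   `NA`-valued when its denominator is zero.
#' @examples
#' wald_accuracy_tests(paired_counts(473, 29, 81, 25, 22, 46, 44, 151))
#' @export
wald_accuracy_tests <- function(x) {
  x <- as_paired_counts(x)
  cl <- as.list(x$cells)
  den_se <- 4 * cl$s10 * cl$s01 + (cl$s11 + cl$s00) * (cl$s10 + cl$s01)
  den_sp <- 4 * cl$r10 * cl$r01 + (cl$r11 + cl$r00) * (cl$r10 + cl$r01)
  w_se <- if (den_se > 0) x$s * (cl$s10 - cl$s01)^2 / den_se else NA_real_
  w_sp <- if (den_sp > 0) x$r * (cl$r10 - cl$r01)^2 / den_sp else NA_real_
  list(se = bdt_test(w_se, "chi2_1", "Wald (Se)"),
       sp = bdt_test(w_sp, "chi2_1", "Wald (Sp)"),
       global = bdt_test(w_se + w_sp, "chi2_2", "Wald (global)"))
}

#' Likelihood-ratio statistics for the paired comparison of accuracies
#'
#' Deviance statistics built from the discordant cells,
#' `chi2_Se = 2 [s10 ln(2 s10 / (s10 + s01)) + s01 ln(2 s01 / (s10 + s01))]`
#' (and the `r`-cell analogue); defined only when all discordant cells of the
#' group are positive. Each individual statistic is referred to a chi-square
#' with 1 df (its signed square root, reported as attribute `"signed_root"`,
#' is the corresponding normal deviate); the global statistic is their sum
#' with 2 df.
#'
#' @inheritParams wald_accuracy_tests
#' @return A list of `bdt_test` objects `se`, `sp`, `global`; `NA`-valued
#'   where a discordant cell is zero.
#' @export
lrt_accuracy_tests <- function(x) {
  x <- as_paired_counts(x)
  cl <- as.list(x$cells)
  dev2 <- function(a, b)
    if (a > 0 && b > 0) 2 * (a * log(2 * a / (a + b)) + b * log(2 * b / (a + b)))
    else NA_real_
  l_se <- dev2(cl$s10, cl$s01)
  l_sp <- dev2(cl$r10, cl$r01)
  out <- list(se = bdt_test(l_se, "chi2_1", "LRT (Se)"),
              sp = bdt_test(l_sp, "chi2_1", "LRT (Sp)"),
              global = bdt_test(l_se + l_sp, "chi2_2", "LRT (global)"))
  attr(out$se, "signed_root") <- sign(cl$s10 - cl$s01) * sqrt(l_se)
  attr(out$sp, "signed_root") <- sign(cl$r10 - cl$r01) * sqrt(l_sp)
  out
}

#' McNemar test with continuity correction for one pair of discordant counts
#'
#' `chi2 = (|a - b| - 1)^2 / (a + b)`, referred to a chi-square with 1 df.
#' Requires `a + b > 0`.
#'
#' @param a,b Discordant counts (e.g. `s10` and `s01` for the sensitivities).
#' @return A `bdt_test` object.
#' @examples
#' mcnemar_cc(29, 81)  # statistic 23.645
#' @export
mcnemar_cc <- function(a, b) {
  if (a + b <= 0)
    stop(errorCondition("McNemar test needs at least one discordant pair (a + b > 0)",
                        class = c("compbdt_infeasible", "error", "condition")))
  bdt_test((abs(a - b) - 1)^2 / (a + b), "chi2_1", "McNemar (cc)")
}

# which individual test backs up a significant global accuracy test:
# Wald for n <= 100 or n >= 1000, McNemar with continuity correction otherwise
accuracy_branch <- function(n) if (n <= 100 || n >= 1000) "wald" else "mcnemar"

#' Compare the accuracies (Se and Sp) of the two tests
#'
#' Applies the prevalence/sample-size decision rules for paired accuracy
#' comparisons:
#' * rule (a) — estimated prevalence <= 10% and `n <= 100`: no global
#'   statistic; the two individual Wald tests are solved directly with Holm
#'   step-down at `alpha`.
#' * rule (b) — otherwise: the global Wald test (2 df) is solved first (the
#'   global likelihood-ratio test is also reported when the discordant cells
#'   allow it); only if significant are the individual nulls resolved, by
#'   Wald tests when `n <= 100` or `n >= 1000` and by McNemar tests with
#'   continuity correction when `100 < n < 1000`, again with Holm.
#'
#' For each rejected individual null an oriented
#' [bonett_laplace_diff_interval()] (larger minus smaller parameter) is
#' attached.
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @param alpha Significance level.
#' @return A list of class `bdt_comparison` with elements `family`, `rule`
#'   (`"a"` or `"b"`), `global` (list with `wald` and possibly `lrt`; absent
#'   under rule (a)), `individual` (list with `method`, `se`, `sp`), `holm`,
#'   `intervals` (oriented CIs for rejected nulls), and `notes` (character
#'   vector of infeasibility messages).
#' @examples
#' compare_accuracies(paired_counts(473, 29, 81, 25, 22, 46, 44, 151))
#' @export
compare_accuracies <- function(x, alpha = 0.05) {
  x <- as_paired_counts(x)
  check_alpha(alpha)
  q <- acc_quantities(x)
  fl <- feas_flags(x)
  notes <- character()
  wald <- wald_accuracy_tests(x)
  rule <- if (q$prev <= 0.10 && x$n <= 100) "a" else "b"
  out <- list(family = "accuracy", rule = rule, alpha = alpha,
              estimates = q, global = NULL, individual = NULL,
              holm = NULL, intervals = list(), notes = notes)

  individual <- function(branch) {
    if (branch == "wald") {
      list(method = "wald", se = wald$se, sp = wald$sp)
    } else {
      cl <- as.list(x$cells)
      se <- if (fl$mcnemar_se) mcnemar_cc(cl$s10, cl$s01) else bdt_test(NA_real_, "chi2_1", "McNemar (cc)")
      sp <- if (fl$mcnemar_sp) mcnemar_cc(cl$r10, cl$r01) else bdt_test(NA_real_, "chi2_1", "McNemar (cc)")
      list(method = "mcnemar_cc", se = se, sp = sp)
    }
  }
  attach_intervals <- function(out) {
    rej <- out$holm$reject
    if (isTRUE(rej[1])) {
      cl <- as.list(x$cells)
      if (q$Se2 >= q$Se1)
        out$intervals$se <- bonett_laplace_diff_interval(cl$s01, cl$s10, x$s, alpha)
      else
        out$intervals$se <- bonett_laplace_diff_interval(cl$s10, cl$s01, x$s, alpha)
      out$intervals$se$larger <- if (q$Se2 >= q$Se1) "Test 2" else "Test 1"
      out$intervals$se$label <- if (q$Se2 >= q$Se1) "Se2 - Se1" else "Se1 - Se2"
    }
    if (isTRUE(rej[2])) {
      cl <- as.list(x$cells)
      if (q$Sp2 >= q$Sp1)
        out$intervals$sp <- bonett_laplace_diff_interval(cl$r01, cl$r10, x$r, alpha)
      else
        out$intervals$sp <- bonett_laplace_diff_interval(cl$r10, cl$r01, x$r, alpha)
      out$intervals$sp$larger <- if (q$Sp2 >= q$Sp1) "Test 2" else "Test 1"
      out$intervals$sp$label <- if (q$Sp2 >= q$Sp1) "Sp2 - Sp1" else "Sp1 - Sp2"
    }
    out
  }

  if (rule == "a") {
    out$individual <- individual("wald")
    if (!fl$wald_se) notes <- c(notes, "Wald statistic for Se1 = Se2 is not computable (degenerate denominator).")
    if (!fl$wald_sp) notes <- c(notes, "Wald statistic for Sp1 = Sp2 is not computable (degenerate denominator).")
    p <- c(out$individual$se$p_value, out$individual$sp$p_value)
    out$holm <- holm_partial(p, alpha)
    out <- attach_intervals(out)
  } else {
    if (!fl$wald_se || !fl$wald_sp) {
      notes <- c(notes, "Global Wald statistic is not computable (degenerate denominator); accuracies cannot be compared on this table.")
      out$global <- list(wald = wald$global)
    } else {
      out$global <- list(wald = wald$global)
      if (fl$lrt_se && fl$lrt_sp) out$global$lrt <- lrt_accuracy_tests(x)$global
      else notes <- c(notes, "Global likelihood-ratio statistic not computed: a discordant cell is zero.")
      if (wald$global$p_value <= alpha) {
        br <- accuracy_branch(x$n)
        out$individual <- individual(br)
        p <- c(out$individual$se$p_value, out$individual$sp$p_value)
        out$holm <- holm_partial(p, alpha)
        out <- attach_intervals(out)
      }
    }
  }
  out$notes <- notes
  class(out) <- "bdt_comparison"
  out
}
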