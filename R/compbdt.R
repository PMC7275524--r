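#' Estimate and compare two binary diagnostic tests under a paired design
#'
#' Full analysis of a paired-design table: validation (including positive
#' Youden indices and feasibility of each statistic), estimation of
#' prevalence, sensitivities, specificities, predictive values and likelihood
#' ratios with their standard errors and confidence intervals, the three
#' simultaneous comparisons ([compare_accuracies()], [compare_lrs()],
#' [compare_pvs()]) with Holm-resolved individual tests and oriented
#' contrast intervals, and a Monte Carlo estimate of the power (or of the
#' probability of a type II error) of each global test.
#'
#' @param s11,s10,s01,s00 Diseased-group cell counts (Test 1 result then
#'   Test 2 result; 1 positive, 0 negative).
#' @param r11,r10,r01,r00 Non-diseased-group cell counts.
#' @param alpha Significance level for every test and interval.
#' @param decip Decimal places used when printing the report.
#' @param reps Monte Carlo replicates for the power estimates.
#' @param seed Integer seed for the Monte Carlo draws (fixed default so
#'   reports are reproducible).
#' @param design `"paired"` for a single cohort sample (default) or
#'   `"case_control"` when the diseased and non-diseased sample sizes were
#'   fixed by the researcher; under `"case_control"` the prevalence and every
#'   predictive-value result are suppressed as invalid.
#' @return An object of class `compbdt` with components `counts`,
#'   `estimates`, `accuracy`, `likelihood_ratios`, `predictive_values`
#'   (comparison outcomes), `power` (named list per family), `feasibility`,
#'   `youden`, and the configuration. Its print method renders the full
#'   report.
#' @examples
#' res <- compbdt(473, 29, 81, 25, 22, 46, 44, 151, reps = 200)
#' res$estimates
#' @export
compbdt <- function(s11, s10, s01, s00, r11, r10, r01, r00,
                    alpha = 0.05, decip = 3, reps = 10000, seed = 1234,
                    design = c("paired", "case_control")) {
  design <- match.arg(design)
  check_alpha(alpha)
  if (decip < 0) stop("`decip` must be >= 0")
  x <- paired_counts(s11, s10, s01, s00, r11, r10, r01, r00)
  youden <- check_youden(x)
  feas <- feasibility(x)
  estimates <- estimate_parameters(x, alpha)
  acc <- compare_accuracies(x, alpha)
  lr <- compare_lrs(x, alpha)
  pv <- if (design == "paired") compare_pvs(x, alpha) else NULL
  families <- c("accuracy", "likelihood_ratios",
                if (design == "paired") "predictive_values")
  if (!is.null(seed)) set.seed(seed)
  power <- lapply(stats::setNames(families, families), function(f) {
    tryCatch(estimate_power(x, f, alpha, reps),
             error = function(e) conditionMessage(e))
  })
  structure(list(counts = x, youden = youden, feasibility = feas,
                 estimates = estimates, accuracy = acc,
                 likelihood_ratios = lr, predictive_values = pv,
                 power = power, alpha = alpha, decip = decip, reps = reps,
                 seed = seed, design = design),
            class = "compbdt")
}

# --- report rendering ------------------------------------------------------

ci_txt <- function(lo, hi, decip, pct = TRUE) {
  if (pct) sprintf("(%s; %s)", fmt_pct(lo, decip), fmt_pct(hi, decip))
  else sprintf("(%s; %s)", fmt_num(lo, decip), fmt_num(hi, decip))
}

est_line <- function(est, label, parameter, decip, level, pct = TRUE) {
  row <- est[est$parameter == parameter, ]
  if (is.na(row$estimate))
    return(sprintf("%s is not estimable on this table.", label))
  sprintf("Estimated %s is %s and its standard error is %s. %g%% confidence interval for the %s is %s.",
          label,
          if (pct) fmt_pct(row$estimate, decip) else fmt_num(row$estimate, decip),
          fmt_num(row$se, decip), 100 * level, label,
          ci_txt(row$lower, row$upper, decip, pct))
}

power_lines <- function(pw, decip, alpha) {
  if (is.character(pw))
    return(sprintf("Power / type II error not estimated: %s", pw))
  if (pw$mode == "power")
    sprintf("Estimated power (to an alpha error of %g%%) is %s.",
            100 * alpha, fmt_pct(pw$value, decip))
  else
    sprintf("Estimated probability of a type II error (to an alpha error of %g%%) is %s.",
            100 * alpha, fmt_pct(pw$value, decip))
}

holm_sentence <- function(labels, reject) {
  verdict <- function(lab, rej) {
    if (is.na(rej)) sprintf("the hypothesis H0: %s could not be tested", lab)
    else if (rej) sprintf("we reject the hypothesis H0: %s", lab)
    else sprintf("we do not reject the hypothesis H0: %s", lab)
  }
  paste0("Applying the Holm method, ", verdict(labels[1], reject[1]),
         " and ", verdict(labels[2], reject[2]), ".")
}

render_prevalence <- function(z) {
  lvl <- 1 - z$alpha
  c("Prevalence of the disease",
    "-------------------------",
    est_line(z$estimates, "prevalence of the disease", "prevalence", z$decip, lvl))
}

render_accuracy <- function(z) {
  a <- z$accuracy; d <- z$decip; lvl <- 1 - z$alpha; est <- z$estimates
  out <- c("Comparison of the accuracies (sensitivities and specificities)",
           "---------------------------------------------------------------",
           est_line(est, "sensitivity of Test 1", "Se1", d, lvl),
           est_line(est, "sensitivity of Test 2", "Se2", d, lvl),
           est_line(est, "specificity of Test 1", "Sp1", d, lvl),
           est_line(est, "specificity of Test 2", "Sp2", d, lvl), "")
  if (a$rule == "a") {
    out <- c(out,
      "Estimated prevalence is at most 10% and n <= 100: the two individual Wald tests are solved directly (no global statistic).",
      sprintf("Wald test statistic for H0: Se1 = Se2 is %s and the two-sided p-value is %s.",
              fmt_num(a$individual$se$statistic, d), fmt_p(a$individual$se$p_value, d)),
      sprintf("Wald test statistic for H0: Sp1 = Sp2 is %s and the two-sided p-value is %s.",
              fmt_num(a$individual$sp$statistic, d), fmt_p(a$individual$sp$p_value, d)),
      holm_sentence(c("Se1 = Se2", "Sp1 = Sp2"), a$holm$reject))
  } else if (!is.null(a$global) && !is.na(a$global$wald$statistic)) {
    out <- c(out,
      sprintf("Wald test statistic for the global hypothesis test H0: (Se1 = Se2 and Sp1 = Sp2) is %s. Global p-value is %s.",
              fmt_num(a$global$wald$statistic, d), fmt_p(a$global$wald$p_value, d)))
    if (!is.null(a$global$lrt))
      out <- c(out, sprintf("Likelihood-ratio test statistic for the global hypothesis test is %s (p-value %s).",
                            fmt_num(a$global$lrt$statistic, d), fmt_p(a$global$lrt$p_value, d)))
    if (a$global$wald$p_value <= z$alpha) {
      meth <- if (a$individual$method == "mcnemar_cc") "McNemar test statistic (with cc)" else "Wald test statistic"
      out <- c(out,
        "The global hypothesis of equal accuracies is rejected. Investigation of the causes of significance:",
        sprintf("%s for H0: Se1 = Se2 is %s and the two-sided p-value is %s.",
                meth, fmt_num(a$individual$se$statistic, d), fmt_p(a$individual$se$p_value, d)),
        sprintf("%s for H0: Sp1 = Sp2 is %s and the two-sided p-value is %s.",
                meth, fmt_num(a$individual$sp$statistic, d), fmt_p(a$individual$sp$p_value, d)),
        holm_sentence(c("Se1 = Se2", "Sp1 = Sp2"), a$holm$reject))
    } else {
      out <- c(out, "The equality of the accuracies of the two tests is not rejected.")
    }
  }
  for (ci in a$intervals) {
    par <- if (grepl("^Se", ci$label)) "sensitivity" else "specificity"
    small <- setdiff(c("Test 1", "Test 2"), ci$larger)
    out <- c(out,
      sprintf("The %s of %s is significantly greater than the %s of %s. %g%% confidence interval for the difference %s is %s.",
              par, ci$larger, par, small, 100 * lvl, ci$label,
              ci_txt(ci$lower, ci$upper, d)))
  }
  out <- c(out, a$notes, power_lines(z$power$accuracy, d, z$alpha))
  out
}

render_lrs <- function(z) {
  l <- z$likelihood_ratios; d <- z$decip; lvl <- 1 - z$alpha; est <- z$estimates
  out <- c("Comparison of the likelihood ratios",
           "-----------------------------------",
           est_line(est, "positive LR of Test 1", "PLR1", d, lvl, pct = FALSE),
           est_line(est, "positive LR of Test 2", "PLR2", d, lvl, pct = FALSE),
           est_line(est, "negative LR of Test 1", "NLR1", d, lvl, pct = FALSE),
           est_line(est, "negative LR of Test 2", "NLR2", d, lvl, pct = FALSE), "")
  if (!is.null(l$global)) {
    out <- c(out,
      sprintf("Test statistic for the global hypothesis test H0: (PLR1 = PLR2 and NLR1 = NLR2) is %s. Global p-value is %s.",
              fmt_num(l$global$wald$statistic, d), fmt_p(l$global$wald$p_value, d)))
    if (l$global$wald$p_value <= z$alpha) {
      out <- c(out,
        "The global hypothesis of equal likelihood ratios is rejected. Investigation of the causes of significance:",
        sprintf("Test statistic for H0: PLR1 = PLR2 is %s and the two-sided p-value is %s.",
                fmt_num(l$individual$plr$statistic, d), fmt_p(l$individual$plr$p_value, d)),
        sprintf("Test statistic for H0: NLR1 = NLR2 is %s and the two-sided p-value is %s.",
                fmt_num(l$individual$nlr$statistic, d), fmt_p(l$individual$nlr$p_value, d)),
        holm_sentence(c("PLR1 = PLR2", "NLR1 = NLR2"), l$holm$reject))
    } else {
      out <- c(out, "The equality of the likelihood ratios of the two tests is not rejected.")
    }
  }
  for (ci in l$intervals) {
    par <- if (grepl("^PLR", ci$label)) "positive likelihood ratio" else "negative likelihood ratio"
    small <- setdiff(c("Test 1", "Test 2"), ci$larger)
    out <- c(out,
      sprintf("The %s of %s is significantly greater than the %s of %s. %g%% confidence interval for the ratio %s is %s.",
              par, ci$larger, par, small, 100 * lvl, ci$label,
              ci_txt(ci$lower, ci$upper, d, pct = FALSE)))
  }
  out <- c(out, l$notes, power_lines(z$power$likelihood_ratios, d, z$alpha))
  out
}

render_pvs <- function(z) {
  d <- z$decip; lvl <- 1 - z$alpha
  if (z$design == "case_control")
    return(c("Comparison of the predictive values",
             "-----------------------------------",
             "Sampling is case-control: the diseased and non-diseased sample sizes were fixed by design, so neither the prevalence nor any predictive-value result is valid. These outputs are suppressed."))
  p <- z$predictive_values; est <- z$estimates
  out <- c("Comparison of the predictive values",
           "-----------------------------------",
           est_line(est, "positive PV of Test 1", "PPV1", d, lvl),
           est_line(est, "positive PV of Test 2", "PPV2", d, lvl),
           est_line(est, "negative PV of Test 1", "NPV1", d, lvl),
           est_line(est, "negative PV of Test 2", "NPV2", d, lvl), "")
  if (!is.null(p$global)) {
    out <- c(out,
      sprintf("Wald test statistic for the global hypothesis test H0: (PPV1 = PPV2 and NPV1 = NPV2) is %s. Global p-value is %s.",
              fmt_num(p$global$wald$statistic, d), fmt_p(p$global$wald$p_value, d)))
    if (p$global$wald$p_value <= z$alpha) {
      out <- c(out,
        "The global hypothesis of equal predictive values is rejected. Investigation of the causes of significance:",
        sprintf("Weighted generalized score statistic for H0: PPV1 = PPV2 is %s and the two-sided p-value is %s.",
                fmt_num(p$individual$ppv$statistic, d), fmt_p(p$individual$ppv$p_value, d)),
        sprintf("Weighted generalized score statistic for H0: NPV1 = NPV2 is %s and the two-sided p-value is %s.",
                fmt_num(p$individual$npv$statistic, d), fmt_p(p$individual$npv$p_value, d)),
        holm_sentence(c("PPV1 = PPV2", "NPV1 = NPV2"), p$holm$reject))
    } else {
      out <- c(out, "The equality of the predictive values of the two tests is not rejected.")
    }
  }
  for (ci in p$intervals) {
    par <- if (grepl("^PPV", ci$label)) "positive PV" else "negative PV"
    small <- setdiff(c("Test 1", "Test 2"), ci$larger)
    out <- c(out,
      sprintf("The %s of %s is significantly greater than the %s of %s. %g%% confidence interval for the difference %s is %s.",
              par, ci$larger, par, small, 100 * lvl, ci$label,
              ci_txt(ci$lower, ci$upper, d)))
  }
  out <- c(out, p$notes, power_lines(z$power$predictive_values, d, z$alpha))
  out
}

#' @export
print.compbdt <- function(x, ...) {
  blocks <- list(
    if (x$design == "paired") render_prevalence(x)
    else c("Prevalence of the disease", "-------------------------",
           "Sampling is case-control: the prevalence cannot be estimated from the data (the group sizes were fixed by design)."),
    render_accuracy(x), render_lrs(x), render_pvs(x))
  cat(paste(unlist(lapply(blocks, function(b) c(b, ""))), collapse = "\n"))
  invisible(x)
}

#' Write the three comparison report files
#'
#' Renders the accuracy, likelihood-ratio and predictive-value blocks of a
#' [compbdt()] result into `Results_Comparison_Accuracies.txt`,
#' `Results_Comparison_LRs.txt` and `Results_Comparison_PVs.txt` inside
#' `out_dir` (created if needed). The prevalence block is prepended to the
#' accuracies file. Output is deterministic given the seed used in
#' [compbdt()].
#'
#' @param report A `compbdt` object.
#' @param out_dir Output directory.
#' @return Invisibly, the three file paths.
#' @export
write_reports <- function(report, out_dir = ".") {
  if (!inherits(report, "compbdt")) stop("`report` must be a `compbdt` result")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("Results_Comparison_Accuracies.txt",
                                "Results_Comparison_LRs.txt",
                                "Results_Comparison_PVs.txt"))
  prev <- if (report$design == "paired") render_prevalence(report)
    else c("Prevalence of the disease", "-------------------------",
           "Sampling is case-control: the prevalence cannot be estimated from the data (the group sizes were fixed by design).")
  writeLines(c(prev, "", render_accuracy(report)), paths[1])
  writeLines(render_lrs(report), paths[2])
  writeLines(render_pvs(report), paths[3])
  invisible(paths)
}
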