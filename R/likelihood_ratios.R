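# Comparison of the likelihood ratios via the log-ratio contrast
# (ln(PLR1/PLR2), ln(NLR1/NLR2)) and its delta-method covariance.

#' Log-ratio contrast of the likelihood ratios and its covariance
#'
#' Computes `omega = (ln(PLR1/PLR2), ln(NLR1/NLR2))` and its estimated 2 x 2
#' covariance matrix by the delta method. Sensitivities and specificities are
#' conditional binomial proportions given the group totals, correlated within
#' a group through the joint cells (`Cov(Se1, Se2) = (s11/s - Se1 Se2)/s`,
#' `Cov(Sp1, Sp2) = (r00/r - Sp1 Sp2)/r`); the diseased and non-diseased
#' groups are independent.
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @return A list with `omega` (length-2 vector), `sigma` (2 x 2 matrix), and
#'   `z` (the two standardized statistics `omega / sqrt(diag(sigma))`).
#' @examples
#' lr_contrast(paired_counts(473, 29, 81, 25, 22, 46, 44, 151))$z
#' @export
lr_contrast <- function(x) {
  x <- as_paired_counts(x)
  if (!feas_flags(x)$lr_contrast)
    stop(errorCondition("likelihood ratios are not all positive and finite on this table",
                        class = c("compbdt_infeasible", "error", "condition")))
  q <- acc_quantities(x)
  omega <- c(plr = log((q$Se1 / (1 - q$Sp1)) / (q$Se2 / (1 - q$Sp2))),
             nlr = log(((1 - q$Se1) / q$Sp1) / ((1 - q$Se2) / q$Sp2)))
  # gradients of the two log-ratios w.r.t. (Se1, Se2, Sp1, Sp2)
  gP <- c(1 / q$Se1, -1 / q$Se2, 1 / (1 - q$Sp1), -1 / (1 - q$Sp2))
  gN <- c(-1 / (1 - q$Se1), 1 / (1 - q$Se2), -1 / q$Sp1, 1 / q$Sp2)
  S4 <- matrix(0, 4, 4)
  S4[1, 1] <- q$vSe1; S4[2, 2] <- q$vSe2; S4[1, 2] <- S4[2, 1] <- q$cSe
  S4[3, 3] <- q$vSp1; S4[4, 4] <- q$vSp2; S4[3, 4] <- S4[4, 3] <- q$cSp
  G <- rbind(gP, gN)
  sigma <- G %*% S4 %*% t(G)
  dimnames(sigma) <- list(c("plr", "nlr"), c("plr", "nlr"))
  # clamp round-off: identical tests give variances that are zero in exact
  # arithmetic but can come out at -1e-19
  list(omega = omega, sigma = sigma, z = omega / sqrt(pmax(diag(sigma), 0)))
}

#' Compare the likelihood ratios of the two tests
#'
#' Solves the global null `PLR1 = PLR2 and NLR1 = NLR2` with the Wald
#' quadratic form `omega' sigma^{-1} omega` (chi-square, 2 df). If
#' significant, the two individual log-ratio z tests are resolved with Holm
#' step-down, and for each rejected null an oriented (ratio > 1) confidence
#' interval is attached: on the log scale for the PLR ratio,
#' `ratio * exp(+/- z sqrt(Var))`, and of Wald type for the NLR ratio,
#' `ratio * (1 +/- z sqrt(Var))`, `Var` being the delta-method variance of
#' the log-ratio in both cases.
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @param alpha Significance level.
#' @return A list of class `bdt_comparison` with elements `family`,
#'   `contrast` (the [lr_contrast()] result), `global`, `individual`, `holm`,
#'   `intervals`, `notes`.
#' @examples
#' compare_lrs(paired_counts(473, 29, 81, 25, 22, 46, 44, 151))
#' @export
compare_lrs <- function(x, alpha = 0.05) {
  x <- as_paired_counts(x)
  check_alpha(alpha)
  out <- list(family = "likelihood_ratios", alpha = alpha, contrast = NULL,
              global = NULL, individual = NULL, holm = NULL,
              intervals = list(), notes = character())
  if (!feas_flags(x)$lr_contrast) {
    out$notes <- "Likelihood ratios cannot be compared: at least one estimated LR is zero or undefined."
    class(out) <- "bdt_comparison"
    return(out)
  }
  ct <- lr_contrast(x)
  out$contrast <- ct
  det_s <- ct$sigma[1, 1] * ct$sigma[2, 2] - ct$sigma[1, 2]^2
  if (!is.finite(det_s) || det_s <= 0) {
    out$notes <- "Covariance matrix of the log-ratio contrast is singular; global test skipped."
    class(out) <- "bdt_comparison"
    return(out)
  }
  stat <- drop(t(ct$omega) %*% solve(ct$sigma) %*% ct$omega)
  out$global <- list(wald = bdt_test(stat, "chi2_2", "Wald (global, log-ratio)"))
  if (out$global$wald$p_value <= alpha) {
    z_p <- bdt_test(ct$z[["plr"]], "std_normal", "log-ratio z (PLR)")
    z_n <- bdt_test(ct$z[["nlr"]], "std_normal", "log-ratio z (NLR)")
    out$individual <- list(method = "log_ratio_z", plr = z_p, nlr = z_n)
    out$holm <- holm_adjust(c(z_p$p_value, z_n$p_value), alpha)
    lrs <- estimate_likelihood_ratios(x)
    est <- stats::setNames(lrs$estimate, lrs$parameter)
    zq <- z_alpha(alpha)
    if (isTRUE(out$holm$reject[1])) {
      big <- if (est[["PLR1"]] >= est[["PLR2"]]) "PLR1 / PLR2" else "PLR2 / PLR1"
      ratio <- max(est[["PLR1"]] / est[["PLR2"]], est[["PLR2"]] / est[["PLR1"]])
      hw <- zq * sqrt(ct$sigma[1, 1])
      out$intervals$plr <- bdt_ci(ratio * exp(-hw), ratio * exp(hw), 1 - alpha,
                                  "ratio", larger = if (est[["PLR1"]] >= est[["PLR2"]]) "Test 1" else "Test 2",
                                  label = big)
    }
    if (isTRUE(out$holm$reject[2])) {
      big <- if (est[["NLR1"]] >= est[["NLR2"]]) "NLR1 / NLR2" else "NLR2 / NLR1"
      ratio <- max(est[["NLR1"]] / est[["NLR2"]], est[["NLR2"]] / est[["NLR1"]])
      rel <- zq * sqrt(ct$sigma[2, 2])
      out$intervals$nlr <- bdt_ci(ratio * (1 - rel), ratio * (1 + rel), 1 - alpha,
                                  "ratio", larger = if (est[["NLR1"]] >= est[["NLR2"]]) "Test 1" else "Test 2",
                                  label = big)
    }
  }
  class(out) <- "bdt_comparison"
  out
}
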