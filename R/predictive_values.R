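# Comparison of the predictive values: the weighted generalized score (WGS)
# statistics of Kosinski for the individual nulls, and the global Wald test on
# the 4-vector of predictive values with a delta-method covariance under the
# full 8-cell multinomial (predictive values mix diseased and non-diseased
# cells, so the prevalence is treated as random).

# pooled predictive values and their C components (paired-overlap corrections)
kosinski_components <- function(x) {
  cl <- as.list(x$cells); m <- x$margins
  dP <- 2 * m$n11 + m$n10 + m$n01
  dN <- 2 * m$n00 + m$n01 + m$n10
  PPVp <- (2 * cl$s11 + cl$s10 + cl$s01) / dP
  NPVp <- (2 * cl$r00 + cl$r01 + cl$r10) / dN
  list(PPVp = PPVp, NPVp = NPVp,
       C_ppv = (cl$s11 * (1 - PPVp)^2 + cl$r11 * PPVp^2) / dP,
       C_npv = (cl$s00 * NPVp^2 + cl$r00 * (1 - NPVp)^2) / dN)
}

# variance term of the WGS statistic (also the squared half-width scale of the
# inverted difference interval)
wgs_var_term <- function(x, which = c("PPV", "NPV")) {
  which <- match.arg(which)
  k <- kosinski_components(x); m <- x$margins
  if (which == "PPV") {
    if (m$n1. <= 0 || m$n.1 <= 0) return(NA_real_)
    (k$PPVp * (1 - k$PPVp) - 2 * k$C_ppv) * (1 / m$n1. + 1 / m$n.1)
  } else {
    if (m$n0. <= 0 || m$n.0 <= 0) return(NA_real_)
    (k$NPVp * (1 - k$NPVp) - 2 * k$C_npv) * (1 / m$n0. + 1 / m$n.0)
  }
}

#' Weighted generalized score statistic for one pair of predictive values
#'
#' Kosinski's score-type statistic for `H0: PPV1 = PPV2` (or
#' `H0: NPV1 = NPV2`) under a paired design:
#' `T = (PV1 - PV2)^2 / [{PVp (1 - PVp) - 2 Cp} (1/d1 + 1/d2)]`, where `PVp`
#' is the pooled predictive value, `Cp` its paired-overlap correction, and
#' `d1`, `d2` the numbers of subjects with the relevant result on each test;
#' referred to a chi-square with 1 df.
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @param which `"PPV"` or `"NPV"`.
#' @return A `bdt_test` object with the pooled components attached as
#'   attribute `"components"`.
#' @examples
#' kosinski_wgs(paired_counts(473, 29, 81, 25, 22, 46, 44, 151), "NPV")
#' @export
kosinski_wgs <- function(x, which = c("PPV", "NPV")) {
  x <- as_paired_counts(x)
  which <- match.arg(which)
  pv <- pv_quantities(x)
  d <- if (which == "PPV") pv$PPV1$est - pv$PPV2$est else pv$NPV1$est - pv$NPV2$est
  vt <- wgs_var_term(x, which)
  # identical estimates take the null value 0 even when the variance term
  # degenerates (tests agreeing on every subject give an exact 0/0)
  stat <- if (isTRUE(d == 0)) 0
  else if (is.na(d) || is.na(vt) || vt <= 0) NA_real_
  else d^2 / vt
  out <- bdt_test(stat, "chi2_1", sprintf("WGS (%s)", which))
  attr(out, "components") <- kosinski_components(x)
  out
}

# delta-method covariance of (PPV1, PPV2, NPV1, NPV2) under one multinomial
# of size n over the eight cells
pv_eta_sigma <- function(cells, n) {
  p <- cells / n
  sets <- list(PPV1 = list(a = c(1, 2), b = c(5, 6)),
               PPV2 = list(a = c(1, 3), b = c(5, 7)),
               NPV1 = list(a = c(7, 8), b = c(3, 4)),
               NPV2 = list(a = c(6, 8), b = c(2, 4)))
  J <- matrix(0, 4, 8)
  eta <- numeric(4)
  for (i in seq_along(sets)) {
    a <- sum(p[sets[[i]]$a]); b <- sum(p[sets[[i]]$b])
    if (a + b <= 0) return(NULL)
    eta[i] <- a / (a + b)
    J[i, sets[[i]]$a] <- b / (a + b)^2
    J[i, sets[[i]]$b] <- -a / (a + b)^2
  }
  names(eta) <- names(sets)
  cov_p <- (diag(p) - tcrossprod(p)) / n
  sigma <- J %*% cov_p %*% t(J)
  dimnames(sigma) <- list(names(sets), names(sets))
  list(eta = eta, sigma = sigma)
}

#' Global Wald test for simultaneous equality of the predictive values
#'
#' Tests `H0: (PPV1 = PPV2 and NPV1 = NPV2)` with the quadratic form
#' `eta' phi' (phi Sigma phi')^{-1} phi eta`, where
#' `eta = (PPV1, PPV2, NPV1, NPV2)`, `phi = ((1,-1,0,0), (0,0,1,-1))` and
#' `Sigma` is the delta-method covariance of `eta` under the 8-cell
#' multinomial; chi-square with 2 df under the null.
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @return A `bdt_test` object with attribute `"contrast"` carrying `eta`,
#'   `sigma` and `phi`.
#' @examples
#' pv_global_test(paired_counts(473, 29, 81, 25, 22, 46, 44, 151))
#' @export
pv_global_test <- function(x) {
  x <- as_paired_counts(x)
  es <- pv_eta_sigma(x$cells, x$n)
  if (is.null(es))
    stop(errorCondition("not all four predictive values are estimable",
                        class = c("compbdt_infeasible", "error", "condition")))
  phi <- rbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  V <- phi %*% es$sigma %*% t(phi)
  d <- drop(phi %*% es$eta)
  if (all(d == 0)) {
    stat <- 0  # identical estimates: null value, even if V is singular
  } else {
    if (!is.finite(det(V)) || det(V) <= 0)
      stop(errorCondition("contrast covariance of the predictive values is singular",
                          class = c("compbdt_infeasible", "error", "condition")))
    stat <- drop(t(d) %*% solve(V) %*% d)
  }
  out <- bdt_test(stat, "chi2_2", "Wald (global, predictive values)")
  attr(out, "contrast") <- list(eta = es$eta, sigma = es$sigma, phi = phi)
  out
}

#' Confidence interval for a predictive-value difference by statistic inversion
#'
#' Inverts the weighted generalized score statistic:
#' `PV1 - PV2 +/- z * sqrt(variance term)`, the variance term being the
#' denominator of [kosinski_wgs()].
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @param which `"PPV"` or `"NPV"`.
#' @param alpha Significance level.
#' @param oriented If `TRUE` (default), the difference is oriented larger
#'   minus smaller so the interval is reported positive, with the larger test
#'   recorded in the result; if `FALSE` the signed difference Test 1 minus
#'   Test 2 is used.
#' @return A `bdt_ci` object on the difference scale.
#' @examples
#' pv_diff_interval(paired_counts(473, 29, 81, 25, 22, 46, 44, 151), "NPV")
#' @export
pv_diff_interval <- function(x, which = c("PPV", "NPV"), alpha = 0.05,
                             oriented = TRUE) {
  x <- as_paired_counts(x)
  which <- match.arg(which)
  check_alpha(alpha)
  pv <- pv_quantities(x)
  d <- if (which == "PPV") pv$PPV1$est - pv$PPV2$est else pv$NPV1$est - pv$NPV2$est
  vt <- wgs_var_term(x, which)
  if (is.na(d) || is.na(vt) || vt < 0)
    stop(errorCondition("predictive-value difference interval is not computable on this table",
                        class = c("compbdt_infeasible", "error", "condition")))
  larger <- NULL; label <- sprintf("%s1 - %s2", which, which)
  if (oriented) {
    larger <- if (d >= 0) "Test 1" else "Test 2"
    label <- if (d >= 0) sprintf("%s1 - %s2", which, which) else sprintf("%s2 - %s1", which, which)
    d <- abs(d)
  }
  hw <- z_alpha(alpha) * sqrt(vt)
  bdt_ci(d - hw, d + hw, 1 - alpha, "difference", larger = larger, label = label)
}

#' Compare the predictive values of the two tests
#'
#' Solves the global null `PPV1 = PPV2 and NPV1 = NPV2` with
#' [pv_global_test()]; if significant, the two individual weighted
#' generalized score tests are resolved with Holm step-down and, for each
#' rejected null, the oriented [pv_diff_interval()] is attached.
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @param alpha Significance level.
#' @return A list of class `bdt_comparison` with elements `family`, `global`,
#'   `individual`, `holm`, `intervals`, `notes`.
#' @examples
#' compare_pvs(paired_counts(473, 29, 81, 25, 22, 46, 44, 151))
#' @export
compare_pvs <- function(x, alpha = 0.05) {
  x <- as_paired_counts(x)
  check_alpha(alpha)
  out <- list(family = "predictive_values", alpha = alpha, global = NULL,
              individual = NULL, holm = NULL, intervals = list(),
              notes = character())
  glob <- tryCatch(pv_global_test(x), compbdt_infeasible = function(e) e)
  if (inherits(glob, "error")) {
    out$notes <- paste0("Predictive values cannot be compared: ", conditionMessage(glob))
    class(out) <- "bdt_comparison"
    return(out)
  }
  out$global <- list(wald = glob)
  if (glob$p_value <= alpha) {
    t_p <- kosinski_wgs(x, "PPV")
    t_n <- kosinski_wgs(x, "NPV")
    out$individual <- list(method = "wgs", ppv = t_p, npv = t_n)
    out$holm <- holm_partial(c(t_p$p_value, t_n$p_value), alpha)
    if (isTRUE(out$holm$reject[1]))
      out$intervals$ppv <- pv_diff_interval(x, "PPV", alpha)
    if (isTRUE(out$holm$reject[2]))
      out$intervals$npv <- pv_diff_interval(x, "NPV", alpha)
  }
  class(out) <- "bdt_comparison"
  out
}
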