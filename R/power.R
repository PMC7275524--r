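# Monte Carlo estimation of power / probability of a type II error by
# multinomial resampling of the observed table. Replicates on which the
# relevant statistic is not computable are discarded and regenerated, so the
# requested number of analysable replicates is always reached.

#' Draw one paired table from a multinomial model
#'
#' One multinomial draw of size `n` over the eight cell probabilities,
#' arranged as a [paired_counts] object. Used by the power machinery, which
#' resamples the observed relative frequencies.
#'
#' @param probs Eight non-negative cell probabilities summing to 1, in the
#'   order `s11, s10, s01, s00, r11, r10, r01, r00`.
#' @param n Sample size of the draw.
#' @return A [paired_counts] object (or an error if a group comes out empty;
#'   see [estimate_power()] for the regenerating loop).
#' @export
sample_paired_table <- function(probs, n) {
  if (length(probs) != 8L || any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("`probs` must be eight non-negative probabilities summing to 1")
  as_paired_counts(drop(stats::rmultinom(1, n, probs)))
}

# --- vectorized replicate tests -------------------------------------------
# Each takes an 8 x B matrix of counts (rows in cell order) and returns a
# logical rejection vector with NA where the statistic is not computable.

reject_accuracy_global <- function(M, alpha) {
  s10 <- M[2, ]; s01 <- M[3, ]; r10 <- M[6, ]; r01 <- M[7, ]
  s <- colSums(M[1:4, , drop = FALSE]); r <- colSums(M[5:8, , drop = FALSE])
  den_se <- 4 * s10 * s01 + (M[1, ] + M[4, ]) * (s10 + s01)
  den_sp <- 4 * r10 * r01 + (M[5, ] + M[8, ]) * (r10 + r01)
  ok <- s > 0 & r > 0 & den_se > 0 & den_sp > 0
  stat <- s * (s10 - s01)^2 / den_se + r * (r10 - r01)^2 / den_sp
  out <- stats::pchisq(stat, df = 2, lower.tail = FALSE) <= alpha
  out[!ok] <- NA
  out
}

# rule (a) branch: individual Wald pair resolved with Holm; reject if any
# null is rejected (for m = 2 that is min(p) <= alpha / 2)
reject_accuracy_holm_wald <- function(M, alpha) {
  s10 <- M[2, ]; s01 <- M[3, ]; r10 <- M[6, ]; r01 <- M[7, ]
  s <- colSums(M[1:4, , drop = FALSE]); r <- colSums(M[5:8, , drop = FALSE])
  den_se <- 4 * s10 * s01 + (M[1, ] + M[4, ]) * (s10 + s01)
  den_sp <- 4 * r10 * r01 + (M[5, ] + M[8, ]) * (r10 + r01)
  ok <- s > 0 & r > 0 & den_se > 0 & den_sp > 0
  p_se <- stats::pchisq(s * (s10 - s01)^2 / den_se, df = 1, lower.tail = FALSE)
  p_sp <- stats::pchisq(r * (r10 - r01)^2 / den_sp, df = 1, lower.tail = FALSE)
  out <- pmin(p_se, p_sp) <= alpha / 2
  out[!ok] <- NA
  out
}

reject_lr_global <- function(M, alpha) {
  s <- colSums(M[1:4, , drop = FALSE]); r <- colSums(M[5:8, , drop = FALSE])
  s1 <- M[1, ] + M[2, ]; sc1 <- M[1, ] + M[3, ]
  r0 <- M[7, ] + M[8, ]; rc0 <- M[6, ] + M[8, ]
  ok <- s > 0 & r > 0 & s1 > 0 & s1 < s & sc1 > 0 & sc1 < s &
    r0 > 0 & r0 < r & rc0 > 0 & rc0 < r
  Se1 <- s1 / s; Se2 <- sc1 / s; Sp1 <- r0 / r; Sp2 <- rc0 / r
  vSe1 <- Se1 * (1 - Se1) / s; vSe2 <- Se2 * (1 - Se2) / s
  vSp1 <- Sp1 * (1 - Sp1) / r; vSp2 <- Sp2 * (1 - Sp2) / r
  cSe <- (M[1, ] / s - Se1 * Se2) / s
  cSp <- (M[8, ] / r - Sp1 * Sp2) / r
  vP <- vSe1 / Se1^2 + vSe2 / Se2^2 - 2 * cSe / (Se1 * Se2) +
    vSp1 / (1 - Sp1)^2 + vSp2 / (1 - Sp2)^2 - 2 * cSp / ((1 - Sp1) * (1 - Sp2))
  vN <- vSe1 / (1 - Se1)^2 + vSe2 / (1 - Se2)^2 - 2 * cSe / ((1 - Se1) * (1 - Se2)) +
    vSp1 / Sp1^2 + vSp2 / Sp2^2 - 2 * cSp / (Sp1 * Sp2)
  cPN <- -vSe1 / (Se1 * (1 - Se1)) + cSe * (1 / (Se1 * (1 - Se2)) + 1 / (Se2 * (1 - Se1))) -
    vSe2 / (Se2 * (1 - Se2)) -
    vSp1 / (Sp1 * (1 - Sp1)) + cSp * (1 / ((1 - Sp1) * Sp2) + 1 / ((1 - Sp2) * Sp1)) -
    vSp2 / (Sp2 * (1 - Sp2))
  om1 <- log(Se1 / (1 - Sp1)) - log(Se2 / (1 - Sp2))
  om2 <- log((1 - Se1) / Sp1) - log((1 - Se2) / Sp2)
  det_s <- vP * vN - cPN^2
  ok <- ok & is.finite(det_s) & det_s > 0
  stat <- (om1^2 * vN - 2 * om1 * om2 * cPN + om2^2 * vP) / det_s
  out <- stats::pchisq(stat, df = 2, lower.tail = FALSE) <= alpha
  out[!ok] <- NA
  out
}

reject_pv_global <- function(M, alpha) {
  phi <- rbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  n <- colSums(M)
  apply_one <- function(j) {
    es <- pv_eta_sigma(M[, j], n[j])
    if (is.null(es)) return(NA)
    V <- phi %*% es$sigma %*% t(phi)
    dv <- V[1, 1] * V[2, 2] - V[1, 2]^2
    if (!is.finite(dv) || dv <= 0) return(NA)
    d <- phi %*% es$eta
    stat <- (d[1]^2 * V[2, 2] - 2 * d[1] * d[2] * V[1, 2] + d[2]^2 * V[1, 1]) / dv
    stats::pchisq(stat, df = 2, lower.tail = FALSE) <= alpha
  }
  vapply(seq_len(ncol(M)), apply_one, NA)
}

replicate_test <- function(family, branch) {
  switch(family,
    accuracy = if (identical(branch, "a")) reject_accuracy_holm_wald else reject_accuracy_global,
    likelihood_ratios = reject_lr_global,
    predictive_values = reject_pv_global,
    stop("unknown family"))
}

#' Monte Carlo rejection rate of a family's test under a multinomial model
#'
#' Draws multinomial paired tables of size `n` with cell probabilities
#' `probs`, applies the requested family's test at level `alpha` to each, and
#' returns the fraction rejected. Replicates on which the test cannot be
#' computed are discarded and redrawn until `reps` analysable replicates are
#' obtained. This is the engine behind [estimate_power()]; with `probs` taken
#' from a null configuration it measures the empirical type I error.
#'
#' @param probs Eight cell probabilities (order `s11, ..., r00`) summing to 1.
#' @param n Sample size of each replicate.
#' @param family `"accuracy"`, `"likelihood_ratios"` or
#'   `"predictive_values"`.
#' @param alpha Significance level applied within each replicate.
#' @param reps Number of analysable replicates.
#' @param branch For the accuracy family, `"b"` (default; global Wald test)
#'   or `"a"` (Holm-resolved pair of individual Wald tests, reject when any
#'   null is rejected).
#' @param max_attempts Cap on total draws (guards pathological tables).
#' @return A list with `rejection_rate`, `reps_used` and `resampled` (number
#'   of discarded replicates).
#' @export
mc_rejection_rate <- function(probs, n, family = c("accuracy", "likelihood_ratios",
                                                   "predictive_values"),
                              alpha = 0.05, reps = 10000, branch = "b",
                              max_attempts = 100 * reps) {
  family <- match.arg(family)
  check_alpha(alpha)
  if (reps < 1) stop("`reps` must be >= 1")
  rfun <- replicate_test(family, branch)
  got <- 0L; rejected <- 0L; attempts <- 0L; discarded <- 0L
  while (got < reps) {
    batch <- max(1000L, as.integer(ceiling((reps - got) * 1.1)))
    if (attempts + batch > max_attempts) batch <- max_attempts - attempts
    if (batch <= 0L)
      stop(sprintf("exceeded %d draws without reaching %d analysable replicates", max_attempts, reps))
    M <- stats::rmultinom(batch, n, probs)
    rj <- rfun(M, alpha)
    ok <- which(!is.na(rj))
    take <- ok[seq_len(min(length(ok), reps - got))]
    rejected <- rejected + sum(rj[take])
    got <- got + length(take)
    attempts <- attempts + batch
    discarded <- discarded + (batch - length(ok))  # degenerate draws, regenerated
  }
  list(rejection_rate = rejected / reps, reps_used = reps, resampled = discarded)
}

#' Retrospective power or probability of a type II error
#'
#' Estimates, by Monte Carlo, the operating characteristic of the global test
#' actually applied to the observed table: `reps` multinomial samples of the
#' observed size are drawn with the observed relative frequencies as cell
#' probabilities, the family's test is applied to each at level `alpha`, and
#' the rejection fraction is returned as the power (when the observed test
#' was significant) or one minus it as the probability of a type II error
#' (when it was not). Samples on which the test cannot be applied are
#' replaced by fresh draws. The replicate test reuses the decision-rule
#' branch selected by the observed table.
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @param family `"accuracy"`, `"likelihood_ratios"` or
#'   `"predictive_values"`.
#' @param alpha Significance level.
#' @param reps Number of analysable Monte Carlo replicates.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of class `bdt_power` with `mode` (`"power"` or
#'   `"type_II_error"`), `value`, `mc_se` (binomial Monte Carlo standard
#'   error), `reps_used`, `resampled`, `family`, `alpha`.
#' @examples
#' x <- paired_counts(473, 29, 81, 25, 22, 46, 44, 151)
#' estimate_power(x, "accuracy", reps = 500, seed = 1)
#' @export
estimate_power <- function(x, family = c("accuracy", "likelihood_ratios",
                                         "predictive_values"),
                           alpha = 0.05, reps = 10000, seed = NULL) {
  x <- as_paired_counts(x)
  family <- match.arg(family)
  check_alpha(alpha)
  if (!is.null(seed)) set.seed(seed)
  q <- acc_quantities(x); pv <- pv_quantities(x)
  differ <- switch(family,
    accuracy = q$Se1 != q$Se2 || q$Sp1 != q$Sp2,
    likelihood_ratios = {
      lr <- estimate_likelihood_ratios(x)
      any(lr$estimate[c(1, 3)] != lr$estimate[c(2, 4)], na.rm = TRUE)
    },
    predictive_values = !isTRUE(all.equal(pv$PPV1$est, pv$PPV2$est)) ||
      !isTRUE(all.equal(pv$NPV1$est, pv$NPV2$est)))
  if (!differ)
    stop(errorCondition(
      sprintf("the observed %s estimates of the two tests are identical; the alternative used to define the type II error is empty", family),
      class = c("compbdt_nonidentifiable_power", "error", "condition")))
  # observed outcome fixes both the replicate branch and the reported mode
  obs <- switch(family,
    accuracy = compare_accuracies(x, alpha),
    likelihood_ratios = compare_lrs(x, alpha),
    predictive_values = compare_pvs(x, alpha))
  branch <- if (family == "accuracy") obs$rule else "global"
  significant <- if (family == "accuracy" && obs$rule == "a")
    any(obs$holm$reject, na.rm = TRUE)
  else if (!is.null(obs$global))
    obs$global$wald$p_value <= alpha
  else
    stop(errorCondition("the global test could not be applied to the observed table",
                        class = c("compbdt_infeasible", "error", "condition")))
  mc <- mc_rejection_rate(x$cells / x$n, x$n, family, alpha, reps, branch)
  value <- if (significant) mc$rejection_rate else 1 - mc$rejection_rate
  structure(list(mode = if (significant) "power" else "type_II_error",
                 value = value,
                 mc_se = sqrt(value * (1 - value) / mc$reps_used),
                 reps_used = mc$reps_used, resampled = mc$resampled,
                 family = family, alpha = alpha),
            class = "bdt_power")
}

#' @export
print.bdt_power <- function(x, ...) {
  cat(sprintf("Estimated %s for the %s comparison: %.4f (MC se %.4f, %d replicates, %d regenerated)\n",
              if (x$mode == "power") "power" else "probability of a type II error",
              gsub("_", " ", x$family), x$value, x$mc_se, x$reps_used, x$resampled))
  invisible(x)
}
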