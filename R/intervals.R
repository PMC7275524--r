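#' Modified-Wilson confidence interval for a binomial proportion
#'
#' The interval of Yu and co-workers, a modification of the Wilson score
#' interval with better small-sample coverage, used here for every proportion
#' parameter (prevalence, sensitivity, specificity, predictive values). The
#' centre is shrunk towards 1/2 by the factor `(m + z^4/53) / (m + z^2)` and
#' the half-width is `z / (m + z^2) * sqrt(m p (1 - p) + z^2 / 4)`, with `z`
#' the `1 - alpha/2` standard-normal quantile.
#'
#' @param k Number of successes (0 <= k <= m).
#' @param m Number of trials (>= 1).
#' @param alpha Significance level; the interval has confidence `1 - alpha`.
#' @return A `bdt_ci` object with elements `lower` and `upper`, clipped to
#'   `[0, 1]`.
#' @examples
#' yu_interval(608, 871)  # (0.66681, 0.72768)
#' @export
yu_interval <- function(k, m, alpha = 0.05) {
  check_alpha(alpha)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1)
    stop("`m` must be a positive number of trials")
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0 || k > m)
    stop("`k` must lie in [0, m]")
  z <- z_alpha(alpha)
  p <- k / m
  centre <- 0.5 + (m + z^4 / 53) / (m + z^2) * (p - 0.5)
  half <- z / (m + z^2) * sqrt(m * p * (1 - p) + z^2 / 4)
  bdt_ci(centre - half, centre + half, 1 - alpha, "proportion")
}

#' Adjusted Wald interval for a paired difference of proportions
#'
#' Wald interval with the Laplace-type adjustment recommended by Fagerland and
#' co-workers for the difference of two paired binomial proportions (here the
#' two sensitivities, based on the discordant diseased cells, or the two
#' specificities, based on the discordant non-diseased cells). For a group of
#' size `t` with discordant counts `a` (first parameter larger) and `b`, the
#' interval is
#' `(a - b)/(t + 2) +/- z * sqrt((a + b + 2)/(t + 2)^2 - (a - b)^2/(t + 2)^3)`,
#' clipped to `[-1, 1]`.
#'
#' @param a,b Discordant cell counts; the estimated difference is oriented as
#'   the proportion fed through `a` minus the one fed through `b`.
#' @param group_total Group size `t` (with `t >= a + b`).
#' @param alpha Significance level.
#' @return A `bdt_ci` object on the difference scale.
#' @examples
#' # difference Se2 - Se1 on a table with s10 = 29, s01 = 81, s = 608:
#' bonett_laplace_diff_interval(81, 29, 608)
#' @export
bonett_laplace_diff_interval <- function(a, b, group_total, alpha = 0.05) {
  check_alpha(alpha)
  if (group_total < a + b) stop("`group_total` must be at least a + b")
  z <- z_alpha(alpha)
  t2 <- group_total + 2
  centre <- (a - b) / t2
  half <- z * sqrt((a + b + 2) / t2^2 - (a - b)^2 / t2^3)
  bdt_ci(centre - half, centre + half, 1 - alpha, "difference")
}

# Approximate-score interval for the ratio of two independent binomial
# proportions (a/m1) / (b/m2), computed on 0.5-adjusted frequencies
# (Martin-Andres & Alvarez-Hernandez). Boundary replacement: when a limit of
# the quadratic-form interval falls outside the admissible range or on the
# wrong side of the point estimate, it is replaced by the closed-form
# single-proportion bound.
score_ratio_raw <- function(a, m1, b, m2, alpha = 0.05) {
  z <- z_alpha(alpha)
  at <- a + 0.5; bt <- b + 0.5
  m1t <- m1 + 1; m2t <- m2 + 1; nt <- m1 + m2 + 2
  p1 <- at / m1t; p2 <- bt / m2t
  est <- (a / m1) / (b / m2)  # unadjusted point estimate guides the replacement rule
  mid <- nt * at * bt + z^2 / 2 * (m1t * at + m2t * bt - 2 * at * bt)
  radq <- nt^2 * at * bt * (at + bt - nt * p1 * p2) +
    z^2 / 4 * (m1t * at - m2t * bt)^2
  rad <- if (radq >= 0) z * sqrt(radq) else NaN  # no real roots: use the closed-form bounds
  den <- bt * (nt * m1t * p2 - z^2 * (m1t - bt))
  lower <- (mid - rad) / den
  upper <- (mid + rad) / den
  if (!is.finite(lower) || lower < at / (nt - bt) || lower > est) {
    disc <- z^2 / 4 + at * (p2 - p1)
    lower <- if (disc >= 0)
      (at * p2 + z^2 / 2 - z * sqrt(disc)) / (m1t * p2^2 + z^2)
    else 0
  }
  if (!is.finite(upper) || upper > (nt - at) / bt || upper < est) {
    disc <- z^2 / 4 + bt * (p1 - p2)
    upper <- if (disc >= 0)
      (bt * p1 + z^2 / 2 + z * sqrt(disc)) / (m2t * p2^2)
    else Inf
  }
  c(lower = lower, upper = upper)
}

#' Approximate-score confidence interval for a likelihood ratio
#'
#' A likelihood ratio is the ratio of two independent binomial proportions
#' (one per disease group), i.e. a relative risk. The interval implemented is
#' the approximation to the score method computed after adding 0.5 to the
#' observed margins, the interval with the best coverage among those compared
#' by Martin-Andres and Alvarez-Hernandez, including their closed-form
#' boundary-limit replacements.
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @param which One of `"PLR1"`, `"PLR2"`, `"NLR1"`, `"NLR2"`.
#' @param alpha Significance level.
#' @return A `bdt_ci` object on the ratio scale.
#' @examples
#' x <- paired_counts(473, 29, 81, 25, 22, 46, 44, 151)
#' score_ratio_interval(x, "PLR1")  # (2.610, 3.952)
#' score_ratio_interval(x, "NLR2")  # (0.090, 0.153)
#' @export
score_ratio_interval <- function(x, which = c("PLR1", "PLR2", "NLR1", "NLR2"),
                                 alpha = 0.05) {
  x <- as_paired_counts(x)
  which <- match.arg(which)
  check_alpha(alpha)
  m <- x$margins
  args <- switch(which,
    PLR1 = list(a = m$s1., b = m$r1.),
    PLR2 = list(a = m$s.1, b = m$r.1),
    NLR1 = list(a = m$s0., b = m$r0.),
    NLR2 = list(a = m$s.0, b = m$r.0))
  lim <- score_ratio_raw(args$a, x$s, args$b, x$r, alpha)
  bdt_ci(lim[["lower"]], lim[["upper"]], 1 - alpha, "ratio", label = which)
}
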