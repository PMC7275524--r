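#' Holm step-down adjustment for a pair of hypotheses
#'
#' Step-down procedure controlling the family-wise error rate for the two
#' individual hypotheses of a family (less conservative than Bonferroni): the
#' smaller p-value is compared against `alpha/2` and, only if rejected, the
#' larger against `alpha`.
#'
#' @param p Numeric vector of two p-values in `[0, 1]`.
#' @param alpha Family-wise significance level.
#' @return A list with `p_adjusted` (via [stats::p.adjust] with
#'   `method = "holm"`) and `reject` (logical vector, same order as `p`).
#' @examples
#' holm_adjust(c(0.01, 0.04))  # both rejected
#' holm_adjust(c(0.03, 0.04))  # neither rejected: 0.03 > 0.05/2
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  check_alpha(alpha)
  if (length(p) != 2L || any(is.na(p)) || any(p < 0 | p > 1))
    stop("`p` must be two p-values in [0, 1]")
  adj <- stats::p.adjust(p, method = "holm")
  list(p_adjusted = adj, reject = adj <= alpha)
}

# Holm over a possibly incomplete pair: entries of `p` may be NA (infeasible
# statistic); the step-down runs over the feasible subset only.
holm_partial <- function(p, alpha) {
  ok <- !is.na(p)
  reject <- rep(NA, length(p)); adj <- rep(NA_real_, length(p))
  if (sum(ok) == 2L) {
    h <- holm_adjust(p, alpha); reject <- h$reject; adj <- h$p_adjusted
  } else if (sum(ok) == 1L) {
    adj[ok] <- p[ok]; reject[ok] <- p[ok] <= alpha
  }
  list(p_adjusted = adj, reject = reject)
}
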