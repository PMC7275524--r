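# shared internal helpers

z_alpha <- function(alpha) stats::qnorm(1 - alpha / 2)

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single number strictly between 0 and 1")
  alpha
}

# confidence interval container
bdt_ci <- function(lower, upper, level, scale = c("proportion", "ratio", "difference"),
                   larger = NULL, label = NULL) {
  scale <- match.arg(scale)
  if (scale == "proportion") { lower <- max(0, lower); upper <- min(1, upper) }
  if (scale == "difference") { lower <- max(-1, lower); upper <- min(1, upper) }
  if (scale == "ratio") lower <- max(0, lower)
  structure(list(lower = lower, upper = upper, level = level, scale = scale,
                 larger = larger, label = label),
            class = "bdt_ci")
}

#' @export
print.bdt_ci <- function(x, ...) {
  cat(sprintf("%g%% confidence interval%s: (%.5g; %.5g)\n", 100 * x$level,
              if (!is.null(x$label)) paste0(" for ", x$label) else "",
              x$lower, x$upper))
  invisible(x)
}

# hypothesis-test container
bdt_test <- function(statistic, distribution = c("chi2_1", "chi2_2", "std_normal"),
                     method, p_value = NULL) {
  distribution <- match.arg(distribution)
  if (is.null(p_value))
    p_value <- switch(distribution,
      chi2_1 = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
      chi2_2 = stats::pchisq(statistic, df = 2, lower.tail = FALSE),
      std_normal = 2 * stats::pnorm(-abs(statistic)))
  structure(list(statistic = statistic, distribution = distribution,
                 p_value = p_value, method = method),
            class = "bdt_test")
}

#' @export
print.bdt_test <- function(x, ...) {
  cat(sprintf("%s statistic = %.5g (%s), two-sided p-value = %.4g\n",
              x$method, x$statistic,
              switch(x$distribution, chi2_1 = "chi-square, 1 df",
                     chi2_2 = "chi-square, 2 df", std_normal = "standard normal"),
              x$p_value))
  invisible(x)
}

fmt_num <- function(x, decip) formatC(x, format = "f", digits = decip)
fmt_pct <- function(x, decip) paste0(formatC(100 * x, format = "f", digits = decip), "%")

# p-values below half the display resolution are shown as "< 0.001"-style
fmt_p <- function(p, decip) {
  thr <- 10^(-decip) / 2
  if (is.na(p)) "NA" else if (p < thr) paste0("< ", formatC(10^(-decip), format = "f", digits = decip))
  else formatC(p, format = "f", digits = decip)
}
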