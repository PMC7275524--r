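# Point estimation of prevalence, Se, Sp, PPV, NPV, PLR, NLR with standard
# errors, plus the conditional-binomial variances and paired covariances used
# by the comparison statistics.

# core accuracy quantities; everything downstream is built from these.
# Se and Sp are conditional binomial proportions given the group totals s and
# r; the two tests are correlated within a group through the joint cells, so
# Cov(Se1, Se2) = (s11/s - Se1 Se2)/s and Cov(Sp1, Sp2) = (r00/r - Sp1 Sp2)/r.
# Diseased and non-diseased groups are independent.
acc_quantities <- function(x) {
  cl <- as.list(x$cells); m <- x$margins
  s <- x$s; r <- x$r
  Se1 <- m$s1. / s; Se2 <- m$s.1 / s
  Sp1 <- m$r0. / r; Sp2 <- m$r.0 / r
  list(
    prev = s / x$n,
    Se1 = Se1, Se2 = Se2, Sp1 = Sp1, Sp2 = Sp2,
    vSe1 = Se1 * (1 - Se1) / s, vSe2 = Se2 * (1 - Se2) / s,
    vSp1 = Sp1 * (1 - Sp1) / r, vSp2 = Sp2 * (1 - Sp2) / r,
    cSe = (cl$s11 / s - Se1 * Se2) / s,
    cSp = (cl$r00 / r - Sp1 * Sp2) / r
  )
}

# predictive values as pooled-column proportions a/(a + b); the standard error
# is the binomial form sqrt(a b / (a + b)^3)
pv_quantities <- function(x) {
  m <- x$margins; cl <- as.list(x$cells)
  one <- function(a, b) {
    if (a + b <= 0) return(list(est = NA_real_, se = NA_real_))
    list(est = a / (a + b), se = sqrt(a * b / (a + b)^3))
  }
  list(PPV1 = one(m$s1., m$r1.), PPV2 = one(m$s.1, m$r.1),
       NPV1 = one(m$r0., m$s0.), NPV2 = one(m$r.0, m$s.0))
}

#' Estimated likelihood ratios of the two tests with delta-method standard errors
#'
#' `PLR = Se / (1 - Sp)` and `NLR = (1 - Se) / Sp`, estimated by the
#' corresponding ratios of observed margins; the standard errors propagate the
#' conditional binomial variances of `Se` and `Sp` by the delta method.
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @return A data frame with one row per parameter (`PLR1`, `PLR2`, `NLR1`,
#'   `NLR2`) and columns `estimate` and `se`; `NA` where a denominator margin
#'   is zero.
#' @examples
#' estimate_likelihood_ratios(paired_counts(473, 29, 81, 25, 22, 46, 44, 151))
#' @export
estimate_likelihood_ratios <- function(x) {
  x <- as_paired_counts(x)
  q <- acc_quantities(x)
  plr <- function(Se, Sp, vSe, vSp) {
    if (1 - Sp <= 0) return(c(NA_real_, NA_real_))
    c(Se / (1 - Sp), sqrt((Se^2 * vSp + (1 - Sp)^2 * vSe) / (1 - Sp)^4))
  }
  nlr <- function(Se, Sp, vSe, vSp) {
    if (Sp <= 0) return(c(NA_real_, NA_real_))
    c((1 - Se) / Sp, sqrt(((1 - Se)^2 * vSp + Sp^2 * vSe) / Sp^4))
  }
  vals <- rbind(PLR1 = plr(q$Se1, q$Sp1, q$vSe1, q$vSp1),
                PLR2 = plr(q$Se2, q$Sp2, q$vSe2, q$vSp2),
                NLR1 = nlr(q$Se1, q$Sp1, q$vSe1, q$vSp1),
                NLR2 = nlr(q$Se2, q$Sp2, q$vSe2, q$vSp2))
  data.frame(parameter = rownames(vals), estimate = vals[, 1], se = vals[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimates, standard errors and confidence intervals for all parameters
#'
#' One-stop estimation table: disease prevalence, sensitivity and specificity
#' of each test, predictive values, and likelihood ratios, each with its
#' standard error and `100(1 - alpha)%` confidence interval. Proportions get
#' the modified-Wilson interval of [yu_interval()] (sensitivities on `s`
#' trials, specificities on `r`, predictive values on the corresponding
#' test-result margins); likelihood ratios get the approximate-score ratio
#' interval of [score_ratio_interval()].
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @param alpha Significance level for the intervals.
#' @return A data frame with columns `parameter`, `estimate`, `se`, `lower`,
#'   `upper`. Parameters whose denominators are zero are reported with `NA`.
#' @examples
#' estimate_parameters(paired_counts(473, 29, 81, 25, 22, 46, 44, 151))
#' @export
estimate_parameters <- function(x, alpha = 0.05) {
  x <- as_paired_counts(x)
  check_alpha(alpha)
  q <- acc_quantities(x); pv <- pv_quantities(x); m <- x$margins
  ci <- function(k, m_) {
    if (m_ < 1) return(c(NA_real_, NA_real_))
    v <- yu_interval(k, m_, alpha); c(v$lower, v$upper)
  }
  rows <- list(
    prevalence = c(q$prev, sqrt(q$prev * (1 - q$prev) / x$n), ci(x$s, x$n)),
    Se1 = c(q$Se1, sqrt(q$vSe1), ci(m$s1., x$s)),
    Se2 = c(q$Se2, sqrt(q$vSe2), ci(m$s.1, x$s)),
    Sp1 = c(q$Sp1, sqrt(q$vSp1), ci(m$r0., x$r)),
    Sp2 = c(q$Sp2, sqrt(q$vSp2), ci(m$r.0, x$r)),
    PPV1 = c(pv$PPV1$est, pv$PPV1$se, ci(m$s1., m$n1.)),
    PPV2 = c(pv$PPV2$est, pv$PPV2$se, ci(m$s.1, m$n.1)),
    NPV1 = c(pv$NPV1$est, pv$NPV1$se, ci(m$r0., m$n0.)),
    NPV2 = c(pv$NPV2$est, pv$NPV2$se, ci(m$r.0, m$n.0))
  )
  lr <- estimate_likelihood_ratios(x)
  lr_ci <- lapply(lr$parameter, function(w) {
    if (is.na(lr$estimate[lr$parameter == w])) return(c(NA_real_, NA_real_))
    v <- score_ratio_interval(x, w, alpha); c(v$lower, v$upper)
  })
  out <- data.frame(
    parameter = c(names(rows), lr$parameter),
    estimate = c(vapply(rows, `[`, 0, 1), lr$estimate),
    se = c(vapply(rows, `[`, 0, 2), lr$se),
    lower = c(vapply(rows, `[`, 0, 3), vapply(lr_ci, `[`, 0, 1)),
    upper = c(vapply(rows, `[`, 0, 4), vapply(lr_ci, `[`, 0, 2)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "level") <- 1 - alpha
  out
}
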