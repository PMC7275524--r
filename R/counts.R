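#' Paired-design counts for two binary diagnostic tests
#'
#' Builds and validates the 2 x 2 x 2 table obtained when two binary
#' diagnostic tests and a gold standard are applied to every subject of one
#' random sample. `s_ij` (`r_ij`) is the number of diseased (non-diseased)
#' subjects with result `i` on Test 1 and result `j` on Test 2 (1 positive,
#' 0 negative).
#'
#' All row, column and group margins are derived at construction and stored on
#' the object: `s`, `r`, `n` (group and overall totals), the pooled cells
#' `n_ij = s_ij + r_ij`, and the dot margins (`s1.` = `s11 + s10`,
#' `s.1` = `s11 + s01`, and so on for `s0.`, `s.0` and the `r` and `n`
#' analogues).
#'
#' @param s11,s10,s01,s00 Non-negative integer cell counts for the diseased
#'   group.
#' @param r11,r10,r01,r00 Non-negative integer cell counts for the
#'   non-diseased group.
#' @return An object of class `paired_counts`: a list with elements `cells`
#'   (named vector of the eight cells, in the order `s11, s10, s01, s00, r11,
#'   r10, r01, r00`), `s`, `r`, `n`, and `margins` (named list of all dot
#'   margins and pooled cells).
#' @examples
#' x <- paired_counts(473, 29, 81, 25, 22, 46, 44, 151)
#' x$n            # 871
#' x$margins$n11  # 495
#' @export
paired_counts <- function(s11, s10, s01, s00, r11, r10, r01, r00) {
  cells <- c(s11 = s11, s10 = s10, s01 = s01, s00 = s00,
             r11 = r11, r10 = r10, r01 = r01, r00 = r00)
  for (nm in names(cells)) {
    v <- cells[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || !is.finite(v))
      stop(errorCondition(sprintf("cell `%s` must be a single finite number", nm),
                          class = c("compbdt_invalid_cell", "error", "condition")))
    if (v < 0)
      stop(errorCondition(sprintf("cell `%s` is negative (%g); counts must be >= 0", nm, v),
                          class = c("compbdt_negative_cell", "error", "condition")))
    if (abs(v - round(v)) > 1e-8)
      stop(errorCondition(sprintf("cell `%s` is not an integer (%g); counts are frequencies", nm, v),
                          class = c("compbdt_noninteger_cell", "error", "condition")))
  }
  cells <- round(cells)
  storage.mode(cells) <- "double"  # keep double: margins of large tables overflow integer
  s <- sum(cells[1:4]); r <- sum(cells[5:8])
  if (s < 1)
    stop(errorCondition("the diseased group is empty (s11 + s10 + s01 + s00 = 0)",
                        class = c("compbdt_empty_group", "error", "condition")))
  if (r < 1)
    stop(errorCondition("the non-diseased group is empty (r11 + r10 + r01 + r00 = 0)",
                        class = c("compbdt_empty_group", "error", "condition")))
  m <- list(
    s1. = cells[["s11"]] + cells[["s10"]], s0. = cells[["s01"]] + cells[["s00"]],
    s.1 = cells[["s11"]] + cells[["s01"]], s.0 = cells[["s10"]] + cells[["s00"]],
    r1. = cells[["r11"]] + cells[["r10"]], r0. = cells[["r01"]] + cells[["r00"]],
    r.1 = cells[["r11"]] + cells[["r01"]], r.0 = cells[["r10"]] + cells[["r00"]],
    n11 = cells[["s11"]] + cells[["r11"]], n10 = cells[["s10"]] + cells[["r10"]],
    n01 = cells[["s01"]] + cells[["r01"]], n00 = cells[["s00"]] + cells[["r00"]]
  )
  m$n1. <- m$n11 + m$n10; m$n0. <- m$n01 + m$n00
  m$n.1 <- m$n11 + m$n01; m$n.0 <- m$n10 + m$n00
  structure(list(cells = cells, s = s, r = r, n = s + r, margins = m),
            class = "paired_counts")
}

#' Coerce a vector of eight cell counts to `paired_counts`
#'
#' @param x Numeric vector of length 8 in the order
#'   `s11, s10, s01, s00, r11, r10, r01, r00`.
#' @return A [paired_counts] object.
#' @export
as_paired_counts <- function(x) {
  if (inherits(x, "paired_counts")) return(x)
  x <- unname(unlist(x))
  if (length(x) != 8L)
    stop("expected eight cell counts (s11, s10, s01, s00, r11, r10, r01, r00)")
  do.call(paired_counts, as.list(x))
}

#' @export
print.paired_counts <- function(x, ...) {
  tab <- matrix(c(x$cells[1:4], x$cells[5:8],
                  x$margins$n11, x$margins$n10, x$margins$n01, x$margins$n00),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("Diseased", "Non-diseased", "Total"),
                                c("T1+T2+", "T1+T2-", "T1-T2+", "T1-T2-")))
  tab <- cbind(tab, Total = c(x$s, x$r, x$n))
  cat("Paired-design counts for two binary diagnostic tests\n")
  print(tab)
  invisible(x)
}

#' Estimated Youden indices of the two tests
#'
#' The Youden index `Y = Se + Sp - 1` must be positive for a test to be
#' informative (better than chance).
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @return Named numeric vector `c(test1 = , test2 = )`.
#' @examples
#' youden_indices(paired_counts(473, 29, 81, 25, 22, 46, 44, 151))
#' @export
youden_indices <- function(x) {
  x <- as_paired_counts(x)
  m <- x$margins
  c(test1 = m$s1. / x$s + m$r0. / x$r - 1,
    test2 = m$s.1 / x$s + m$r.0 / x$r - 1)
}

# stop unless both estimated Youden indices are > 0
check_youden <- function(x) {
  y <- youden_indices(x)
  bad <- which(y <= 0)
  if (length(bad))
    stop(errorCondition(
      sprintf("estimated Youden index of Test %s is not positive (%s); the test is non-informative",
              paste(bad, collapse = " and "),
              paste(sprintf("%.3f", y[bad]), collapse = ", ")),
      class = c("compbdt_noninformative_test", "error", "condition")))
  invisible(y)
}

#' Feasibility of each statistic given the observed zero pattern
#'
#' Paired comparisons are driven by the discordant cells; when too many
#' frequencies are zero some statistics are undefined. This reports, per
#' analysis family, which statistics can be computed on `x` and why not
#' otherwise. Downstream comparison functions consult this report and mark
#' infeasible statistics as not computable rather than aborting.
#'
#' @param x A [paired_counts] object (or eight counts coercible to one).
#' @return A data frame with columns `family`, `statistic`, `feasible`,
#'   `reason` (`NA` when feasible).
#' @examples
#' feasibility(paired_counts(473, 29, 81, 25, 22, 46, 44, 151))
#' @export
feasibility <- function(x) {
  x <- as_paired_counts(x)
  cl <- as.list(x$cells); m <- x$margins
  row <- function(family, statistic, feasible, reason)
    data.frame(family = family, statistic = statistic, feasible = feasible,
               reason = if (feasible) NA_character_ else reason,
               stringsAsFactors = FALSE)
  wald_se_ok <- (4 * cl$s10 * cl$s01 + (cl$s11 + cl$s00) * (cl$s10 + cl$s01)) > 0
  wald_sp_ok <- (4 * cl$r10 * cl$r01 + (cl$r11 + cl$r00) * (cl$r10 + cl$r01)) > 0
  lrt_se_ok <- cl$s10 > 0 && cl$s01 > 0
  lrt_sp_ok <- cl$r10 > 0 && cl$r01 > 0
  # LR estimation/comparison needs every Se and Sp strictly inside (0, 1)
  lr_ok <- all(unlist(m[c("s1.", "s0.", "s.1", "s.0", "r1.", "r0.", "r.1", "r.0")]) > 0)
  pv_den_ok <- m$n1. > 0 && m$n0. > 0 && m$n.1 > 0 && m$n.0 > 0
  out <- rbind(
    row("accuracy", "wald_se", wald_se_ok, "Wald Se statistic degenerate: no discordant or mixed diseased pairs"),
    row("accuracy", "wald_sp", wald_sp_ok, "Wald Sp statistic degenerate: no discordant or mixed non-diseased pairs"),
    row("accuracy", "lrt_se", lrt_se_ok, "likelihood-ratio test needs s10 > 0 and s01 > 0"),
    row("accuracy", "lrt_sp", lrt_sp_ok, "likelihood-ratio test needs r10 > 0 and r01 > 0"),
    row("accuracy", "mcnemar_se", (cl$s10 + cl$s01) > 0, "McNemar test needs s10 + s01 > 0"),
    row("accuracy", "mcnemar_sp", (cl$r10 + cl$r01) > 0, "McNemar test needs r10 + r01 > 0"),
    row("likelihood_ratios", "lr_contrast", lr_ok, "all four likelihood ratios must be positive and finite (every Se and Sp margin strictly between 0 and its group total)"),
    row("predictive_values", "wgs_ppv", m$n1. > 0 && m$n.1 > 0, "weighted generalized score needs positive subjects with each test positive"),
    row("predictive_values", "wgs_npv", m$n0. > 0 && m$n.0 > 0, "weighted generalized score needs positive subjects with each test negative"),
    row("predictive_values", "pv_global", pv_den_ok, "all four predictive values must be estimable (positive test-result margins)")
  )
  rownames(out) <- NULL
  out
}

# quick lookup: feasibility as a named logical list
feas_flags <- function(x) {
  f <- feasibility(x)
  stats::setNames(as.list(f$feasible), f$statistic)
}
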