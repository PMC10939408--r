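# Method-agreement statistics: Bland-Altman limits of agreement, regression
# against the identity line, and the paired t test.

#' Bland-Altman agreement of two paired measurement series
#'
#' Differences are taken as `y - x` (comparator minus reference). Limits of
#' agreement are `mean +/- 1.96 * SD` of the differences, with the sample
#' standard deviation (n - 1 denominator).
#'
#' @param x Reference measurements.
#' @param y Comparator measurements, same length.
#' @return List with `n`, `mean_diff`, `sd_diff` and `loa` (length-2 vector,
#'   lower then upper limit).
#' @examples
#' bland_altman(c(0, 2), c(0, 0))
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("at least 2 pairs are required")
  d <- y - x
  m <- mean(d)
  s <- stats::sd(d)
  list(n = length(d), mean_diff = m, sd_diff = s,
       loa = c(m - 1.96 * s, m + 1.96 * s))
}

#' Regression of a comparator on a reference series
#'
#' Simple OLS of `y` on `x` with the squared Pearson correlation, used to
#' judge how close the relationship is to the identity line.
#'
#' @param x Reference measurements (must vary).
#' @param y Comparator measurements.
#' @return List with `slope`, `intercept`, `r2` and `n`.
#' @examples
#' identity_regression(1:10, 2 * (1:10) + 1)
#' @export
identity_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 pairs are required")
  if (stats::var(x) == 0) stop("x is degenerate (zero variance)")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
       r2 = summary(fit)$r.squared, n = length(x))
}

#' Paired t test on two series
#'
#' Classical paired t statistic on the differences `y - x` with a
#' two-sided p value. Zero-variance differences are degenerate: with zero
#' mean the statistic is undefined (reported as `NA` with
#' `degenerate = TRUE`); with non-zero mean the shift is exact and the
#' statistic is likewise flagged.
#'
#' @param x,y Paired measurements, equal length >= 2.
#' @return List with `t_stat`, `p_value`, `df`, `mean_diff` and
#'   `degenerate`.
#' @examples
#' paired_t(c(1, 2, 3, 4), c(0.9, 2.1, 2.9, 4.1))
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("at least 2 pairs are required")
  d <- y - x
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(list(t_stat = NA_real_, p_value = NA_real_, df = n - 1L,
                mean_diff = m, degenerate = TRUE))
  }
  t_stat <- m / (s / sqrt(n))
  list(t_stat = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1L),
       df = n - 1L, mean_diff = m, degenerate = FALSE)
}

# Full agreement report combining the three statistics.
.agreement_report <- function(reference, comparator) {
  ba <- bland_altman(reference, comparator)
  reg <- identity_regression(reference, comparator)
  tt <- paired_t(reference, comparator)
  structure(
    list(n = ba$n,
         mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
         loa_lower = ba$loa[1L], loa_upper = ba$loa[2L],
         slope = reg$slope, intercept = reg$intercept, r2 = reg$r2,
         t_stat = tt$t_stat, p_value = tt$p_value,
         degenerate_t = tt$degenerate),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d pairs (comparator - reference):\n", x$n))
  cat(sprintf("  mean difference %.4f +/- %.4f (LoA %.4f to %.4f)\n",
              x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper))
  cat(sprintf("  regression: slope %.4f, intercept %.4f, R2 %.4f\n",
              x$slope, x$intercept, x$r2))
  if (isTRUE(x$degenerate_t)) cat("  paired t: degenerate (zero-variance differences)\n")
  else cat(sprintf("  paired t = %.3f, p = %.3g\n", x$t_stat, x$p_value))
  invisible(x)
}
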