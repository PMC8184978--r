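mk_var_s <- function(n, tie_sizes = integer()) {
  tie_sizes <- tie_sizes[tie_sizes > 1L]
  (n * (n - 1) * (2 * n + 5) -
     sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))) / 18
}

mk_z <- function(S, varS) {
  if (S == 0 || varS <= 0) return(0)
  (S - sign(S)) / sqrt(varS)
}

#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotonic trend in an ordered series, used here
#' on the daily pre-onset values of each rolling-window indicator. The
#' statistic is the pair-sign sum `S = sum_{i<j} sign(x_j - x_i)`; its null
#' variance carries the standard tie correction
#' `varS = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` over tie-group sizes
#' `t`, and the normal deviate uses the continuity correction
#' `z = (S -/+ 1)/sqrt(varS)` (zero at `S = 0`). Kendall's tau is reported in
#' its classical (tau-a) form `S / (n(n-1)/2)`. Missing values are dropped,
#' preserving order.
#'
#' @param values Ordered numeric series; `NA` entries are dropped.
#' @return An object of class `mann_kendall`: list with `S`, `varS`, `z`,
#'   `tau`, `n`, `p` (two-sided) and `direction` ("increase", "decrease" or
#'   "none", from the sign of `S`).
#' @examples
#' mann_kendall(1:10)           # perfect increasing trend, tau = 1
#' mann_kendall(c(3, 1, 2, 5, 4))
#' @export
mann_kendall <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 3L) stop("Mann-Kendall test needs at least 3 non-missing values")
  d <- sign(outer(x, x, "-"))
  S <- sum(d[lower.tri(d)])
  tie_sizes <- as.integer(table(x))
  varS <- mk_var_s(n, tie_sizes)
  tau <- S / (n * (n - 1) / 2)
  if (varS <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- mk_z(S, varS)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  direction <- if (S > 0) "increase" else if (S < 0) "decrease" else "none"
  structure(list(S = S, varS = varS, z = z, tau = tau, n = n, p = p,
                 direction = direction),
            class = "mann_kendall")
}

#' @export
print.mann_kendall <- function(x, ...) {
  cat(sprintf("Mann-Kendall: S = %.0f, z = %.3f, tau = %.3f, n = %d, p = %.4g (%s)\n",
              x$S, x$z, x$tau, x$n, x$p, x$direction))
  invisible(x)
}

#' Mann-Kendall statistics from summary quantities
#'
#' Reconstructs the normal deviate and p-value from a pair-sign sum `S` (or
#' from tau via `S = tau * n(n-1)/2`) without the raw series — useful for
#' checking published tables that report only tau and n.
#'
#' @param S Integer pair-sign sum; rounded if derived from tau.
#' @param n Number of values the test used.
#' @param tie_sizes Integer tie-group sizes (default: no ties).
#' @return A `mann_kendall` object (with `S`, `varS`, `z`, `tau`, `n`, `p`,
#'   `direction`).
#' @export
mann_kendall_stats <- function(S, n, tie_sizes = integer()) {
  n <- as.integer(n)
  if (n < 3L) stop("n must be at least 3")
  S <- round(S)
  npairs <- n * (n - 1) / 2
  if (abs(S) > npairs) stop("|S| cannot exceed n(n-1)/2")
  varS <- mk_var_s(n, as.integer(tie_sizes))
  z <- mk_z(S, varS)
  p <- if (varS <= 0) 1 else min(1, 2 * stats::pnorm(-abs(z)))
  direction <- if (S > 0) "increase" else if (S < 0) "decrease" else "none"
  structure(list(S = S, varS = varS, z = z, tau = S / npairs, n = n, p = p,
                 direction = direction),
            class = "mann_kendall")
}

#' Fisher's method for combining p-values
#'
#' Combines independent per-patient p-values for one indicator into a group
#' test: `chi2 = -2 sum log(p_i)` referred to a chi-square distribution with
#' `2k` degrees of freedom.
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]`.
#' @return An object of class `fisher_combined`: list with `chi2`, `df`, `p`.
#' @examples
#' fisher_combine(c(0.01, 0.20, 0.03))
#' @export
fisher_combine <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) < 1L) stop("at least one p-value is required")
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("all p-values must lie in (0, 1]")
  }
  chi2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "fisher_combined")
}

#' @export
print.fisher_combined <- function(x, ...) {
  cat(sprintf("Fisher combination: chi2 = %.3f on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Significance stars
#'
#' `"**"` for p <= 0.01, `"*"` for p <= 0.05, `""` otherwise. Vectorised.
#'
#' @param p Numeric p-values in `(0, 1]`.
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  if (any(is.na(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ""))
}
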