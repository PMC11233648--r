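#' Modified asymptotic (MA) test for comparing two overlapping correlations
#'
#' Tests whether two correlations that share a common variable differ, using
#' asymptotic confidence limits on the correlation difference. Given the
#' correlation `r1` between variables (X, Y1), `r2` between (X, Y2) and `r3`
#' between (Y1, Y2), all estimated from the same `n` samples, the test builds
#' confidence limits `(L, U)` for `r1 - r2` from the single-correlation limits
#' `l = r - z * sqrt(var(r))`, `u = r + z * sqrt(var(r))` with
#' `var(r) = (1 - r^2)^2 / n`, combined through the estimated correlation
#' between the two correlation estimates:
#'
#' `L = r1 - r2 - sqrt((r1-l1)^2 + (u2-r2)^2 - 2*corr(r1,r2)*(r1-l1)*(u2-r2))`
#' `U = r1 - r2 + sqrt((u1-r1)^2 + (r2-l2)^2 - 2*corr(r1,r2)*(u1-r1)*(r2-l2))`
#'
#' where `cov(r1, r2) = ((r3 - r1*r2/2) * (1 - r1^2 - r2^2 - r3^2) + r3^3) / n`.
#' `r1` is declared significantly larger than `r2` when `L > 0`, and smaller
#' when the mirrored limit `L(r2, r1) > 0`.
#'
#' @param r1,r2 Correlations to compare; both share a variable with each other
#'   through the third. Must lie strictly inside (-1, 1).
#' @param r3 Correlation between the two non-shared variables, strictly inside
#'   (-1, 1).
#' @param n Sample size used to estimate the correlations; at least 4.
#' @param alpha Significance level, default 0.05.
#' @return An object of class `ma_test` with elements `r1`, `r2`, `r3`, `n`,
#'   `alpha`, `l1`, `u1`, `l2`, `u2` (single-correlation limits), `var_r1`,
#'   `var_r2`, `cov_r12`, `corr_r12`, `L`, `U` (limits for `r1 - r2`) and
#'   `decision` (one of `"r1_higher"`, `"r2_higher"`, `"none"`).
#' @examples
#' ma_test(0.6, 0.1, 0.2, n = 200)
#' @export
ma_test <- function(r1, r2, r3, n, alpha = 0.05) {
  stopifnot(length(r1) == 1L, length(r2) == 1L, length(r3) == 1L)
  if (any(abs(c(r1, r2, r3)) >= 1))
    stop_ccgnet("ma_test: correlations must lie strictly inside (-1, 1)")
  if (!is.numeric(n) || length(n) != 1L || n < 4)
    stop_ccgnet("ma_test: n must be a single integer >= 4")
  if (alpha <= 0 || alpha >= 1) stop_ccgnet("ma_test: alpha must be in (0, 1)")
  n <- as.integer(n)

  z <- stats::qnorm(1 - alpha / 2)
  var_r <- function(r) (1 - r^2)^2 / n
  v1 <- var_r(r1); v2 <- var_r(r2)
  l1 <- r1 - z * sqrt(v1); u1 <- r1 + z * sqrt(v1)
  l2 <- r2 - z * sqrt(v2); u2 <- r2 + z * sqrt(v2)

  cov12 <- ((r3 - 0.5 * r1 * r2) * (1 - r1^2 - r2^2 - r3^2) + r3^3) / n
  corr12 <- cov12 / sqrt(v1 * v2)

  # Radicands can go slightly negative when corr12 is extreme; floor at 0.
  rad_L <- (r1 - l1)^2 + (u2 - r2)^2 - 2 * corr12 * (r1 - l1) * (u2 - r2)
  rad_U <- (u1 - r1)^2 + (r2 - l2)^2 - 2 * corr12 * (u1 - r1) * (r2 - l2)
  if (rad_L < 0 || rad_U < 0)
    warning("ma_test: negative radicand floored at 0; corr(r1, r2) estimate is extreme")
  L <- r1 - r2 - sqrt(max(rad_L, 0))
  U <- r1 - r2 + sqrt(max(rad_U, 0))

  # Mirrored lower limit for r2 - r1 decides the other direction.
  rad_Lm <- (r2 - l2)^2 + (u1 - r1)^2 - 2 * corr12 * (r2 - l2) * (u1 - r1)
  L_mirror <- r2 - r1 - sqrt(max(rad_Lm, 0))
  decision <- if (L > 0) "r1_higher" else if (L_mirror > 0) "r2_higher" else "none"

  structure(
    list(r1 = r1, r2 = r2, r3 = r3, n = n, alpha = alpha,
         l1 = l1, u1 = u1, l2 = l2, u2 = u2,
         var_r1 = v1, var_r2 = v2, cov_r12 = cov12, corr_r12 = corr12,
         L = L, U = U, decision = decision),
    class = "ma_test")
}

#' @export
print.ma_test <- function(x, ...) {
  cat("MA test for overlapping correlations\n")
  cat(sprintf("  r1 = %.4f, r2 = %.4f, r3 = %.4f, n = %d, alpha = %.3f\n",
              x$r1, x$r2, x$r3, x$n, x$alpha))
  cat(sprintf("  CI for r1 - r2: [%.4f, %.4f]\n", x$L, x$U))
  cat(sprintf("  decision: %s\n", x$decision))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values; a thin wrapper over [stats::p.adjust()] so the
#' pipeline's multiple-testing correction has a single documented entry point.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_ccgnet("bh_adjust: p values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cochran-Armitage trend test for binary outcomes across ordered bins
#'
#' Tests for a linear trend in proportions across ordered groups using the
#' Cochran-Armitage statistic with equally spaced scores (by default) and a
#' standard-normal reference; the two-sided p value equals that of the
#' chi-squared form used by [stats::prop.trend.test()].
#'
#' @param successes Integer vector: number of positive outcomes per bin.
#' @param totals Integer vector: number of trials per bin.
#' @param scores Numeric scores attached to the ordered bins; defaults to
#'   `seq_along(successes)`.
#' @return A list with `statistic` (signed z; positive means proportions
#'   increase with score), `p.value` (two-sided) and `estimate` (per-bin
#'   proportions).
#' @export
trend_test <- function(successes, totals, scores = seq_along(successes)) {
  stopifnot(length(successes) == length(totals), length(scores) == length(successes))
  if (length(successes) < 2) stop_ccgnet("trend_test: need at least 2 ordered bins")
  if (any(totals <= 0)) stop_ccgnet("trend_test: all bin totals must be positive")
  if (any(successes < 0 | successes > totals))
    stop_ccgnet("trend_test: successes must lie in [0, totals]")

  N <- sum(totals)
  pbar <- sum(successes) / N
  if (pbar == 0 || pbar == 1) {
    # All outcomes identical: no trend information.
    return(list(statistic = 0, p.value = 1, estimate = successes / totals))
  }
  sbar <- sum(totals * scores) / N
  num <- sum(successes * (scores - sbar))
  den <- sqrt(pbar * (1 - pbar) * sum(totals * (scores - sbar)^2))
  z <- num / den
  list(statistic = z,
       p.value = 2 * stats::pnorm(-abs(z)),
       estimate = successes / totals)
}
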