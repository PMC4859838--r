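# Small-sample statistics: exact Mann-Whitney U and ordinary least squares
# with a pointwise confidence band.  Written from first principles for
# small n (these are reporting utilities, not the package's contribution).

#' Mann-Whitney U test
#'
#' Two-sided test of two independent groups.  For groups of up to
#' `exact_max` observations each the null distribution of U is enumerated
#' exactly over all assignments of the pooled values (so ties are handled
#' exactly); larger groups use the normal approximation with tie
#' correction and continuity correction.  The two-sided exact p-value sums
#' the probability of all arrangements whose U deviates from the null mean
#' `n1 n2 / 2` at least as much as observed.
#'
#' @param a,b numeric vectors (each nonempty).
#' @param exact_max per-group size limit for exact enumeration.
#' @return list with `U` (statistic of group `a`), `p_value`, `method`.
#' @export
compare_groups <- function(a, b, exact_max = 8) {
  if (!length(a) || !length(b)) stop("compare_groups: empty group")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    r_all <- rank(pooled)
    Us <- apply(combs, 2, function(idx) sum(r_all[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(U_obs - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U_obs, p_value = p, method = method)
}

#' Ordinary least squares with a pointwise confidence band
#'
#' Fits `y = intercept + slope * x`, returns the Pearson correlation and a
#' t-based pointwise confidence band for the regression line: half-width
#' at `x0` is `t * s * sqrt(1/n + (x0 - mean(x))^2 / Sxx)`.
#'
#' @param x,y numeric vectors, `n >= 3`, `x` non-constant.
#' @param level confidence level (default 0.95).
#' @param at x-positions for the band (default: sorted `x`).
#' @return list with `slope`, `intercept`, `r`, `sigma`, and `band`
#'   (`data.frame` of `x`, `fit`, `lower`, `upper`).
#' @export
regression_with_band <- function(x, y, level = 0.95, at = NULL) {
  n <- length(x)
  if (n < 3 || length(y) != n)
    stop("regression_with_band: need n >= 3 paired observations")
  if (diff(range(x)) == 0) stop("regression_with_band: constant x")
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  resid <- y - intercept - slope * x
  s <- sqrt(sum(resid^2) / (n - 2))
  r <- if (sd(y) == 0) {
    if (all(abs(resid) < 1e-12)) 1 else 0
  } else sum((x - xm) * (y - ym)) / sqrt(sxx * sum((y - ym)^2))
  if (is.null(at)) at <- sort(x)
  tq <- qt(1 - (1 - level) / 2, df = n - 2)
  half <- tq * s * sqrt(1 / n + (at - xm)^2 / sxx)
  fit <- intercept + slope * at
  list(slope = slope, intercept = intercept, r = r, sigma = s,
       band = data.frame(x = at, fit = fit, lower = fit - half,
                         upper = fit + half))
}
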