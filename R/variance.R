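# Closed-form sampling variances. Both formulas are exact for bivariate
# normal data (the estimator follows a scaled noncentral t), and take the
# *uncorrected* point estimate; corrected variances are obtained by scaling
# with c(n-1)^2 < 1.

#' Sampling variance of Cohen's d_z
#'
#' \deqn{Var[d_z] = \frac{n-1}{n(n-3)}\,(1 + d_z^2 n) -
#'   \frac{d_z^2}{c(n-1)^2}}
#' For the Hedges-corrected estimate the variance is this quantity
#' multiplied by \eqn{c(n-1)^2}, which always decreases it.
#'
#' @param dz The uncorrected d_z point estimate.
#' @param n Number of pairs (>= 4; the formula has an n - 3 denominator).
#' @param corrected If `TRUE`, return the variance of the Hedges-corrected
#'   estimate.
#' @param exact Use the exact gamma-ratio correction factor inside the
#'   formula (see [hedges_c()]).
#' @return The sampling variance (squared SMD units).
#' @examples
#' var_dz(0.5, n = 20)
#' @export
var_dz <- function(dz, n, corrected = FALSE, exact = FALSE) {
  dz <- check_numeric_vec(dz, "dz")
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 4)) {
    stop_formula_undefined("`n` must be >= 4: the variance formula has an n - 3 denominator.")
  }
  cf <- hedges_c(n - 1, exact = exact)
  v <- (n - 1) / (n * (n - 3)) * (1 + dz^2 * n) - dz^2 / cf^2
  if (corrected) v <- v * cf^2
  v
}

#' Sampling variance of Glass's Delta_pre
#'
#' \deqn{Var[\Delta_{pre}] = \frac{n-1}{n(n-3)}\,(2(1-r) +
#'   \Delta_{pre}^2 n) - \frac{\Delta_{pre}^2}{c(n-1)^2}}
#' Decreasing in the pre-post correlation r for fixed \eqn{\Delta}: the more
#' homogeneous the change, the more precise the magnitude-based estimate.
#' Coincides with [var_dz()] when r = 0.5 and the two estimates are equal.
#'
#' @param delta The uncorrected \eqn{\Delta_{pre}} point estimate.
#' @param n Number of pairs (>= 4).
#' @param r Pre-post correlation in \[-1, 1\].
#' @inheritParams var_dz
#' @return The sampling variance (squared SMD units).
#' @examples
#' var_delta_pre(0.5, n = 20, r = 0.8)
#' @export
var_delta_pre <- function(delta, n, r, corrected = FALSE, exact = FALSE) {
  delta <- check_numeric_vec(delta, "delta")
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 4)) {
    stop_formula_undefined("`n` must be >= 4: the variance formula has an n - 3 denominator.")
  }
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < -1) || any(r > 1)) {
    stop_invalid_input("`r` must lie in [-1, 1].")
  }
  cf <- hedges_c(n - 1, exact = exact)
  v <- (n - 1) / (n * (n - 3)) * (2 * (1 - r) + delta^2 * n) - delta^2 / cf^2
  if (corrected) v <- v * cf^2
  v
}

new_interval <- function(point, variance, se, level, lower, upper, method,
                         replicates = 0L, seed = NA_integer_) {
  out <- tibble(
    point = as.double(point), variance = as.double(variance),
    se = as.double(se), level = as.double(level),
    lower = as.double(lower), upper = as.double(upper),
    method = method, replicates = as.integer(replicates),
    seed = as.integer(seed)
  )
  class(out) <- c("smd_interval", class(out))
  out
}

#' Wald (normal-approximation) confidence interval
#'
#' \eqn{point \pm z_{(1+level)/2}\sqrt{variance}}. Symmetric by
#' construction; adequate at moderate n. For small samples prefer the
#' subject-level bootstrap ([bootstrap_ci()]).
#'
#' @param point Point estimate (dimensionless SMD).
#' @param variance Sampling variance (>= 0), e.g. from [var_dz()] or
#'   [var_delta_pre()].
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A one-row `smd_interval` tibble with columns `point`, `variance`,
#'   `se`, `level`, `lower`, `upper`, `method`.
#' @examples
#' wald_ci(0.5, var_dz(0.5, 20))
#' @export
wald_ci <- function(point, variance, level = 0.95) {
  point <- check_numeric_vec(point, "point")
  variance <- check_numeric_vec(variance, "variance")
  if (any(variance < 0)) stop_invalid_input("`variance` must be >= 0.")
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1) {
    stop_invalid_input("`level` must lie strictly inside (0, 1).")
  }
  z <- qnorm((1 + level) / 2)
  se <- sqrt(variance)
  new_interval(point, variance, se, level,
               lower = point - z * se, upper = point + z * se,
               method = "wald")
}
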