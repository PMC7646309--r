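# Point estimators. All kernels are vectorised over their numeric arguments
# and validate the whole vector up front; zero-spread denominators raise
# typed errors instead of returning infinities.

check_numeric_vec <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x))) {
    stop_invalid_input(sprintf("`%s` must be finite and numeric.", name))
  }
  as.double(x)
}

#' Cohen's d_z: the signal-to-noise SMD
#'
#' The mean change score divided by the standard deviation of change scores,
#' \eqn{d_z = \bar\delta / \sigma_\delta}. This is a signal-to-noise
#' statistic: it measures the consistency of change, not its magnitude, and
#' is algebraically tied to the paired t-statistic (see [dz_from_t()]).
#'
#' @param mean_change Mean change score \eqn{\bar\delta} (outcome units).
#' @param sd_change Standard deviation of change scores \eqn{\sigma_\delta}
#'   (outcome units, > 0).
#' @return The dimensionless SMD, with the sign of `mean_change`.
#' @examples
#' cohen_dz(1, 2)
#' @export
cohen_dz <- function(mean_change, sd_change) {
  mean_change <- check_numeric_vec(mean_change, "mean_change")
  sd_change <- check_numeric_vec(sd_change, "sd_change")
  if (any(sd_change < 0)) stop_invalid_input("`sd_change` must be >= 0.")
  if (any(sd_change == 0)) {
    stop_zero_variance("change scores have no spread (sd_change = 0); d_z is undefined.")
  }
  mean_change / sd_change
}

#' Cohen's d_z from a paired t-statistic
#'
#' Uses the identity \eqn{d_z = t / \sqrt{n}}, the exact algebraic inverse of
#' the paired t computed from the same data. Convenient when only the test
#' statistic and sample size are reported.
#'
#' @param t_stat Paired t-statistic.
#' @param n Number of pairs (>= 1).
#' @return The dimensionless SMD.
#' @examples
#' dz_from_t(3.54, 8)
#' @export
dz_from_t <- function(t_stat, n) {
  t_stat <- check_numeric_vec(t_stat, "t_stat")
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    stop_invalid_input("`n` must be a pair count >= 1.")
  }
  t_stat / sqrt(n)
}

#' Glass's Delta_pre: the magnitude-based SMD
#'
#' The mean change standardized by the pre-intervention standard deviation,
#' \eqn{\Delta_{pre} = \bar\delta / \sigma_{pre}}. Interpreted as the
#' expected change in units of the baseline between-subject spread; unlike
#' \eqn{d_z} it does not depend on the pre-post correlation.
#'
#' @param mean_change Mean change score (outcome units).
#' @param sd_pre Pre-intervention standard deviation (outcome units, > 0).
#' @return The dimensionless SMD.
#' @examples
#' glass_delta_pre(3.0, 6.05)
#' @export
glass_delta_pre <- function(mean_change, sd_pre) {
  mean_change <- check_numeric_vec(mean_change, "mean_change")
  sd_pre <- check_numeric_vec(sd_pre, "sd_pre")
  if (any(sd_pre < 0)) stop_invalid_input("`sd_pre` must be >= 0.")
  if (any(sd_pre == 0)) {
    stop_zero_variance("pre-test scores have no spread (sd_pre = 0); Delta_pre is undefined.")
  }
  mean_change / sd_pre
}

#' Cohen's d_av: mean change over the average pre/post SD
#'
#' \eqn{d_{av} = \bar\delta / ((\sigma_{pre} + \sigma_{post})/2)}. A
#' magnitude-based SMD; identical to Glass's \eqn{\Delta_{pre}} when the
#' pre- and post-intervention SDs are equal.
#'
#' @param mean_change Mean change score (outcome units).
#' @param sd_pre,sd_post Pre- and post-intervention SDs (outcome units).
#' @return The dimensionless SMD.
#' @examples
#' cohen_dav(2, 1, 3)
#' @export
cohen_dav <- function(mean_change, sd_pre, sd_post) {
  mean_change <- check_numeric_vec(mean_change, "mean_change")
  sd_pre <- check_numeric_vec(sd_pre, "sd_pre")
  sd_post <- check_numeric_vec(sd_post, "sd_post")
  if (any(sd_pre < 0) || any(sd_post < 0)) {
    stop_invalid_input("standard deviations must be >= 0.")
  }
  avg <- (sd_pre + sd_post) / 2
  if (any(avg == 0)) {
    stop_zero_variance("both SDs are zero; d_av is undefined.")
  }
  mean_change / avg
}

#' Cohen's d_rm: correlation-adjusted repeated-measures SMD
#'
#' \eqn{d_{rm} = (\bar\delta / \sigma_\delta)\sqrt{2(1-r)}} with
#' \eqn{\sigma_\delta = \sqrt{\sigma_{pre}^2 + \sigma_{post}^2 -
#' 2 r \sigma_{pre} \sigma_{post}}}. A magnitude-based SMD; identical to
#' Glass's \eqn{\Delta_{pre}} and \eqn{d_{av}} when the pre- and
#' post-intervention SDs are equal (for any \eqn{-1 \le r < 1}).
#'
#' @param mean_change Mean change score (outcome units).
#' @param sd_pre,sd_post Pre- and post-intervention SDs (outcome units).
#' @param r Pre-post Pearson correlation in \[-1, 1\].
#' @return The dimensionless SMD.
#' @examples
#' cohen_drm(1, 1, 1, r = 0.5)
#' @export
cohen_drm <- function(mean_change, sd_pre, sd_post, r) {
  mean_change <- check_numeric_vec(mean_change, "mean_change")
  sd_pre <- check_numeric_vec(sd_pre, "sd_pre")
  sd_post <- check_numeric_vec(sd_post, "sd_post")
  r <- check_numeric_vec(r, "r")
  if (any(r < -1) || any(r > 1)) stop_invalid_input("`r` must lie in [-1, 1].")
  if (any(sd_pre < 0) || any(sd_post < 0)) {
    stop_invalid_input("standard deviations must be >= 0.")
  }
  sd_delta <- sqrt(pmax(sd_pre^2 + sd_post^2 - 2 * r * sd_pre * sd_post, 0))
  if (any(sd_delta == 0)) {
    stop_zero_variance("change scores have no spread (sd_delta = 0); d_rm is undefined.")
  }
  mean_change / sd_delta * sqrt(2 * (1 - r))
}

#' Pretest-posttest-control effect size
#'
#' \eqn{\Delta_{ppc} = \Delta_T - \Delta_C}: the treatment group's Glass's
#' \eqn{\Delta_{pre}} minus the control group's. Both inputs must be
#' `delta_pre`-family estimates (bare numerics are accepted and treated as
#' such); passing an estimate from another family is an error, since mixing
#' families makes the difference uninterpretable.
#'
#' @param delta_treatment,delta_control Glass's \eqn{\Delta_{pre}} for the
#'   treatment and control groups: numbers or `smd_estimate` rows.
#' @return The dimensionless contrast as a number.
#' @examples
#' delta_ppc(0.5, 0.2)
#' @export
delta_ppc <- function(delta_treatment, delta_control) {
  take <- function(x, name) {
    if (inherits(x, "smd_estimate")) {
      if (nrow(x) != 1L) {
        stop_invalid_input(sprintf("`%s` must be a single estimate row.", name))
      }
      if (x$family != "delta_pre") {
        stop_invalid_family(sprintf(
          "`%s` is a %s estimate; Delta_ppc is defined for the delta_pre family only.",
          name, x$family
        ))
      }
      return(x$estimate)
    }
    check_numeric_vec(x, name)
  }
  take(delta_treatment, "delta_treatment") - take(delta_control, "delta_control")
}

# ---- estimate container ----------------------------------------------------

smd_families <- c("dz", "delta_pre", "d_av", "d_rm")

new_smd_estimate <- function(family, estimate, n,
                             corrected = FALSE, correction_factor = 1,
                             df = NA_integer_) {
  out <- tibble(
    family = family,
    estimate = as.double(estimate),
    corrected = corrected,
    correction_factor = as.double(correction_factor),
    df = as.integer(df),
    n = as.integer(n)
  )
  class(out) <- c("smd_estimate", class(out))
  out
}

#' @method tidy smd_estimate
#' @export
tidy.smd_estimate <- function(x, ...) {
  out <- tibble(
    term = x$family,
    estimate = x$estimate,
    std.error = if ("se" %in% names(x)) x$se else NA_real_,
    conf.low = if ("lower" %in% names(x)) x$lower else NA_real_,
    conf.high = if ("upper" %in% names(x)) x$upper else NA_real_
  )
  out
}
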