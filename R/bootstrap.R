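#' Subject-level bootstrap confidence interval for an SMD
#'
#' Resamples complete pairs with replacement (never pre and post
#' independently, so the within-pair correlation is preserved), recomputes
#' the chosen SMD on every resample, and forms a percentile or
#' bias-corrected-and-accelerated (BCa) interval. The bootstrap is the
#' recommended interval for small samples and the only interval offered for
#' d_av / d_rm, which have no closed-form variance here.
#'
#' Resamples on which the estimator is undefined (zero spread in the
#' relevant denominator) are dropped and counted; if more than 10\% of
#' replicates are degenerate the data cannot support a bootstrap and a
#' `degenerate_resample` error is raised. With a fixed `seed` the interval
#' is bit-for-bit reproducible.
#'
#' @param sample A [paired_data] tibble with n >= 5 pairs.
#' @param family One of `"delta_pre"`, `"dz"`, `"d_av"`, `"d_rm"`.
#' @param level Confidence level in (0, 1).
#' @param replicates Number of bootstrap resamples (>= 200; default 2000).
#' @param seed Integer RNG seed; required for a reproducible report.
#' @param method `"percentile"` (default) or `"bca"`.
#' @return A one-row `smd_interval` tibble (see [wald_ci()]) with
#'   `method`, `replicates` and `seed` recorded, plus attributes
#'   `bias` (mean of replicate estimates minus the point estimate, i.e. the
#'   bootstrap bias estimate) and `n_dropped` (degenerate resamples).
#' @examples
#' s <- generate_paired(30, mean_change = 0.5, sd_pre = 1, r = 0.6, seed = 1)
#' bootstrap_ci(s, "delta_pre", replicates = 500, seed = 42)
#' @export
bootstrap_ci <- function(sample, family = c("delta_pre", "dz", "d_av", "d_rm"),
                         level = 0.95, replicates = 2000, seed = NULL,
                         method = c("percentile", "bca")) {
  family <- rlang::arg_match(family)
  method <- rlang::arg_match(method)
  if (!is_paired_data(sample)) {
    stop_invalid_input("`sample` must be a `paired_data` object.")
  }
  n <- nrow(sample)
  if (n < 5L) stop_insufficient_data("Bootstrap intervals need at least 5 pairs.")
  if (!is.numeric(replicates) || replicates < 200) {
    stop_invalid_input("`replicates` must be >= 200.")
  }
  replicates <- as.integer(replicates)
  if (level <= 0 || level >= 1) {
    stop_invalid_input("`level` must lie strictly inside (0, 1).")
  }

  full <- col_paired_stats(matrix(sample$pre), matrix(sample$post))
  point <- family_stat(family, full)
  if (is.na(point)) {
    stop_degenerate_resample(sprintf(
      "the %s estimate is undefined on the observed sample (zero spread).", family
    ))
  }

  draw <- function() {
    idx <- matrix(sample.int(n, n * replicates, replace = TRUE), nrow = n)
    cs <- col_paired_stats(matrix(sample$pre[idx], nrow = n),
                           matrix(sample$post[idx], nrow = n))
    family_stat(family, cs)
  }
  stats <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())

  n_dropped <- sum(is.na(stats))
  if (n_dropped > 0.10 * replicates) {
    stop_degenerate_resample(sprintf(
      "%d of %d bootstrap resamples (%.0f%%) left the %s estimate undefined; the data cannot support a bootstrap interval.",
      n_dropped, replicates, 100 * n_dropped / replicates, family
    ))
  }
  stats <- stats[!is.na(stats)]
  alpha <- 1 - level

  if (method == "percentile") {
    bounds <- unname(quantile(stats, c(alpha / 2, 1 - alpha / 2), names = FALSE))
  } else {
    # BCa: bias-correction z0 from the proportion of replicates below the
    # point estimate (clamped away from 0/1 so qnorm stays finite), and
    # acceleration from the jackknife.
    prop <- mean(stats < point)
    prop <- min(max(prop, 1 / (length(stats) + 1)), length(stats) / (length(stats) + 1))
    z0 <- qnorm(prop)
    jack <- vapply(seq_len(n), function(i) {
      cs <- col_paired_stats(matrix(sample$pre[-i]), matrix(sample$post[-i]))
      family_stat(family, cs)
    }, numeric(1))
    if (anyNA(jack)) {
      stop_degenerate_resample(
        "a jackknife leave-one-out estimate is undefined; BCa acceleration cannot be computed."
      )
    }
    jm <- mean(jack)
    num <- sum((jm - jack)^3)
    den <- 6 * (sum((jm - jack)^2))^1.5
    a <- if (den == 0) 0 else num / den
    adj <- function(q) {
      zq <- qnorm(q)
      pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    }
    bounds <- unname(quantile(stats, c(adj(alpha / 2), adj(1 - alpha / 2)),
                              names = FALSE))
  }

  out <- new_interval(
    point = point, variance = var(stats), se = sd(stats), level = level,
    lower = bounds[1], upper = bounds[2],
    method = paste0("bootstrap_", method),
    replicates = replicates,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  attr(out, "bias") <- mean(stats) - point
  attr(out, "n_dropped") <- n_dropped
  out
}
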