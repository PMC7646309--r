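#' Generate a synthetic paired sample
#'
#' Draws (pre, post) from a bivariate normal with means `mean_pre` and
#' `mean_pre + mean_change`, the given SDs, and pre-post correlation `r`.
#' In `"lognormal"` mode the same machinery runs on the log scale and the
#' result is exponentiated — suitable for outcomes such as perceived
#' soreness that are multiplicative rather than additive (the generator
#' parameters are then log-scale parameters).
#'
#' @param n Number of pairs (>= 2).
#' @param mean_pre Baseline mean (outcome units; log units in lognormal
#'   mode).
#' @param mean_change Mean change \eqn{\bar\delta}; the post mean is
#'   `mean_pre + mean_change`.
#' @param sd_pre,sd_post Marginal SDs (> 0); `sd_post` defaults to `sd_pre`.
#' @param r Pre-post correlation strictly inside (-1, 1).
#' @param seed Integer seed; the same seed reproduces the sample exactly.
#' @param distribution `"normal"` (default) or `"lognormal"`.
#' @return A [paired_data] tibble with n rows.
#' @examples
#' generate_paired(20, mean_pre = 3.9, mean_change = 0.24,
#'                 sd_pre = 0.22, r = 0.8, seed = 7)
#' @export
generate_paired <- function(n, mean_pre = 0, mean_change = 0,
                            sd_pre = 1, sd_post = sd_pre, r = 0.5,
                            seed = NULL,
                            distribution = c("normal", "lognormal")) {
  distribution <- rlang::arg_match(distribution)
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop_invalid_input("`n` must be a pair count >= 2.")
  }
  check_number(mean_pre, "mean_pre"); check_number(mean_change, "mean_change")
  check_number(sd_pre, "sd_pre"); check_number(sd_post, "sd_post")
  if (sd_pre <= 0 || sd_post <= 0) stop_invalid_input("SDs must be > 0.")
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || abs(r) >= 1) {
    stop_invalid_input("`r` must lie strictly inside (-1, 1) for generation.")
  }
  n <- as.integer(n)
  draw <- function() {
    m <- draw_pairs_matrix(n, 1L, mean_pre, mean_change, sd_pre, sd_post, r)
    if (distribution == "lognormal") {
      m$pre <- exp(m$pre); m$post <- exp(m$post)
    }
    new_paired_data(as.character(seq_len(n)), drop(m$pre), drop(m$post))
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# Matrix generator (pairs x replicates) used by the sweep/bias machinery:
# Cholesky construction post | pre via r*z1 + sqrt(1-r^2)*z2.
draw_pairs_matrix <- function(n, reps, mean_pre, mean_change,
                              sd_pre, sd_post, r) {
  z1 <- matrix(rnorm(n * reps), nrow = n)
  z2 <- matrix(rnorm(n * reps), nrow = n)
  pre <- mean_pre + sd_pre * z1
  post <- mean_pre + mean_change + sd_post * (r * z1 + sqrt(1 - r^2) * z2)
  list(pre = pre, post = post)
}

#' Monte Carlo sweep configuration
#'
#' Defines a grid of simulated pre-post studies: every combination of
#' pre-post correlation and pre-intervention SD is a cell, and each cell is
#' simulated `replicates` times with `n` pairs. The defaults reproduce the
#' estimator-property study shipped with the package: n = 20 participants,
#' mean change 1, 1000 replicates per cell, correlations from -0.5 up to
#' 0.95 and pre-intervention SDs from 0.25 to 3 — spanning the regimes where
#' the signal-to-noise SMD blows up (r near 1) and where every SMD blows up
#' (spread near 0).
#'
#' @param n Pairs per simulated study.
#' @param mean_pre Baseline mean.
#' @param mean_change True mean change \eqn{\bar\delta}.
#' @param sd_pre_grid Vector of pre-intervention SDs.
#' @param sd_post_rule `"equal"` (post SD = pre SD) or a numeric vector
#'   parallel to `sd_pre_grid`.
#' @param r_grid Vector of pre-post correlations strictly inside (-1, 1).
#' @param replicates Simulated studies per cell (>= 1).
#' @param seed Master seed; per-cell substreams are derived from it (see
#'   [sim_sweep()]).
#' @param distribution Passed to the generator.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 20, mean_pre = 0, mean_change = 1,
                       sd_pre_grid = c(0.25, 0.5, 1, 2, 3),
                       sd_post_rule = "equal",
                       r_grid = c(-0.5, -0.25, 0, 0.25, 0.5, 0.75, 0.9, 0.95),
                       replicates = 1000, seed = 1L,
                       distribution = c("normal", "lognormal")) {
  distribution <- rlang::arg_match(distribution)
  if (!is.numeric(sd_pre_grid) || any(!is.finite(sd_pre_grid)) ||
      any(sd_pre_grid <= 0)) {
    stop_invalid_input("`sd_pre_grid` must be finite and > 0.")
  }
  if (!is.numeric(r_grid) || any(!is.finite(r_grid)) || any(abs(r_grid) >= 1)) {
    stop_invalid_input("`r_grid` values must lie strictly inside (-1, 1).")
  }
  if (!is.numeric(replicates) || replicates < 1) {
    stop_invalid_input("`replicates` must be >= 1.")
  }
  sd_post_grid <- if (identical(sd_post_rule, "equal")) {
    sd_pre_grid
  } else {
    if (!is.numeric(sd_post_rule) || length(sd_post_rule) != length(sd_pre_grid)) {
      stop_invalid_input("`sd_post_rule` must be \"equal\" or a numeric vector parallel to `sd_pre_grid`.")
    }
    sd_post_rule
  }
  structure(list(
    n = as.integer(n), mean_pre = mean_pre, mean_change = mean_change,
    sd_pre_grid = sd_pre_grid, sd_post_grid = sd_post_grid,
    r_grid = r_grid, replicates = as.integer(replicates),
    seed = as.integer(seed), distribution = distribution
  ), class = "sim_config")
}

#' Read a sweep configuration from a flat YAML/JSON file
#'
#' Recognised keys match the arguments of [sim_config()] (with
#' `sd_pre_grid`, `r_grid` as sequences); unknown keys are rejected.
#'
#' @param path Path to the file.
#' @return A `sim_config` list.
#' @export
read_sim_config <- function(path) {
  vals <- read_flat_yaml(path)
  allowed <- c("n", "mean_pre", "mean_change", "sd_pre_grid", "sd_post_rule",
               "r_grid", "replicates", "seed", "distribution")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0L) {
    stop_invalid_input(sprintf("Unknown simulation config key(s): %s.",
                               paste(unknown, collapse = ", ")))
  }
  vals$sd_pre_grid <- unlist(vals$sd_pre_grid)
  vals$r_grid <- unlist(vals$r_grid)
  if (!is.null(vals$sd_post_rule) && !identical(vals$sd_post_rule, "equal")) {
    vals$sd_post_rule <- unlist(vals$sd_post_rule)
  }
  do.call(sim_config, vals)
}

# Deterministic per-cell substreams: seeding the master stream once and
# drawing one sub-seed per cell makes each cell's draws independent of the
# order in which cells are executed.
cell_seeds <- function(master_seed, n_cells) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max, n_cells))
}

#' Monte Carlo sweep over correlation and baseline-spread grids
#'
#' For every (r, sd_pre) cell, simulates `replicates` paired studies,
#' computes all four SMD families per study (uncorrected and
#' Hedges-corrected), and aggregates the mean estimate, the empirical SD of
#' estimates (the empirical standard error), the empirical bias against the
#' true population value, and — for d_z and Delta_pre — the closed-form
#' sampling variance evaluated at the true value, so formula and simulation
#' can be compared side by side.
#'
#' True population values under the equal-variance generator: Delta_pre,
#' d_av and d_rm all equal `mean_change / sd_pre`, while d_z equals
#' `mean_change / sqrt(2 * sd_pre^2 * (1 - r))` — a function of both the
#' spread *and* the correlation, which is precisely the property the sweep
#' visualises.
#'
#' @param config A [sim_config()] object.
#' @return A tibble of class `smd_sweep`: one row per cell x family x
#'   correction status with columns `r`, `sd_pre`, `family`, `corrected`,
#'   `mean_estimate`, `emp_se`, `bias`, `true_value`, `formula_variance`,
#'   `n_replicates`, `n_dropped`.
#' @examples
#' res <- sim_sweep(sim_config(r_grid = c(0, 0.5), sd_pre_grid = 1,
#'                             replicates = 200, seed = 2))
#' @export
sim_sweep <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_invalid_input("`config` must come from sim_config() / read_sim_config().")
  }
  grid <- tidyr::expand_grid(
    r = config$r_grid,
    sd_idx = seq_along(config$sd_pre_grid)
  )
  seeds <- cell_seeds(config$seed, nrow(grid))
  n <- config$n
  cf <- hedges_c(n - 1)

  cells <- purrr::pmap(
    list(grid$r, grid$sd_idx, seeds),
    function(r, sd_idx, cell_seed) {
      sd_pre <- config$sd_pre_grid[sd_idx]
      sd_post <- config$sd_post_grid[sd_idx]
      cs <- withr::with_seed(cell_seed, {
        m <- draw_pairs_matrix(n, config$replicates, config$mean_pre,
                               config$mean_change, sd_pre, sd_post, r)
        if (config$distribution == "lognormal") {
          m$pre <- exp(m$pre); m$post <- exp(m$post)
        }
        col_paired_stats(m$pre, m$post)
      })
      sd_delta_true <- sqrt(sd_pre^2 + sd_post^2 - 2 * r * sd_pre * sd_post)
      purrr::map_dfr(smd_families, function(fam) {
        est <- family_stat(fam, cs)
        ok <- est[!is.na(est)]
        true_value <- switch(fam,
          dz = config$mean_change / sd_delta_true,
          config$mean_change / sd_pre
        )
        fv <- switch(fam,
          dz = var_dz(true_value, n),
          delta_pre = var_delta_pre(true_value, n, r),
          NA_real_
        )
        tibble(
          r = r, sd_pre = sd_pre,
          family = fam, corrected = c(FALSE, TRUE),
          mean_estimate = c(mean(ok), mean(ok) * cf),
          emp_se = c(sd(ok), sd(ok) * cf),
          bias = c(mean(ok) - true_value, mean(ok) * cf - true_value),
          true_value = true_value,
          formula_variance = c(fv, fv * cf^2),
          n_replicates = length(ok),
          n_dropped = sum(is.na(est))
        )
      })
    }
  )
  out <- dplyr::bind_rows(cells)
  attr(out, "config") <- config
  class(out) <- c("smd_sweep", class(out))
  out
}

#' Write sweep results to tidy CSV and/or a JSON summary
#'
#' @param result An `smd_sweep` tibble from [sim_sweep()].
#' @param csv,json Output paths; either may be `NULL` to skip.
#' @return `result`, invisibly.
#' @export
write_sim_result <- function(result, csv = NULL, json = NULL) {
  if (!inherits(result, "smd_sweep")) {
    stop_invalid_input("`result` must come from sim_sweep().")
  }
  if (!is.null(csv)) readr::write_csv(result, csv)
  if (!is.null(json)) {
    cfg <- attr(result, "config")
    jsonlite::write_json(
      list(config = unclass(cfg), cells = as.data.frame(result)),
      json, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(result)
}

#' Per-study SMD estimates from simulated paired studies
#'
#' Simulates `replicates` independent paired studies from the bivariate
#' normal generator and returns the uncorrected estimate of one SMD family
#' for each study. This is the raw material for empirical checks of the
#' bias and variance laws: its sample mean estimates
#' \eqn{E[\hat d] = d/c(n-1)} and its sample variance estimates the
#' closed-form sampling variance.
#'
#' @param n Pairs per study (>= 2).
#' @param replicates Number of simulated studies.
#' @param mean_change True mean change.
#' @param sd_pre,sd_post Generator SDs.
#' @param r Generator pre-post correlation, strictly inside (-1, 1).
#' @param family One of `"dz"`, `"delta_pre"`, `"d_av"`, `"d_rm"`.
#' @param seed Integer seed.
#' @return A numeric vector of per-study estimates (degenerate studies,
#'   which have probability zero under this generator, would be dropped).
#' @examples
#' est <- simulate_estimates(20, 1000, mean_change = 0.5, r = 0.5,
#'                           family = "dz", seed = 4)
#' mean(est); var(est)
#' @export
simulate_estimates <- function(n, replicates, mean_change = 0,
                               sd_pre = 1, sd_post = sd_pre, r = 0.5,
                               family = c("dz", "delta_pre", "d_av", "d_rm"),
                               seed = 1L) {
  family <- rlang::arg_match(family)
  if (!is.numeric(n) || n < 2) stop_invalid_input("`n` must be >= 2.")
  if (!is.numeric(r) || abs(r) >= 1) {
    stop_invalid_input("`r` must lie strictly inside (-1, 1).")
  }
  if (sd_pre <= 0 || sd_post <= 0) stop_invalid_input("SDs must be > 0.")
  cs <- withr::with_seed(as.integer(seed), {
    m <- draw_pairs_matrix(as.integer(n), as.integer(replicates), 0,
                           mean_change, sd_pre, sd_post, r)
    col_paired_stats(m$pre, m$post)
  })
  est <- family_stat(family, cs)
  est[!is.na(est)]
}

#' Empirical validation of the small-sample bias law
#'
#' Simulates `replicates` studies of `n` pairs with a known true effect and
#' returns the ratio of the mean uncorrected estimate to the true value
#' (expected ~ 1/c(n-1)) alongside the Hedges-corrected ratio (expected
#' ~ 1). When `true_effect = 0` the ratio is undefined and the absolute
#' biases are returned instead.
#'
#' @param n Pairs per study (>= 4).
#' @param true_effect True population SMD for the chosen family.
#' @param family `"dz"` or `"delta_pre"`.
#' @param replicates Simulated studies (default 1e4).
#' @param seed Integer seed.
#' @param r Pre-post correlation of the generator (default 0.5, which makes
#'   the change-score SD equal the pre SD so `true_effect` means the same
#'   thing for both families).
#' @return A one-row tibble with `family`, `n`, `replicates`, `measure`
#'   (`"ratio"` or `"absolute_bias"`), `uncorrected`, `mc_se_uncorrected`,
#'   `corrected`, `mc_se_corrected`, `expected_uncorrected` (= 1/c(n-1) for
#'   ratios, 0 for absolute bias).
#' @examples
#' validate_bias(10, 0.5, "dz", replicates = 5000, seed = 3)
#' @export
validate_bias <- function(n, true_effect, family = c("dz", "delta_pre"),
                          replicates = 1e4, seed = 1L, r = 0.5) {
  family <- rlang::arg_match(family)
  if (!is.numeric(n) || n < 4) stop_invalid_input("`n` must be >= 4.")
  check_number(true_effect, "true_effect")
  if (replicates < 1) stop_invalid_input("`replicates` must be >= 1.")
  n <- as.integer(n); replicates <- as.integer(replicates)
  # Equal SDs of 1 with correlation r: sd_delta = sqrt(2(1 - r)); pick the
  # mean change that makes the requested family's true value = true_effect.
  sd_delta <- sqrt(2 * (1 - r))
  mean_change <- if (family == "dz") true_effect * sd_delta else true_effect
  cs <- withr::with_seed(as.integer(seed), {
    m <- draw_pairs_matrix(n, replicates, 0, mean_change, 1, 1, r)
    col_paired_stats(m$pre, m$post)
  })
  est <- family_stat(family, cs)
  est <- est[!is.na(est)]
  cf <- hedges_c(n - 1)
  if (true_effect == 0) {
    tibble(
      family = family, n = n, replicates = length(est),
      measure = "absolute_bias",
      uncorrected = mean(est), mc_se_uncorrected = sd(est) / sqrt(length(est)),
      corrected = mean(est) * cf, mc_se_corrected = cf * sd(est) / sqrt(length(est)),
      expected_uncorrected = 0
    )
  } else {
    tibble(
      family = family, n = n, replicates = length(est),
      measure = "ratio",
      uncorrected = mean(est) / true_effect,
      mc_se_uncorrected = sd(est) / sqrt(length(est)) / abs(true_effect),
      corrected = mean(est) * cf / true_effect,
      mc_se_corrected = cf * sd(est) / sqrt(length(est)) / abs(true_effect),
      expected_uncorrected = 1 / cf
    )
  }
}
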