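#' Estimate standardized mean differences
#'
#' The main estimation verb: takes raw paired data or printed summary
#' statistics, returns one tidy row per requested SMD family with optional
#' Hedges correction and confidence interval. Pipe-friendly:
#' `paired_data(df) |> smd("delta_pre", correction = "hedges", ci = "wald")`.
#'
#' Requirements by family when starting from summary statistics:
#' d_z needs `sd_change` (or `t_stat` with n, or `sd_pre`, `sd_post` and `r`
#' through the change-variance identity); Delta_pre needs `sd_pre`; d_av
#' needs both SDs; d_rm needs both SDs and `r`. A request that cannot be met
#' fails with a `missing_input` error naming the absent fields rather than
#' silently returning fewer rows.
#'
#' Closed-form (Wald) intervals exist for d_z and Delta_pre only; d_av and
#' d_rm must use the bootstrap, which in turn needs raw data.
#'
#' @param data A [paired_data] or [summary_stats] object (or a plain data
#'   frame with `pre`/`post` columns, coerced via [paired_data()]).
#' @param family Character vector of families among
#'   `"delta_pre"`, `"dz"`, `"d_av"`, `"d_rm"`, or `"all"`.
#' @param correction `"none"` or `"hedges"` (paired df m = n - 1).
#' @param ci `"none"`, `"wald"`, `"boot_percentile"` or `"boot_bca"`.
#' @param level Confidence level in (0, 1).
#' @param replicates Bootstrap replicates (when `ci` is a bootstrap method).
#' @param seed Seed for the bootstrap.
#' @param exact_correction Use the exact gamma-ratio Hedges factor.
#' @return An `smd_estimate` tibble: one row per family with columns
#'   `family`, `estimate`, `corrected`, `correction_factor`, `df`, `n`, and
#'   (with a CI) `variance`, `se`, `lower`, `upper`, `level`, `ci_method`,
#'   `replicates`, `seed`.
#' @examples
#' generate_paired(20, mean_change = 0.5, sd_pre = 1, r = 0.7, seed = 1) |>
#'   smd(c("delta_pre", "dz"), correction = "hedges", ci = "wald")
#' @export
smd <- function(data, family = "delta_pre",
                correction = c("none", "hedges"),
                ci = c("none", "wald", "boot_percentile", "boot_bca"),
                level = 0.95, replicates = 2000, seed = NULL,
                exact_correction = FALSE) {
  correction <- rlang::arg_match(correction)
  ci <- rlang::arg_match(ci)
  if (identical(family, "all")) family <- smd_families
  bad <- setdiff(family, smd_families)
  if (length(bad) > 0L) {
    stop_invalid_family(sprintf(
      "Unknown SMD family: %s. Choose among %s.",
      paste(bad, collapse = ", "), paste(smd_families, collapse = ", ")
    ))
  }

  raw <- NULL
  if (is.data.frame(data) && !is_summary_stats(data) && !is_paired_data(data)) {
    data <- paired_data(data)
  }
  if (is_paired_data(data)) {
    raw <- data
    stats <- change_stats(data)
  } else if (is_summary_stats(data)) {
    stats <- data
  } else {
    stop_invalid_input("`data` must be paired data or summary statistics.")
  }

  if (startsWith(ci, "boot") && is.null(raw)) {
    stop_missing_input(
      "Bootstrap intervals resample subjects and therefore need raw paired data, not summary statistics.",
      fields = "raw data"
    )
  }
  if (ci == "wald" && any(family %in% c("d_av", "d_rm"))) {
    stop_invalid_input(
      "No closed-form variance is implemented for d_av / d_rm; use a bootstrap interval (requires raw data)."
    )
  }

  n <- stats$n
  # lapply, not purrr::map: typed errors (e.g. missing_input) must propagate
  # with their own condition class for callers and the CLI exit-code map
  rows <- lapply(family, function(fam) {
    est <- point_from_stats(fam, stats)
    row <- new_smd_estimate(fam, est$value, n)
    if (ci == "wald") {
      v <- switch(fam,
        dz = var_dz(est$value, n, exact = exact_correction),
        delta_pre = {
          if (is.na(stats$r)) {
            stop_missing_input(
              "The Delta_pre variance formula needs the pre-post correlation `r`.",
              fields = "r"
            )
          }
          var_delta_pre(est$value, n, stats$r, exact = exact_correction)
        }
      )
      iv <- wald_ci(est$value, v, level)
      row <- add_interval_cols(row, iv)
    } else if (startsWith(ci, "boot")) {
      iv <- bootstrap_ci(raw, fam, level = level, replicates = replicates,
                         seed = seed,
                         method = sub("boot_", "", ci))
      row <- add_interval_cols(row, iv)
    }
    if (correction == "hedges") {
      row <- hedges_g(row, exact = exact_correction)
      if (startsWith(ci, "boot")) {
        # bootstrap bounds describe the uncorrected statistic's sampling
        # distribution; shrink them with the same factor as the point
        row$lower <- row$lower * row$correction_factor
        row$upper <- row$upper * row$correction_factor
      } else if (ci == "wald") {
        z <- qnorm((1 + level) / 2)
        row$lower <- row$estimate - z * row$se
        row$upper <- row$estimate + z * row$se
      }
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("smd_estimate", setdiff(class(out), "smd_estimate"))
  out
}

point_from_stats <- function(fam, stats) {
  need <- function(ok, fields, what) {
    if (!ok) {
      stop_missing_input(sprintf(
        "Cannot compute %s from the supplied summary statistics: missing %s.",
        what, paste(fields, collapse = ", ")
      ), fields = fields)
    }
  }
  has <- function(x) !is.na(x)
  switch(fam,
    dz = {
      if (has(stats$mean_change) && has(stats$sd_change)) {
        list(value = cohen_dz(stats$mean_change, stats$sd_change), source = "sd_change")
      } else if (has(stats$t_stat)) {
        list(value = dz_from_t(stats$t_stat, stats$n), source = "t")
      } else {
        need(FALSE, c("sd_change (or sd_pre + sd_post + r)", "t"), "d_z")
      }
    },
    delta_pre = {
      need(has(stats$mean_change) && has(stats$sd_pre),
           c("mean_change", "sd_pre")[c(!has(stats$mean_change), !has(stats$sd_pre))],
           "Glass's Delta_pre")
      list(value = glass_delta_pre(stats$mean_change, stats$sd_pre), source = "summary")
    },
    d_av = {
      need(has(stats$mean_change) && has(stats$sd_pre) && has(stats$sd_post),
           c("mean_change", "sd_pre", "sd_post")[
             c(!has(stats$mean_change), !has(stats$sd_pre), !has(stats$sd_post))],
           "d_av")
      list(value = cohen_dav(stats$mean_change, stats$sd_pre, stats$sd_post),
           source = "summary")
    },
    d_rm = {
      need(has(stats$mean_change) && has(stats$sd_pre) && has(stats$sd_post) &&
             has(stats$r),
           c("mean_change", "sd_pre", "sd_post", "r")[
             c(!has(stats$mean_change), !has(stats$sd_pre),
               !has(stats$sd_post), !has(stats$r))],
           "d_rm")
      list(value = cohen_drm(stats$mean_change, stats$sd_pre, stats$sd_post,
                             stats$r),
           source = "summary")
    }
  )
}

add_interval_cols <- function(row, iv) {
  row$variance <- iv$variance
  row$se <- iv$se
  row$lower <- iv$lower
  row$upper <- iv$upper
  row$level <- iv$level
  row$ci_method <- iv$method
  row$replicates <- iv$replicates
  row$seed <- iv$seed
  row
}
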