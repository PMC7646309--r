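#' Construct a paired (pre/post) sample
#'
#' Assembles a tidy paired sample from a data frame with one row per subject.
#' Rows with a missing pre or post value are incomplete pairs: they are
#' dropped and the number dropped is reported via a message and stored in the
#' `n_dropped` attribute.
#'
#' @param data A data frame with one row per subject.
#' @param pre,post Columns (tidy-eval) holding the pre- and post-intervention
#'   measurements, in the same outcome units.
#' @param id Optional column of subject labels; row numbers are used when
#'   absent.
#'
#' @return A tibble of class `paired_data` with columns `id`, `pre`, `post`
#'   and at least 2 complete pairs.
#' @examples
#' d <- data.frame(pre = c(3.8, 4.1, 3.9), post = c(4.0, 4.3, 4.1))
#' paired_data(d)
#' @export
paired_data <- function(data, pre = pre, post = post, id = NULL) {
  if (!is.data.frame(data)) {
    stop_invalid_input("`data` must be a data frame of one row per subject.")
  }
  pre_v <- rlang::eval_tidy(rlang::enquo(pre), data)
  post_v <- rlang::eval_tidy(rlang::enquo(post), data)
  id_q <- rlang::enquo(id)
  id_v <- if (rlang::quo_is_null(id_q)) {
    as.character(seq_len(nrow(data)))
  } else {
    as.character(rlang::eval_tidy(id_q, data))
  }
  new_paired_data(id_v, pre_v, post_v)
}

new_paired_data <- function(id, pre, post) {
  if (!is.numeric(pre) || !is.numeric(post)) {
    stop_invalid_input("`pre` and `post` must be numeric measurement vectors.")
  }
  if (length(pre) != length(post)) {
    stop_invalid_input("`pre` and `post` must have the same length.")
  }
  complete <- is.finite(pre) & is.finite(post)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    inform(sprintf("Dropped %d incomplete pair(s).", n_dropped))
  }
  out <- tibble(
    id = id[complete],
    pre = as.double(pre[complete]),
    post = as.double(post[complete])
  )
  if (nrow(out) < 2L) {
    stop_insufficient_data("At least 2 complete pre/post pairs are required.")
  }
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("paired_data", class(out))
  out
}

is_paired_data <- function(x) inherits(x, "paired_data")

#' Read a paired sample from CSV
#'
#' Two dialects are supported. *Wide*: columns `id`, `pre`, `post`, one row
#' per subject. *Long*: columns `id`, `time` (values `pre`/`post`) and
#' `value`, pivoted internally; subjects lacking either time point are
#' dropped with a message.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param format `"wide"` (default) or `"long"`.
#' @return A [paired_data] tibble.
#' @export
read_paired_csv <- function(path, format = c("wide", "long")) {
  format <- rlang::arg_match(format)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (format == "wide") {
    need <- c("id", "pre", "post")
    if (!all(need %in% names(raw))) {
      stop_invalid_input(sprintf(
        "Wide CSV must have columns id, pre, post; found: %s",
        paste(names(raw), collapse = ", ")
      ))
    }
    return(paired_data(raw, pre = pre, post = post, id = id))
  }
  need <- c("id", "time", "value")
  if (!all(need %in% names(raw))) {
    stop_invalid_input(sprintf(
      "Long CSV must have columns id, time, value; found: %s",
      paste(names(raw), collapse = ", ")
    ))
  }
  bad_time <- setdiff(unique(raw$time), c("pre", "post"))
  if (length(bad_time) > 0L) {
    stop_invalid_input(sprintf(
      "`time` must be 'pre' or 'post'; found: %s", paste(bad_time, collapse = ", ")
    ))
  }
  wide <- tidyr::pivot_wider(raw, id_cols = "id", names_from = "time",
                             values_from = "value")
  for (col in c("pre", "post")) if (!col %in% names(wide)) wide[[col]] <- NA_real_
  paired_data(wide, pre = pre, post = post, id = id)
}

#' Summary statistics of a paired sample
#'
#' Computes the sufficient statistics used by every SMD estimator directly
#' from the change scores \eqn{\delta_i = post_i - pre_i}: sample means and
#' SDs (n-1 denominator), the Pearson pre-post correlation, the mean change
#' and the SD of change scores. When raw data are available this direct
#' `sd_change` is always preferred over the equal-variance identity
#' \eqn{\sigma_\delta = \sqrt{2\sigma^2(1-r)}}.
#'
#' @param sample A [paired_data] tibble.
#' @return A one-row `summary_stats` tibble with columns `n`, `mean_pre`,
#'   `mean_post`, `sd_pre`, `sd_post`, `r`, `mean_change`, `sd_change`,
#'   `t_stat` (NA here; populated when ingested from printed statistics).
#' @examples
#' change_stats(paired_data(data.frame(pre = c(1, 2, 3), post = c(2, 3, 4))))
#' @export
change_stats <- function(sample) {
  if (!is_paired_data(sample)) {
    stop_invalid_input("`sample` must be a `paired_data` object; see `paired_data()`.")
  }
  n <- nrow(sample)
  if (n < 2L) stop_insufficient_data("At least 2 pairs are required.")
  delta <- sample$post - sample$pre
  sd_pre <- sd(sample$pre)
  sd_post <- sd(sample$post)
  r <- if (sd_pre > 0 && sd_post > 0) cor(sample$pre, sample$post) else NA_real_
  new_summary_stats(
    n = n,
    mean_pre = mean(sample$pre), mean_post = mean(sample$post),
    sd_pre = sd_pre, sd_post = sd_post, r = r,
    mean_change = mean(delta), sd_change = sd(delta),
    t_stat = NA_real_
  )
}

new_summary_stats <- function(n, mean_pre, mean_post, sd_pre, sd_post, r,
                              mean_change, sd_change, t_stat) {
  out <- tibble(
    n = as.integer(n),
    mean_pre = as.double(mean_pre), mean_post = as.double(mean_post),
    sd_pre = as.double(sd_pre), sd_post = as.double(sd_post),
    r = as.double(r),
    mean_change = as.double(mean_change), sd_change = as.double(sd_change),
    t_stat = as.double(t_stat)
  )
  class(out) <- c("summary_stats", class(out))
  out
}

is_summary_stats <- function(x) inherits(x, "summary_stats")

# Relative tolerance for cross-checks among printed statistics; generous
# enough to absorb rounding in published tables (e.g. a mean change printed
# as 0.23 against means printed as 4.13 and 3.89).
.summary_rel_tol <- 0.05

rel_diff <- function(a, b) {
  abs(a - b) / max(abs(a), abs(b), .Machine$double.eps)
}

#' Assemble summary statistics from printed values
#'
#' Builds a `summary_stats` record from published statistics (as opposed to
#' raw data, for which see [change_stats()]). Derivable fields are filled in
#' where possible: `mean_change` from the means, `sd_change` from the
#' equal-variance-free identity
#' \eqn{\sigma_\delta^2 = \sigma_{pre}^2 + \sigma_{post}^2 -
#' 2 r \sigma_{pre}\sigma_{post}}. Redundant inputs are cross-checked at a
#' relative tolerance of 0.05 (printed values are rounded); inconsistencies
#' raise a warning and the supplied value is kept, never overwritten.
#'
#' @param n Number of complete pairs (>= 2).
#' @param mean_pre,mean_post,sd_pre,sd_post Means and SDs in outcome units.
#' @param r Pearson pre-post correlation in \[-1, 1\].
#' @param mean_change,sd_change Mean and SD of change scores (outcome units).
#' @param t_stat Paired t-statistic, when that is what the source reports.
#' @return A one-row `summary_stats` tibble.
#' @examples
#' summary_stats(n = 8, t_stat = 3.54)
#' summary_stats(n = 10, mean_pre = 46, mean_post = 27, sd_pre = 11, sd_post = 7)
#' @export
summary_stats <- function(n, mean_pre = NA, mean_post = NA,
                          sd_pre = NA, sd_post = NA, r = NA,
                          mean_change = NA, sd_change = NA, t_stat = NA) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 2) {
    stop_insufficient_data("`n` must be a single pair count >= 2.")
  }
  num1 <- function(x, name) {
    if (length(x) != 1L) stop_invalid_input(sprintf("`%s` must be length 1.", name))
    as.double(x)
  }
  mean_pre <- num1(mean_pre, "mean_pre"); mean_post <- num1(mean_post, "mean_post")
  sd_pre <- num1(sd_pre, "sd_pre"); sd_post <- num1(sd_post, "sd_post")
  r <- num1(r, "r"); mean_change <- num1(mean_change, "mean_change")
  sd_change <- num1(sd_change, "sd_change"); t_stat <- num1(t_stat, "t_stat")

  for (nm in c("sd_pre", "sd_post", "sd_change")) {
    v <- get(nm)
    if (!is.na(v) && v < 0) stop_invalid_input(sprintf("`%s` must be >= 0.", nm))
  }
  if (!is.na(r) && (r < -1 || r > 1)) {
    stop_invalid_input("`r` must lie in [-1, 1].")
  }

  derived_mc <- if (!is.na(mean_pre) && !is.na(mean_post)) mean_post - mean_pre else NA_real_
  if (!is.na(mean_change) && !is.na(derived_mc) &&
      rel_diff(mean_change, derived_mc) > .summary_rel_tol) {
    warn(sprintf(
      "`mean_change` (%g) is inconsistent with mean_post - mean_pre (%g); keeping the supplied value.",
      mean_change, derived_mc
    ))
  }
  if (is.na(mean_change)) mean_change <- derived_mc

  derived_sdc <- if (!is.na(sd_pre) && !is.na(sd_post) && !is.na(r)) {
    sqrt(max(sd_pre^2 + sd_post^2 - 2 * r * sd_pre * sd_post, 0))
  } else {
    NA_real_
  }
  if (!is.na(sd_change) && !is.na(derived_sdc) &&
      rel_diff(sd_change^2, derived_sdc^2) > .summary_rel_tol) {
    warn(sprintf(
      "`sd_change` (%g) is inconsistent with the value implied by sd_pre, sd_post and r (%g); keeping the supplied value.",
      sd_change, derived_sdc
    ))
  }
  if (is.na(sd_change)) sd_change <- derived_sdc

  new_summary_stats(n, mean_pre, mean_post, sd_pre, sd_post, r,
                    mean_change, sd_change, t_stat)
}

# Flat YAML/JSON reader that protects bare keys from YAML 1.1 boolean
# resolution ('n', 'y', 'no', ... would otherwise parse as logicals and the
# key name would be lost).
read_flat_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  quoted <- sub("^(\\s*)([A-Za-z_][A-Za-z0-9_.]*)(\\s*):", '\\1"\\2"\\3:', lines)
  yaml::yaml.load(paste(quoted, collapse = "\n"))
}

# Keys accepted in flat summary-statistic config files; `t` maps to t_stat.
.summary_keys <- c("n", "mean_pre", "mean_post", "sd_pre", "sd_post",
                   "r", "t", "mean_change", "sd_change")

#' Read printed summary statistics from a flat YAML/JSON file
#'
#' The file must be a flat mapping using keys `n`, `mean_pre`, `mean_post`,
#' `sd_pre`, `sd_post`, `r`, `t`, `mean_change`, `sd_change`; unknown keys
#' are rejected so typos cannot silently drop an input.
#'
#' @param path Path to a YAML (or JSON) file.
#' @return A one-row `summary_stats` tibble.
#' @export
read_summary_stats <- function(path) {
  vals <- read_flat_yaml(path)
  if (!is.list(vals) || is.null(names(vals))) {
    stop_invalid_input("Summary-statistics file must be a flat key: value mapping.")
  }
  unknown <- setdiff(names(vals), .summary_keys)
  if (length(unknown) > 0L) {
    stop_invalid_input(sprintf(
      "Unknown summary-statistics key(s): %s. Allowed: %s.",
      paste(unknown, collapse = ", "), paste(.summary_keys, collapse = ", ")
    ))
  }
  if (is.null(vals$n)) stop_missing_input("Key `n` is required.", fields = "n")
  get_or_na <- function(key) vals[[key]] %||% NA_real_
  summary_stats(
    n = vals$n,
    mean_pre = get_or_na("mean_pre"), mean_post = get_or_na("mean_post"),
    sd_pre = get_or_na("sd_pre"), sd_post = get_or_na("sd_post"),
    r = get_or_na("r"),
    mean_change = get_or_na("mean_change"), sd_change = get_or_na("sd_change"),
    t_stat = get_or_na("t")
  )
}
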