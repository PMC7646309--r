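#' Common language effect size from Cohen's d_z
#'
#' \eqn{CLES = \Phi(d_z)}: under normality of change scores, the probability
#' that a randomly selected individual's change score is greater than zero
#' (also called the probability of superiority). CLES > 0.5 exactly when
#' d_z > 0.
#'
#' @param dz Cohen's d_z (finite).
#' @return A probability in (0, 1).
#' @examples
#' cles_from_dz(0.25)   # ~0.599
#' @export
cles_from_dz <- function(dz) {
  dz <- check_numeric_vec(dz, "dz")
  pnorm(dz)
}

#' Cohen's d_z from a common language effect size
#'
#' The inverse conversion \eqn{d_z = \Phi^{-1}(CLES)}; round-trips with
#' [cles_from_dz()].
#'
#' @param cles A probability strictly inside (0, 1).
#' @return Cohen's d_z.
#' @examples
#' dz_from_cles(0.5987)
#' @export
dz_from_cles <- function(cles) {
  cles <- check_numeric_vec(cles, "cles")
  if (any(cles <= 0) || any(cles >= 1)) {
    stop_invalid_input("`cles` must lie strictly inside (0, 1).")
  }
  qnorm(cles)
}

#' Percentile shift implied by a magnitude-based SMD
#'
#' Under a normal outcome distribution, a median individual who improves by
#' the expected change moves from the 50th percentile to
#' \eqn{100\,\Phi(\Delta)}. This is the interpretive device for
#' magnitude-based SMDs: e.g. \eqn{\Delta_{pre} = 0.5} moves the median
#' person to the 69th percentile.
#'
#' @param delta A magnitude-based SMD (finite).
#' @return The destination percentile in (0, 100).
#' @seealso [percentile_label()] for the rendered ordinal form.
#' @examples
#' percentile_shift(0.5)
#' @export
percentile_shift <- function(delta) {
  delta <- check_numeric_vec(delta, "delta")
  100 * pnorm(delta)
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

ordinal_suffix <- function(k) {
  k <- as.integer(k)
  last2 <- k %% 100L
  last1 <- k %% 10L
  ifelse(last2 %in% 11:13, "th",
         ifelse(last1 == 1L, "st",
                ifelse(last1 == 2L, "nd",
                       ifelse(last1 == 3L, "rd", "th"))))
}

#' Rendered percentile label for a magnitude-based SMD
#'
#' Rounds the [percentile_shift()] half away from zero to an integer and
#' attaches the ordinal suffix, e.g. `"69th"`.
#'
#' @inheritParams percentile_shift
#' @return A character vector like `"69th"`.
#' @examples
#' percentile_label(0.5)
#' percentile_label(0.25)
#' @export
percentile_label <- function(delta) {
  p <- round_half_away(percentile_shift(delta))
  paste0(format(p, trim = TRUE, scientific = FALSE), ordinal_suffix(p))
}
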