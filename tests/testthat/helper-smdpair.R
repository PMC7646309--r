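# Shared fixture builders. Everything is generated in code; no stored data.

# A small bivariate-normal paired sample with known generator parameters.
make_paired <- function(n = 20, mean_pre = 10, mean_change = 0.5,
                        sd_pre = 2, sd_post = sd_pre, r = 0.6, seed = 101) {
  generate_paired(n, mean_pre = mean_pre, mean_change = mean_change,
                  sd_pre = sd_pre, sd_post = sd_post, r = r, seed = seed)
}

# Independent textbook recomputation of paired summary statistics, written
# against sums rather than stats:: helpers, as an oracle for change_stats().
oracle_change_stats <- function(pre, post) {
  n <- length(pre)
  delta <- post - pre
  m <- function(x) sum(x) / n
  s <- function(x) sqrt(sum((x - m(x))^2) / (n - 1))
  r_num <- sum((pre - m(pre)) * (post - m(post)))
  r_den <- sqrt(sum((pre - m(pre))^2) * sum((post - m(post))^2))
  list(n = n, mean_pre = m(pre), mean_post = m(post),
       sd_pre = s(pre), sd_post = s(post), r = r_num / r_den,
       mean_change = m(delta), sd_change = s(delta))
}

# Explicit-formula paired t oracle: t = mean(delta) / (sd(delta)/sqrt(n)).
oracle_paired_t <- function(pre, post) {
  delta <- post - pre
  n <- length(delta)
  mean(delta) / (sd(delta) / sqrt(n))
}

# Round half away from zero (the package's rendering rule for percentages).
round_half_away2 <- function(x) sign(x) * floor(abs(x) + 0.5)

expect_smd_error <- function(expr, kind) {
  testthat::expect_error(expr, class = paste0("smdpair_error_", kind))
}
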