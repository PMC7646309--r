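# Column-wise paired summary statistics over matrices (pairs x replicates).
# Shared fast path for the bootstrap and the Monte Carlo simulator; sample
# moments use the n - 1 denominator throughout.

col_means <- function(m) .colMeans(m, nrow(m), ncol(m))

col_paired_stats <- function(pre, post) {
  n <- nrow(pre)
  mp <- col_means(pre)
  mq <- col_means(post)
  cp <- pre - rep(mp, each = n)
  cq <- post - rep(mq, each = n)
  ss_pre <- .colSums(cp * cp, n, ncol(pre))
  ss_post <- .colSums(cq * cq, n, ncol(pre))
  ss_cross <- .colSums(cp * cq, n, ncol(pre))
  sd_pre <- sqrt(ss_pre / (n - 1))
  sd_post <- sqrt(ss_post / (n - 1))
  denom <- sqrt(ss_pre * ss_post)
  r <- ifelse(denom > 0, ss_cross / denom, NA_real_)
  d <- post - pre
  md <- col_means(d)
  cd <- d - rep(md, each = n)
  sd_change <- sqrt(.colSums(cd * cd, n, ncol(pre)) / (n - 1))
  list(n = n, mean_change = md, sd_pre = sd_pre, sd_post = sd_post,
       r = r, sd_change = sd_change)
}

# Per-replicate estimator evaluation with NA (not an error) where the
# estimate is undefined; callers count and handle the degenerate columns.
family_stat <- function(family, cs) {
  switch(family,
    dz = ifelse(cs$sd_change > 0, cs$mean_change / cs$sd_change, NA_real_),
    delta_pre = ifelse(cs$sd_pre > 0, cs$mean_change / cs$sd_pre, NA_real_),
    d_av = {
      avg <- (cs$sd_pre + cs$sd_post) / 2
      ifelse(avg > 0, cs$mean_change / avg, NA_real_)
    },
    d_rm = {
      sdd <- sqrt(pmax(cs$sd_pre^2 + cs$sd_post^2 -
                         2 * cs$r * cs$sd_pre * cs$sd_post, 0))
      ifelse(!is.na(cs$r) & sdd > 0 & cs$r < 1,
             cs$mean_change / sdd * sqrt(2 * (1 - cs$r)), NA_real_)
    },
    stop_invalid_family(sprintf("Unknown SMD family '%s'.", family))
  )
}
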