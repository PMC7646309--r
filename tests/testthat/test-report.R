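test_that("paired_t matches the explicit-formula oracle", {
  pd <- make_paired(n = 8, mean_pre = 3.9, mean_change = 0.24, sd_pre = 0.2,
                    r = 0.5, seed = 71)
  tt <- paired_t(pd)
  expect_equal(tt$statistic, oracle_paired_t(pd$pre, pd$post),
               tolerance = 1e-10)
  expect_equal(tt$df, 7)
  expect_true(tt$p.value > 0 && tt$p.value <= 1)

  # symmetric null data: t = 0, p = 1
  sym <- paired_data(data.frame(pre = c(1, 2, 3, 4), post = c(2, 3, 2, 3)))
  t0 <- paired_t(sym)
  expect_equal(t0$statistic, 0, tolerance = 1e-12)
  expect_equal(t0$p.value, 1, tolerance = 1e-12)

  shift <- paired_data(data.frame(pre = 1:5, post = 3:7))
  expect_smd_error(paired_t(shift), "zero_variance")
})

test_that("a printed t of 3.54 with 8 pairs renders a CLES of 89%", {
  ss <- summary_stats(n = 8, t_stat = 3.54)
  bundle <- smd_analyze(ss, family = "dz", correction = "none", ci = "wald")
  expect_equal(bundle$cles$percent, 89)
  expect_match(bundle$narrative, "is 89%\\.$")
  expect_match(bundle$narrative, "experiencing an increase")
})

test_that("a printed t of -6.90 with 10 pairs renders a 99% reduction CLES", {
  ss <- summary_stats(n = 10, t_stat = -6.90)
  bundle <- smd_analyze(ss, family = "dz", correction = "none", ci = "wald")
  expect_equal(bundle$cles$percent, 99)
  expect_match(bundle$narrative, "experiencing a reduction is 99%\\.$")
})

test_that("a Delta_pre of 0.5 narrates the 69th-percentile shift", {
  ss <- summary_stats(n = 20, mean_change = 3.0, sd_pre = 6.05)
  bundle <- smd_analyze(ss, family = "delta_pre", correction = "none",
                        ci = "none")
  expect_equal(bundle$estimates$estimate, 3.0 / 6.05, tolerance = 1e-12)
  expect_equal(round(bundle$estimates$estimate, 1), 0.5)
  expect_match(bundle$narrative, "0\\.50")
  expect_match(bundle$narrative, "69th percentile")
})

test_that("narratives are deterministic and numbers re-parse to the fields", {
  pd <- make_paired(n = 8, mean_pre = 3.9, mean_change = 0.24, sd_pre = 0.2,
                    r = 0.5, seed = 71)
  b1 <- smd_analyze(pd, family = "delta_pre", ci = "wald")
  b2 <- smd_analyze(pd, family = "delta_pre", ci = "wald")
  expect_identical(b1$narrative, b2$narrative)
  expect_identical(render_narrative(b1), render_narrative(b1))

  nums <- as.numeric(unlist(regmatches(
    b1$narrative, gregexpr("-?[0-9]+\\.[0-9]+", b1$narrative)
  )))
  expected <- c(
    sprintf("%.2f", c(b1$stats$mean_post, b1$stats$sd_post,
                      b1$stats$mean_pre, b1$stats$sd_pre,
                      b1$t$statistic)),
    sub("p = ", "", fmt_p <- sprintf("%.3f", b1$t$p.value)),
    sprintf("%.2f", c(b1$t$mean_change, b1$t$conf.low, b1$t$conf.high,
                      b1$estimates$estimate, b1$estimates$lower,
                      b1$estimates$upper))
  )
  expect_equal(nums, as.numeric(expected))
})

test_that("analyze from raw data and from its own summary stats agree", {
  pd <- make_paired(n = 15, seed = 81)
  from_raw <- smd_analyze(pd, family = c("delta_pre", "dz"), ci = "none")
  from_sum <- smd_analyze(change_stats(pd), family = c("delta_pre", "dz"),
                          ci = "none")
  expect_equal(from_raw$estimates$estimate, from_sum$estimates$estimate,
               tolerance = 1e-12)
  expect_equal(from_raw$cles$cles, from_sum$cles$cles, tolerance = 1e-12)
})

test_that("underdetermined summary statistics fail with the missing fields", {
  ss <- summary_stats(n = 8, mean_change = 0.5)   # no SDs, no t
  err <- tryCatch(smd_analyze(ss, family = "delta_pre", ci = "none"),
                  smdpair_error_missing_input = function(e) e)
  expect_s3_class(err, "smdpair_error_missing_input")
  expect_true("sd_pre" %in% err$fields)
  expect_smd_error(smd(ss, "d_rm"), "missing_input")
})

test_that("percent-change input is refused with an explanation", {
  pd <- make_paired(seed = 91)
  err <- tryCatch(smd_analyze(pd, percent_change = TRUE),
                  smdpair_error_percent_change = function(e) e)
  expect_s3_class(err, "smdpair_error_percent_change")
  expect_match(conditionMessage(err), "percent-change")
  expect_match(conditionMessage(err), "cannot be recovered")
})

test_that("scenario style demands its fields; compact degrades gracefully", {
  ss <- summary_stats(n = 8, t_stat = 3.54)
  bundle <- smd_analyze(ss, family = "dz", correction = "none", ci = "none")
  err <- tryCatch(render_narrative(bundle, style = "scenario"),
                  smdpair_error_template_incomplete = function(e) e)
  expect_s3_class(err, "smdpair_error_template_incomplete")
  expect_true(length(err$fields) > 0)
  compact <- render_narrative(bundle, style = "compact")
  expect_match(compact, "t\\(7\\) = 3.54")
})

test_that("report bundles serialize to versioned JSON with provenance", {
  pd <- make_paired(n = 20, seed = 15)
  bundle <- smd_analyze(pd, family = "delta_pre", ci = "boot_percentile",
                        replicates = 300, seed = 42)
  js <- jsonlite::parse_json(report_json(bundle))
  expect_equal(js$provenance$schema_version, "1.0")
  expect_equal(js$provenance$seed, 42)
  expect_equal(js$estimates[[1]]$seed, 42)
  expect_equal(js$estimates[[1]]$replicates, 300)
  expect_identical(js$narrative, bundle$narrative)

  g <- glance(bundle)
  expect_equal(g$n, 20L)
  td <- tidy(bundle)
  expect_equal(td$term, "delta_pre")
})

test_that("null-effect bundles say 50%", {
  sym <- paired_data(data.frame(pre = c(1, 2, 3, 4, 5, 6),
                                post = c(2, 3, 2, 3, 4.5, 3.5)))
  cs <- change_stats(sym)
  ss <- summary_stats(n = 6, mean_change = 0, sd_change = cs$sd_change)
  bundle <- smd_analyze(ss, family = "dz", correction = "none", ci = "none")
  expect_equal(bundle$cles$percent, 50)
  expect_match(bundle$narrative, "is 50%\\.")
})
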