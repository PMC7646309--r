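test_that("Cohen's d_z is the mean change over the change-score SD", {
  expect_equal(cohen_dz(0, 1), 0)
  expect_equal(cohen_dz(1, 2), 0.5)
  expect_equal(cohen_dz(-1, 2), -0.5)

  # brute-force oracle on simulated lognormal scores analysed on the log scale
  pd <- generate_paired(10, mean_pre = 3.6, mean_change = -0.5, sd_pre = 0.25,
                        r = 0.4, seed = 23, distribution = "lognormal")
  lpre <- log(pd$pre); lpost <- log(pd$post)
  delta <- lpost - lpre
  cs <- change_stats(paired_data(data.frame(pre = lpre, post = lpost)))
  expect_equal(cohen_dz(cs$mean_change, cs$sd_change),
               mean(delta) / sd(delta), tolerance = 1e-12)

  expect_smd_error(cohen_dz(1, 0), "zero_variance")
  expect_error(cohen_dz(1, 0), "change scores have no spread")
  expect_smd_error(cohen_dz(1, -1), "invalid_input")
  expect_smd_error(cohen_dz(Inf, 1), "invalid_input")
})

test_that("d_z from the t-statistic is t over root n", {
  expect_equal(dz_from_t(0, 8), 0)
  expect_equal(dz_from_t(3.54, 8), 3.54 / sqrt(8), tolerance = 1e-12)
  expect_equal(dz_from_t(3.54, 8), 1.2515790, tolerance = 1e-6)
  expect_equal(dz_from_t(6.90, 10), 2.1819715, tolerance = 1e-6)
  expect_smd_error(dz_from_t(1, 0), "invalid_input")
})

test_that("Glass's Delta_pre is the mean change over the pre-test SD", {
  expect_equal(glass_delta_pre(3.0, 6.05), 3.0 / 6.05)
  expect_equal(round(glass_delta_pre(3.0, 6.05), 1), 0.5)
  expect_equal(glass_delta_pre(0, 5), 0)
  expect_equal(glass_delta_pre(0.23, 0.21), 0.23 / 0.21, tolerance = 1e-12)
  expect_smd_error(glass_delta_pre(1, 0), "zero_variance")
  expect_error(glass_delta_pre(1, 0), "pre-test scores have no spread")
})

test_that("d_av and d_rm follow their conventions and errors", {
  expect_equal(cohen_dav(2, 1, 3), 1)
  expect_equal(cohen_dav(0, 1, 3), 0)
  expect_equal(cohen_dav(3.0, 6.05, 6.05), glass_delta_pre(3.0, 6.05))
  expect_smd_error(cohen_dav(1, 0, 0), "zero_variance")

  expect_equal(cohen_drm(1, 1, 1, r = 0.5), 1)   # sd_delta = 1, factor = 1
  expect_equal(cohen_drm(0, 1, 1, r = 0.3), 0)
  expect_smd_error(cohen_drm(1, 1, 1, r = 1), "zero_variance")
  expect_smd_error(cohen_drm(1, 1, 2, r = 1.2), "invalid_input")
})

test_that("Delta_ppc subtracts control from treatment within the family", {
  expect_equal(delta_ppc(0.5, 0.2), 0.3)
  expect_equal(delta_ppc(0.4, 0.4), 0)

  trt <- smd(make_paired(seed = 1), "delta_pre")
  ctl <- smd(make_paired(mean_change = 0, seed = 2), "delta_pre")
  expect_equal(delta_ppc(trt, ctl), trt$estimate - ctl$estimate)

  wrong <- smd(make_paired(seed = 3), "dz")
  expect_smd_error(delta_ppc(wrong, ctl), "invalid_family")
})

test_that("Delta_ppc recovers a known population contrast by simulation", {
  # true Delta_pre = 0.8 in treatment, 0.0 in control, n = 500 each
  trt <- generate_paired(500, mean_change = 0.8, sd_pre = 1, r = 0.5, seed = 31)
  ctl <- generate_paired(500, mean_change = 0.0, sd_pre = 1, r = 0.5, seed = 32)
  est <- delta_ppc(smd(trt, "delta_pre"), smd(ctl, "delta_pre"))
  # 3 Monte-Carlo SEs of the contrast from the closed-form variances
  tol <- 3 * sqrt(var_delta_pre(0.8, 500, 0.5) + var_delta_pre(0, 500, 0.5))
  expect_lt(abs(est - 0.8), tol)
})

test_that("Hedges' factor matches its printed approximation and exact form", {
  expect_equal(hedges_c(14), 1 - 3 / 55)
  expect_equal(hedges_c(9), 1 - 3 / 35)
  expect_lt(abs(hedges_c(1e6) - 1), 1e-5)
  # strictly increasing toward 1, both variants
  ms <- c(2, 3, 5, 9, 14, 30, 100, 1000)
  for (exact in c(FALSE, TRUE)) {
    cc <- hedges_c(ms, exact = exact)
    expect_true(all(diff(cc) > 0))
    expect_true(all(cc > 0 & cc < 1))
  }
  # approximation within 0.2% of the exact factor for m >= 9
  ms9 <- 9:60
  expect_lt(max(abs(hedges_c(ms9) - hedges_c(ms9, TRUE)) / hedges_c(ms9, TRUE)),
            0.002)
  expect_smd_error(hedges_c(1), "invalid_df")
})

test_that("hedges_g shrinks estimates and refuses double correction", {
  expect_equal(hedges_g(1.0, m = 14), 1 - 3 / 55)
  expect_equal(hedges_g(0, m = 14), 0)
  d <- c(-2, -0.5, 0.3, 1.7)
  expect_true(all(abs(hedges_g(d, m = 9)) < abs(d)))

  est <- smd(make_paired(seed = 4), "delta_pre")
  g <- hedges_g(est)
  expect_true(g$corrected)
  expect_equal(g$df, est$n - 1L)
  expect_equal(g$estimate, est$estimate * hedges_c(est$n - 1))
  expect_smd_error(hedges_g(g), "already_corrected")
  expect_smd_error(hedges_g(0.5), "invalid_input")  # bare number needs m
})

test_that("CLES conversions match the normal CDF and round-trip", {
  expect_equal(cles_from_dz(0), 0.5)
  expect_equal(cles_from_dz(0.25), 0.5987, tolerance = 5e-4)
  expect_gt(cles_from_dz(11.62), 0.99)
  expect_true(all(diff(cles_from_dz(seq(-3, 3, 0.25))) > 0))

  expect_equal(dz_from_cles(0.5), 0)
  expect_equal(dz_from_cles(0.5987), 0.25, tolerance = 5e-4)
  grid <- seq(-3, 3, length.out = 61)
  expect_equal(dz_from_cles(cles_from_dz(grid)), grid, tolerance = 1e-9)

  expect_smd_error(cles_from_dz(Inf), "invalid_input")
  expect_smd_error(dz_from_cles(0), "invalid_input")
  expect_smd_error(dz_from_cles(1), "invalid_input")
})

test_that("percentile shift renders the expected ordinals", {
  expect_equal(percentile_shift(0), 50)
  expect_equal(percentile_shift(0.5), 69.1, tolerance = 0.05)
  expect_equal(percentile_shift(0.25), 59.9, tolerance = 0.05)
  expect_equal(percentile_label(0.5), "69th")
  expect_equal(percentile_label(0.25), "60th")
  expect_equal(percentile_label(0), "50th")
  expect_equal(percentile_label(qnorm(0.505)), "51st")
  expect_equal(percentile_label(qnorm(0.52)), "52nd")
  expect_equal(percentile_label(qnorm(0.113)), "11th")  # teens take 'th'
  expect_smd_error(percentile_shift(NaN), "invalid_input")
})
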