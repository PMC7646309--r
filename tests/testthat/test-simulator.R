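test_that("the paired-sample generator hits its parameters at large n", {
  pd <- generate_paired(1e5, mean_pre = 2, mean_change = 0.5, sd_pre = 1,
                        sd_post = 1, r = 0.7, seed = 14)
  expect_equal(cor(pd$pre, pd$post), 0.7, tolerance = 0.01)
  expect_equal(mean(pd$post - pd$pre), 0.5, tolerance = 3 * sqrt(2 * (1 - 0.7)) / sqrt(1e5) + 0.01)
  expect_equal(sd(pd$pre), 1, tolerance = 0.01)
})

test_that("the generator is seed-deterministic and validates inputs", {
  a <- generate_paired(50, mean_change = 1, r = 0.3, seed = 8)
  b <- generate_paired(50, mean_change = 1, r = 0.3, seed = 8)
  expect_identical(a, b)
  expect_smd_error(generate_paired(10, r = 1), "invalid_input")
  expect_smd_error(generate_paired(10, sd_pre = 0), "invalid_input")

  ln <- generate_paired(100, mean_pre = 3, mean_change = -0.4, sd_pre = 0.3,
                        r = 0.5, seed = 9, distribution = "lognormal")
  expect_true(all(ln$pre > 0) && all(ln$post > 0))
})

test_that("a null generator produces a near-zero mean change", {
  pd <- generate_paired(200, mean_change = 0, sd_pre = 1, r = 0.5, seed = 21)
  sd_delta <- sqrt(2 * (1 - 0.5))
  expect_lt(abs(mean(pd$post - pd$pre)), 3 * sd_delta / sqrt(200))
})

test_that("sim_sweep aggregates every cell x family x correction", {
  cfg <- sim_config(n = 20, mean_change = 1, sd_pre_grid = c(0.5, 1, 2),
                    r_grid = c(0, 0.5, 0.9), replicates = 300, seed = 5)
  res <- sim_sweep(cfg)
  expect_s3_class(res, "smd_sweep")
  expect_equal(nrow(res), 3 * 3 * 4 * 2)  # cells x families x correction
  expect_setequal(unique(res$family), c("dz", "delta_pre", "d_av", "d_rm"))

  # magnitude-based means track 1/sd_pre; d_z means increase with r
  dpre <- dplyr::filter(res, family == "delta_pre", !corrected)
  for (s in c(0.5, 1, 2)) {
    cell <- dplyr::filter(dpre, sd_pre == s)
    expect_equal(mean(cell$mean_estimate), (1 / s) / hedges_c(19),
                 tolerance = 0.1 / s)
  }
  dz <- dplyr::filter(res, family == "dz", !corrected, sd_pre == 1)
  expect_true(all(diff(dz$mean_estimate[order(dz$r)]) > 0))

  # same master seed reproduces the sweep exactly
  res2 <- sim_sweep(cfg)
  expect_equal(as.data.frame(res), as.data.frame(res2))
})

test_that("sweep configs round-trip through flat files", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n: 12", "mean_change: 0.5", "sd_pre_grid: [1, 2]",
               "r_grid: [0, 0.5]", "replicates: 50", "seed: 3"), f)
  cfg <- read_sim_config(f)
  expect_equal(cfg$n, 12L)
  expect_equal(cfg$sd_pre_grid, c(1, 2))
  expect_equal(cfg$sd_post_grid, c(1, 2))

  writeLines(c("n: 12", "bogus: 1"), f)
  expect_smd_error(read_sim_config(f), "invalid_input")
  expect_smd_error(sim_config(r_grid = c(0, 1)), "invalid_input")
  expect_smd_error(sim_config(sd_pre_grid = 0), "invalid_input")
})

test_that("sweep results export to tidy CSV and JSON", {
  res <- sim_sweep(sim_config(sd_pre_grid = 1, r_grid = c(0, 0.5),
                              replicates = 100, seed = 4))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_sim_result(res, csv = csv, json = js)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(res))
  parsed <- jsonlite::read_json(js)
  expect_equal(length(parsed$cells), nrow(res))
  expect_equal(parsed$config$n, 20L)
})

test_that("simulate_estimates mean and variance track the closed forms", {
  est <- simulate_estimates(20, 2e4, mean_change = 0.5, r = 0.5,
                            family = "dz", seed = 44)
  expect_equal(length(est), 2e4)
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5 / hedges_c(19)), 3 * mc_se)
  v <- var(est)
  mc_se_v <- sd((est - mean(est))^2) / sqrt(length(est))
  expect_lt(abs(v - var_dz(0.5, 20)), 3 * mc_se_v)
})

test_that("validate_bias recovers the 1/c(n-1) inflation and its removal", {
  vb <- validate_bias(10, 0.5, "dz", replicates = 4e4, seed = 17)
  expect_equal(vb$expected_uncorrected, 1 / hedges_c(9))
  expect_lt(abs(vb$uncorrected - vb$expected_uncorrected),
            3 * vb$mc_se_uncorrected + 1e-3)
  expect_lt(abs(vb$corrected - 1), 3 * vb$mc_se_corrected + 1e-3)

  # large n: bias essentially gone
  vb200 <- validate_bias(200, 0.5, "dz", replicates = 2e4, seed = 18)
  expect_lt(abs(vb200$uncorrected - 1.0038), 3 * vb200$mc_se_uncorrected + 1e-3)

  # null effect: absolute bias reported instead of a ratio
  vb0 <- validate_bias(10, 0, "delta_pre", replicates = 1e4, seed = 19)
  expect_equal(vb0$measure, "absolute_bias")
  expect_lt(abs(vb0$uncorrected), 3 * vb0$mc_se_uncorrected)
})

test_that("sweep plots build for each metric", {
  res <- sim_sweep(sim_config(sd_pre_grid = c(0.5, 1), r_grid = c(0, 0.5),
                              replicates = 100, seed = 6))
  for (m in c("estimate", "bias", "se")) {
    p <- plot_sweep(res, metric = m)
    expect_s3_class(p, "ggplot")
  }
})
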