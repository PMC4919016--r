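test_that("rrmse and rbias match hand computations", {
  rho <- 5000
  expect_equal(rrmse(rep(rho, 10), rho), 0)
  expect_equal(rrmse(2 * rho, rho), 1)
  expect_equal(rrmse(c(rho, 2 * rho), rho), sqrt(0.5))
  expect_equal(rbias(rep(rho, 3), rho), 0)
  expect_equal(rbias(rep(1.5 * rho, 4), rho), 0.5)
  expect_equal(rbias(c(0.5 * rho, 1.5 * rho), rho), 0)
  expect_error(rrmse(c(1, 2), 0), class = "pcqm_invalid_true_density")
  expect_error(rbias(numeric(0), 10), class = "pcqm_invalid_spec")
  # metrics also accept density_estimate objects
  s <- pcqm_sample(matrix(1, 1, 4), g = 1)
  expect_equal(rbias(list(density_corrected(s)), 3 / pi * 1e4), 0)
})

small_cfg <- function(reps = 40, seed = 5) {
  scenario_config(pattern_spec("random", 600, pcqm_window(50, 50)),
                  sample_sizes = c(5, 10), orders = 1:2,
                  replicates = reps, seed = seed, scenario_id = "unit")
}

test_that("run_scenario produces a full, consistent, reproducible grid", {
  res <- run_scenario(small_cfg())
  expect_identical(nrow(res$metrics), 2L * 2L * 2L)  # N x order x family
  expect_identical(nrow(res$raw), 8L * 40L)
  expect_identical(res$true_density, 600 / 2500 * 1e4)
  expect_true(all(res$metrics$n_ok == 40 & res$metrics$n_failed == 0))
  # RMSE dominates the absolute bias in every cell (Jensen)
  expect_true(all(res$metrics$rrmse >= abs(res$metrics$rbias)))
  # metrics agree with recomputation from the raw estimates
  for (i in seq_len(nrow(res$metrics))) {
    m <- res$metrics[i, ]
    v <- res$raw$density_ha[res$raw$samples == m$samples &
                              res$raw$pcqm_type == m$pcqm_type &
                              res$raw$pcqm_eqn == m$pcqm_eqn]
    expect_equal(m$rrmse, rrmse(v, res$true_density))
    expect_equal(m$rbias, rbias(v, res$true_density))
  }
  # bit-exact replay under the same master seed
  res2 <- run_scenario(small_cfg())
  expect_identical(res$raw$density_ha, res2$raw$density_ha)
  # a different master seed gives different estimates
  res3 <- run_scenario(small_cfg(seed = 6))
  expect_false(any(res3$raw$density_ha == res$raw$density_ha))
})

test_that("the two families differ only by their numerators within a replicate", {
  res <- run_scenario(small_cfg(reps = 25))
  raw <- res$raw
  for (n_pts in c(5, 10)) {
    for (g in 1:2) {
      pub <- raw$density_ha[raw$samples == n_pts & raw$pcqm_type == g &
                              raw$pcqm_eqn == "published"]
      corr <- raw$density_ha[raw$samples == n_pts & raw$pcqm_type == g &
                               raw$pcqm_eqn == "corrected"]
      ratio <- pcqm_numerator("published", g, n_pts) /
        pcqm_numerator("corrected", g, n_pts)
      expect_equal(pub, corr * ratio, tolerance = 1e-12)
      # hence the bias link between the families is exact here
      m_pub <- rbias(pub, res$true_density)
      m_corr <- rbias(corr, res$true_density)
      expect_equal(m_pub + 1, (m_corr + 1) * ratio, tolerance = 1e-10)
    }
  }
})

test_that("corrected first-order RRMSE shrinks as the survey grows", {
  cfg <- scenario_config(pattern_spec("random", 1000, ha_window()),
                         sample_sizes = c(5, 10, 20, 40), orders = 1,
                         estimators = "corrected", replicates = 200,
                         seed = 13, scenario_id = "conv")
  m <- run_scenario(cfg)$metrics
  expect_true(all(diff(m$rrmse[order(m$samples)]) < 0))
})

test_that("replicates that cannot be surveyed are marked, not dropped", {
  sparse <- point_pattern(c(10, 50, 90), c(10, 50, 90), ha_window())
  cfg <- scenario_config(sparse, sample_sizes = 4, orders = 3,
                         replicates = 5, seed = 2, scenario_id = "sparse")
  res <- run_scenario(cfg)
  expect_identical(res$metrics$n_failed, rep(5L, nrow(res$metrics)))
  expect_true(all(is.na(res$raw$density_ha)))
  expect_true(all(res$raw$status == "failed"))
  expect_true(all(is.na(res$metrics$rrmse)))
})

test_that("family and order comparisons behave at the extremes", {
  set.seed(30)
  x <- rnorm(200, 5000, 300)
  expect_gt(compare_estimator_families(x, x)$p.value, 0.99)
  expect_lt(compare_estimator_families(x, x + 5000)$p.value, 1e-10)
  same <- compare_orders(x, x, x)
  expect_gt(same$omnibus$p.value, 0.99)
  shifted <- compare_orders(x, x + 10 * sd(x), rnorm(200, 5000, 300))
  expect_lt(shifted$omnibus$p.value, 1e-6)
  expect_identical(nrow(shifted$posthoc), 3L)
  expect_true(all(shifted$posthoc$p_adjusted >= shifted$posthoc$p_value))
  expect_error(compare_estimator_families(numeric(0), x),
               class = "pcqm_invalid_spec")
})

test_that("results CSV round trips and reports malformed rows", {
  res <- run_scenario(small_cfg(reps = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(res$raw, path)
  back <- read_results_csv(path)
  expect_identical(nrow(back), nrow(res$raw))
  expect_equal(back$density_ha, res$raw$density_ha, tolerance = 1e-9)
  expect_identical(back$samples, as.numeric(res$raw$samples))
  expect_identical(back$pcqm_eqn, res$raw$pcqm_eqn)

  empty <- res$raw[0, ]
  write_results_csv(empty, path)
  expect_identical(nrow(read_results_csv(path)), 0L)

  writeLines(c("scenario_id,pattern_kind,true_density,samples,pcqm_eqn,pcqm_type,replicate,density_ha,status",
               "s,random,5000,10,corrected,1,1,oops,ok"), path)
  err <- expect_error(read_results_csv(path), class = "pcqm_parse_error")
  expect_match(conditionMessage(err), "row 1")
})
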