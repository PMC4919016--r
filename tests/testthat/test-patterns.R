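test_that("every generator returns exactly n points, inside the window, reproducibly", {
  w_small <- pcqm_window(50, 40)
  set.seed(99)
  for (i in 1:30) {
    kind <- sample(c("random", "aggregated", "regular"), 1)
    n <- sample(5:400, 1)
    spec <- switch(kind,
      random = pattern_spec("random", n, w_small, seed = i),
      aggregated = pattern_spec("aggregated", n, w_small,
                                cluster_radius = runif(1, 0.5, 3),
                                intensity = runif(1), seed = i),
      regular = pattern_spec("regular", n, w_small,
                             repulsion = runif(1, 0, 0.5), seed = i))
    p <- generate_pattern(spec)
    expect_identical(p$n, as.integer(n))
    expect_true(all(p$x >= 0 & p$x <= 50 & p$y >= 0 & p$y <= 40))
    # bit-for-bit determinism under the same spec + seed
    p2 <- generate_pattern(spec)
    expect_identical(p$x, p2$x)
    expect_identical(p$y, p2$y)
    if (kind == "regular" && n > 1) {
      expect_gte(min_pairwise_dist(p), spec$repulsion)
    }
  }
  expect_equal(true_density(mk_random_pattern(1)), 1)  # 1 tree / ha
})

test_that("invalid pattern specifications are rejected", {
  w <- ha_window()
  expect_error(pattern_spec("random", 0, w), class = "pcqm_invalid_spec")
  expect_error(pattern_spec("aggregated", 10, w, cluster_radius = -1,
                            intensity = 0.5), class = "pcqm_invalid_spec")
  expect_error(pattern_spec("aggregated", 10, w, cluster_radius = 1,
                            intensity = 1.5), class = "pcqm_invalid_spec")
  expect_error(pattern_spec("regular", 10, w, repulsion = -0.1),
               class = "pcqm_invalid_spec")
  # parameters of the wrong kind are an error, not silently ignored
  expect_error(pattern_spec("random", 10, w, repulsion = 1),
               class = "pcqm_invalid_spec")
  expect_error(pattern_spec("regular", 10, w, repulsion = 1,
                            intensity = 0.2), class = "pcqm_invalid_spec")
  expect_error(pcqm_window(0, 10), class = "pcqm_invalid_spec")
  expect_error(point_pattern(11, 5, pcqm_window(10, 10)),
               class = "pcqm_invalid_spec")
})

test_that("infeasible hard-core packing fails with a packing error", {
  spec <- pattern_spec("regular", 300, ha_window(), repulsion = 10,
                       seed = 5)
  # ~115 discs of radius 10 m at most fit in a hectare, far below 300
  err <- expect_error(generate_regular(spec), class = "pcqm_packing_failure")
  expect_match(conditionMessage(err), "proposals")
})

test_that("Clark-Evans index matches hand computations and flags degenerate input", {
  unit <- pcqm_window(1, 1)
  corners <- point_pattern(c(0, 1, 0, 1), c(0, 0, 1, 1), unit)
  # mean NN distance 1, CSR expectation 0.5/sqrt(4) = 0.25
  expect_equal(clark_evans_index(corners), 4)
  coincident <- point_pattern(c(0.5, 0.5), c(0.5, 0.5), unit)
  expect_equal(clark_evans_index(coincident), 0)
  expect_error(clark_evans_index(point_pattern(0.5, 0.5, unit)),
               class = "pcqm_insufficient_points")
})

test_that("random patterns give R near 1 on average", {
  r_vals <- vapply(1:500, function(i) {
    clark_evans_index(mk_random_pattern(2000, seed = 10000 + i))
  }, numeric(1))
  expect_gte(mean(r_vals), 0.98)
  expect_lte(mean(r_vals), 1.02)
})

test_that("the index orders patterns by aggregation and repulsion", {
  w <- ha_window()
  mean_r <- function(make) mean(vapply(1:3, make, numeric(1)))
  r_by_int <- vapply(c(0, 0.25, 0.5), function(int) {
    mean_r(function(i) {
      clark_evans_index(generate_aggregated(pattern_spec(
        "aggregated", 1500, w, cluster_radius = 1, intensity = int,
        seed = 300 + i)))
    })
  }, numeric(1))
  expect_true(all(diff(r_by_int) < 0))  # more clustering, lower R
  r_by_rep <- vapply(c(0.25, 0.5, 1.0), function(rd) {
    mean_r(function(i) {
      clark_evans_index(generate_regular(pattern_spec(
        "regular", 1500, w, repulsion = rd, seed = 400 + i)))
    })
  }, numeric(1))
  expect_true(all(diff(r_by_rep) > 0))  # more repulsion, higher R
  # zero aggregation intensity degenerates to complete randomness
  r0 <- clark_evans_index(generate_aggregated(pattern_spec(
    "aggregated", 2000, w, cluster_radius = 1, intensity = 0, seed = 6)))
  expect_lt(abs(r0 - 1), 0.05)
})

test_that("pattern CSV round trips exactly and reports bad rows", {
  w <- pcqm_window(10, 10)
  p <- mk_random_pattern(37, w, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pattern_csv(p, path)
  p2 <- read_pattern_csv(path, w)
  expect_identical(p2$x, p$x)
  expect_identical(p2$y, p$y)

  writeLines("x,y", path)
  expect_error(read_pattern_csv(path, w), class = "pcqm_empty_pattern")
  writeLines(c("x,y", "5.0,5.0"), path)
  expect_identical(read_pattern_csv(path, w)$n, 1L)
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_pattern_csv(path, w), class = "pcqm_parse_error")
  writeLines(c("x,y", "1,2", "3,oops"), path)
  err <- expect_error(read_pattern_csv(path, w), class = "pcqm_parse_error")
  expect_match(conditionMessage(err), "row 2")
  writeLines(c("x,y", "1,2", "11,2"), path)
  err <- expect_error(read_pattern_csv(path, w), class = "pcqm_parse_error")
  expect_match(conditionMessage(err), "row 2")
})
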