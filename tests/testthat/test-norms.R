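test_that("logistic evaluation matches the closed form", {
  med <- ref_params(0.5)
  # at the inflection age the curve sits midway between the asymptotes
  expect_equal(logistic_eval(med, med[["a4"]]),
               (med[["a1"]] + med[["a2"]]) / 2)
  expect_equal(logistic_eval(med, 18.5796), 34.0026, tolerance = 1e-6)
  # frozen hand evaluations of the published median parameters
  expect_equal(logistic_eval(med, 3), 12.634319, tolerance = 1e-6)
  expect_equal(logistic_eval(med, 24), 43.175568, tolerance = 1e-6)
  # degenerate constant curve
  expect_equal(logistic_eval(c(5, 5, 0.1, 10), 33), 5)
})

test_that("logistic curves are strictly increasing and approach a2", {
  for (seed in 1:25) {
    p <- withr::with_seed(seed, {
      a1 <- runif(1, -40, 30); a2 <- runif(1, a1 + 1, 64)
      c(a1, a2, runif(1, 0.01, 1), runif(1, 1, 60))
    })
    ages <- sort(withr::with_seed(seed + 100, runif(20, 0.1, 72)))
    vals <- logistic_eval(p, ages)
    # non-strict numerically: the upper tail saturates at double precision
    expect_true(all(diff(vals) >= 0))
    expect_gt(vals[length(vals)], vals[1])
    expect_lt(abs(logistic_eval(p, 72) - p[2]), abs(logistic_eval(p, 3) - p[2]))
  }
})

test_that("packaged reference table carries the published parameters exactly", {
  expect_equal(nrow(ref_table), 7)
  expect_identical(ref_table$tau, c(0.05, 0.10, 0.16, 0.50, 0.84, 0.90, 0.95))
  expect_identical(ref_table$a2[ref_table$tau == 0.95], 64.0000)
  expect_identical(ref_table$a1[ref_table$tau == 0.05], -25.3196)
  expect_identical(ref_table$a4[ref_table$tau == 0.10], 16.8049)
  expect_equal(attr(ref_table, "min_age"), 3)
})

test_that("corrupted percentile tables fail integrity checks", {
  path <- withr::local_tempfile(fileext = ".json")
  bad <- as.data.frame(ref_table)
  bad$a2[4] <- bad$a1[4] - 1  # upper asymptote below lower
  jsonlite::write_json(list(min_age = 3, entries = bad), path,
                       auto_unbox = TRUE, digits = NA)
  expect_error(load_reference_table(path), "integrity")
  writeLines("{", path)
  expect_error(load_reference_table(path), "parse")
})

test_that("norm evaluation clamps, orders and flags correctly", {
  ev <- evaluate_norms(ref_table, 3)
  expect_equal(unname(ev$values),
               c(2.756138, 6.190931, 7.519918, 12.634319, 17.007628,
                 18.893938, 19.722712),
               tolerance = 1e-6)
  expect_false(ev$below_min_age)
  expect_false(any(ev$clamped))
  expect_true(all(diff(ev$values) >= 0))

  expect_true(evaluate_norms(ref_table, 2)$below_min_age)
  expect_error(evaluate_norms(ref_table, 0), "\\(0, 72\\]")
  expect_error(evaluate_norms(ref_table, 73), "\\(0, 72\\]")

  # the 5th-centile curve is negative below about 1 month: the reported
  # value clamps to 0
  ev1 <- evaluate_norms(ref_table, 0.5)
  expect_identical(unname(ev1$values[1]), 0)
  expect_true(ev1$clamped[[1]])
  expect_lt(ev1$raw[[1]], 0)
})

test_that("reference centiles do not cross on the reporting range", {
  rep <- check_non_crossing(ref_table, seq(3, 72, by = 0.1))
  expect_true(rep$ok)
  expect_equal(nrow(rep$violations), 0)

  # ties are allowed
  tied <- percentile_table(data.frame(
    tau = c(0.25, 0.75), a1 = c(1, 1), a2 = c(30, 30),
    a3 = c(0.1, 0.1), a4 = c(20, 20)))
  expect_true(check_non_crossing(tied, 3:72)$ok)

  # swapping the 50th and 84th rows constructs a violation
  swapped <- as.data.frame(ref_table)
  swapped[c(4, 5), c("a1", "a2", "a3", "a4")] <-
    swapped[c(5, 4), c("a1", "a2", "a3", "a4")]
  swapped <- percentile_table(swapped)
  expect_false(check_non_crossing(swapped, 3:72)$ok)

  expect_error(check_non_crossing(ref_table, numeric(0)), "non-empty")
})

test_that("score-to-centile inversion uses normal-score interpolation", {
  # midpoint of the median curve inverts to tau = 0.5
  med <- ref_params(0.5)
  res <- score_to_percentile(ref_table, 18.5796, 34.0026)
  expect_equal(res$tau, 0.5, tolerance = 1e-4)
  expect_equal(res$band, "16th-84th")
  expect_false(res$outside_fitted_range)

  # frozen hand interpolation between the 50th and 84th curves at 24 months
  res70 <- score_to_percentile(ref_table, 24, 48.097747)
  expect_equal(res70$tau, 0.70, tolerance = 1e-4)

  # above the fitted family: boundary level with flag
  top <- score_to_percentile(ref_table, 24, 64)
  expect_equal(top$tau, 0.95)
  expect_true(top$outside_fitted_range)
  expect_equal(top$band, "above-95th")

  expect_error(score_to_percentile(ref_table, 24, 65), "\\[0, 64\\]")
})

test_that("centile inversion round-trips the fitted curves", {
  for (age in c(3, 7.5, 12, 24, 36.25, 48, 60, 72)) {
    vals <- vapply(ref_table$tau,
                   function(tau) logistic_eval(ref_params(tau), age), numeric(1))
    for (i in seq_along(vals)) {
      if (vals[i] < 0 || vals[i] > 64) next
      expect_equal(score_to_percentile(ref_table, age, vals[i])$tau,
                   ref_table$tau[i], tolerance = 1e-6)
    }
  }
})
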