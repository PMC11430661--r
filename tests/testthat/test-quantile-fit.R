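test_that("pinball loss matches its definition", {
  expect_equal(pinball_loss(c(0, 0, 0), 0.5), 0)
  expect_equal(pinball_loss(c(2, -1), 0.9), 1.9)
  expect_equal(pinball_loss(c(1, -1), 0.5), 1.0)
  expect_error(pinball_loss(c(1, 2), 1.2), "tau")
  # invariant under permutation of residuals
  r <- withr::with_seed(1, rnorm(50))
  expect_equal(pinball_loss(r, 0.3), pinball_loss(rev(r), 0.3))
})

test_that("fitting noiseless data on a known curve recovers it", {
  truth <- c(2, 60, 0.15, 20)
  cohort <- exact_curve_cohort(truth)
  for (tau in c(0.25, 0.5, 0.9)) {
    fit <- fit_quantile_curve(cohort, tau, seed = 42)
    expect_lt(fit$loss, 0.05)
    expect_equal(unname(fit$params[["a2"]]), truth[2], tolerance = 0.05)
    expect_equal(unname(fit$params[["a4"]]), truth[4], tolerance = 0.5)
  }
})

test_that("fit refuses degenerate inputs", {
  small <- exact_curve_cohort(c(2, 60, 0.15, 20), n = 10)
  expect_error(fit_quantile_curve(small, 0.5), "at least 20")
  narrow <- exact_curve_cohort(c(2, 60, 0.15, 20), n = 30,
                               ages = seq(20, 25, length.out = 30))
  expect_error(fit_quantile_curve(narrow, 0.5), "span")
  ok <- exact_curve_cohort(c(2, 60, 0.15, 20))
  expect_error(fit_quantile_curve(ok, 1.5), "tau")
})

test_that("fits are deterministic given records, seed and options", {
  cohort <- generate_cohort(design_target(), ref_table, seed = 11)
  f1 <- fit_quantile_curve(cohort, 0.5, seed = 7, n_starts = 4)
  f2 <- fit_quantile_curve(cohort, 0.5, seed = 7, n_starts = 4)
  expect_identical(f1, f2)
  # relabelling children does not change the objective or the fit
  relabelled <- cohort
  relabelled$child_id <- rev(cohort$child_id)
  f3 <- fit_quantile_curve(relabelled, 0.5, seed = 7, n_starts = 4)
  expect_identical(unclass(f1$params), unclass(f3$params))
})

test_that("at constant age the fitted median curve passes through the sample median", {
  # 200 children all at 30 months plus a thin age scaffold to satisfy the
  # span requirement with negligible loss weight
  sc <- withr::with_seed(5, runif(200, 20, 60))
  cohort <- data.frame(child_id = sprintf("c%03d", 1:200),
                       age_months = 30, score = sc)
  scaffold <- data.frame(
    child_id = c("s1", "s2"), age_months = c(3, 70),
    score = c(12.6, 63))
  fit <- fit_quantile_curve(rbind(cohort, scaffold), 0.5, seed = 3)
  expect_equal(logistic_eval(fit$params, 30), median(sc), tolerance = 0.3)
})

test_that("simplex optimiser never loses to the brute-force grid oracle", {
  set.seed(99)
  worse <- 0
  for (rep in 1:25) {
    truth <- c(runif(1, -5, 10), runif(1, 50, 64), runif(1, 0.08, 0.3),
               runif(1, 10, 30))
    n <- 60
    ages <- runif(n, 1, 72)
    noise <- rnorm(n, 0, 3)
    cohort <- data.frame(
      child_id = sprintf("c%02d", 1:n), age_months = ages,
      score = pmin(pmax(oracle_4pl(truth[1], truth[2], truth[3], truth[4],
                                   ages) + noise, 0), 64))
    tau <- sample(c(0.25, 0.5, 0.75), 1)
    grid <- list(a1 = seq(-10, 15, length.out = 6),
                 a2 = seq(45, 64, length.out = 6),
                 a3 = seq(0.05, 0.35, length.out = 6),
                 a4 = seq(5, 35, length.out = 6))
    gb <- brute_force_fit(cohort, tau, grid)
    opt <- fit_quantile_curve(cohort, tau, seed = rep, n_starts = 8)
    if (opt$loss > gb$loss + 1e-8) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("brute-force grid search honours its contracts", {
  truth <- c(2, 60, 0.15, 20)
  cohort <- exact_curve_cohort(truth, n = 30)
  # grid containing the generating parameters recovers them with zero loss
  grid <- list(a1 = c(0, 2, 5), a2 = c(55, 60), a3 = c(0.1, 0.15), a4 = c(15, 20))
  res <- brute_force_fit(cohort, 0.5, grid)
  expect_equal(unname(res$params), truth)
  expect_equal(res$loss, 0, tolerance = 1e-9)
  # one-point grid returns that point
  one <- brute_force_fit(cohort, 0.5,
                         list(a1 = 1, a2 = 50, a3 = 0.2, a4 = 18))
  expect_equal(unname(one$params), c(1, 50, 0.2, 18))
  expect_error(
    brute_force_fit(cohort, 0.5,
                    list(a1 = 1:200, a2 = 1:200, a3 = 1:200, a4 = 1:2)),
    "grid too large")
})

test_that("fitting a full centile family returns a coherent table", {
  cohort <- generate_cohort(design_actual(), ref_table, seed = 21)
  tab <- fit_all_percentiles(cohort, taus = c(0.16, 0.5, 0.84), seed = 2,
                             n_starts = 6)
  expect_s3_class(tab, "flip_norms")
  expect_equal(tab$tau, c(0.16, 0.5, 0.84))
  expect_true(all(diff(tab$a4) < 40))  # sane scale
  expect_false(is.null(attr(tab, "non_crossing")))

  single <- fit_all_percentiles(cohort, taus = 0.5, seed = 2, n_starts = 4)
  expect_equal(nrow(single), 1)
  expect_error(fit_all_percentiles(cohort, taus = numeric(0)), "non-empty")
})
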