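test_that("binned sample percentiles follow the order-statistic estimator", {
  rec <- data.frame(child_id = letters[1:9], age_months = seq(13, 17, length.out = 9),
                    score = 1:9)
  bins <- binned_sample_percentiles(rec, taus = c(0.16, 0.5, 0.84))
  row <- bins[bins$lo == 12, ]
  expect_equal(row$count, 9)
  expect_equal(row$p0.5, 5)  # odd-length median
  expect_equal(row$midpoint, 15)
  # constant sample: every percentile equals the constant
  const <- data.frame(child_id = letters[1:6], age_months = rep(20, 6), score = 10)
  cb <- binned_sample_percentiles(const, taus = c(0.16, 0.5, 0.84))
  expect_true(all(unlist(cb[cb$lo == 18, c("p0.16", "p0.5", "p0.84")]) == 10))
  # bins below the minimum count carry NA
  expect_true(all(is.na(cb$p0.5[cb$lo != 18])))
  expect_error(binned_sample_percentiles(rec, bin_width = 7), "divide 72")
})

test_that("every record lands in exactly one bin of the partition", {
  cohort <- generate_cohort(design_actual(), ref_table, seed = 8)
  bins <- binned_sample_percentiles(cohort, taus = 0.5)
  expect_equal(sum(bins$count), nrow(cohort))
  expect_equal(bins$lo, seq(0, 66, 6))
  expect_equal(bins$hi, seq(6, 72, 6))
})

test_that("bin-vs-curve comparison is exact on self-generated values and antisymmetric", {
  # bins whose percentile values are the curve values themselves differ by 0
  mids <- seq(3, 69, by = 6)
  bins <- data.frame(lo = mids - 3, hi = mids + 3, midpoint = mids, count = 100)
  bins$p0.5 <- logistic_eval(ref_params(0.5), mids)
  cmp <- compare_bins_to_curves(bins, ref_table)
  expect_equal(cmp$max_abs, 0, tolerance = 1e-12)

  # shifting the sample values negates the differences symmetrically
  up <- bins; up$p0.5 <- up$p0.5 + 1.5
  down <- bins; down$p0.5 <- down$p0.5 - 1.5
  expect_equal(compare_bins_to_curves(up, ref_table)$by_tau$`0.5`$diff,
               -compare_bins_to_curves(down, ref_table)$by_tau$`0.5`$diff)

  empty <- bins[0, ]
  expect_true(is.na(compare_bins_to_curves(empty, ref_table)$max_abs))
})

test_that("a mega-cohort's binned medians agree with the generating median curve", {
  big_design <- design_target()
  big_design$blocks$count <- 2000L
  cohort <- generate_cohort(big_design, ref_table, seed = 77)
  bins <- binned_sample_percentiles(cohort, taus = 0.5)
  cmp <- compare_bins_to_curves(bins, ref_table)
  expect_lt(cmp$max_abs, 1.0)
})

test_that("segmented linear fit recovers exact lines and the early-steeper pattern", {
  # collinear records in each segment reproduce the lines with R^2 = 1
  ages <- c(seq(2, 28, 2), seq(32, 52, 2), seq(56, 70, 2))
  seg_of <- findInterval(ages, c(0, 30, 54, 72), left.open = TRUE)
  slopes <- c(2, 0.5, 0.1); ints <- c(0, 20, 40)
  rec <- data.frame(child_id = sprintf("c%02d", seq_along(ages)),
                    age_months = ages,
                    score = ints[seg_of] + slopes[seg_of] * ages)
  fit <- suppressWarnings(segmented_linear_fit(rec))  # exact fit: summary.lm grumbles
  expect_equal(fit$slope, slopes, tolerance = 1e-9)
  expect_equal(fit$intercept, ints, tolerance = 1e-8)
  expect_equal(fit$r_squared, rep(1, 3), tolerance = 1e-9)

  # simulated normative cohort: early acquisition much steeper than late
  cohort <- generate_cohort(design_actual(), ref_table, seed = 31)
  fitc <- segmented_linear_fit(cohort)
  expect_gt(fitc$slope[1], fitc$slope[3])

  # records confined to one segment are a data error naming the segment
  mid_only <- rec[rec$age_months > 30 & rec$age_months <= 54, ]
  expect_error(segmented_linear_fit(mid_only), "segment")
})

test_that("a trajectory on the median curve is unflagged and inside the envelope", {
  ages <- seq(6, 60, by = 6)
  traj <- child_trajectory("on-median", ages,
                           logistic_eval(ref_params(0.5), ages))
  rep <- trajectory_report(traj, ref_table)
  expect_true(all(rep$points$band == "16th-84th"))
  expect_equal(unname(rep$flags), c(FALSE, FALSE, FALSE))
  expect_equal(rep$points$tau, rep_len(0.5, length(ages)), tolerance = 1e-6)
})

test_that("the plateau-and-recovery demonstration trajectory raises the expected flags", {
  traj <- demo_trajectory("B")
  rep <- trajectory_report(traj, ref_table)
  expect_true(rep$flags[["divergence"]])
  expect_true(rep$flags[["plateau"]])
  expect_true(rep$flags[["converging"]])
  # the plateau interval sits below the envelope
  mid <- rep$points$age_months >= 18 & rep$points$age_months <= 40
  expect_true(all(rep$points$below_envelope[mid]))
  # early assessments start inside the envelope
  expect_equal(rep$points$band[1], "16th-84th")

  # the early-implant demonstration child converges to the median band
  repA <- trajectory_report(demo_trajectory("A"), ref_table)
  expect_equal(utils::tail(repA$points$band, 1), "16th-84th")
  expect_false(repA$flags[["plateau"]])
})

test_that("trajectory flags ignore annotations and child id", {
  ages <- c(10, 20, 30, 40)
  scores <- c(10, 12, 13, 13.5)
  t1 <- child_trajectory("a", ages, scores)
  t2 <- child_trajectory("b", ages, scores,
                         annotations = data.frame(age_months = 20, label = "x"))
  r1 <- trajectory_report(t1, ref_table)
  r2 <- trajectory_report(t2, ref_table)
  expect_identical(r1$flags, r2$flags)
  expect_identical(r1$points$band, r2$points$band)

  # single-point trajectory: bands computed, trend flags absent
  single <- trajectory_report(child_trajectory("s", 24, 30), ref_table)
  expect_equal(nrow(single$points), 1)
  expect_equal(unname(single$flags), c(FALSE, FALSE, FALSE))
})
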