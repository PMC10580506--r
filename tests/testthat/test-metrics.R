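test_that("trace constructor enforces baseline, ordering and positivity", {
  expect_error(glucose_trace(c(15, 30), c(6, 7)), "t = 0")
  expect_error(glucose_trace(c(0, 30, 30), c(6, 7, 8)), "strictly increasing")
  expect_error(glucose_trace(c(0, 15), c(6, -1)), "positive")
  tr <- glucose_trace(c(0, 15), c(6, 7), subject_id = "S01", arm = "NPM-CC")
  expect_s3_class(tr, "glucose_trace")
  expect_equal(as.data.frame(tr)$glucose_mmol_l, c(6, 7))
})

test_that("window means use closed intervals over the readings", {
  tr <- glucose_trace(c(0, 15, 30), c(6, 8, 10))
  expect_equal(mean_glucose(tr, 0, 30), 8)
  expect_equal(mean_glucose(constant_trace(7), 40, 260), 7)
  expect_equal(mean_glucose(ramp_trace(6, 10), 0, 300), 8)
  # boundary reading contributes to both adjacent windows
  tr2 <- ramp_trace(6, 10)
  expect_true(120 %in% tr2$times)
  sel_a <- tr2$times >= 0 & tr2$times <= 120
  sel_b <- tr2$times >= 120 & tr2$times <= 240
  expect_equal(mean_glucose(tr2, 0, 120), mean(tr2$values[sel_a]))
  expect_equal(mean_glucose(tr2, 120, 240), mean(tr2$values[sel_b]))
  expect_error(mean_glucose(tr, 40, 50), "no readings")
})

test_that("peak excludes the baseline reading and breaks ties early", {
  tr <- glucose_trace(c(0, 60, 120, 180), c(6, 9, 12, 8))
  expect_equal(peak_glucose(tr), list(peak = 12, time_to_peak = 120))
  tie <- glucose_trace(c(0, 60, 120), c(6, 10, 10))
  expect_equal(peak_glucose(tie)$time_to_peak, 60)
  falling <- glucose_trace(c(0, 15, 30, 45), c(12, 11, 10, 9))
  expect_equal(peak_glucose(falling), list(peak = 11, time_to_peak = 15))
})

test_that("trapezoidal AUC matches closed forms and a Riemann oracle", {
  expect_equal(total_auc(constant_trace(7), 300), 2100)
  expect_equal(total_auc(ramp_trace(6, 10), 300), 2400)
  expect_equal(total_auc(glucose_trace(c(0, 15), c(6, 8)), 15), 105)
  expect_error(total_auc(constant_trace(7), 400), "beyond")
  set.seed(101)
  for (i in 1:100) {
    tr <- random_trace()
    t_end <- sample(c(150, 300, 247), 1)  # off-grid end exercises interpolation
    expect_equal(total_auc(tr, t_end), riemann_auc(tr, t_end), tolerance = 1e-6)
  }
})

test_that("incremental AUC honours the baseline and both sign policies", {
  expect_equal(incremental_auc(constant_trace(7), 300, "net"), 0)
  expect_equal(incremental_auc(constant_trace(7), 300, "positive_only"), 0)
  expect_equal(incremental_auc(ramp_trace(6, 10), 300, "net"), 600)
  vt <- glucose_trace(c(0, 150, 300), c(6, 4, 6))
  expect_equal(incremental_auc(vt, 300, "net"), -300)
  expect_equal(incremental_auc(vt, 300, "positive_only"), 0)
  # crossing segments are clipped by linear interpolation
  wt <- glucose_trace(c(0, 100, 200), c(6, 8, 4))
  # up-leg: full trapezoid 100; down-leg crosses baseline at t = 150
  expect_equal(incremental_auc(wt, 200, "positive_only"), 100 + 50 * 2 / 2)
})

test_that("net iAUC identity and positive-policy dominance hold on random traces", {
  set.seed(202)
  for (i in 1:100) {
    tr <- random_trace()
    t_end <- sample(seq(30, 300, 30), 1)
    net <- incremental_auc(tr, t_end, "net")
    expect_equal(net, total_auc(tr, t_end) - tr$values[1] * t_end, tolerance = 1e-10)
    pos <- incremental_auc(tr, t_end, "positive_only")
    expect_gte(pos, net - 1e-12)
    # iauc non-decreasing in t_end under positive_only
    if (t_end < 300) {
      expect_gte(incremental_auc(tr, t_end + 30, "positive_only"), pos - 1e-12)
    }
    # all-above-baseline traces: both policies agree
    hi <- glucose_trace(tr$times, tr$values - min(tr$values) + tr$values[1] + 0.1)
    hi <- glucose_trace(hi$times, c(tr$values[1], hi$values[-1]))
    if (all(hi$values >= hi$values[1])) {
      expect_equal(incremental_auc(hi, 300, "positive_only"),
                   incremental_auc(hi, 300, "net"))
    }
  }
})

test_that("time in ranges counts readings with a closed target interval", {
  tr <- glucose_trace(c(0, 15, 30, 45), c(3.5, 5, 11, 7))
  expect_equal(unname(time_in_ranges(tr)), c(50, 25, 25))
  expect_equal(unname(time_in_ranges(constant_trace(6.5))), c(100, 0, 0))
  edge <- glucose_trace(c(0, 15), c(10.0, 3.9))
  expect_equal(unname(time_in_ranges(edge)), c(100, 0, 0))  # bounds in range
  expect_error(time_in_ranges(tr, low = 10, high = 3.9), "below")
  set.seed(303)
  for (i in 1:100) {
    r <- time_in_ranges(random_trace(lo = 2.5, hi = 14))
    expect_equal(sum(r), 100)
  }
})

test_that("hypoglycemia episodes are maximal below-threshold runs", {
  v <- rep(6, 21); v[4] <- 3.5
  one <- glucose_trace(grid15, v)
  ep <- detect_hypoglycemia(one)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$onset_min, 45)
  expect_equal(ep$nadir_mmol_l, 3.5)
  expect_equal(nrow(detect_hypoglycemia(constant_trace(6))), 0)
  v2 <- rep(6, 21); v2[5:6] <- c(3.5, 3.7); v2[13] <- 3.0
  two <- glucose_trace(grid15, v2)
  ep2 <- detect_hypoglycemia(two)
  expect_equal(nrow(ep2), 2)
  expect_equal(ep2$onset_min, c(60, 180))
  expect_equal(ep2$end_min, c(75, 180))
  set.seed(404)
  for (i in 1:100) {
    tr <- random_trace(lo = 3, hi = 6)
    expect_equal(nrow(detect_hypoglycemia(tr)),
                 brute_episode_count(tr$values))
  }
})

test_that("30-min excursions difference the exact grid readings", {
  expect_equal(unname(excursions_30min(constant_trace(7))), rep(0, 10))
  expect_equal(excursions_30min(ramp_trace(6, 8))[["exc_30"]], 0.2)
  expect_equal(unname(excursions_30min(ramp_trace(6, 10))), rep(0.4, 10),
               tolerance = 1e-12)
  gap <- glucose_trace(c(0, 15, 45, 60), c(6, 7, 8, 9))  # no reading at 30
  expect_error(excursions_30min(gap, t_end = 60), "missing")
})

test_that("MAGE matches a brute-force extrema scan and its invariances", {
  expect_equal(mage(constant_trace(7)), 0)
  # two sine periods on the 15-min grid: the boundary half-swings (start to
  # first crest, last trough to end, ~1.9 each) qualify alongside the full
  # crest-to-trough swing (~3.8), so MAGE is their mean, ~2.53
  sine <- glucose_trace(grid15, 8 + 2 * sin(2 * pi * grid15 / 150))
  expect_equal(mage(sine), brute_mage(sine$values))
  expect_equal(mage(sine), 2.53615, tolerance = 1e-4)
  rise <- glucose_trace(c(0, 30, 60, 90, 120), c(6, 9, 12, 12, 12))
  expect_equal(mage(rise), 6)
  expect_error(mage(glucose_trace(c(0, 15), c(6, 7))), "3 readings")
  set.seed(505)
  for (i in 1:50) {
    tr <- random_trace()
    m0 <- mage(tr)
    expect_equal(m0, brute_mage(tr$values))
    shifted <- glucose_trace(tr$times, tr$values + 2.5)
    expect_equal(mage(shifted), m0, tolerance = 1e-10)
    scaled <- glucose_trace(tr$times, tr$values * 1.7)
    expect_equal(mage(scaled), 1.7 * m0, tolerance = 1e-10)
  }
})

test_that("trace summary agrees with its component metrics", {
  flat <- summarize_trace(constant_trace(7))
  expect_equal(flat$peak, 7)
  expect_equal(flat$delta_peak, 0)
  expect_equal(flat$delta_low, 0)
  expect_true(all(flat$iauc == 0))
  expect_equal(flat$tir_pct, 100)
  expect_equal(nrow(flat$episodes), 0)

  tr <- ramp_trace(6, 10)
  gs <- summarize_trace(tr)
  expect_equal(gs$window_means[["mean_0_300"]], mean_glucose(tr, 0, 300))
  expect_equal(gs$window_means[["mean_240_300"]], mean_glucose(tr, 240, 300))
  expect_equal(gs$peak, 10)
  expect_equal(gs$time_to_peak, 300)
  expect_equal(gs$total_auc, 2400)
  expect_equal(unname(gs$iauc), vapply(seq(30, 300, 30), function(e)
    incremental_auc(tr, e), numeric(1)))
  expect_equal(gs$mage, mage(tr))
  expect_equal(gs$delta_peak, 4)

  v <- rep(6, 21); v[8] <- 3.2
  dip <- summarize_trace(glucose_trace(grid15, v))
  expect_gt(dip$tbr_pct, 0)
  expect_equal(nrow(dip$episodes), 1)
  expect_equal(dip$delta_low, 3.2 - 6)
})

test_that("cohort summaries report mean and SE per arm with explicit n", {
  t1 <- ramp_trace(6, 10, subject_id = "A", arm = "X-CC")
  t2 <- ramp_trace(6, 10, subject_id = "B", arm = "X-CC")
  t3 <- ramp_trace(5, 9, subject_id = "A", arm = "X-FPU")
  t4 <- ramp_trace(7, 11, subject_id = "B", arm = "X-FPU")
  co <- cohort_summarize(list(t1, t2, t3, t4))
  s <- co$stats
  expect_equal(s$se[s$arm == "X-CC" & s$metric == "peak"], 0)
  expect_equal(s$mean[s$arm == "X-FPU" & s$metric == "peak"], 10)
  expect_equal(s$se[s$arm == "X-FPU" & s$metric == "peak"], sd(c(9, 11)) / sqrt(2))
  expect_true(all(s$n == 2))
  expect_error(cohort_summarize(list(t1)), "at least 2")
})
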