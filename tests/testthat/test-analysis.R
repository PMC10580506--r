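test_that("paired t test matches the textbook closed form", {
  res <- paired_t_test(c(1, 2, 3))
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-10)
  flip <- paired_t_test(-c(1, 2, 3))
  expect_equal(flip$statistic, -res$statistic, tolerance = 1e-12)
  expect_equal(flip$p_value, res$p_value, tolerance = 1e-12)
  zeros <- paired_t_test(rep(0, 5))
  expect_equal(zeros$statistic, 0)
  expect_equal(zeros$p_value, 1)
  expect_true(zeros$degenerate)
  expect_true(is.na(paired_t_test(rep(2, 4))$p_value))
  expect_error(paired_t_test(1), "at least 2")
  set.seed(606)
  for (i in 1:20) {
    d <- rnorm(sample(3:20, 1))
    res <- paired_t_test(d)
    tstat <- mean(d) / (sd(d) / sqrt(length(d)))
    expect_equal(res$statistic, tstat, tolerance = 1e-10)
    expect_equal(res$p_value, 2 * pt(-abs(tstat), length(d) - 1), tolerance = 1e-10)
  }
})

test_that("exact signed-rank p equals brute-force sign enumeration", {
  res <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(res$statistic, 6)   # positive-rank sum
  expect_equal(res$p_value, 0.25)  # 2 * (1/8)
  expect_equal(res$method, "exact")
  balanced <- wilcoxon_signed_rank(c(1, -1, 2, -2))
  expect_equal(balanced$p_value, 1)
  allzero <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(allzero$degenerate)
  set.seed(707)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    d <- round(rnorm(n, sd = 2), 1)
    d[d == 0] <- 0.5
    if (i %% 3 == 0) d <- c(d, d[1])  # inject ties in |d|
    expect_equal(wilcoxon_signed_rank(d)$p_value, brute_wilcoxon_p(d))
  }
})

test_that("exact signed-rank p agrees with wilcox.test on tie-free data", {
  set.seed(808)
  for (i in 1:20) {
    d <- rnorm(sample(5:12, 1))
    ours <- wilcoxon_signed_rank(d)
    ref <- wilcox.test(d, mu = 0, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-n signed-rank uses a continuity-corrected normal tail", {
  set.seed(909)
  d <- rnorm(30, mean = 0.3)
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$method, "normal-approximation")
  ref <- wilcox.test(d, mu = 0, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

make_arm_pair <- function(values_cc, values_fpu, n, jitter = 0.3) {
  traces <- list()
  for (i in seq_len(n)) {
    id <- sprintf("S%02d", i)
    traces <- c(traces, list(
      glucose_trace(grid15, values_cc + (i - 1) * jitter / n,
                    subject_id = id, arm = "NPM-CC"),
      glucose_trace(grid15, values_fpu + (i - 1) * jitter / n,
                    subject_id = id, arm = "NPM-FPU")))
  }
  traces
}

test_that("compare_arms pairs subjects and handles identical arms", {
  base <- 6 + 3 * exp(-((grid15 - 140) / 70)^2)
  traces <- make_arm_pair(base, base, n = 5)
  cmp <- compare_arms(traces, "NPM")
  expect_true(all(cmp$mean_diff == 0))
  expect_true(all(cmp$n_pairs == 5))
  # every p is degenerate-NA or 1 when the arms coincide
  expect_true(all(is.na(cmp$p_value) | cmp$p_value == 1))
})

test_that("unmatched subjects are excluded and counted", {
  base <- 6 + 3 * exp(-((grid15 - 140) / 70)^2)
  traces <- make_arm_pair(base, base - 0.5, n = 5)
  traces <- c(traces, list(glucose_trace(grid15, base, subject_id = "S99",
                                         arm = "NPM-CC")))
  cmp <- compare_arms(traces, "NPM")
  expect_equal(cmp$n_pairs[1], 5)
  expect_equal(attr(cmp, "n_excluded"), 1)
})

test_that("compare_arms is invariant to the ordering of input traces", {
  set.seed(111)
  trial <- simulate_trial(default_calibration(n_subjects = 8, seed = 13))
  cmp1 <- compare_arms(trial, "HPFM")
  shuffled <- trial$traces[sample(length(trial$traces))]
  cmp2 <- compare_arms(shuffled, "HPFM")
  expect_equal(as.data.frame(cmp1), as.data.frame(cmp2))
})

test_that("FPU dosing lowers late glucose in the simulated high protein-fat meal", {
  trial <- simulate_trial(default_calibration(n_subjects = 30, seed = 17))
  cmp <- compare_arms(trial, "HPFM")
  late <- cmp[cmp$metric == "mean_240_300", ]
  expect_gt(late$mean_diff, 0)  # CC minus FPU: FPU is lower
  expect_gt(late$mean_cc, late$mean_fpu)
})

test_that("hypoglycemia table counts discordant pairs exactly", {
  flat <- rep(6, 21)
  dip <- flat; dip[10] <- 3.4
  mk <- function(id, arm, v) glucose_trace(grid15, v, subject_id = id, arm = arm)
  # 5 pairs discordant in one direction: FPU dips, CC never does
  traces <- list()
  for (i in 1:5) {
    traces <- c(traces, list(mk(paste0("S", i), "NPM-CC", flat),
                             mk(paste0("S", i), "NPM-FPU", dip)))
  }
  ht <- hypoglycemia_table(traces)
  expect_equal(ht$by_arm$n_with_episode[ht$by_arm$arm == "NPM-FPU"], 5)
  expect_equal(ht$by_arm$pct_with_episode[ht$by_arm$arm == "NPM-FPU"], 100)
  expect_equal(ht$tests$p_value, 2 * (1 / 2)^5)  # 0.0625
  # balanced discordance
  traces2 <- list(mk("A", "NPM-CC", dip), mk("A", "NPM-FPU", flat),
                  mk("B", "NPM-CC", flat), mk("B", "NPM-FPU", dip))
  expect_equal(hypoglycemia_table(traces2)$tests$p_value, 1)
  # no episodes at all
  traces3 <- list(mk("A", "NPM-CC", flat), mk("A", "NPM-FPU", flat))
  ht3 <- hypoglycemia_table(traces3)
  expect_equal(ht3$tests$p_value, 1)
  expect_true(all(ht3$by_arm$n_with_episode == 0))
  # denominators always reported
  expect_true(all(c("n_subjects", "pct_with_episode") %in% names(ht3$by_arm)))
})
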