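#' Paired t test on within-subject differences
#'
#' One-sample t test of the differences against zero, two-sided. When every
#' difference is identical the statistic is degenerate and the p value is
#' returned as `NA` with `degenerate = TRUE` (by convention `p = 1` when all
#' differences are exactly zero and `zero_is_p1 = TRUE`).
#'
#' @param differences Numeric vector of paired differences, length >= 2.
#' @param zero_is_p1 Report `p = 1` instead of `NA` when all differences are 0.
#' @return List with `statistic`, `df`, `p_value`, `mean_diff`, `n`,
#'   `degenerate`.
#' @examples
#' paired_t_test(c(1, 2, 3))  # t = 3.464, p ~= 0.0742
#' @export
paired_t_test <- function(differences, zero_is_p1 = TRUE) {
  d <- as.numeric(differences)
  n <- length(d)
  if (n < 2) stop("need at least 2 differences", call. = FALSE)
  stderr <- stats::sd(d) / sqrt(n)
  if (stderr <= 10 * .Machine$double.eps * max(1, abs(mean(d)))) {
    all_zero <- all(d == 0)
    p <- if (all_zero && zero_is_p1) 1 else NA_real_
    return(list(statistic = if (all_zero) 0 else sign(mean(d)) * Inf,
                df = n - 1, p_value = p, mean_diff = mean(d), n = n,
                degenerate = TRUE))
  }
  tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), n = n, degenerate = FALSE)
}

#' Wilcoxon signed-rank test on within-subject differences
#'
#' Two-sided signed-rank test. Zero differences are dropped (Wilcoxon's
#' convention); ties in the absolute differences receive average ranks. For
#' `n <= exact_max` non-zero differences the null distribution of the
#' positive-rank sum V is enumerated exactly over all sign assignments
#' (valid under ties as well); beyond that a normal approximation with tie
#' correction and continuity correction is used. The statistic reported is
#' V, the positive-rank sum.
#'
#' @param differences Numeric vector of paired differences.
#' @param exact_max Largest n for exact enumeration (default 15).
#' @return List with `statistic` (V), `p_value`, `n` (non-zero differences),
#'   `n_dropped` (zeros), `method`, `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))  # V = 6, exact p = 0.25
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 15) {
  d <- as.numeric(differences)
  if (length(d) < 2) stop("need at least 2 differences", call. = FALSE)
  n_dropped <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = n,
                n_dropped = n_dropped, method = "undefined", degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: V over all 2^n equally likely sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = v, p_value = p, n = n, n_dropped = n_dropped,
       method = method, degenerate = FALSE)
}

# subjects present in both arms, in first-arm order
matched_subjects <- function(manifest_ids_a, manifest_ids_b) {
  intersect(manifest_ids_a, manifest_ids_b)
}

#' Paired comparison of dosing algorithms within a meal type
#'
#' The model-fitting entry point of the crossover analysis: for one meal
#' type, every glycemic outcome is compared between the carbohydrate-counting
#' arm (`<meal_type>-CC`) and the fat-protein-unit arm (`<meal_type>-FPU`)
#' with a paired test on the within-subject differences (CC minus FPU).
#' Subjects missing either arm are excluded and counted.
#'
#' @param dataset A `cgm_trial` from [simulate_trial()] or a list of
#'   [glucose_trace()] objects with arm labels.
#' @param meal_type Meal-type prefix of the two arms, e.g. `"NPM"` or
#'   `"HPFM"`.
#' @param test `"t"` (paired t) or `"wilcoxon"` (signed-rank).
#' @param ... Passed to [summarize_trace()].
#' @return An object of class `crossover_comparison`: a data frame with one
#'   row per metric (`metric`, `mean_cc`, `se_cc`, `mean_fpu`, `se_fpu`,
#'   `mean_diff`, `statistic`, `p_value`, `n_pairs`) plus attributes
#'   `meal_type`, `test`, `n_excluded`.
#' @examples
#' trial <- simulate_trial(default_calibration(n_subjects = 5, seed = 2))
#' compare_arms(trial, "NPM")
#' @export
compare_arms <- function(dataset, meal_type, test = c("t", "wilcoxon"), ...) {
  test <- match.arg(test)
  traces <- if (inherits(dataset, "cgm_trial")) dataset$traces else dataset
  arms <- vapply(traces, `[[`, "", "arm")
  ids <- vapply(traces, `[[`, "", "subject_id")
  arm_cc <- paste0(meal_type, "-CC"); arm_fpu <- paste0(meal_type, "-FPU")
  ids_cc <- ids[arms == arm_cc]; ids_fpu <- ids[arms == arm_fpu]
  common <- sort(intersect(ids_cc, ids_fpu))
  if (length(common) < 2) {
    stop("fewer than 2 subjects with both arms for meal type ", meal_type,
         call. = FALSE)
  }
  n_excluded <- length(union(ids_cc, ids_fpu)) - length(common)
  grab <- function(arm) {
    sel <- which(arms == arm & ids %in% common)
    sel <- sel[match(common, ids[sel])]
    do.call(rbind, lapply(traces[sel], function(tr)
      summary_scalars(summarize_trace(tr, ...))))
  }
  mat_cc <- grab(arm_cc); mat_fpu <- grab(arm_fpu)
  n <- length(common)
  rows <- lapply(colnames(mat_cc), function(metric) {
    a <- mat_cc[, metric]; b <- mat_fpu[, metric]
    d <- a - b
    res <- if (test == "t") paired_t_test(d) else wilcoxon_signed_rank(d)
    data.frame(metric = metric,
               mean_cc = mean(a), se_cc = stats::sd(a) / sqrt(n),
               mean_fpu = mean(b), se_fpu = stats::sd(b) / sqrt(n),
               mean_diff = mean(d),
               statistic = if (is.null(res$statistic)) NA_real_ else res$statistic,
               p_value = res$p_value, n_pairs = n)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("crossover_comparison", "data.frame")
  attr(out, "meal_type") <- meal_type
  attr(out, "test") <- test
  attr(out, "n_excluded") <- n_excluded
  out
}

#' @export
print.crossover_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Paired %s comparison, CC vs FPU, meal type %s (n = %d pairs%s)\n",
              ifelse(attr(x, "test") == "t", "t", "Wilcoxon signed-rank"),
              attr(x, "meal_type"), x$n_pairs[1],
              if (attr(x, "n_excluded") > 0)
                sprintf(", %d unmatched subject(s) excluded", attr(x, "n_excluded"))
              else ""))
  df <- as.data.frame(x)
  df$mean_cc <- round(df$mean_cc, digits); df$mean_fpu <- round(df$mean_fpu, digits)
  df$mean_diff <- round(df$mean_diff, digits)
  df$statistic <- round(df$statistic, digits)
  df$p_value <- signif(df$p_value, digits)
  print(df[, c("metric", "mean_cc", "mean_fpu", "mean_diff", "statistic", "p_value")],
        row.names = FALSE)
  cat(sprintf("%d outcomes compared; p values are unadjusted for multiplicity.\n",
              nrow(x)))
  invisible(x)
}

#' Hypoglycemia counts per arm with a paired exact comparison
#'
#' Per arm: the number of subjects with at least one episode, with its
#' explicit denominator. Within each meal type, the CC and FPU arms are
#' compared by the exact discordant-pair binomial test (exact McNemar): the
#' number of pairs discordant in each direction is tested against Binomial(b
#' + c, 1/2).
#'
#' @param dataset A `cgm_trial` or list of arm-labelled [glucose_trace()]s.
#' @param threshold Episode threshold in mmol/L (default 3.9).
#' @return An object of class `hypoglycemia_table`: list with `by_arm`
#'   (arm, n_subjects, n_with_episode, pct_with_episode, n_episodes) and
#'   `tests` (meal_type, discordant_cc_only, discordant_fpu_only, p_value).
#' @export
hypoglycemia_table <- function(dataset, threshold = 3.9) {
  traces <- if (inherits(dataset, "cgm_trial")) dataset$traces else dataset
  arms <- vapply(traces, `[[`, "", "arm")
  ids <- vapply(traces, `[[`, "", "subject_id")
  has_ep <- vapply(traces, function(tr)
    nrow(detect_hypoglycemia(tr, threshold)) > 0, logical(1))
  n_ep <- vapply(traces, function(tr)
    nrow(detect_hypoglycemia(tr, threshold)), numeric(1))
  by_arm <- do.call(rbind, lapply(sort(unique(arms)), function(a) {
    sel <- arms == a
    data.frame(arm = a, n_subjects = sum(sel),
               n_with_episode = sum(has_ep[sel]),
               pct_with_episode = 100 * sum(has_ep[sel]) / sum(sel),
               n_episodes = sum(n_ep[sel]))
  }))
  meal_types <- unique(sub("-(CC|FPU)$", "", grep("-(CC|FPU)$", arms, value = TRUE)))
  tests <- do.call(rbind, lapply(meal_types, function(mt) {
    cc <- paste0(mt, "-CC"); fpu <- paste0(mt, "-FPU")
    common <- intersect(ids[arms == cc], ids[arms == fpu])
    e_cc <- has_ep[arms == cc][match(common, ids[arms == cc])]
    e_fpu <- has_ep[arms == fpu][match(common, ids[arms == fpu])]
    b <- sum(e_cc & !e_fpu); cc_only <- b
    c_ <- sum(!e_cc & e_fpu)
    p <- if (b + c_ == 0) 1 else stats::binom.test(b, b + c_, 0.5)$p.value
    data.frame(meal_type = mt, n_pairs = length(common),
               discordant_cc_only = cc_only, discordant_fpu_only = c_,
               p_value = p)
  }))
  structure(list(by_arm = by_arm, tests = tests), class = "hypoglycemia_table")
}

#' @export
print.hypoglycemia_table <- function(x, ...) {
  cat("Hypoglycemic episodes by arm:\n")
  a <- x$by_arm
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-9s %d/%d subjects (%.1f%%), %d episode(s)\n",
                a$arm[i], a$n_with_episode[i], a$n_subjects[i],
                a$pct_with_episode[i], a$n_episodes[i]))
  }
  if (!is.null(x$tests) && nrow(x$tests)) {
    cat("Exact discordant-pair tests (CC vs FPU):\n")
    t <- x$tests
    for (i in seq_len(nrow(t))) {
      cat(sprintf("  %s: %d vs %d discordant pairs, p = %.4g (n = %d pairs)\n",
                  t$meal_type[i], t$discordant_cc_only[i],
                  t$discordant_fpu_only[i], t$p_value[i], t$n_pairs[i]))
    }
  }
  invisible(x)
}
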