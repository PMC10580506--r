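#' Mean glucose over a time window
#'
#' Arithmetic mean of the readings with `t_start <= t <= t_end` (closed
#' interval, so a reading at a window boundary contributes to both adjacent
#' windows).
#'
#' @param trace A [glucose_trace()].
#' @param t_start,t_end Window bounds in minutes.
#' @return Mean glucose in mmol/L.
#' @export
mean_glucose <- function(trace, t_start, t_end) {
  stopifnot(inherits(trace, "glucose_trace"))
  sel <- trace$times >= t_start & trace$times <= t_end
  if (!any(sel)) stop("no readings in window [", t_start, ", ", t_end, "]", call. = FALSE)
  mean(trace$values[sel])
}

#' Peak postprandial glucose and time to peak
#'
#' The highest reading after the meal (t > 0); the baseline reading does not
#' compete. Ties are broken by the earliest time.
#'
#' @param trace A [glucose_trace()].
#' @return A list with elements `peak` (mmol/L) and `time_to_peak` (min).
#' @export
peak_glucose <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  post <- trace$times > 0
  if (!any(post)) stop("trace has no post-baseline readings", call. = FALSE)
  v <- trace$values[post]; t <- trace$times[post]
  i <- which.max(v)  # which.max takes the first maximum: earliest-tie rule
  list(peak = v[i], time_to_peak = t[i])
}

# trapezoid over the (times, values) polyline from 0 to t_end, interpolating
# the right endpoint if t_end falls between readings
trapz_to <- function(times, values, t_end) {
  if (t_end > times[length(times)]) {
    stop("t_end is beyond the last reading", call. = FALSE)
  }
  if (t_end < times[1]) stop("t_end precedes the first reading", call. = FALSE)
  keep <- times <= t_end
  tt <- times[keep]; vv <- values[keep]
  if (tt[length(tt)] < t_end) {
    tt <- c(tt, t_end)
    vv <- c(vv, stats::approx(times, values, xout = t_end)$y)
  }
  if (length(tt) < 2L) return(0)
  sum(diff(tt) * (vv[-length(vv)] + vv[-1]) / 2)
}

#' Total area under the glucose curve
#'
#' Trapezoidal integral of glucose over `[0, t_end]`, in mmol/L x min.
#'
#' @param trace A [glucose_trace()].
#' @param t_end Upper limit in minutes (defaults to the last reading).
#' @return AUC in mmol/L x min.
#' @export
total_auc <- function(trace, t_end = max(trace$times)) {
  stopifnot(inherits(trace, "glucose_trace"))
  trapz_to(trace$times, trace$values, t_end)
}

#' Incremental area under the glucose curve
#'
#' Trapezoidal integral of the excursion above the pre-meal baseline,
#' `G(t) - G0`, over `[0, t_end]`. Under the default `"net"` policy, segments
#' below baseline contribute negative area, so the algebraic identity
#' `iAUC = AUC - G0 * t_end` holds. Under `"positive_only"`, sub-baseline
#' area is truncated at zero segment-wise, interpolating the baseline
#' crossing linearly within a segment.
#'
#' @param trace A [glucose_trace()].
#' @param t_end Upper limit in minutes.
#' @param policy `"net"` (default) or `"positive_only"`.
#' @return Incremental AUC in mmol/L x min.
#' @export
incremental_auc <- function(trace, t_end = max(trace$times),
                            policy = c("net", "positive_only")) {
  stopifnot(inherits(trace, "glucose_trace"))
  policy <- match.arg(policy)
  g0 <- trace_g0(trace)
  d <- trace$values - g0
  if (policy == "net") return(trapz_to(trace$times, d + g0, t_end) - g0 * t_end)
  # positive_only: clip each linear segment at the baseline
  keep <- trace$times <= t_end
  tt <- trace$times[keep]; dd <- d[keep]
  if (tt[length(tt)] < t_end) {
    tt <- c(tt, t_end)
    dd <- c(dd, stats::approx(trace$times, d, xout = t_end)$y)
  }
  area <- 0
  for (i in seq_len(length(tt) - 1L)) {
    h <- tt[i + 1L] - tt[i]; d1 <- dd[i]; d2 <- dd[i + 1L]
    if (d1 >= 0 && d2 >= 0) {
      area <- area + h * (d1 + d2) / 2
    } else if (d1 > 0 && d2 < 0) {
      area <- area + h * d1 / (d1 - d2) * d1 / 2      # triangle before crossing
    } else if (d1 < 0 && d2 > 0) {
      area <- area + h * d2 / (d2 - d1) * d2 / 2      # triangle after crossing
    }                                                  # both below: nothing
  }
  area
}

#' Fraction of readings in, above and below the glycemic target range
#'
#' Time in range is computed as the percentage of discrete sensor readings
#' (not interpolated durations). The target range is the closed interval
#' `[low, high]`; "above" and "below" are strict.
#'
#' @param trace A [glucose_trace()].
#' @param low,high Range bounds in mmol/L (defaults 3.9 and 10).
#' @return Named numeric vector `c(tir_pct, tar_pct, tbr_pct)` summing to 100.
#' @export
time_in_ranges <- function(trace, low = 3.9, high = 10) {
  stopifnot(inherits(trace, "glucose_trace"))
  if (low >= high) stop("low must be below high", call. = FALSE)
  v <- trace$values
  n <- length(v)
  c(tir_pct = 100 * sum(v >= low & v <= high) / n,
    tar_pct = 100 * sum(v > high) / n,
    tbr_pct = 100 * sum(v < low) / n)
}

#' Detect hypoglycemic episodes
#'
#' An episode is a maximal run of consecutive readings strictly below the
#' threshold; a single sub-threshold reading qualifies. The onset is the time
#' of the first sub-threshold reading of the run.
#'
#' @param trace A [glucose_trace()].
#' @param threshold Hypoglycemia threshold in mmol/L (default 3.9).
#' @return A data frame with one row per episode: `onset_min`, `end_min`,
#'   `nadir_mmol_l`. Zero rows when no reading is below threshold.
#' @export
detect_hypoglycemia <- function(trace, threshold = 3.9) {
  stopifnot(inherits(trace, "glucose_trace"))
  below <- trace$values < threshold
  if (!any(below)) {
    return(data.frame(onset_min = numeric(0), end_min = numeric(0),
                      nadir_mmol_l = numeric(0)))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  data.frame(
    onset_min = trace$times[starts[runs]],
    end_min = trace$times[ends[runs]],
    nadir_mmol_l = vapply(runs, function(k)
      min(trace$values[starts[k]:ends[k]]), numeric(1))
  )
}

#' Glucose excursions at 30-minute intervals
#'
#' The change in glucose over each successive 30-min interval,
#' `G(30k) - G(30(k-1))`. Readings must exist exactly at the 30-min marks;
#' no interpolation is performed.
#'
#' @param trace A [glucose_trace()].
#' @param t_end Last 30-min mark (default 300, giving ten excursions).
#' @return Numeric vector of excursions in mmol/L, named by interval end time.
#' @export
excursions_30min <- function(trace, t_end = 300) {
  stopifnot(inherits(trace, "glucose_trace"))
  marks <- seq(0, t_end, by = 30)
  idx <- match(marks, trace$times)
  if (anyNA(idx)) {
    stop("missing readings at 30-min marks: ",
         paste(marks[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  g <- trace$values[idx]
  stats::setNames(diff(g), paste0("exc_", marks[-1]))
}

#' Mean amplitude of glycemic excursions (MAGE)
#'
#' Classical turning-point definition: amplitudes are measured between
#' consecutive local extrema of the reading sequence (including the
#' endpoints); amplitudes exceeding one standard deviation of all readings
#' qualify, and MAGE is the mean of the qualifying amplitudes taken in the
#' direction (rising or falling) of the first qualifying amplitude. Returns 0
#' when no amplitude exceeds 1 SD.
#'
#' @param trace A [glucose_trace()].
#' @return MAGE in mmol/L.
#' @export
mage <- function(trace) {
  stopifnot(inherits(trace, "glucose_trace"))
  v <- trace$values
  if (length(v) < 3L) stop("MAGE needs at least 3 readings", call. = FALSE)
  s <- stats::sd(v)
  # collapse plateaus so turning points are well defined
  u <- v[c(TRUE, diff(v) != 0)]
  if (length(u) < 2L) return(0)
  dirs <- sign(diff(u))
  turning <- c(TRUE, dirs[-1] != dirs[-length(dirs)], TRUE)  # endpoints count
  ext <- u[turning]
  amp <- diff(ext)                 # signed amplitudes between extrema
  qual <- abs(amp) > s
  if (!any(qual)) return(0)
  first_dir <- sign(amp[which(qual)[1]])
  mean(abs(amp[qual & sign(amp) == first_dir]))
}

#' Full glycemic summary of one postprandial trace
#'
#' Computes every outcome parameter reported for the trial: window means
#' (0-120, 0-240, 0-300, 120-240, 240-300 min), peak glucose and time to
#' peak, total AUC, incremental AUC at every 30-min end time, MAGE, peak and
#' nadir excursions from baseline, time in/above/below range, hypoglycemic
#' episodes, and 30-min excursions.
#'
#' @param trace A [glucose_trace()].
#' @param iauc_policy Incremental AUC sign policy, see [incremental_auc()].
#' @param low,high Target range bounds in mmol/L.
#' @return An object of class `glycemic_summary`.
#' @export
summarize_trace <- function(trace, iauc_policy = c("net", "positive_only"),
                            low = 3.9, high = 10) {
  stopifnot(inherits(trace, "glucose_trace"))
  iauc_policy <- match.arg(iauc_policy)
  t_max <- max(trace$times)
  pk <- peak_glucose(trace)
  g0 <- trace_g0(trace)
  windows <- list(c(0, 120), c(0, 240), c(0, 300), c(120, 240), c(240, 300))
  wm <- vapply(windows, function(w)
    mean_glucose(trace, w[1], min(w[2], t_max)), numeric(1))
  names(wm) <- vapply(windows, function(w)
    sprintf("mean_%d_%d", w[1], w[2]), character(1))
  iauc_ends <- seq(30, min(300, t_max), by = 30)
  iauc <- vapply(iauc_ends, function(e)
    incremental_auc(trace, e, iauc_policy), numeric(1))
  names(iauc) <- paste0("iauc_0_", iauc_ends)
  ranges <- time_in_ranges(trace, low, high)
  eps <- detect_hypoglycemia(trace, threshold = low)
  exc <- tryCatch(excursions_30min(trace, t_end = min(300, t_max)),
                  error = function(e) NULL)
  structure(
    list(subject_id = trace$subject_id, arm = trace$arm,
         window_means = wm,
         peak = pk$peak, time_to_peak = pk$time_to_peak,
         total_auc = total_auc(trace, min(300, t_max)),
         iauc = iauc, iauc_policy = iauc_policy,
         mage = mage(trace),
         delta_peak = pk$peak - g0,
         delta_low = min(trace$values) - g0,
         tir_pct = unname(ranges["tir_pct"]),
         tar_pct = unname(ranges["tar_pct"]),
         tbr_pct = unname(ranges["tbr_pct"]),
         episodes = eps, excursions = exc),
    class = "glycemic_summary"
  )
}

#' @export
print.glycemic_summary <- function(x, ...) {
  cat(sprintf("Glycemic summary%s%s\n",
              if (is.na(x$subject_id)) "" else paste0(": subject ", x$subject_id),
              if (is.na(x$arm)) "" else paste0(" [", x$arm, "]")))
  cat(sprintf("  peak %.2f mmol/L at %g min (dPeak %+.2f, dLow %+.2f)\n",
              x$peak, x$time_to_peak, x$delta_peak, x$delta_low))
  for (nm in names(x$window_means)) {
    w <- sub("mean_", "", nm)
    cat(sprintf("  mean %-8s %.2f mmol/L\n", gsub("_", "-", w), x$window_means[[nm]]))
  }
  cat(sprintf("  AUC %.1f, iAUC(0-%g, %s) %.1f mmol/L*min, MAGE %.2f mmol/L\n",
              x$total_auc, max(as.numeric(sub("iauc_0_", "", names(x$iauc)))),
              x$iauc_policy, x$iauc[length(x$iauc)], x$mage))
  cat(sprintf("  TIR %.1f%% / TAR %.1f%% / TBR %.1f%%; %d hypoglycemic episode(s)\n",
              x$tir_pct, x$tar_pct, x$tbr_pct, nrow(x$episodes)))
  invisible(x)
}

# flatten a glycemic_summary to the named scalar vector used by cohort tables
summary_scalars <- function(gs) {
  out <- c(gs$window_means,
           peak = gs$peak, time_to_peak = gs$time_to_peak,
           total_auc = gs$total_auc, gs$iauc, mage = gs$mage,
           delta_peak = gs$delta_peak, delta_low = gs$delta_low,
           tir_pct = gs$tir_pct, tar_pct = gs$tar_pct, tbr_pct = gs$tbr_pct,
           n_episodes = nrow(gs$episodes))
  if (!is.null(gs$excursions)) out <- c(out, gs$excursions)
  out
}

#' Per-arm cohort summary of glycemic outcomes
#'
#' Summarizes each trace, groups by arm, and reports the mean and standard
#' error (sample SD / sqrt(n)) of every scalar outcome, plus hypoglycemia
#' episode counts with their explicit denominator.
#'
#' @param traces A list of [glucose_trace()] objects (or a `cgm_trial`).
#' @param ... Passed to [summarize_trace()].
#' @return An object of class `cohort_summary`: list with `stats` (data frame
#'   of arm/metric/mean/se/n) and `hypoglycemia` (data frame of arm,
#'   n_subjects, n_with_episode, pct_with_episode, n_episodes).
#' @export
cohort_summarize <- function(traces, ...) {
  if (inherits(traces, "cgm_trial")) traces <- traces$traces
  stopifnot(is.list(traces), length(traces) > 0)
  summaries <- lapply(traces, summarize_trace, ...)
  arms <- vapply(summaries, `[[`, "", "arm")
  counts <- table(arms)
  if (any(counts < 2)) {
    stop("each arm needs at least 2 traces; offending arm(s): ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  stats_rows <- list(); hypo_rows <- list()
  for (arm in sort(unique(arms))) {
    grp <- summaries[arms == arm]
    mat <- do.call(rbind, lapply(grp, summary_scalars))
    n <- nrow(mat)
    stats_rows[[arm]] <- data.frame(
      arm = arm, metric = colnames(mat),
      mean = colMeans(mat),
      se = apply(mat, 2, stats::sd) / sqrt(n),
      n = n, row.names = NULL)
    with_ep <- vapply(grp, function(g) nrow(g$episodes) > 0, logical(1))
    hypo_rows[[arm]] <- data.frame(
      arm = arm, n_subjects = n,
      n_with_episode = sum(with_ep),
      pct_with_episode = 100 * sum(with_ep) / n,
      n_episodes = sum(vapply(grp, function(g) nrow(g$episodes), numeric(1))),
      row.names = NULL)
  }
  structure(list(stats = do.call(rbind, c(stats_rows, make.row.names = FALSE)),
                 hypoglycemia = do.call(rbind, c(hypo_rows, make.row.names = FALSE)),
                 summaries = summaries),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, metrics = c("peak", "time_to_peak",
                                                "mean_0_300", "mean_240_300",
                                                "tir_pct", "tar_pct", "tbr_pct"),
                                 ...) {
  cat("Cohort glycemic summary (mean +- SE)\n")
  sub <- x$stats[x$stats$metric %in% metrics, ]
  for (arm in unique(sub$arm)) {
    s <- sub[sub$arm == arm, ]
    cat(sprintf("  %s (n = %d):\n", arm, s$n[1]))
    for (i in seq_len(nrow(s))) {
      cat(sprintf("    %-12s %8.2f +- %.2f\n", s$metric[i], s$mean[i], s$se[i]))
    }
  }
  cat("Hypoglycemia:\n")
  h <- x$hypoglycemia
  for (i in seq_len(nrow(h))) {
    cat(sprintf("  %s: %d/%d subjects (%.1f%%), %d episode(s)\n",
                h$arm[i], h$n_with_episode[i], h$n_subjects[i],
                h$pct_with_episode[i], h$n_episodes[i]))
  }
  invisible(x)
}
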