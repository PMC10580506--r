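#' Read CGM traces from the package CSV dialect
#'
#' The dialect is one reading per row with header
#' `subject_id,arm,time_min,glucose_mmol_l`. Rows are sorted by time within
#' each (subject, arm); duplicate (subject, arm, time) rows are rejected, and
#' every trace must include a baseline reading at t = 0.
#'
#' @param path Path to the CSV file.
#' @param units `"mmol_l"` (default) or `"mg_dl"`; mg/dL input is converted
#'   by dividing by 18.016 at the boundary.
#' @return A list of [glucose_trace()] objects, named `subject_id.arm`.
#' @export
read_cgm_csv <- function(path, units = c("mmol_l", "mg_dl")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("CGM file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("subject_id", "arm", "time_min", "glucose_mmol_l")
  if (!identical(names(df), need)) {
    stop("malformed CGM header: expected ", paste(need, collapse = ","),
         " but found ", paste(names(df), collapse = ","), call. = FALSE)
  }
  time_min <- suppressWarnings(as.numeric(df$time_min))
  glucose <- suppressWarnings(as.numeric(df$glucose_mmol_l))
  bad <- which(!is.finite(time_min) | !is.finite(glucose))
  if (length(bad)) {
    stop("non-numeric time or glucose at data row ", bad[1], call. = FALSE)
  }
  if (units == "mg_dl") glucose <- glucose / 18.016
  key <- paste(df$subject_id, df$arm, sep = ".")
  dup <- duplicated(data.frame(key, time_min))
  if (any(dup)) {
    stop("duplicate (subject, arm, time) at data row ", which(dup)[1], call. = FALSE)
  }
  traces <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    o <- idx[order(time_min[idx])]
    glucose_trace(time_min[o], glucose[o],
                  subject_id = df$subject_id[o[1]], arm = df$arm[o[1]])
  })
  traces[order(names(traces))]
}

#' Write CGM traces in the package CSV dialect
#'
#' Inverse of [read_cgm_csv()]; output is deterministic, so identical input
#' yields byte-identical files.
#'
#' @param x A `cgm_trial`, a list of [glucose_trace()]s, or a single trace.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(x, path) {
  if (inherits(x, "cgm_trial")) x <- x$traces
  if (inherits(x, "glucose_trace")) x <- list(x)
  rows <- do.call(rbind, lapply(x, as.data.frame))
  rows$glucose_mmol_l <- sprintf("%.10g", rows$glucose_mmol_l)
  rows$time_min <- sprintf("%.10g", rows$time_min)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a FreeStyle Libre-style export to a postprandial trace
#'
#' Reads a sensor export CSV with a device-timestamp column
#' (`dd-mm-yyyy HH:MM`) and a historic-glucose column, and converts the
#' timestamps to minutes relative to a stated meal start, keeping readings
#' in `[0, horizon]`.
#'
#' @param path Path to the export CSV.
#' @param meal_start Meal-start timestamp, `"dd-mm-yyyy HH:MM"`.
#' @param timestamp_col,glucose_col Column names in the export.
#' @param horizon Postprandial window length in minutes (default 300).
#' @param subject_id,arm Labels for the resulting trace.
#' @param units Glucose units of the export, as in [read_cgm_csv()].
#' @return A [glucose_trace()].
#' @export
read_libre_csv <- function(path, meal_start,
                           timestamp_col = "Device Timestamp",
                           glucose_col = "Historic Glucose mmol/L",
                           horizon = 300,
                           subject_id = NA_character_, arm = NA_character_,
                           units = c("mmol_l", "mg_dl")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("Libre export not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(timestamp_col, glucose_col)) {
    if (!col %in% names(df)) stop("missing column: ", col, call. = FALSE)
  }
  fmt <- "%d-%m-%Y %H:%M"
  t0 <- as.POSIXct(meal_start, format = fmt, tz = "UTC")
  if (is.na(t0)) stop("meal_start must be 'dd-mm-yyyy HH:MM'", call. = FALSE)
  ts <- as.POSIXct(df[[timestamp_col]], format = fmt, tz = "UTC")
  if (anyNA(ts)) {
    stop("unparseable timestamp at data row ", which(is.na(ts))[1], call. = FALSE)
  }
  mins <- as.numeric(difftime(ts, t0, units = "mins"))
  glucose <- suppressWarnings(as.numeric(df[[glucose_col]]))
  keep <- mins >= 0 & mins <= horizon & is.finite(glucose)
  if (units == "mg_dl") glucose <- glucose / 18.016
  o <- order(mins[keep])
  glucose_trace(mins[keep][o], glucose[keep][o],
                subject_id = subject_id, arm = arm)
}

# fixed-precision number formatting for report files:
# percent -> 1 decimal, everything else -> 2 decimals
fmt_metric <- function(metric, value) {
  ifelse(grepl("pct$|^pct", metric), sprintf("%.1f", value), sprintf("%.2f", value))
}

#' Full crossover trial report
#'
#' Runs the whole analysis on a dataset: per-arm cohort summary, paired
#' CC-vs-FPU comparison per meal type, and the hypoglycemia table.
#'
#' @param dataset A `cgm_trial` or list of arm-labelled [glucose_trace()]s.
#' @param meal_types Meal-type prefixes to compare (default from arm labels).
#' @param test Paired test for [compare_arms()].
#' @param ... Passed to [summarize_trace()].
#' @return An object of class `trial_report`: list with `cohort`,
#'   `comparisons` (one `crossover_comparison` per meal type) and
#'   `hypoglycemia`.
#' @export
trial_report <- function(dataset, meal_types = NULL, test = c("t", "wilcoxon"),
                         ...) {
  test <- match.arg(test)
  traces <- if (inherits(dataset, "cgm_trial")) dataset$traces else dataset
  arms <- vapply(traces, `[[`, "", "arm")
  if (is.null(meal_types)) {
    meal_types <- sort(unique(sub("-(CC|FPU)$", "",
                                  grep("-(CC|FPU)$", arms, value = TRUE))))
  }
  comparisons <- lapply(meal_types, function(mt)
    compare_arms(dataset, mt, test = test, ...))
  names(comparisons) <- meal_types
  structure(list(cohort = cohort_summarize(traces, ...),
                 comparisons = comparisons,
                 hypoglycemia = hypoglycemia_table(dataset)),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  print(x$cohort)
  for (cmp in x$comparisons) print(cmp)
  print(x$hypoglycemia)
  invisible(x)
}

#' Write a trial report to TSV and JSON files
#'
#' Writes `cohort_summary.tsv`, one `comparison_<meal>.tsv` per meal type,
#' `hypoglycemia.tsv` and a `results.json` bundle holding the unrounded
#' numbers. TSV values are fixed-precision (two decimals, one decimal for
#' percentages), and output is deterministic: identical input produces
#' byte-identical files.
#'
#' @param report A `trial_report` (or `cohort_summary`).
#' @param dir Output directory, created if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(report, "cohort_summary")) {
    report <- structure(list(cohort = report, comparisons = list(),
                             hypoglycemia = NULL), class = "trial_report")
  }
  stopifnot(inherits(report, "trial_report"))
  files <- character(0)
  write_tsv <- function(df, fname) {
    p <- file.path(dir, fname)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  co <- report$cohort$stats
  co$mean <- fmt_metric(co$metric, co$mean)
  co$se <- fmt_metric(co$metric, co$se)
  write_tsv(co, "cohort_summary.tsv")
  for (mt in names(report$comparisons)) {
    cmp <- as.data.frame(report$comparisons[[mt]])
    for (col in c("mean_cc", "se_cc", "mean_fpu", "se_fpu", "mean_diff")) {
      cmp[[col]] <- fmt_metric(cmp$metric, cmp[[col]])
    }
    cmp$statistic <- sprintf("%.3f", cmp$statistic)
    cmp$p_value <- sprintf("%.4f", cmp$p_value)
    write_tsv(cmp, paste0("comparison_", mt, ".tsv"))
  }
  if (!is.null(report$hypoglycemia)) {
    h <- report$hypoglycemia$by_arm
    h$pct_with_episode <- sprintf("%.1f", h$pct_with_episode)
    write_tsv(h, "hypoglycemia.tsv")
  }
  json <- list(
    cohort = report$cohort$stats,
    comparisons = lapply(report$comparisons, as.data.frame),
    hypoglycemia = if (is.null(report$hypoglycemia)) NULL else
      report$hypoglycemia[c("by_arm", "tests")])
  jpath <- file.path(dir, "results.json")
  jsonlite::write_json(json, jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, jpath)
  invisible(files)
}

#' Write a simulated trial as CSV plus JSON manifest
#'
#' Writes the CGM CSV dialect (`cgm.csv`) and a `manifest.json` recording
#' per-trace arm assignment, dose, subject parameters, rescue counts and the
#' seed.
#'
#' @param trial A `cgm_trial`.
#' @param dir Output directory.
#' @return Character vector of files written, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "cgm_trial"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "cgm.csv")
  write_cgm_csv(trial, csv)
  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(seed = trial$config$seed, n_subjects = trial$config$n_subjects,
         dt = trial$config$dt, horizon = trial$config$horizon,
         noise_sd = trial$config$noise_sd, ar1_rho = trial$config$ar1_rho,
         rescue_enabled = trial$config$rescue_enabled,
         glucose_floor = trial$config$glucose_floor,
         population = trial$config$population,
         kernels = list(
           carb = unclass(trial$config$carb_kernel),
           protein_fat = unclass(trial$config$pf_kernel),
           insulin = unclass(trial$config$insulin_kernel)),
         assignments = trial$manifest),
    man, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, man))
}
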