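#' Construct a postprandial CGM trace
#'
#' A trace is a series of interstitial glucose readings at minutes relative
#' to the start of the meal (t = 0 is the first bite). The trial design is a
#' 15-min grid over 0-300 min, but any strictly increasing time vector that
#' includes a baseline reading at t = 0 is accepted; operations that require
#' the grid (e.g. [excursions_30min()]) check for it themselves.
#'
#' @param times Minutes since meal start, strictly increasing, first element 0.
#' @param values Glucose in mmol/L, finite and positive, same length as `times`.
#' @param subject_id Subject label.
#' @param arm Trial arm label, conventionally one of `"NPM-CC"`, `"NPM-FPU"`,
#'   `"HPFM-CC"`, `"HPFM-FPU"`; free-form labels are allowed.
#' @return An object of class `glucose_trace`.
#' @export
glucose_trace <- function(times, values, subject_id = NA_character_,
                          arm = NA_character_) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values) || length(times) == 0L) {
    stop("times and values must be non-empty and of equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  if (times[1] != 0) {
    stop("trace must include a baseline reading at t = 0", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("glucose values must be finite and positive", call. = FALSE)
  }
  structure(
    list(times = times, values = values,
         subject_id = as.character(subject_id), arm = as.character(arm)),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("CGM trace%s%s: %d readings over %g-%g min, G0 = %.2f mmol/L\n",
              if (is.na(x$subject_id)) "" else paste0(" subject ", x$subject_id),
              if (is.na(x$arm)) "" else paste0(" [", x$arm, "]"),
              length(x$times), min(x$times), max(x$times), x$values[1]))
  invisible(x)
}

#' @export
as.data.frame.glucose_trace <- function(x, ...) {
  data.frame(subject_id = x$subject_id, arm = x$arm,
             time_min = x$times, glucose_mmol_l = x$values)
}

#' @export
plot.glucose_trace <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "b", pch = 16, cex = 0.6,
                 xlab = "minutes after meal", ylab = "glucose (mmol/L)",
                 main = paste0(ifelse(is.na(x$subject_id), "", x$subject_id),
                               ifelse(is.na(x$arm), "", paste0(" [", x$arm, "]"))),
                 ...)
  graphics::abline(h = c(3.9, 10), lty = 3, col = "grey40")
  invisible(x)
}

# baseline (t = 0) glucose
trace_g0 <- function(trace) trace$values[trace$times == 0][1]
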