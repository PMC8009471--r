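#' Fluorescence-to-temperature conversion constants
#'
#' The temperature-sensitive dye loses a fixed percentage of fluorescence per
#' degree of heating; the default 2.8% per degree Celsius, with cells starting
#' from a 25 degC baseline.
#'
#' @param decrement_per_degree Percent fluorescence decrement per degC (> 0).
#' @param baseline_temperature Starting temperature of the cells, degC.
#' @return An object of class `conversion_constants`.
#' @export
conversion_constants <- function(decrement_per_degree = 2.8,
                                 baseline_temperature = 25) {
  stopifnot(is.numeric(decrement_per_degree), length(decrement_per_degree) == 1L,
            is.numeric(baseline_temperature), length(baseline_temperature) == 1L)
  if (decrement_per_degree <= 0)
    stop("'decrement_per_degree' must be positive", call. = FALSE)
  structure(list(decrement_per_degree = decrement_per_degree,
                 baseline_temperature = baseline_temperature),
            class = "conversion_constants")
}

#' A fluorescence time trace with its baseline window
#'
#' @param times Sample times, s.
#' @param fluorescence Fluorescence values, arbitrary units (> 0).
#' @param baseline_window Two times (s) delimiting the pre-stimulation
#'   baseline, inclusive; default the first 60 s of imaging.
#' @return An object of class `fluorescence_trace` (a data frame with columns
#'   `time` and `fluorescence`, attribute `baseline_window`).
#' @export
fluorescence_trace <- function(times, fluorescence, baseline_window = c(0, 60)) {
  if (length(times) != length(fluorescence) || length(times) < 1L)
    stop("'times' and 'fluorescence' must have equal positive length",
         call. = FALSE)
  if (any(!is.finite(fluorescence)) || any(fluorescence <= 0))
    stop("fluorescence values must be positive and finite", call. = FALSE)
  if (length(baseline_window) != 2L || baseline_window[1L] > baseline_window[2L])
    stop("'baseline_window' must be an ordered pair of times", call. = FALSE)
  structure(data.frame(time = times, fluorescence = fluorescence),
            baseline_window = baseline_window,
            class = c("fluorescence_trace", "data.frame"))
}

#' Normalize a fluorescence trace to its baseline (F/F0)
#'
#' Divides the trace by the mean fluorescence over the baseline window, so the
#' baseline mean of the result is exactly 1.
#'
#' @param trace A [fluorescence_trace()].
#' @return A `fluorescence_trace` holding F/F0 values.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  win <- attr(trace, "baseline_window")
  in_win <- trace$time >= win[1L] & trace$time <= win[2L]
  if (!any(in_win))
    stop("baseline window contains no samples", call. = FALSE)
  f0 <- mean(trace$fluorescence[in_win])
  fluorescence_trace(trace$time, trace$fluorescence / f0,
                     baseline_window = win)
}

#' Convert normalized fluorescence to a temperature increment
#'
#' Every `decrement_per_degree` percent of fluorescence decrement below
#' baseline maps to one degree Celsius of heating:
#' `delta_T = (1 - F/F0) * 100 / decrement_per_degree`. Values of F/F0 above 1
#' yield negative increments (cooling/recovery).
#'
#' @param f_over_f0 Normalized fluorescence (> 0), vectorised.
#' @param constants A [conversion_constants()] object.
#' @return Temperature increment, degC.
#' @export
#' @examples
#' fluorescence_to_delta_T(0.972)  # 1 degC
fluorescence_to_delta_T <- function(f_over_f0,
                                    constants = conversion_constants()) {
  stopifnot(inherits(constants, "conversion_constants"))
  if (any(!is.finite(f_over_f0)) || any(f_over_f0 <= 0))
    stop("'f_over_f0' must be positive and finite", call. = FALSE)
  (1 - f_over_f0) * 100 / constants$decrement_per_degree
}

#' Convert a temperature increment to normalized fluorescence
#'
#' Exact inverse of [fluorescence_to_delta_T()]:
#' `F/F0 = 1 - decrement_per_degree * delta_T / 100`. Errors if the increment
#' is so large that F/F0 would be non-positive.
#'
#' @param delta_T Temperature increment, degC, vectorised.
#' @param constants A [conversion_constants()] object.
#' @return Normalized fluorescence F/F0.
#' @export
#' @examples
#' delta_T_to_fluorescence(9.40)  # 0.7368
delta_T_to_fluorescence <- function(delta_T,
                                    constants = conversion_constants()) {
  stopifnot(inherits(constants, "conversion_constants"))
  f <- 1 - constants$decrement_per_degree * delta_T / 100
  if (any(f <= 0))
    stop("temperature increment too large: F/F0 would be non-positive",
         call. = FALSE)
  f
}

#' Absolute temperature from an increment
#'
#' @param delta_T Temperature increment, degC.
#' @param constants A [conversion_constants()] object.
#' @return `baseline_temperature + delta_T`, degC.
#' @export
absolute_temperature <- function(delta_T, constants = conversion_constants()) {
  stopifnot(inherits(constants, "conversion_constants"))
  constants$baseline_temperature + delta_T
}

#' Convert a fluorescence trace to a temperature-increment trace
#'
#' Normalizes the trace to its baseline and applies the linear conversion.
#' An optional centered moving average (off by default) can smooth the trace
#' before conversion.
#'
#' @param trace A [fluorescence_trace()] (raw or already normalized).
#' @param constants A [conversion_constants()] object.
#' @param smooth_width Odd width (samples) of a centered moving average
#'   applied before conversion; `NULL` (default) applies none.
#' @return A data frame with columns `time` (s) and `delta_T` (degC).
#' @export
trace_to_delta_T <- function(trace, constants = conversion_constants(),
                             smooth_width = NULL) {
  norm <- normalize_trace(trace)
  f <- norm$fluorescence
  if (!is.null(smooth_width)) {
    smooth_width <- as.integer(smooth_width)
    if (smooth_width < 1L || smooth_width %% 2L == 0L)
      stop("'smooth_width' must be a positive odd integer", call. = FALSE)
    if (smooth_width > 1L) {
      half <- smooth_width %/% 2L
      n <- length(f)
      f <- vapply(seq_len(n), function(i) {
        mean(f[max(1L, i - half):min(n, i + half)])
      }, numeric(1))
    }
  }
  data.frame(time = norm$time,
             delta_T = fluorescence_to_delta_T(f, constants))
}
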