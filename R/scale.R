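#' UTCI heat-stress scale
#'
#' Defines the banding of UTCI (Universal Thermal Climate Index, in degrees
#' Celsius) into five ordinal heat-stress levels 0--4. The default
#' breakpoints follow the standard UTCI heat-stress categories: no thermal
#' stress up to 26, moderate (level 1) to 32, strong (level 2) to 38, very
#' strong (level 3) to 46, extreme (level 4) above 46. Cold stress is outside
#' the model: every UTCI at or below the first breakpoint maps to level 0.
#'
#' @param breakpoints Numeric vector of exactly four strictly increasing UTCI
#'   thresholds in degrees Celsius separating levels 0|1, 1|2, 2|3, 3|4.
#' @param labels Character vector of five level names.
#' @return An object of class `heat_stress_scale`.
#' @examples
#' sc <- heat_stress_scale()
#' classify_level(c(20, 34, 40, 47), sc)
#' @export
heat_stress_scale <- function(breakpoints = c(26, 32, 38, 46),
                              labels = c("none", "moderate", "strong",
                                         "very strong", "extreme")) {
  if (length(breakpoints) != 4L || anyNA(breakpoints) ||
      !all(is.finite(breakpoints))) {
    stop("`breakpoints` must be four finite UTCI thresholds", call. = FALSE)
  }
  if (any(diff(breakpoints) <= 0)) {
    stop("`breakpoints` must be strictly increasing", call. = FALSE)
  }
  if (length(labels) != 5L) {
    stop("`labels` must name the five levels 0-4", call. = FALSE)
  }
  structure(list(breakpoints = as.numeric(breakpoints),
                 labels = as.character(labels)),
            class = "heat_stress_scale")
}

#' @export
print.heat_stress_scale <- function(x, ...) {
  bp <- x$breakpoints
  lo <- c("-Inf", bp)
  hi <- c(bp, "Inf")
  cat("UTCI heat-stress scale (deg C):\n")
  for (i in seq_len(5L)) {
    cat(sprintf("  level %d (%s): (%s, %s]\n", i - 1L, x$labels[i],
                lo[i], hi[i]))
  }
  invisible(x)
}

#' Pedestrian heat-tolerance parameters
#'
#' Bundles the tunable parameters of the cumulative heat-stress model: the
#' stress budget `H` (maximum tolerant heat discomfort, in stress-minutes,
#' i.e. minutes weighted by heat-stress level), the walking speed, the time
#' quantum to which segment durations are rounded, the rounding rule, and an
#' optional recovery rate credited while walking through level-0 (no stress)
#' segments. The defaults reproduce the applied model: H = 60 stress-minutes
#' (calibrated from level-4 tolerance of 15 min), 1 m/s walking speed,
#' durations rounded up to 0.1 min, no recovery.
#'
#' @param H Stress budget in stress-minutes; must be positive.
#' @param walking_speed Walking speed in m/s; must be positive.
#' @param time_quantum Duration resolution in minutes; must be positive.
#' @param duration_rounding Either `"up"` (round up to the quantum, the
#'   default and the rule consistent with published segment durations) or
#'   `"nearest"`.
#' @param recovery_rate Stress-minutes recovered per minute spent on level-0
#'   segments; must be non-negative. Default 0 (no alleviation), matching the
#'   applied model.
#' @return An object of class `tolerance_params`.
#' @examples
#' p <- tolerance_params()
#' walk_duration(44.8, p)
#' @export
tolerance_params <- function(H = 60, walking_speed = 1, time_quantum = 0.1,
                             duration_rounding = c("up", "nearest"),
                             recovery_rate = 0) {
  duration_rounding <- match.arg(duration_rounding)
  if (!is.numeric(H) || length(H) != 1L || !is.finite(H) || H <= 0) {
    stop("`H` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(walking_speed) || length(walking_speed) != 1L ||
      !is.finite(walking_speed) || walking_speed <= 0) {
    stop("`walking_speed` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(time_quantum) || length(time_quantum) != 1L ||
      !is.finite(time_quantum) || time_quantum <= 0) {
    stop("`time_quantum` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(recovery_rate) || length(recovery_rate) != 1L ||
      !is.finite(recovery_rate) || recovery_rate < 0) {
    stop("`recovery_rate` must be non-negative", call. = FALSE)
  }
  structure(list(H = H, walking_speed = walking_speed,
                 time_quantum = time_quantum,
                 duration_rounding = duration_rounding,
                 recovery_rate = recovery_rate),
            class = "tolerance_params")
}

#' @export
print.tolerance_params <- function(x, ...) {
  cat(sprintf(paste0("Tolerance parameters: H = %g stress-min, speed = %g",
                     " m/s,\n  quantum = %g min (rounding: %s),",
                     " recovery = %g stress-min/min at level 0\n"),
              x$H, x$walking_speed, x$time_quantum, x$duration_rounding,
              x$recovery_rate))
  invisible(x)
}

#' Classify UTCI into a heat-stress level
#'
#' Maps UTCI values to integer levels 0--4 via the scale breakpoints. A value
#' exactly on a breakpoint maps to the higher (more severe) level, the
#' conservative choice for contiguous published bands.
#'
#' @param utci Numeric vector of UTCI values in degrees Celsius; must be
#'   finite.
#' @param scale A [heat_stress_scale()].
#' @return Integer vector of levels in 0--4.
#' @examples
#' classify_level(40)  # very strong heat stress
#' @export
classify_level <- function(utci, scale = heat_stress_scale()) {
  stopifnot(inherits(scale, "heat_stress_scale"))
  if (!is.numeric(utci) || anyNA(utci) || !all(is.finite(utci))) {
    stop("`utci` must be finite numeric", call. = FALSE)
  }
  findInterval(utci, scale$breakpoints)
}

#' Heat-stress level of a street segment from its UTCI range
#'
#' A segment whose UTCI summary spans more than one band is assigned the
#' level of its maximum UTCI: exposure is assessed at the worst point of the
#' segment.
#'
#' @param utci_min,utci_max Numeric vectors: UTCI range along each segment,
#'   `utci_min <= utci_max`, both finite.
#' @inheritParams classify_level
#' @return Integer vector of levels in 0--4.
#' @examples
#' segment_level(37, 40)  # spans strong and very strong: classified 3
#' @export
segment_level <- function(utci_min, utci_max, scale = heat_stress_scale()) {
  if (!is.numeric(utci_min) || !is.numeric(utci_max) ||
      anyNA(utci_min) || anyNA(utci_max) ||
      !all(is.finite(utci_min)) || !all(is.finite(utci_max))) {
    stop("UTCI range bounds must be finite numeric", call. = FALSE)
  }
  if (any(utci_min > utci_max)) {
    stop("`utci_min` must not exceed `utci_max`", call. = FALSE)
  }
  classify_level(utci_max, scale)
}

#' Quantized walking duration of a segment
#'
#' Converts segment length to walking time at the configured speed and rounds
#' it to the time quantum. The default rule rounds up: a pedestrian cannot
#' finish a segment in less than its true traversal time, and up-rounding is
#' the rule consistent with published per-segment durations (44.8 m at 1 m/s
#' is 0.8 min, not 0.7).
#'
#' @param length_m Numeric vector of segment lengths in meters, each >= 0.
#' @param params A [tolerance_params()].
#' @return Numeric vector of durations in minutes, multiples of the quantum.
#' @examples
#' walk_duration(c(71.1, 44.8, 60))
#' @export
walk_duration <- function(length_m, params = tolerance_params()) {
  stopifnot(inherits(params, "tolerance_params"))
  if (!is.numeric(length_m) || anyNA(length_m) ||
      !all(is.finite(length_m)) || any(length_m < 0)) {
    stop("`length_m` must be finite and non-negative", call. = FALSE)
  }
  q <- params$time_quantum
  ratio <- length_m / params$walking_speed / 60 / q
  # guard against 0.2/0.1-style binary representation excess before ceiling
  n <- switch(params$duration_rounding,
              up = ceiling(ratio - 1e-9),
              nearest = round(ratio))
  n * q
}
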