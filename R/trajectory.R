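#' Cumulative heat stress along an ordered sequence of exposures
#'
#' Heat stress accumulates as the running sum of level x duration
#' (stress-minutes) over traversed segments. With a positive
#' `recovery_rate`, level-0 segments instead credit recovery at that rate,
#' and the running total is floored at zero; the default rate of 0
#' reproduces the pure accumulation model.
#'
#' @param level Integer vector of per-segment heat-stress levels 0--4.
#' @param duration_min Numeric vector of per-segment durations in minutes.
#' @param params A [tolerance_params()].
#' @param initial_stress Stress already accumulated before the first segment,
#'   in stress-minutes.
#' @return Numeric vector: the running cumulative stress S_t after each
#'   segment (length 0 input gives length 0; the empty-route total is
#'   `initial_stress`).
#' @examples
#' cumulative_stress(level = 2, duration_min = 1.2)  # 2.4 stress-minutes
#' @export
cumulative_stress <- function(level, duration_min,
                              params = tolerance_params(),
                              initial_stress = 0) {
  stopifnot(inherits(params, "tolerance_params"),
            length(level) == length(duration_min))
  if (length(level) == 0L) return(numeric(0))
  if (any(level < 0 | level > 4) || anyNA(level)) {
    stop("levels must be in 0-4", call. = FALSE)
  }
  if (anyNA(duration_min) || any(duration_min < 0)) {
    stop("durations must be non-negative", call. = FALSE)
  }
  delta <- ifelse(level == 0, -params$recovery_rate * duration_min,
                  level * duration_min)
  if (params$recovery_rate == 0) {
    # pure accumulation: plain cumulative sum
    initial_stress + cumsum(delta)
  } else {
    s <- numeric(length(delta))
    acc <- initial_stress
    for (i in seq_along(delta)) {
      acc <- max(0, acc + delta[i])
      s[i] <- acc
    }
    s
  }
}

#' Remaining tolerant heat discomfort
#'
#' The walkability currency of a route: `R_t = H - S_t`, the share of the
#' stress budget still available. Returns the raw (possibly negative) value,
#' a view clamped at zero, and an exhaustion flag (`S_t >= H` means the
#' pedestrian has to stop walking and rest).
#'
#' @param S_t Numeric vector of cumulative stress values in stress-minutes,
#'   each >= 0.
#' @param params A [tolerance_params()].
#' @return A list with numeric vectors `r_t` and `clamped`, and logical
#'   vector `exhausted`.
#' @examples
#' remaining_tolerance(2.4)$r_t  # 57.6
#' @export
remaining_tolerance <- function(S_t, params = tolerance_params()) {
  stopifnot(inherits(params, "tolerance_params"))
  if (!is.numeric(S_t) || anyNA(S_t) || any(S_t < 0)) {
    stop("`S_t` must be non-negative numeric", call. = FALSE)
  }
  r <- params$H - S_t
  list(r_t = r, clamped = pmax(r, 0), exhausted = S_t >= params$H)
}

#' Evaluate a walking route segment by segment
#'
#' Runs the full dynamic-attenuation pipeline over an ordered table of street
#' segments: classify each segment's heat-stress level from its UTCI range
#' (worst case), quantize its walking duration, accumulate stress, and track
#' the remaining tolerant heat discomfort after every segment. The whole
#' trajectory is returned even past exhaustion, with the first exhausted
#' segment flagged.
#'
#' @param segments A data frame with columns `length_m`, and either
#'   `utci_min` and `utci_max` or a single `utci` column; an optional
#'   `segment_id` column names the segments. Must have at least one row.
#' @param scale A [heat_stress_scale()].
#' @param params A [tolerance_params()].
#' @param initial_stress Stress carried over from a preceding walk, in
#'   stress-minutes.
#' @return An object of class `stress_trajectory`: a data frame with one row
#'   per segment and columns `segment_id`, `utci_min`, `utci_max`,
#'   `length_m`, `level`, `duration_min`, `stress_contrib`, `s_t`, `r_t`,
#'   plus attributes `params`, `scale`, `exhausted_at` (index of the first
#'   segment with `r_t <= 0`, or `NA`).
#' @examples
#' seg <- data.frame(segment_id = "ab", utci_min = 34, utci_max = 36,
#'                   length_m = 71.1)
#' evaluate_route(seg)
#' @export
evaluate_route <- function(segments, scale = heat_stress_scale(),
                           params = tolerance_params(), initial_stress = 0) {
  stopifnot(is.data.frame(segments))
  if (nrow(segments) == 0L) {
    stop("`segments` must contain at least one segment", call. = FALSE)
  }
  if (!"utci_min" %in% names(segments) && "utci" %in% names(segments)) {
    segments$utci_min <- segments$utci
    segments$utci_max <- segments$utci
  }
  req <- c("utci_min", "utci_max", "length_m")
  miss <- setdiff(req, names(segments))
  if (length(miss)) {
    stop("`segments` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  id <- if ("segment_id" %in% names(segments)) {
    as.character(segments$segment_id)
  } else {
    sprintf("s%d", seq_len(nrow(segments)))
  }
  level <- segment_level(segments$utci_min, segments$utci_max, scale)
  dur <- walk_duration(segments$length_m, params)
  s_t <- cumulative_stress(level, dur, params, initial_stress)
  r_t <- params$H - s_t
  out <- data.frame(segment_id = id,
                    utci_min = segments$utci_min,
                    utci_max = segments$utci_max,
                    length_m = segments$length_m,
                    level = level,
                    duration_min = dur,
                    stress_contrib = level * dur,
                    s_t = s_t,
                    r_t = r_t,
                    stringsAsFactors = FALSE)
  exh <- which(r_t <= 0)
  structure(out,
            params = params, scale = scale,
            initial_stress = initial_stress,
            exhausted_at = if (length(exh)) exh[1L] else NA_integer_,
            class = c("stress_trajectory", "data.frame"))
}

#' Terminal values of a stress trajectory
#'
#' @param object A `stress_trajectory` from [evaluate_route()].
#' @param ... Unused.
#' @return A list with `total_length_m`, `total_duration_min`, terminal `s_t`
#'   and `r_t`, `exhausted` flag and `exhausted_at` index.
#' @export
summary.stress_trajectory <- function(object, ...) {
  n <- nrow(object)
  p <- attr(object, "params")
  res <- list(n_segments = n,
              total_length_m = sum(object$length_m),
              total_duration_min = sum(object$duration_min),
              s_t = object$s_t[n],
              r_t = object$r_t[n],
              H = p$H,
              exhausted = object$r_t[n] <= 0,
              exhausted_at = attr(object, "exhausted_at"))
  class(res) <- "summary.stress_trajectory"
  res
}

#' @export
print.summary.stress_trajectory <- function(x, ...) {
  cat(sprintf("Walk of %d segment(s), %.1f m, %.1f min\n", x$n_segments,
              x$total_length_m, x$total_duration_min))
  cat(sprintf("  cumulative stress S_t = %.1f stress-min (budget H = %g)\n",
              x$s_t, x$H))
  cat(sprintf("  remaining tolerance R_t = %.1f stress-min%s\n", x$r_t,
              if (x$exhausted) sprintf(" [exhausted at segment %d]",
                                       x$exhausted_at) else ""))
  invisible(x)
}

#' @export
print.stress_trajectory <- function(x, ...) {
  cat("Heat-stress trajectory:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  print(summary(x))
  invisible(x)
}

#' Plot the remaining tolerance along a route
#'
#' Step plot of R_t against cumulative walking time, with the exhaustion
#' line at zero.
#'
#' @param x A `stress_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.stress_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  tt <- c(0, cumsum(x$duration_min))
  rr <- c(p$H - attr(x, "initial_stress"), x$r_t)
  graphics::plot(tt, rr, type = "s", xlab = "walking time (min)",
                 ylab = "remaining tolerant heat discomfort (stress-min)",
                 ylim = range(0, rr), ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  invisible(x)
}

#' Read a segment table from CSV
#'
#' Expects columns `segment_id`, `utci_min`, `utci_max`, `length_m` (a
#' single `utci` column is accepted in place of the range).
#'
#' @param path Path to a CSV file.
#' @return A data frame suitable for [evaluate_route()].
#' @export
read_segments <- function(path) {
  seg <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"length_m" %in% names(seg) ||
      !("utci_max" %in% names(seg) || "utci" %in% names(seg))) {
    stop("segment CSV needs columns length_m and utci_min/utci_max (or utci)",
         call. = FALSE)
  }
  seg
}

#' Write an evaluated trajectory to CSV
#'
#' Emits the input columns plus the computed `level`, `duration_min`,
#' `stress_contrib`, `s_t` and `r_t`.
#'
#' @param trajectory A `stress_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "stress_trajectory"))
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
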