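#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))`, with
#' sample variances (n-1 denominator). Used to check the reliability of the
#' per-minute discomfort item series of a walking survey.
#'
#' @param items Numeric matrix or data frame, respondents in rows, items in
#'   columns; at least two of each and no missing values.
#' @return The coefficient (a single number, at most 1; near 0 for
#'   independent items, 1 for perfectly correlated items).
#' @examples
#' x <- cbind(a = c(1, 2, 3), b = c(1, 2, 4))
#' cronbach_alpha(x)  # ~0.947
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (!is.numeric(m)) stop("`items` must be numeric", call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 respondents and 2 items", call. = FALSE)
  }
  if (anyNA(m)) stop("`items` must be complete (no NA)", call. = FALSE)
  k <- ncol(m)
  iv <- apply(m, 2L, stats::var)
  tv <- stats::var(rowSums(m))
  if (tv == 0) {
    stop("total-score variance is zero; alpha undefined", call. = FALSE)
  }
  k / (k - 1) * (1 - sum(iv) / tv)
}

validate_panel <- function(panel) {
  need <- c("respondent_id", "heat_level", "minute", "discomfort")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(panel$minute < 1 | panel$minute > 15)) {
    stop("minutes must be within 1-15", call. = FALSE)
  }
  if (any(panel$heat_level < 1 | panel$heat_level > 4)) {
    stop("heat levels must be within 1-4", call. = FALSE)
  }
  if (any(panel$discomfort < 1 | panel$discomfort > 4)) {
    stop("discomfort categories must be within 1-4", call. = FALSE)
  }
  invisible(panel)
}

#' Read a survey panel from CSV
#'
#' Long format: one row per (respondent, heat level, minute) with the
#' ordinal discomfort response (1 slightly uncomfortable, 2 uncomfortable,
#' 3 very, 4 extremely).
#'
#' @param path CSV path with columns `respondent_id`, `heat_level`,
#'   `minute`, `discomfort`.
#' @return Validated data frame.
#' @export
read_survey_panel <- function(path) {
  validate_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Discomfort timeline for one heat-stress level
#'
#' Aggregates the panel's responses minute by minute (median across
#' respondents, ties resolved to the higher, more severe category — a robust
#' rule for ordinal data) and locates the onset of each discomfort category:
#' the first minute whose aggregate response is at or above it. The
#' tolerated duration is the last minute before extreme discomfort (category
#' 4) sets in, or 15 when it never does.
#'
#' @param panel A survey panel data frame (see [read_survey_panel()]).
#' @param level Heat-stress level in 1--4 to analyze.
#' @return Object of class `discomfort_timeline`: list with `level`,
#'   `per_minute` (data frame `minute`, `category`), `onsets` (named vector,
#'   first minute at or above categories 1-4, `NA` if never reached) and
#'   `tolerated_duration` in minutes.
#' @export
discomfort_timeline <- function(panel, level) {
  validate_panel(panel)
  stopifnot(length(level) == 1L, level %in% 1:4)
  sub <- panel[panel$heat_level == level, ]
  minutes <- 1:15
  covered <- minutes %in% sub$minute
  if (!all(covered)) {
    stop(sprintf("no responses for level %d at minute(s) %s", level,
                 paste(minutes[!covered], collapse = ", ")), call. = FALSE)
  }
  agg <- vapply(minutes, function(m) {
    as.integer(ceiling(stats::median(sub$discomfort[sub$minute == m])))
  }, integer(1))
  onsets <- vapply(1:4, function(cat) {
    hit <- which(agg >= cat)
    if (length(hit)) minutes[hit[1L]] else NA_integer_
  }, integer(1))
  names(onsets) <- c("slightly", "uncomfortable", "very", "extremely")
  tol <- if (is.na(onsets[4L])) 15L else onsets[4L] - 1L
  structure(list(level = level,
                 per_minute = data.frame(minute = minutes, category = agg),
                 onsets = onsets,
                 tolerated_duration = as.integer(tol)),
            class = "discomfort_timeline")
}

#' @export
print.discomfort_timeline <- function(x, ...) {
  cat(sprintf("Discomfort timeline at heat-stress level %d:\n", x$level))
  on <- ifelse(is.na(x$onsets), "never", sprintf("min %d", x$onsets))
  for (i in seq_along(x$onsets)) {
    cat(sprintf("  %-14s onset: %s\n", names(x$onsets)[i], on[i]))
  }
  cat(sprintf("  tolerated duration: %d min\n", x$tolerated_duration))
  invisible(x)
}

#' Calibrate the heat-tolerance budget H
#'
#' The stress budget is the product of a heat-stress level and the walking
#' duration tolerated at that level: a range of tolerated durations maps to
#' a range of H values (in stress-minutes). The chosen H defaults to the
#' upper end of the range (the aspirational policy); the lower end or the
#' midpoint can be chosen instead.
#'
#' @param level Heat-stress level in 1--4 at which tolerance was observed
#'   (level 0 accrues no stress, so H is undefined there).
#' @param tolerated_duration Tolerated walking duration in minutes, a single
#'   value or a `c(lower, upper)` range, each in (0, 15].
#' @param choose Policy for the chosen H: `"upper"` (default), `"lower"`,
#'   or `"midpoint"`.
#' @return Object of class `tolerance_estimate`: list with `level`,
#'   `duration_range`, `H_range`, `H`, `policy`.
#' @examples
#' estimate_H(4, c(13, 15))  # H range 52-60, chosen 60
#' @export
estimate_H <- function(level, tolerated_duration,
                       choose = c("upper", "lower", "midpoint")) {
  choose <- match.arg(choose)
  if (length(level) != 1L || !level %in% 1:4) {
    if (identical(as.numeric(level), 0)) {
      stop("H is undefined at level 0: no stress accrues", call. = FALSE)
    }
    stop("`level` must be a single value in 1-4", call. = FALSE)
  }
  d <- sort(as.numeric(tolerated_duration))
  if (!length(d) %in% 1:2 || anyNA(d) || any(d <= 0) || any(d > 15)) {
    stop("`tolerated_duration` must be one or two values in (0, 15]",
         call. = FALSE)
  }
  if (length(d) == 1L) d <- c(d, d)
  H_range <- level * d
  H <- switch(choose, upper = H_range[2L], lower = H_range[1L],
              midpoint = mean(H_range))
  structure(list(level = level, duration_range = d, H_range = H_range,
                 H = H, policy = choose),
            class = "tolerance_estimate")
}

#' @export
print.tolerance_estimate <- function(x, ...) {
  cat(sprintf(
    "Tolerance budget from level-%d walking tolerance of %g-%g min:\n",
    x$level, x$duration_range[1L], x$duration_range[2L]))
  cat(sprintf("  H range %g-%g stress-min; chosen H = %g (%s policy)\n",
              x$H_range[1L], x$H_range[2L], x$H, x$policy))
  invisible(x)
}

#' Per-level survey reliability
#'
#' Treats the 15 per-minute responses at each heat-stress level as an item
#' series (respondents x minutes) and computes Cronbach's alpha per level.
#' Respondents with incomplete series at a level are dropped for that level.
#'
#' @param panel A survey panel data frame.
#' @return Named numeric vector of alpha per heat-stress level present in
#'   the panel (`NA` where the statistic is undefined, e.g. zero variance).
#' @export
survey_reliability <- function(panel) {
  validate_panel(panel)
  levels_present <- sort(unique(panel$heat_level))
  vapply(levels_present, function(l) {
    sub <- panel[panel$heat_level == l, ]
    wide <- stats::reshape(sub[, c("respondent_id", "minute", "discomfort")],
                           idvar = "respondent_id", timevar = "minute",
                           direction = "wide")
    m <- as.matrix(wide[, -1L, drop = FALSE])
    m <- m[stats::complete.cases(m), , drop = FALSE]
    tryCatch(cronbach_alpha(m), error = function(e) NA_real_)
  }, numeric(1)) |> stats::setNames(paste0("level", levels_present))
}
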