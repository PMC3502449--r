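# Pseudo-random signal-contingent prompt scheduling.
#
# The daily sampling window is split into as many equal-width epochs as there
# are prompts; one alarm time is drawn uniformly (whole minutes) within each
# epoch and consecutive alarms are forced at least `min_gap` minutes apart.

#' Prompt-schedule configuration
#'
#' Defaults encode the study protocol: six prompts per day at pseudo-random
#' times between 09:00 and 21:00, at least one hour apart, a five-minute
#' snooze, a 15-minute response window anchored at the initial alarm, for
#' seven days (42 scheduled entries).
#'
#' @param window_start,window_end Sampling window, minutes since midnight.
#' @param prompts_per_day Number of alarms per day.
#' @param min_gap Minimum gap between consecutive alarms, minutes.
#' @param snooze_delay Snooze reminder delay, minutes.
#' @param response_window Minutes from the initial alarm before expiry.
#' @param days Number of sampling days.
#' @param seed Optional integer seed; when given, schedule generation is
#'   reproducible without touching the caller's RNG state otherwise.
#' @return An `ema_schedule_config` list.
#' @export
schedule_config <- function(window_start = 540, window_end = 1260,
                            prompts_per_day = 6, min_gap = 60,
                            snooze_delay = 5, response_window = 15,
                            days = 7, seed = NULL) {
  cfg <- list(
    window_start = as.integer(window_start),
    window_end = as.integer(window_end),
    prompts_per_day = as.integer(prompts_per_day),
    min_gap = as.integer(min_gap),
    snooze_delay = as.integer(snooze_delay),
    response_window = as.integer(response_window),
    days = as.integer(days), seed = seed
  )
  if (cfg$prompts_per_day < 1L) {
    stop("prompts_per_day must be at least 1")
  }
  if (cfg$window_end - cfg$window_start < cfg$prompts_per_day * cfg$min_gap) {
    stop(
      "infeasible schedule: window shorter than prompts_per_day * min_gap"
    )
  }
  structure(cfg, class = "ema_schedule_config")
}

#' Draw one day's pseudo-random prompt times
#'
#' The window is stratified into `prompts_per_day` equal epochs; each time is
#' uniform (whole minutes) within its epoch. A draw violating the minimum gap
#' to its predecessor is re-drawn within its epoch (up to 100 retries), then
#' deterministically repaired to the earliest feasible minute. Uses the
#' current RNG state; seed via [set.seed()] or `config$seed` through
#' [make_week_schedule()].
#'
#' @param config An `ema_schedule_config`.
#' @return Integer vector of `prompts_per_day` minutes-since-midnight,
#'   strictly increasing with gaps `>= min_gap`.
#' @export
make_day_schedule <- function(config) {
  n <- config$prompts_per_day
  width <- (config$window_end - config$window_start) / n
  times <- integer(n)
  for (k in seq_len(n)) {
    lo <- config$window_start + (k - 1) * width
    hi <- config$window_start + k * width
    draw <- function() as.integer(floor(stats::runif(1, lo, hi)))
    t <- draw()
    if (k > 1L) {
      tries <- 0L
      while (t - times[k - 1] < config$min_gap && tries < 100L) {
        t <- draw()
        tries <- tries + 1L
      }
      if (t - times[k - 1] < config$min_gap) {
        t <- max(as.integer(ceiling(lo)), times[k - 1] + config$min_gap)
      }
    }
    times[k] <- t
  }
  times
}

#' Generate a full week of alarms
#'
#' @param config An `ema_schedule_config`; at defaults this yields
#'   `7 * 6 = 42` alarms.
#' @return An `ema_week_schedule`: a data frame with columns `day`,
#'   `alarm_index` (within day), `global_index` (1-based across the week,
#'   drives set alternation), `time` and `expiry` (minutes since midnight),
#'   with the configuration attached as attribute `config`.
#' @examples
#' sched <- make_week_schedule(schedule_config(seed = 1))
#' nrow(sched)
#' @export
make_week_schedule <- function(config = schedule_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  days <- rep(seq_len(config$days), each = config$prompts_per_day)
  times <- unlist(lapply(seq_len(config$days), function(d) {
    make_day_schedule(config)
  }))
  out <- data.frame(
    day = days,
    alarm_index = rep(seq_len(config$prompts_per_day), config$days),
    global_index = seq_along(days),
    time = times,
    expiry = times + config$response_window
  )
  attr(out, "config") <- config
  class(out) <- c("ema_week_schedule", "data.frame")
  out
}

#' Construct a single alarm event
#'
#' @param day 1-based day index.
#' @param time Alarm time, minutes since midnight.
#' @param config An `ema_schedule_config` (supplies the response window).
#' @return An `ema_alarm` list with fields `day`, `time`, `reminder_time`
#'   (NA until snoozed), `snooze_used` and `expiry` (fixed at
#'   `time + response_window`, anchored to the initial alarm).
#' @export
alarm_event <- function(day, time, config = schedule_config()) {
  structure(
    list(
      day = as.integer(day), time = as.integer(time),
      reminder_time = NA_integer_, snooze_used = FALSE,
      expiry = as.integer(time) + config$response_window,
      snooze_delay = config$snooze_delay
    ),
    class = "ema_alarm"
  )
}

#' Apply the snooze function to an alarm
#'
#' Schedules a single repeat reminder `snooze_delay` minutes after the alarm.
#' The response-window expiry is anchored to the initial alarm and does not
#' move. A second snooze is rejected.
#'
#' @param alarm An `ema_alarm`.
#' @return The alarm with `reminder_time` set and `snooze_used = TRUE`.
#' @export
apply_snooze <- function(alarm) {
  if (isTRUE(alarm$snooze_used)) {
    stop(errorCondition("snooze has already been used for this alarm",
      class = c("emadiary_snooze_error", "emadiary_error")
    ))
  }
  alarm$reminder_time <- alarm$time + alarm$snooze_delay
  alarm$snooze_used <- TRUE
  alarm
}

#' Classify a response time against the alarm's window
#'
#' @param alarm An `ema_alarm`.
#' @param answered_at Completion time, minutes since midnight
#'   (`>= alarm$time`).
#' @return `"on_time"` if `answered_at <= expiry` (the boundary minute still
#'   counts), else `"expired"`.
#' @export
classify_response_time <- function(alarm, answered_at) {
  stopifnot(answered_at >= alarm$time)
  if (answered_at <= alarm$expiry) "on_time" else "expired"
}
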