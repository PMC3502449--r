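# Scale scoring, composites, person-level aggregation and compliance.

#' Compliance rule
#'
#' Compliance requires completing at least a fraction of all scheduled
#' entries; the threshold count is the smallest integer at or above
#' `fraction * n_possible` (at the defaults, 33% of 42 = 14 or more).
#'
#' @param fraction_threshold Minimum completed fraction (default 0.33).
#' @param n_possible Scheduled entries (default 42).
#' @return An `ema_compliance_rule` with the derived `threshold_count`.
#' @export
compliance_rule <- function(fraction_threshold = 0.33, n_possible = 42L) {
  structure(
    list(
      fraction_threshold = fraction_threshold,
      n_possible = as.integer(n_possible),
      threshold_count = as.integer(ceiling(fraction_threshold * n_possible))
    ),
    class = "ema_compliance_rule"
  )
}

#' Score one scale at one time-point
#'
#' The scale score is the mean of the scale's answered items on the 1--7
#' continuum, after applying item recodes (the first grandiosity item via
#' [recode_grandiosity1()]). Branch items hidden in that session are excluded
#' from the mean, not imputed. If no item of the scale was displayed the score
#' is undefined (`NA`), never zero.
#'
#' @param entry A completed `ema_session`.
#' @param scale A scale definition from the bank (or bank view).
#' @return Numeric scalar in `[1, 7]`, or `NA_real_`.
#' @export
score_entry_scale <- function(entry, scale) {
  vals <- numeric(0)
  for (it in scale$items) {
    v <- get_response(entry$responses, it$item_id)
    if (is.na(v)) next
    if (identical(it$recode, "grandiosity1")) v <- recode_grandiosity1(v)
    vals <- c(vals, v)
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Delusions composite score
#'
#' Mirrors how the corresponding interview item is rated: the mean of every
#' configured delusion item response together with the session's grandiosity,
#' somatic-concern and suspiciousness scale means. With no delusions
#' configured, it is the mean of those three scale means alone.
#'
#' @param entry A completed set-two `ema_session`.
#' @param view The participant's `ema_bank_view`.
#' @return Numeric scalar in `[1, 7]`, or `NA_real_` when no component is
#'   available.
#' @export
composite_delusions <- function(entry, view) {
  del_vals <- numeric(0)
  for (it in view$scales$delusions$items) {
    v <- get_response(entry$responses, it$item_id)
    if (!is.na(v)) del_vals <- c(del_vals, v)
  }
  comps <- c(
    del_vals,
    score_entry_scale(entry, view$scales$grandiosity),
    score_entry_scale(entry, view$scales$somatic_concern),
    score_entry_scale(entry, view$scales$suspiciousness)
  )
  comps <- comps[!is.na(comps)]
  if (length(comps) == 0L) return(NA_real_)
  mean(comps)
}

#' Depression composite score
#'
#' The mean of the session's depression item responses together with the
#' hopelessness scale mean (hopelessness informs the interview depression
#' rating).
#'
#' @param entry A completed set-one `ema_session`.
#' @param view Bank or bank view.
#' @return Numeric scalar in `[1, 7]`, or `NA_real_`.
#' @export
composite_depression <- function(entry, view) {
  dep_vals <- numeric(0)
  for (it in view$scales$depression$items) {
    v <- get_response(entry$responses, it$item_id)
    if (!is.na(v)) dep_vals <- c(dep_vals, v)
  }
  comps <- c(dep_vals, score_entry_scale(entry, view$scales$hopelessness))
  comps <- comps[!is.na(comps)]
  if (length(comps) == 0L) return(NA_real_)
  mean(comps)
}

#' Score all sessions of a participant
#'
#' Produces one row per (session, scale) with a defined score. The delusions
#' and depression rows carry their composite scores; all other scales their
#' plain item means.
#'
#' @param sessions List of `ema_session` objects for one participant.
#' @param view The participant's `ema_bank_view`.
#' @return data.frame `participant_id`, `day`, `alarm_index`, `set`,
#'   `scale_id`, `value`.
#' @export
score_sessions <- function(sessions, view) {
  rows <- lapply(sessions, function(s) {
    if (s$status != "completed") return(NULL)
    set_scales <- Filter(function(sc) sc$set == s$set, view$scales)
    vals <- vapply(set_scales, function(sc) {
      switch(sc$composite,
        delusions_composite = composite_delusions(s, view),
        depression_composite = composite_depression(s, view),
        score_entry_scale(s, sc)
      )
    }, 0)
    keep <- !is.na(vals)
    if (!any(keep)) return(NULL)
    data.frame(
      participant_id = s$participant_id, day = s$day,
      alarm_index = s$alarm_index, set = s$set,
      scale_id = names(set_scales)[keep], value = unname(vals[keep])
    )
  })
  out <- rbind_rows(rows)
  if (is.null(out)) {
    out <- data.frame(
      participant_id = character(), day = integer(), alarm_index = integer(),
      set = integer(), scale_id = character(), value = numeric()
    )
  }
  out
}

#' Person-level mean of a time-point series
#'
#' Unweighted mean over the available (non-missing) time-points; undefined
#' (`NA`) for an empty series.
#'
#' @param scores Numeric vector of time-point scale scores (may contain NA).
#' @return Numeric scalar or `NA_real_`.
#' @examples
#' person_mean(c(2, NA, 4))
#' @export
person_mean <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0L) return(NA_real_)
  mean(scores)
}

#' Classify compliance
#'
#' @param n_completed Completed entries.
#' @param rule An `ema_compliance_rule`.
#' @return TRUE iff `n_completed >= threshold_count`.
#' @examples
#' classify_compliance(14, compliance_rule())
#' @export
classify_compliance <- function(n_completed, rule = compliance_rule()) {
  stopifnot(n_completed >= 0, n_completed <= rule$n_possible)
  n_completed >= rule$threshold_count
}

#' Completion percentage, rounded to the nearest integer
#'
#' @param n_completed,n_possible Counts, `n_possible > 0`.
#' @return Integer percentage.
#' @examples
#' completion_percent(36, 44)
#' @export
completion_percent <- function(n_completed, n_possible) {
  stopifnot(n_possible > 0)
  as.integer(round(100 * n_completed / n_possible))
}

#' Summarise per-person scale means, entry counts and compliance
#'
#' @param scores A time-point score table from [score_sessions()] (possibly
#'   row-bound over participants).
#' @param n_completed Named integer vector: completed entries per participant
#'   (distinct prompts, both sets). If NULL it is counted from `scores`.
#' @param rule An `ema_compliance_rule`.
#' @return data.frame `participant_id`, `scale_id`, `mean`, `n_obs` (time
#'   points behind the mean), `n_completed`, `n_possible`, `compliant`.
#' @export
person_summaries <- function(scores, n_completed = NULL,
                             rule = compliance_rule()) {
  if (is.null(n_completed)) {
    keys <- unique(scores[c("participant_id", "day", "alarm_index")])
    n_completed <- table(keys$participant_id)
  }
  agg <- stats::aggregate(value ~ participant_id + scale_id,
    data = scores,
    FUN = function(v) c(mean = person_mean(v), n = length(v))
  )
  out <- data.frame(
    participant_id = agg$participant_id, scale_id = agg$scale_id,
    mean = agg$value[, "mean"], n_obs = as.integer(agg$value[, "n"])
  )
  nc <- as.integer(n_completed[out$participant_id])
  nc[is.na(nc)] <- 0L
  out$n_completed <- nc
  out$n_possible <- rule$n_possible
  out$compliant <- vapply(nc, classify_compliance, NA, rule = rule)
  out[order(out$participant_id, out$scale_id), , drop = FALSE]
}
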