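# Administration of one prompted session: set alternation, branching flow,
# analogue-to-Likert capture, completion status.

#' Which item set a prompt administers
#'
#' Sets alternate across the week's prompts: odd global alarm indices present
#' set one, even indices set two.
#'
#' @param global_alarm_index 1-based alarm index across the whole run.
#' @return Integer 1 or 2.
#' @examples
#' assign_set(1:6)
#' @export
assign_set <- function(global_alarm_index) {
  stopifnot(all(global_alarm_index >= 1))
  ifelse(global_alarm_index %% 2 == 1, 1L, 2L)
}

# Items a session walks through, in administration order: the set's scales in
# bank order (branch items gated at run time), then for set 2 the configured
# delusion block, then the two reactivity statements.
session_item_sequence <- function(view, set) {
  items <- set_items(view, set)
  if (set == 2L) items <- c(items, view$scales$delusions$items)
  react <- lapply(view$reactivity_items, function(r) {
    list(
      item_id = r$item_id, scale_id = "reactivity", text = r$text,
      role = "stem", condition = NULL, recode = "none"
    )
  })
  c(items, react)
}

#' Administer one prompted session
#'
#' Walks the set's items in bank order. Stems are always presented; a branch
#' item is presented iff its display condition holds given the responses
#' captured earlier in the same session (an unanswered source hides the
#' branch). Analogue responses are converted to 7-point Likert values at
#' capture. The configured delusion block (set two) and both reactivity
#' statements are appended. If the responder fails mid-session the entry is
#' recorded as missed with no responses retained.
#'
#' @param view An `ema_bank` or participant `ema_bank_view` (use
#'   [configure_delusions()] for set-two sessions with delusions).
#' @param set 1 or 2.
#' @param responder Function `(item_id, text, scale_id) -> analogue fraction`
#'   in `[0, 1]`, or NULL to record a missed entry.
#' @param participant_id,day,alarm_index Session identifiers.
#' @param first_of_day Flag: first prompt of the day (relates to the period
#'   since waking; metadata only, no scoring difference).
#' @param answered_at Completion time in minutes since midnight (optional).
#' @return An `ema_session`: list with `responses` (named integer Likert
#'   vector in display order), `status` (`"completed"` or `"missed"`), and the
#'   identifiers above.
#' @export
administer_session <- function(view, set, responder,
                               participant_id = "p01", day = 1L,
                               alarm_index = 1L, first_of_day = alarm_index == 1L,
                               answered_at = NA_integer_) {
  entry <- structure(
    list(
      participant_id = participant_id, day = as.integer(day),
      alarm_index = as.integer(alarm_index), set = as.integer(set),
      responses = integer(0), status = "missed",
      first_of_day = isTRUE(first_of_day), answered_at = answered_at
    ),
    class = "ema_session"
  )
  if (is.null(responder)) return(entry)
  seq_items <- session_item_sequence(view, set)
  responses <- integer(0)
  ok <- TRUE
  for (it in seq_items) {
    shown <- is.null(it$condition) || evaluate_branch(it$condition, responses)
    if (!shown) next
    frac <- tryCatch(responder(it$item_id, it$text, it$scale_id),
      error = function(e) NA_real_
    )
    if (is.null(frac) || length(frac) != 1L || is.na(frac)) {
      ok <- FALSE
      break
    }
    responses[[it$item_id]] <- analogue_to_likert(frac)
  }
  if (ok) {
    entry$responses <- responses
    entry$status <- "completed"
  }
  entry
}

#' Flatten sessions into a response log
#'
#' One row per item response of each completed session (missed sessions
#' contribute no rows), in the column layout used by [read_response_log()].
#'
#' @param sessions List of `ema_session` objects.
#' @param view Bank view used to administer them (resolves scale ids).
#' @return data.frame with columns `participant_id`, `day`, `alarm_index`,
#'   `set`, `item_id`, `scale_id`, `response_likert`, `answered_at_hhmm`,
#'   `status`.
#' @export
sessions_to_log <- function(sessions, view) {
  item_scale <- item_scale_map(view)
  rows <- lapply(sessions, function(s) {
    if (s$status != "completed" || length(s$responses) == 0L) return(NULL)
    ids <- names(s$responses)
    data.frame(
      participant_id = s$participant_id, day = s$day,
      alarm_index = s$alarm_index, set = s$set,
      item_id = ids,
      scale_id = unname(item_scale[ids]),
      response_likert = unname(s$responses),
      answered_at_hhmm = minutes_to_hhmm(s$answered_at),
      status = s$status
    )
  })
  out <- rbind_rows(rows)
  if (is.null(out)) out <- empty_log()
  out
}

# rbind a list of data frames, ignoring NULL elements.
rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

item_scale_map <- function(view) {
  items <- c(set_items(view, 1L), set_items(view, 2L), view$scales$delusions$items)
  m <- vapply(items, `[[`, "", "scale_id")
  names(m) <- vapply(items, `[[`, "", "item_id")
  for (r in view$reactivity_items) m[[r$item_id]] <- "reactivity"
  m
}

empty_log <- function() {
  data.frame(
    participant_id = character(), day = integer(), alarm_index = integer(),
    set = integer(), item_id = character(), scale_id = character(),
    response_likert = integer(), answered_at_hhmm = character(),
    status = character()
  )
}

minutes_to_hhmm <- function(m) {
  ifelse(is.na(m), NA_character_,
    sprintf("%02d:%02d", as.integer(m) %/% 60L, as.integer(m) %% 60L)
  )
}

hhmm_to_minutes <- function(s) {
  ifelse(is.na(s) | s == "", NA_integer_,
    as.integer(substr(s, 1, 2)) * 60L + as.integer(substr(s, 4, 5))
  )
}
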