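#' @keywords internal
"_PACKAGE"

# Scale membership of the two alternating administration sets.
SET1_SCALES <- c(
  "guilt", "hopelessness", "depression", "social_withdrawal",
  "conceptual_disorganisation", "excitement", "hallucinations"
)
SET2_SCALES <- c(
  "anxiety", "grandiosity", "hostility", "somatic_concern",
  "guilty_ideas_of_reference", "suspiciousness", "delusions"
)

bank_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "emadiary_error")))
}

#' Load and validate an item-bank document
#'
#' Reads a JSON instrument definition (14 symptom scales split over two sets,
#' six delusion templates and two reactivity items) and validates every
#' structural invariant: set membership, branch-condition well-formedness
#' (branch sources must precede the branch in the same set, so no condition
#' can form a cycle), template counts, and that the enumerated per-set
#' question counts lie within the instrument's design bounds of 15--30
#' questions for set one and 11--31 for set two (set two counted over 0--2
#' configured delusions, reactivity items included).
#'
#' @param path Path to the JSON document. Defaults to the packaged instrument.
#' @return An object of class `ema_bank` with elements `scales` (named list of
#'   scale definitions), `delusion_templates` and `reactivity_items`.
#' @examples
#' bank <- default_item_bank()
#' length(bank$scales)
#' @export
load_item_bank <- function(path) {
  doc <- jsonlite::read_json(path)
  bank <- build_item_bank(doc)
  validate_item_bank(bank)
  bank
}

#' @rdname load_item_bank
#' @export
default_item_bank <- function() {
  load_item_bank(system.file("extdata", "item_bank.json",
    package = "emadiary", mustWork = TRUE
  ))
}

build_item_bank <- function(doc) {
  scales <- lapply(doc$scales, function(s) {
    items <- lapply(s$items, function(it) {
      list(
        item_id = it$item_id,
        scale_id = s$scale_id,
        text = it$text,
        role = it$role,
        condition = if (!is.null(it$display_condition)) {
          list(
            source = it$display_condition$source,
            op = it$display_condition$op,
            threshold = as.integer(it$display_condition$threshold)
          )
        },
        recode = if (is.null(it$recode)) "none" else it$recode
      )
    })
    list(
      scale_id = s$scale_id, name = s$name, set = as.integer(s$set),
      interview_map = s$interview_map,
      composite = if (is.null(s$composite)) "none" else s$composite,
      items = items
    )
  })
  names(scales) <- vapply(scales, `[[`, "", "scale_id")
  templates <- lapply(doc$delusion_templates, function(tp) {
    list(
      template_id = tp$template_id, statement = tp$statement,
      sub_items = unlist(tp$sub_items)
    )
  })
  names(templates) <- vapply(templates, `[[`, "", "template_id")
  reactivity <- lapply(doc$reactivity_items, function(r) {
    list(item_id = r$item_id, text = r$text)
  })
  structure(
    list(
      scales = scales, delusion_templates = templates,
      reactivity_items = reactivity
    ),
    class = "ema_bank"
  )
}

validate_item_bank <- function(bank) {
  ids <- names(bank$scales)
  for (set in 1:2) {
    want <- if (set == 1) SET1_SCALES else SET2_SCALES
    have <- ids[vapply(bank$scales, `[[`, 0L, "set") == set]
    if (!setequal(have, want)) {
      bad <- c(setdiff(have, want), setdiff(want, have))
      bank_error(
        sprintf(
          "set %d must contain exactly its 7 scales; mismatch: %s",
          set, paste(bad, collapse = ", ")
        ),
        "emadiary_scale_count_error"
      )
    }
  }
  for (set in 1:2) {
    items <- set_items(bank, set)
    seen <- character()
    for (it in items) {
      if (it$role == "branch") {
        cond <- it$condition
        if (is.null(cond)) {
          bank_error(
            sprintf("branch item '%s' lacks a display condition", it$item_id),
            "emadiary_branch_error"
          )
        }
        if (!cond$op %in% c(">=", ">", "=")) {
          bank_error(
            sprintf("item '%s': unknown comparator '%s'", it$item_id, cond$op),
            "emadiary_branch_error"
          )
        }
        if (!cond$source %in% seen) {
          bank_error(
            sprintf(
              "item '%s': branch source '%s' does not precede it in set %d",
              it$item_id, cond$source, set
            ),
            "emadiary_branch_error"
          )
        }
      } else if (!is.null(it$condition)) {
        bank_error(
          sprintf("stem item '%s' must not carry a display condition", it$item_id),
          "emadiary_branch_error"
        )
      }
      seen <- c(seen, it$item_id)
    }
  }
  if (length(bank$delusion_templates) != 6L) {
    bank_error(
      sprintf(
        "expected 6 delusion templates, found %d",
        length(bank$delusion_templates)
      ),
      "emadiary_template_error"
    )
  }
  for (tp in bank$delusion_templates) {
    if (length(tp$sub_items) != 3L) {
      bank_error(
        sprintf(
          "delusion template '%s' must have exactly 3 sub-items",
          tp$template_id
        ),
        "emadiary_template_error"
      )
    }
  }
  if (length(bank$reactivity_items) != 2L) {
    bank_error("exactly 2 reactivity items are required", "emadiary_template_error")
  }
  bounds <- list(`1` = c(15L, 30L), `2` = c(11L, 31L))
  for (set in 1:2) {
    cnt <- enumerate_question_counts(bank, set)
    b <- bounds[[as.character(set)]]
    if (cnt[["min"]] < b[1] || cnt[["max"]] > b[2]) {
      bank_error(
        sprintf(
          "set %d question counts [%d, %d] fall outside the design bounds [%d, %d]",
          set, cnt[["min"]], cnt[["max"]], b[1], b[2]
        ),
        "emadiary_count_error"
      )
    }
  }
  invisible(bank)
}

# All items of one set in administration order (delusion scale excluded:
# its content comes from configure_delusions()).
set_items <- function(bank, set) {
  out <- list()
  for (sc in bank$scales) {
    if (sc$set == set) out <- c(out, sc$items)
  }
  out
}

cond_holds <- function(op, value, threshold) {
  switch(op,
    ">=" = value >= threshold,
    ">" = value > threshold,
    "=" = value == threshold,
    stop("unknown comparator: ", op)
  )
}

#' Enumerate the displayed-question count range of a set
#'
#' Exhaustively enumerates every satisfiable combination of branch outcomes
#' for one administration set and returns the minimum and maximum number of
#' questions a session can display. The two reactivity statements (shown at
#' every session) are included; for set two the count additionally ranges over
#' the number of configured delusion templates (each contributing one belief
#' statement plus three sub-items).
#'
#' The enumeration is exact for arbitrary condition structures: items are
#' grouped into dependency components and each component is explored
#' recursively over the distinct response classes its branch thresholds
#' induce, so chained conditions (a branch conditioned on another branch) and
#' multiple thresholds on one source are handled.
#'
#' @param bank A validated `ema_bank`.
#' @param set 1 or 2.
#' @param n_delusions For set two, the delusion-template counts to range over
#'   (default `0:2`); ignored for set one.
#' @return Named integer vector `c(min = , max = )`.
#' @examples
#' enumerate_question_counts(default_item_bank(), 1)
#' @export
enumerate_question_counts <- function(bank, set, n_delusions = NULL) {
  stopifnot(set %in% c(1L, 2L))
  items <- set_items(bank, set)
  comps <- dependency_components(items)
  mins <- 0L
  maxs <- 0L
  for (comp in comps) {
    r <- enumerate_component(comp)
    mins <- mins + r[1]
    maxs <- maxs + r[2]
  }
  extra <- length(bank$reactivity_items)
  if (set == 2L) {
    if (is.null(n_delusions)) n_delusions <- 0:2
    del <- 4L * as.integer(n_delusions)
    mins <- mins + min(del)
    maxs <- maxs + max(del)
  }
  c(min = mins + extra, max = maxs + extra)
}

# Partition a set's items into weakly connected components of the
# branch-dependency graph, preserving administration order within each.
dependency_components <- function(items) {
  n <- length(items)
  if (n == 0L) return(list())
  ids <- vapply(items, `[[`, "", "item_id")
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    cond <- items[[i]]$condition
    if (!is.null(cond)) {
      j <- match(cond$source, ids)
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  lapply(unique(roots), function(r) items[roots == r])
}

# Exact min/max displayed count for one dependency component via recursion
# over representative response values (one per distinct condition-outcome
# class of each source item).
enumerate_component <- function(items) {
  ids <- vapply(items, `[[`, "", "item_id")
  # conditions sourced at each item
  conds_on <- lapply(ids, function(id) {
    Filter(Negate(is.null), lapply(items, function(it) {
      if (!is.null(it$condition) && it$condition$source == id) it$condition
    }))
  })
  names(conds_on) <- ids
  reps_for <- function(id) {
    cs <- conds_on[[id]]
    if (length(cs) == 0L) return(1L) # value never inspected downstream
    pat <- vapply(1:7, function(v) {
      paste(vapply(cs, function(c) cond_holds(c$op, v, c$threshold), NA),
        collapse = ""
      )
    }, "")
    (1:7)[!duplicated(pat)]
  }
  recurse <- function(i, vals) {
    if (i > length(items)) return(c(0L, 0L))
    it <- items[[i]]
    shown <- if (is.null(it$condition)) {
      TRUE
    } else {
      src <- vals[[it$condition$source]]
      !is.null(src) && !is.na(src) &&
        cond_holds(it$condition$op, src, it$condition$threshold)
    }
    if (!shown) {
      vals[[it$item_id]] <- NA_integer_
      return(recurse(i + 1L, vals))
    }
    lo <- NA_integer_; hi <- NA_integer_
    for (v in reps_for(it$item_id)) {
      vals[[it$item_id]] <- v
      r <- recurse(i + 1L, vals)
      lo <- min(lo, r[1], na.rm = TRUE)
      hi <- max(hi, r[2], na.rm = TRUE)
    }
    c(lo + 1L, hi + 1L)
  }
  recurse(1L, list())
}

#' Personalise the delusion scale of a bank
#'
#' Builds a participant-specific bank view in which the delusions scale
#' contains one belief statement plus its three sub-items (preoccupation,
#' distress, behavioural impact) per selected template. At most two templates
#' may be configured; with none, the delusion block is absent from
#' administration. All other scales are untouched.
#'
#' @param bank A validated `ema_bank`.
#' @param template_ids Character vector of at most two template ids.
#' @return An `ema_bank_view` (an `ema_bank` carrying the configured delusion
#'   items and a `selected_templates` field).
#' @examples
#' v <- configure_delusions(default_item_bank(), c("tpl_conspiracy"))
#' length(v$scales$delusions$items)
#' @export
configure_delusions <- function(bank, template_ids = character()) {
  template_ids <- as.character(template_ids)
  if (length(template_ids) > 2L) {
    bank_error(
      sprintf(
        "a maximum of 2 delusion templates may be configured (got %d)",
        length(template_ids)
      ),
      "emadiary_delusion_limit_error"
    )
  }
  unknown <- setdiff(template_ids, names(bank$delusion_templates))
  if (length(unknown) > 0L) {
    bank_error(
      paste("unknown delusion template id:", paste(unknown, collapse = ", ")),
      "emadiary_delusion_id_error"
    )
  }
  items <- list()
  sub_slugs <- c("preoccupation", "distress", "impact")
  for (tid in template_ids) {
    tp <- bank$delusion_templates[[tid]]
    items <- c(items, list(list(
      item_id = paste0("del_", tid, "_stem"), scale_id = "delusions",
      text = tp$statement, role = "stem", condition = NULL, recode = "none"
    )))
    for (k in 1:3) {
      items <- c(items, list(list(
        item_id = paste0("del_", tid, "_", sub_slugs[k]),
        scale_id = "delusions", text = tp$sub_items[k],
        role = "stem", condition = NULL, recode = "none"
      )))
    }
  }
  view <- bank
  view$scales$delusions$items <- items
  view$selected_templates <- template_ids
  class(view) <- c("ema_bank_view", "ema_bank")
  view
}

#' Convert an analogue-scale position to a 7-point Likert response
#'
#' The analogue slider position (a fraction of the scale's length) is mapped
#' onto seven equal-width bins: bin k covers `[(k-1)/7, k/7)` with the top bin
#' closed at 1.
#'
#' @param position Numeric vector of fractions in `[0, 1]`.
#' @return Integer vector of Likert responses in 1..7.
#' @examples
#' analogue_to_likert(c(0, 0.5, 1))
#' @export
analogue_to_likert <- function(position) {
  if (any(!is.finite(position)) || any(position < 0) || any(position > 1)) {
    bank_error("analogue position must lie in [0, 1]", "emadiary_range_error")
  }
  as.integer(pmin(floor(position * 7) + 1L, 7L))
}

#' Recode the first grandiosity item
#'
#' Only grandiose (above-average) self-appraisals contribute to the score
#' gradient: responses 1--4 are coded 1, 5 as 2, 6 as 3 and 7 as 4.
#'
#' @param response Integer vector of Likert responses in 1..7.
#' @return Integer vector in 1..4.
#' @examples
#' recode_grandiosity1(1:7)
#' @export
recode_grandiosity1 <- function(response) {
  if (any(is.na(response)) || any(response < 1) || any(response > 7) ||
    any(response != as.integer(response))) {
    bank_error("grandiosity response must be an integer in 1..7", "emadiary_range_error")
  }
  c(1L, 1L, 1L, 1L, 2L, 3L, 4L)[as.integer(response)]
}

#' Evaluate a branch display condition
#'
#' A branch item is displayed if and only if its source item was answered and
#' the comparison holds; an unanswered (or hidden) source evaluates to FALSE.
#'
#' @param condition List with `source`, `op` (one of `>=`, `>`, `=`) and
#'   `threshold`.
#' @param responses Named vector/list of Likert responses collected so far.
#' @return Logical scalar.
#' @export
evaluate_branch <- function(condition, responses) {
  src <- get_response(responses, condition$source)
  if (is.na(src)) return(FALSE)
  isTRUE(cond_holds(condition$op, src, condition$threshold))
}

# Lookup that tolerates absent names in both lists and named vectors.
get_response <- function(responses, id) {
  if (!id %in% names(responses)) return(NA_integer_)
  v <- responses[[id]]
  if (is.null(v)) NA_integer_ else v
}
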