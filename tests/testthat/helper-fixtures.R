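# Fixtures built in code: bank documents, sessions and random branching
# components for oracle comparisons.

# The packaged bank as an R list, for mutation into invalid documents.
read_bank_doc <- function() {
  jsonlite::read_json(system.file("extdata", "item_bank.json",
    package = "emadiary", mustWork = TRUE
  ))
}

write_bank_doc <- function(doc) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}

# A completed session with the given named Likert responses.
make_session <- function(responses, set, participant_id = "p01",
                         day = 1L, alarm_index = 1L) {
  structure(
    list(
      participant_id = participant_id, day = as.integer(day),
      alarm_index = as.integer(alarm_index), set = as.integer(set),
      responses = responses, status = "completed",
      first_of_day = alarm_index == 1L, answered_at = NA_integer_
    ),
    class = "ema_session"
  )
}

# Random dependency component: first item a stem, later items branches with
# probability 0.6, conditioned on a random earlier item.
random_component <- function(m) {
  items <- list(list(
    item_id = "i1", scale_id = "s", text = "", role = "stem",
    condition = NULL, recode = "none"
  ))
  for (i in 2:m) {
    if (stats::runif(1) < 0.6) {
      op <- sample(c(">=", ">", "="), 1)
      items[[i]] <- list(
        item_id = paste0("i", i), scale_id = "s", text = "", role = "branch",
        condition = list(
          source = paste0("i", sample(i - 1, 1)), op = op,
          threshold = sample(if (op == "=") 1:7 else 2:7, 1)
        ),
        recode = "none"
      )
    } else {
      items[[i]] <- list(
        item_id = paste0("i", i), scale_id = "s", text = "", role = "stem",
        condition = NULL, recode = "none"
      )
    }
  }
  items
}

# Brute-force displayed-count range over the full 7^m response grid.
oracle_component_counts <- function(items) {
  m <- length(items)
  grid <- as.matrix(expand.grid(rep(list(1:7), m)))
  counts <- apply(grid, 1, function(vals) {
    resp <- integer(0)
    cnt <- 0L
    for (i in seq_len(m)) {
      it <- items[[i]]
      shown <- is.null(it$condition) || evaluate_branch(it$condition, resp)
      if (shown) {
        cnt <- cnt + 1L
        resp[[it$item_id]] <- vals[i]
      }
    }
    cnt
  })
  c(min(counts), max(counts))
}
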