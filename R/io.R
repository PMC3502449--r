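# File formats: response logs, interview tables and report writers.
# CSV dialect: UTF-8, comma-separated, header row, "." decimal, times HH:MM.

LOG_COLUMNS <- c(
  "participant_id", "day", "alarm_index", "set", "item_id", "scale_id",
  "response_likert", "answered_at_hhmm", "status"
)

io_error <- function(msg, class = "emadiary_io_error") {
  stop(errorCondition(msg, class = c(class, "emadiary_error")))
}

#' Read and validate a response log
#'
#' One row per item response. The schema, Likert ranges and uniqueness of
#' (participant, day, alarm, item) are enforced; violations raise errors
#' naming the problem.
#'
#' @param path CSV file path.
#' @return Validated data.frame in the [sessions_to_log()] layout.
#' @export
read_response_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(LOG_COLUMNS, names(d))
  if (length(missing) > 0L) {
    io_error(paste(
      "response log is missing column(s):",
      paste(missing, collapse = ", ")
    ))
  }
  bad <- !is.na(d$response_likert) &
    (d$response_likert < 1 | d$response_likert > 7 |
      d$response_likert != as.integer(d$response_likert))
  if (any(bad)) {
    io_error(sprintf(
      "illegal Likert value(s) outside 1..7 in %d row(s), first at row %d",
      sum(bad), which(bad)[1]
    ))
  }
  key <- paste(d$participant_id, d$day, d$alarm_index, d$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- d[which(duplicated(key))[1], ]
    io_error(sprintf(
      "duplicate response row for participant %s, day %s, alarm %s, item %s",
      dup$participant_id, dup$day, dup$alarm_index, dup$item_id
    ))
  }
  d
}

#' Read an interview score table
#'
#' @param path CSV with columns `participant_id`, `occasion`, `item_code`,
#'   `rating` (PANSS-style items 1--7; CDS-style items 1--4).
#' @return Validated data.frame.
#' @export
read_interviews <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "occasion", "item_code", "rating")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0L) {
    io_error(paste(
      "interview table is missing column(s):",
      paste(missing, collapse = ", ")
    ))
  }
  levels <- ifelse(startsWith(d$item_code, "CDS"), 4L, 7L)
  bad <- d$rating < 1 | d$rating > levels
  if (any(bad)) {
    io_error(sprintf(
      "interview rating out of range in %d row(s), first at row %d",
      sum(bad), which(bad)[1]
    ))
  }
  d
}

# Tiny FNV-1a hash so runs can be tagged with a configuration fingerprint
# without extra dependencies.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

round_df <- function(d, digits = 2) {
  num <- vapply(d, is.numeric, NA) & !vapply(d, is.integer, NA)
  d[num] <- lapply(d[num], round, digits = digits)
  d
}

#' Write study reports to disk
#'
#' Writes `table2.csv` (validity table, kept sorted by descending rho),
#' `table3.csv` (instability table) and `compliance.json`. CSV floats are
#' rounded to 2 decimal places; the JSON carries full precision plus the seed
#' and a configuration fingerprint. Undefined statistics are written as empty
#' CSV cells / JSON nulls, never 0.
#'
#' @param study An `ema_study` from [run_validity_study()], or a list with
#'   `table2`, `table3`, `compliance` and `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(study, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p2 <- file.path(out_dir, "table2.csv")
  p3 <- file.path(out_dir, "table3.csv")
  pj <- file.path(out_dir, "compliance.json")
  t2 <- study$table2
  if (is.null(t2)) {
    t2 <- data.frame(
      scale_id = character(), item_code = character(), n = integer(),
      rho = numeric(), p = numeric(), excluded = logical(), note = character()
    )
  }
  t3 <- study$table3
  if (is.null(t3)) {
    t3 <- data.frame(
      scale_id = character(), n_persons = integer(), mssd_mean = numeric(),
      mssd_sd = numeric(), sd_mean = numeric(), sd_sd = numeric()
    )
  }
  utils::write.csv(round_df(t2), p2, row.names = FALSE, na = "")
  utils::write.csv(round_df(t3), p3, row.names = FALSE, na = "")
  payload <- c(
    study$compliance,
    list(
      seed = study$seed,
      config_hash = fnv1a_hash(study$compliance),
      package_version = as.character(utils::packageVersion("emadiary"))
    )
  )
  jsonlite::write_json(payload, pj,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(c(table2 = p2, table3 = p3, compliance = pj))
}

#' Write a week schedule as CSV
#'
#' Columns: `participant_id`, `day`, `alarm_index`, `time_hhmm`,
#' `expiry_hhmm`.
#'
#' @param schedule An `ema_week_schedule`.
#' @param path Output CSV path.
#' @param participant_id Id to stamp on every row.
#' @return Invisibly, `path`.
#' @export
write_schedule_csv <- function(schedule, path, participant_id = "p01") {
  d <- data.frame(
    participant_id = participant_id,
    day = schedule$day,
    alarm_index = schedule$alarm_index,
    time_hhmm = minutes_to_hhmm(schedule$time),
    expiry_hhmm = minutes_to_hhmm(schedule$expiry)
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
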