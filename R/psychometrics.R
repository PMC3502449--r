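# Reliability, validity, instability and reactivity statistics.

#' Mean squared successive difference (MSSD)
#'
#' Instability metric sensitive to both variance and temporal order: the mean
#' of squared differences between consecutive available entries,
#' `sum((x[i+1]-x[i])^2) / (n-1)`. Missing time-points are dropped before
#' differencing, so differences may span gaps (entries across days and
#' non-sequential entries are still paired).
#'
#' @param series Numeric vector ordered by time; NAs are removed.
#' @return Non-negative scalar, or `NA_real_` when fewer than two entries are
#'   available.
#' @examples
#' mssd(c(2, 4, 2))
#' @export
mssd <- function(series) {
  x <- series[!is.na(series)]
  if (length(x) < 2L) return(NA_real_)
  mean(diff(x)^2)
}

#' Within-person standard deviation
#'
#' Sample standard deviation (n-1 denominator) of one person's available
#' scale scores.
#'
#' @param series Numeric vector; NAs are removed.
#' @return Non-negative scalar, or `NA_real_` when fewer than two entries.
#' @export
within_person_sd <- function(series) {
  x <- series[!is.na(series)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

#' Cronbach's alpha for one scale
#'
#' Internal consistency across a scale's items,
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`, with
#' sample variances over pooled complete rows (entries across participants
#' and time-points; rows with any missing item, e.g. an untriggered branch,
#' are dropped and the number retained is reported).
#'
#' @param rows Matrix or data frame, one row per entry, one column per item.
#' @return List of class `ema_alpha`: `alpha`, `k`, `n_rows`, `undefined`
#'   (TRUE when the total-score variance is zero, in which case `alpha` is
#'   `NA`).
#' @export
cronbach_alpha <- function(rows) {
  m <- as.matrix(rows)
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2L) stop("cronbach_alpha requires at least 2 items")
  if (nrow(m) < 2L) {
    return(structure(
      list(alpha = NA_real_, k = k, n_rows = nrow(m), undefined = TRUE),
      class = "ema_alpha"
    ))
  }
  item_var <- apply(m, 2, stats::var)
  total_var <- stats::var(rowSums(m))
  if (total_var <= .Machine$double.eps * k) {
    return(structure(
      list(alpha = NA_real_, k = k, n_rows = nrow(m), undefined = TRUE),
      class = "ema_alpha"
    ))
  }
  alpha <- k / (k - 1) * (1 - sum(item_var) / total_var)
  structure(
    list(alpha = alpha, k = k, n_rows = nrow(m), undefined = FALSE),
    class = "ema_alpha"
  )
}

#' Spearman rank correlation with tie-aware ranks
#'
#' Average ranks are assigned to ties; rho is the product-moment correlation
#' of the ranks. The two-sided p-value uses the t-approximation with n-2
#' degrees of freedom; for small samples (`n < 10`, or on request) an exact
#' permutation p-value over all n! pairings is computed instead.
#'
#' @param x,y Paired numeric vectors; pairs with any NA are dropped.
#' @param exact NULL (exact when `n < 10`), TRUE or FALSE.
#' @return List of class `ema_rho`: `rho`, `p`, `n`, `undefined` (TRUE when
#'   either vector has zero variance).
#' @examples
#' spearman_rho(c(1, 2, 2, 4), c(2, 3, 3, 5))
#' @export
spearman_rho <- function(x, y, exact = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("spearman_rho requires at least 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(
      list(rho = NA_real_, p = NA_real_, n = n, undefined = TRUE),
      class = "ema_rho"
    ))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  use_exact <- if (is.null(exact)) n < 10L else isTRUE(exact)
  if (use_exact) {
    p <- perm_p_rho(rx, ry, rho)
  } else {
    r2 <- min(rho^2, 1 - 1e-15)
    tstat <- rho * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  structure(
    list(rho = rho, p = p, n = n, undefined = FALSE),
    class = "ema_rho"
  )
}

# Exact two-sided permutation p-value for Spearman's rho: proportion of the
# n! pairings whose |rho| is at least the observed (small n only).
perm_p_rho <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- all_permutations(n)
  denom <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rhos <- apply(perms, 1, function(idx) {
    sum((rx - mean(rx)) * (ry[idx] - mean(ry))) / denom
  })
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub)))
    out[r:(r + nrow(sub) - 1L), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Diary-vs-interview validity table
#'
#' Correlates each scale's per-person diary mean with its mapped interview
#' item (the follow-up interview, which covers the sampled week), one row per
#' scale ordered by descending rho. Scales endorsed (diary mean above the
#' scale floor of 1) by fewer than `min_endorsed` participants are excluded
#' from analysis and flagged rather than dropped; zero-variance pairs are
#' flagged undefined.
#'
#' @param summaries Person summary table ([person_summaries()]), already
#'   restricted to compliant participants.
#' @param interviews data.frame `participant_id`, `occasion`, `item_code`,
#'   `rating`.
#' @param mapping data.frame `scale_id`, `item_code`. Every scale present in
#'   `summaries` must be mapped.
#' @param occasion Which interview occasion to correlate against (default
#'   `"followup"`).
#' @param min_endorsed Minimum number of endorsing participants (default 3).
#' @return data.frame `scale_id`, `item_code`, `n`, `rho`, `p`, `excluded`,
#'   `note`, sorted by descending rho (flagged rows last).
#' @export
validity_table <- function(summaries, interviews, mapping,
                           occasion = "followup", min_endorsed = 3L) {
  scales <- setdiff(unique(summaries$scale_id), "reactivity")
  unmapped <- setdiff(scales, mapping$scale_id)
  if (length(unmapped) > 0L) {
    stop(errorCondition(
      paste("no interview mapping for scale(s):", paste(unmapped, collapse = ", ")),
      class = c("emadiary_mapping_error", "emadiary_error")
    ))
  }
  iv <- interviews[interviews$occasion == occasion, , drop = FALSE]
  rows <- lapply(scales, function(sid) {
    code <- mapping$item_code[match(sid, mapping$scale_id)]
    d <- summaries[summaries$scale_id == sid, c("participant_id", "mean")]
    i <- iv[iv$item_code == code, c("participant_id", "rating")]
    mm <- merge(d, i, by = "participant_id")
    endorsed <- sum(mm$mean > 1, na.rm = TRUE)
    if (endorsed < min_endorsed) {
      return(data.frame(
        scale_id = sid, item_code = code, n = nrow(mm),
        rho = NA_real_, p = NA_real_, excluded = TRUE,
        note = sprintf("endorsed by %d participant(s); not analysed", endorsed)
      ))
    }
    res <- spearman_rho(mm$mean, mm$rating, exact = FALSE)
    data.frame(
      scale_id = sid, item_code = code, n = res$n,
      rho = res$rho, p = res$p, excluded = FALSE,
      note = if (res$undefined) "zero variance; rho undefined" else ""
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$excluded | is.na(out$rho), -ifelse(is.na(out$rho), -Inf, out$rho)), ,
    drop = FALSE
  ]
}

#' Within-person instability table
#'
#' For each scale, the across-person mean (and SD) of person-level MSSD and
#' within-person SD, computed from each participant's time-ordered available
#' scores. Participants contribute only with two or more entries on the
#' scale. Delusion-scale rows are restricted to participants who had delusion
#' questions configured.
#'
#' @param scores Time-point score table ([score_sessions()] row-bound over
#'   participants; compliant participants only).
#' @param delusion_participants Character vector of participant ids with
#'   configured delusions, or NULL to impose no restriction.
#' @return data.frame `scale_id`, `n_persons`, `mssd_mean`, `mssd_sd`,
#'   `sd_mean`, `sd_sd`.
#' @export
instability_table <- function(scores, delusion_participants = NULL) {
  scores <- scores[order(
    scores$participant_id, scores$day, scores$alarm_index
  ), , drop = FALSE]
  scales <- unique(scores$scale_id)
  rows <- lapply(scales, function(sid) {
    d <- scores[scores$scale_id == sid, , drop = FALSE]
    if (sid == "delusions" && !is.null(delusion_participants)) {
      d <- d[d$participant_id %in% delusion_participants, , drop = FALSE]
    }
    per <- lapply(split(d$value, d$participant_id), function(v) {
      c(mssd = mssd(v), sd = within_person_sd(v))
    })
    m <- do.call(rbind, per)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (is.null(m) || nrow(m) == 0L) {
      return(data.frame(
        scale_id = sid, n_persons = 0L, mssd_mean = NA_real_,
        mssd_sd = NA_real_, sd_mean = NA_real_, sd_sd = NA_real_
      ))
    }
    data.frame(
      scale_id = sid, n_persons = nrow(m),
      mssd_mean = mean(m[, "mssd"]),
      mssd_sd = if (nrow(m) > 1L) stats::sd(m[, "mssd"]) else NA_real_,
      sd_mean = mean(m[, "sd"]),
      sd_sd = if (nrow(m) > 1L) stats::sd(m[, "sd"]) else NA_real_
    )
  })
  rbind_rows(rows)
}

#' Per-person reactivity score
#'
#' Mean of the two self-monitoring reactivity statements ("keeping the diary
#' has influenced my thoughts" / "... my mood") over all of a participant's
#' completed entries. The direction of any reactivity is not measured; the
#' score is a magnitude only.
#'
#' @param log Response-log data.frame (see [read_response_log()]).
#' @param participant Participant id.
#' @return Numeric scalar in `[1, 7]`, or `NA_real_` with no completed
#'   entries.
#' @export
reactivity_mean <- function(log, participant) {
  d <- log[log$participant_id == participant & log$scale_id == "reactivity", ]
  if (nrow(d) == 0L) return(NA_real_)
  mean(d$response_likert)
}
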