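# Synthetic respondents: latent AR(1) symptom trajectories, analogue response
# rendering, severity-dependent missingness, paired interview ratings, and an
# end-to-end validity study runner.

#' Default per-scale generative parameters
#'
#' Latent trajectories live on the 1--7 severity continuum. Group means put
#' acute patients above remitted and ultra-high-risk (UHR) participants on
#' positive scales; AR(1) persistence `phi` is graded so that delusions and
#' grandiosity are the most stable constructs and passive social withdrawal
#' the least, with innovation SDs sized to produce within-person instability
#' of the order seen in ambulatory psychosis data. Guilty ideas of reference
#' are given a floor-level mean so that the scale is rarely endorsed.
#'
#' @return data.frame with columns `scale_id`, `class` (positive, affective,
#'   behavioural), `mu_acute`, `mu_remitted`, `mu_uhr`, `tau` (between-person
#'   SD of the latent mean), `phi` and `sigma` (AR(1) innovation SD).
#' @export
default_scale_params <- function() {
  p <- rbind(
    c("hallucinations", "positive", 3.0, 1.8, 2.2, 1.10, 0.55, 0.70),
    c("delusions", "positive", 3.2, 1.9, 2.3, 1.10, 0.85, 0.65),
    c("suspiciousness", "positive", 3.0, 2.0, 2.4, 1.10, 0.60, 0.75),
    c("grandiosity", "positive", 2.6, 1.8, 1.9, 0.90, 0.80, 0.65),
    c("somatic_concern", "positive", 2.8, 2.2, 2.3, 1.00, 0.50, 0.75),
    c("anxiety", "affective", 3.2, 2.6, 2.9, 1.00, 0.35, 0.95),
    c("depression", "affective", 3.0, 2.6, 2.9, 1.00, 0.50, 0.70),
    c("guilt", "affective", 2.4, 2.0, 2.2, 1.00, 0.40, 0.90),
    c("hopelessness", "affective", 3.0, 2.7, 2.9, 1.00, 0.55, 0.80),
    c("guilty_ideas_of_reference", "affective", 1.3, 1.1, 1.2, 0.30, 0.50, 0.50),
    c("social_withdrawal", "behavioural", 3.4, 2.8, 2.9, 1.00, 0.15, 1.20),
    c("conceptual_disorganisation", "behavioural", 2.6, 1.9, 2.1, 1.00, 0.30, 1.00),
    c("excitement", "behavioural", 2.8, 2.0, 2.2, 1.00, 0.25, 1.05),
    c("hostility", "behavioural", 2.5, 1.9, 2.0, 1.00, 0.30, 0.95)
  )
  out <- data.frame(
    scale_id = p[, 1], class = p[, 2],
    mu_acute = as.numeric(p[, 3]), mu_remitted = as.numeric(p[, 4]),
    mu_uhr = as.numeric(p[, 5]), tau = as.numeric(p[, 6]),
    phi = as.numeric(p[, 7]), sigma = as.numeric(p[, 8])
  )
  out
}

#' Simulation parameters
#'
#' @param n_per_group Participants per severity group (acute, remitted, UHR).
#' @param days,prompts_per_day Sampling design (42 prompts at defaults).
#' @param sigma_item SD of analogue-rendering item noise (fraction units).
#' @param sigma_int SD of interview linkage noise (latent units).
#' @param beta0 Intercept of the per-entry completion logit, placed so that a
#'   participant of average positive-symptom severity completes about 74% of
#'   entries.
#' @param or_pos Odds ratio on completion per unit of positive-symptom
#'   severity (values below 1 make more severe participants less compliant).
#' @param pos_ref Severity value at which the completion probability equals
#'   `plogis(beta0)`.
#' @param scale_params Per-scale generative table
#'   ([default_scale_params()]).
#' @param delusion_probs Per-group probabilities of configuring 0, 1 or 2
#'   delusion templates.
#' @param reactivity_mu Per-group mean of the latent reactivity level.
#' @return An `ema_sim_params` list.
#' @export
sim_params <- function(n_per_group = 12L, days = 7L, prompts_per_day = 6L,
                       sigma_item = 0.06, sigma_int = 0.9,
                       beta0 = 1.05, or_pos = 0.68, pos_ref = 2.5,
                       scale_params = default_scale_params(),
                       delusion_probs = list(
                         acute = c(0.2, 0.3, 0.5),
                         remitted = c(0.5, 0.3, 0.2),
                         uhr = c(0.7, 0.2, 0.1)
                       ),
                       reactivity_mu = c(acute = 3.6, remitted = 2.9, uhr = 2.4)) {
  structure(
    list(
      n_per_group = as.integer(n_per_group), days = as.integer(days),
      prompts_per_day = as.integer(prompts_per_day),
      sigma_item = sigma_item, sigma_int = sigma_int,
      beta0 = beta0, or_pos = or_pos, pos_ref = pos_ref,
      scale_params = scale_params, delusion_probs = delusion_probs,
      reactivity_mu = reactivity_mu
    ),
    class = "ema_sim_params"
  )
}

#' Simulate a stationary latent AR(1) symptom trajectory
#'
#' `L[1] ~ N(mu, sigma^2 / (1 - phi^2))`,
#' `L[t+1] = mu + phi * (L[t] - mu) + e[t]`, `e[t] ~ N(0, sigma^2)`.
#'
#' @param n Series length (one value per scheduled prompt).
#' @param mu Person-level latent mean.
#' @param phi Persistence in `[0, 1)`.
#' @param sigma Innovation SD (`sigma = 0` gives a constant series).
#' @return Numeric vector of length `n`.
#' @export
simulate_latent <- function(n, mu, phi, sigma) {
  stopifnot(phi >= 0, phi < 1, sigma >= 0, n >= 1)
  if (sigma == 0) return(rep(mu, n))
  dev1 <- stats::rnorm(1, 0, sigma / sqrt(1 - phi^2))
  if (n == 1L) return(mu + dev1)
  eps <- stats::rnorm(n - 1L, 0, sigma)
  dev <- stats::filter(eps, phi, method = "recursive", init = dev1)
  c(mu + dev1, mu + as.numeric(dev))
}

# Fixed monotone squashing of the 1-7 latent continuum onto the analogue
# fraction scale; centred at severity 4 with slope chosen so the latent range
# covers all seven Likert bins.
squash_latent <- function(latent) {
  stats::plogis((latent - 4) / 1.5)
}

#' Render analogue responses from a latent severity
#'
#' The analogue fraction is the squashed latent value plus Gaussian item
#' noise, clamped to `[0, 1]`; feeding it to [analogue_to_likert()] yields a
#' 1--7 response.
#'
#' @param latent Numeric vector of latent severities.
#' @param sigma_item Item-noise SD on the fraction scale.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
render_responses <- function(latent, sigma_item) {
  frac <- squash_latent(latent) + stats::rnorm(length(latent), 0, sigma_item)
  pmin(pmax(frac, 0), 1)
}

#' Per-alarm completion flags from the severity-dependent compliance model
#'
#' Each scheduled entry is completed independently with probability
#' `plogis(beta0 + log(or_pos) * (pos_severity - pos_ref))`: an odds ratio
#' below one makes completion decrease monotonically with positive-symptom
#' severity.
#'
#' @param params An `ema_sim_params`.
#' @param pos_severity Person-level positive-symptom latent mean.
#' @param n_alarms Number of scheduled entries.
#' @return Logical vector of length `n_alarms`.
#' @export
simulate_compliance <- function(params, pos_severity, n_alarms) {
  p <- completion_probability(params, pos_severity)
  stats::rbinom(n_alarms, 1L, p) == 1L
}

#' @rdname simulate_compliance
#' @export
completion_probability <- function(params, pos_severity) {
  stats::plogis(params$beta0 + log(params$or_pos) * (pos_severity - params$pos_ref))
}

# One interview rating: clamped, rounded monotone transform of the latent
# mean plus linkage noise. PANSS items use 7 levels, CDS items 4.
interview_rating <- function(mu, sigma_int, levels) {
  noisy <- mu + stats::rnorm(length(mu), 0, sigma_int)
  pmin(pmax(as.integer(round(1 + (levels - 1) * squash_latent(noisy))), 1L), levels)
}

#' Simulate paired interview ratings from latent means
#'
#' @param latent_means data.frame `participant_id`, `scale_id`, `mu` (true
#'   person-level latent mean).
#' @param mapping data.frame `scale_id`, `item_code` (codes starting `CDS`
#'   are rated on 4 levels, all others on 7).
#' @param params An `ema_sim_params` (supplies `sigma_int`).
#' @param occasion Label for the `occasion` column.
#' @return data.frame `participant_id`, `occasion`, `item_code`, `rating`.
#' @export
simulate_interviews <- function(latent_means, mapping, params,
                                occasion = "followup") {
  code <- mapping$item_code[match(latent_means$scale_id, mapping$scale_id)]
  levels <- ifelse(startsWith(code, "CDS"), 4L, 7L)
  data.frame(
    participant_id = latent_means$participant_id,
    occasion = occasion,
    item_code = code,
    rating = interview_rating(latent_means$mu, params$sigma_int, levels)
  )
}

#' Interview mapping of a bank
#'
#' @param bank An `ema_bank`.
#' @return data.frame `scale_id`, `item_code` from the bank's
#'   `interview_map` fields.
#' @export
interview_mapping <- function(bank) {
  data.frame(
    scale_id = names(bank$scales),
    item_code = vapply(bank$scales, `[[`, "", "interview_map")
  )
}

# Vectorised single-scale diary simulation: person latent means `mu` ->
# per-person diary means over the scale's occasions, with item rendering,
# Likert binning and per-entry completion thinning. Used for calibration and
# parameter-recovery studies; the full session engine performs the same
# generative steps item by item.
sim_scale_diary <- function(mu, phi, sigma, sigma_item, n_occasions = 21L,
                            k_items = 4L, p_complete = rep(1, length(mu))) {
  n <- length(mu)
  dev <- matrix(0, n, n_occasions)
  dev[, 1] <- stats::rnorm(n, 0, sigma / sqrt(1 - phi^2))
  if (n_occasions > 1L) {
    for (t in 2:n_occasions) {
      dev[, t] <- phi * dev[, t - 1] + stats::rnorm(n, 0, sigma)
    }
  }
  latent <- mu + dev
  score <- matrix(0, n, n_occasions)
  for (k in seq_len(k_items)) {
    frac <- render_responses(as.numeric(latent), sigma_item)
    score <- score + matrix(analogue_to_likert(frac), n, n_occasions)
  }
  score <- score / k_items
  comp <- matrix(stats::rbinom(n * n_occasions, 1L, rep(p_complete, n_occasions)),
    n, n_occasions
  )
  nc <- rowSums(comp)
  out <- rowSums(score * comp) / nc
  out[nc == 0] <- NA_real_
  out
}

# Person latent means for one scale under the three-group design.
draw_group_mu <- function(n_per_group, sp_row) {
  mus <- c(sp_row$mu_acute, sp_row$mu_remitted, sp_row$mu_uhr)
  rep(mus, each = n_per_group) +
    stats::rnorm(3L * n_per_group, 0, sp_row$tau)
}

#' Calibrate interview linkage noise for a target rank correlation
#'
#' Finds the interview-noise SD at which the diary-vs-interview Spearman
#' correlation for one scale equals `target_rho`, by large-sample simulation
#' of both sides of the linkage (including Likert binning, interview rounding
#' and compliance thinning) and root finding with common random numbers.
#'
#' @param target_rho Desired generating rank correlation.
#' @param params An `ema_sim_params`.
#' @param scale_id Scale whose linkage is calibrated.
#' @param n_cal Calibration sample size.
#' @param levels Interview rating levels (7 for PANSS-style items).
#' @return List: `sigma_int`, `achieved_rho`, `target_rho`, `n_cal`.
#' @export
calibrate_interview_noise <- function(target_rho, params = sim_params(),
                                      scale_id = "hallucinations",
                                      n_cal = 4000L, levels = 7L) {
  sp <- params$scale_params
  row <- sp[sp$scale_id == scale_id, ]
  stopifnot(nrow(row) == 1L)
  mu <- draw_group_mu(ceiling(n_cal / 3), row)[seq_len(n_cal)]
  p <- completion_probability(params, mu)
  diary <- sim_scale_diary(mu, row$phi, row$sigma, params$sigma_item,
    p_complete = p
  )
  z <- stats::rnorm(n_cal)
  rho_at <- function(s) {
    rating <- pmin(pmax(
      as.integer(round(1 + (levels - 1) * squash_latent(mu + s * z))), 1L
    ), levels)
    ok <- !is.na(diary)
    stats::cor(rank(diary[ok]), rank(rating[ok]))
  }
  f <- function(s) rho_at(s) - target_rho
  if (f(1e-3) < 0) {
    stop("target rank correlation unattainable: linkage too noisy at sigma ~ 0")
  }
  root <- stats::uniroot(f, c(1e-3, 8), tol = 1e-3)
  list(
    sigma_int = root$root, achieved_rho = rho_at(root$root),
    target_rho = target_rho, n_cal = n_cal
  )
}

#' Parameter-recovery study for the diary-interview linkage
#'
#' Calibrates the interview noise to a target generating rank correlation,
#' then simulates `n_rep` independent cohorts of `n` participants and runs
#' the pipeline's [spearman_rho()] on each cohort's diary means and interview
#' ratings.
#'
#' @param target_rho Generating rank correlation (default 0.7).
#' @param n_rep Number of replicate cohorts.
#' @param n Cohort size (default 36, the compliant-sample size of a
#'   three-group, 12-per-group design).
#' @param params An `ema_sim_params`.
#' @param scale_id Scale studied.
#' @param seed Integer seed.
#' @return List: `mean_rho`, `rhos`, `sigma_int`, `target_rho`.
#' @export
recovery_study <- function(target_rho = 0.7, n_rep = 200L, n = 36L,
                           params = sim_params(), scale_id = "hallucinations",
                           seed = 1L) {
  set.seed(seed)
  cal <- calibrate_interview_noise(target_rho, params, scale_id)
  sp <- params$scale_params
  row <- sp[sp$scale_id == scale_id, ]
  rhos <- vapply(seq_len(n_rep), function(r) {
    mu <- draw_group_mu(ceiling(n / 3), row)[seq_len(n)]
    p <- completion_probability(params, mu)
    diary <- sim_scale_diary(mu, row$phi, row$sigma, params$sigma_item,
      p_complete = p
    )
    rating <- pmin(pmax(as.integer(round(
      1 + 6 * squash_latent(mu + stats::rnorm(n, 0, cal$sigma_int))
    )), 1L), 7L)
    ok <- !is.na(diary)
    spearman_rho(diary[ok], rating[ok], exact = FALSE)$rho
  }, 0)
  list(
    mean_rho = mean(rhos), rhos = rhos, sigma_int = cal$sigma_int,
    target_rho = target_rho
  )
}

#' Run a complete synthetic validity study
#'
#' Generates a three-group cohort, builds each participant's week schedule
#' and personalised bank view, simulates latent trajectories and completion,
#' administers every completed session through the branching engine, scores
#' the log, applies the compliance filter (non-compliant participants are
#' excluded from all analyses), and assembles the diary-vs-interview validity
#' table, the within-person instability table, per-scale internal
#' consistency, reactivity means and a compliance summary. Fully reproducible
#' from the seed.
#'
#' @param params An `ema_sim_params`.
#' @param seed Integer seed.
#' @param bank An `ema_bank` (default the packaged instrument).
#' @return List of class `ema_study`: `log`, `interviews`, `truth`, `scores`,
#'   `summaries`, `table2`, `table3`, `alphas`, `reactivity`, `compliance`,
#'   `seed`.
#' @export
run_validity_study <- function(params = sim_params(), seed = 1L,
                               bank = default_item_bank()) {
  set.seed(seed)
  cfg <- schedule_config(
    prompts_per_day = params$prompts_per_day, days = params$days
  )
  n_alarms <- cfg$days * cfg$prompts_per_day
  rule <- compliance_rule(n_possible = n_alarms)
  mapping <- interview_mapping(bank)
  sp <- params$scale_params
  groups <- rep(c("acute", "remitted", "uhr"), each = params$n_per_group)
  n_total <- length(groups)
  pos_scales <- sp$scale_id[sp$class == "positive"]

  logs <- list()
  scores <- list()
  truth_rows <- list()
  del_participants <- character()
  n_completed <- integer(0)

  for (i in seq_len(n_total)) {
    pid <- sprintf("p%02d", i)
    grp <- groups[i]
    n_del <- sample(0:2, 1L, prob = params$delusion_probs[[grp]])
    tids <- if (n_del > 0) {
      sample(names(bank$delusion_templates), n_del)
    } else {
      character()
    }
    view <- configure_delusions(bank, tids)
    if (n_del > 0) del_participants <- c(del_participants, pid)

    mu <- stats::setNames(
      sp[[paste0("mu_", grp)]] + stats::rnorm(nrow(sp), 0, sp$tau),
      sp$scale_id
    )
    latent <- t(vapply(
      seq_len(nrow(sp)),
      function(j) simulate_latent(n_alarms, mu[j], sp$phi[j], sp$sigma[j]),
      numeric(n_alarms)
    ))
    rownames(latent) <- sp$scale_id
    react_mu <- params$reactivity_mu[[grp]] + stats::rnorm(1, 0, 0.8)

    sched <- make_week_schedule(cfg)
    pos_sev <- mean(mu[pos_scales])
    flags <- simulate_compliance(params, pos_sev, n_alarms)

    sessions <- lapply(which(flags), function(t) {
      responder <- function(item_id, text, scale_id) {
        l <- if (scale_id == "reactivity") react_mu else latent[scale_id, t]
        render_responses(l, params$sigma_item)
      }
      administer_session(
        view, assign_set(t), responder,
        participant_id = pid, day = sched$day[t],
        alarm_index = sched$alarm_index[t],
        first_of_day = sched$alarm_index[t] == 1L,
        answered_at = sched$time[t] + 5L
      )
    })
    n_completed[pid] <- length(sessions)
    logs[[pid]] <- sessions_to_log(sessions, view)
    scores[[pid]] <- score_sessions(sessions, view)
    truth_rows[[pid]] <- data.frame(
      participant_id = pid, group = grp, scale_id = sp$scale_id,
      mu = unname(mu)
    )
  }

  log <- rbind_rows(logs)
  if (is.null(log)) log <- empty_log()
  score_tab <- rbind_rows(scores)
  truth <- rbind_rows(truth_rows)
  interviews <- rbind(
    simulate_interviews(truth, mapping, params, occasion = "baseline"),
    simulate_interviews(truth, mapping, params, occasion = "followup")
  )

  compliant_ids <- names(n_completed)[
    vapply(n_completed, classify_compliance, NA, rule = rule)
  ]
  compliance <- list(
    n_entered = n_total,
    n_compliant = length(compliant_ids),
    percent_compliant = completion_percent(length(compliant_ids), n_total),
    threshold_count = rule$threshold_count,
    n_possible = rule$n_possible,
    mean_entries_completed = mean(n_completed),
    mean_completion_percent = completion_percent(
      sum(n_completed), n_total * n_alarms
    )
  )

  if (length(compliant_ids) == 0L) {
    warning("no participant met the compliance criterion; analysis tables are empty")
    empty <- list(
      log = log, interviews = interviews, truth = truth, scores = score_tab,
      summaries = NULL, table2 = NULL, table3 = NULL, alphas = NULL,
      reactivity = NULL, compliance = compliance, seed = seed
    )
    return(structure(empty, class = "ema_study"))
  }

  keep <- score_tab$participant_id %in% compliant_ids
  score_keep <- score_tab[keep, , drop = FALSE]
  summaries <- person_summaries(score_keep,
    n_completed = n_completed[compliant_ids], rule = rule
  )
  table2 <- validity_table(summaries, interviews, mapping)
  table3 <- instability_table(score_keep, delusion_participants = del_participants)

  log_keep <- log[log$participant_id %in% compliant_ids, , drop = FALSE]
  alphas <- lapply(bank$scales, function(sc) {
    if (length(sc$items) < 2L) return(NULL)
    cronbach_alpha(scale_item_matrix(log_keep, sc))
  })
  alphas <- Filter(Negate(is.null), alphas)

  reactivity <- data.frame(
    participant_id = compliant_ids,
    reactivity = vapply(compliant_ids, reactivity_mean, 0, log = log_keep),
    group = truth$group[match(compliant_ids, truth$participant_id)]
  )

  structure(
    list(
      log = log, interviews = interviews, truth = truth, scores = score_tab,
      summaries = summaries, table2 = table2, table3 = table3,
      alphas = alphas, reactivity = reactivity, compliance = compliance,
      seed = seed
    ),
    class = "ema_study"
  )
}

# Pooled entries x items matrix for one scale, from a response log.
scale_item_matrix <- function(log, scale) {
  ids <- vapply(scale$items, `[[`, "", "item_id")
  d <- log[log$item_id %in% ids, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(matrix(numeric(0), 0, length(ids), dimnames = list(NULL, ids)))
  }
  key <- interaction(d$participant_id, d$day, d$alarm_index, drop = TRUE)
  m <- matrix(NA_real_, nlevels(key), length(ids),
    dimnames = list(levels(key), ids)
  )
  m[cbind(as.integer(key), match(d$item_id, ids))] <- d$response_likert
  m
}
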