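#' Generate a synthetic community clickstream and trial cohort
#'
#' Simulates a time-stamped event log for an online cessation community
#' (a trial cohort embedded in a larger background membership) together
#' with a participant roster carrying baseline covariates and a binary
#' 30-day abstinence outcome with planted effects.
#'
#' The generative story, in order:
#' 1. Members register (participants uniformly over the enrollment window,
#'    background members earlier and throughout) and receive heavy-tailed
#'    per-user viewing and posting rates (log-normal multipliers). A
#'    `lurker_fraction` share of members never posts; members who post at
#'    all contribute at least one post.
#' 2. Posters author top-level content in channels drawn from
#'    `channel_mix`; private messages are addressed to a uniformly chosen
#'    other member, who reads them with probability `pm_read_prob`.
#' 3. Members browse: each view picks uniformly among the non-PM content
#'    existing at the view time.
#' 4. A reader responds in-thread with probability `reply_prob`
#'    (lurkers never do), and the author of the content responded to views
#'    the response with probability `author_revisit_prob` — the chain that
#'    makes an out-degree tie "aware".
#' 5. The abstinence outcome is drawn from a logistic model on the four
#'    square-root scale centrality features, computed from the generated
#'    events by the same tie/centrality code used at analysis time
#'    ([build_ties()], [mark_awareness()], [weekly_centralities()]), plus
#'    standardized age and confidence-to-quit. Survey non-responders are
#'    coded as smokers.
#'
#' Timestamps have second resolution; simultaneous events are ordered by a
#' deterministic sequence number (`seq`). The function seeds the global
#' RNG from `config$seed`, so identical configurations reproduce the event
#' log and cohort exactly.
#'
#' @param config a [generator_config()].
#' @return a list with elements
#'   \describe{
#'     \item{events}{`data.table` of click events: `user_id`, `timestamp`
#'       (POSIXct UTC, seconds), `action` (view/post/respond/send_pm),
#'       `channel`, `content_id`, `thread_id`, `author_id` (author of the
#'       content acted on; self for authored events), `seq`.}
#'     \item{roster}{`data.table` of members: ids, `registration_time`,
#'       `is_trial_participant`, `is_excluded`, baseline covariates
#'       (participants only) and `abstinent_30d`.}
#'     \item{truth}{planted generative values: outcome coefficients,
#'       covariate standardization constants, and the realized feature
#'       matrix used to draw the outcome — for parameter-recovery tests.}
#'   }
#' @export
generate_community <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  horizon <- config$enrollment_days + config$study_days

  ## -- members ------------------------------------------------------------
  n_p <- config$n_participants
  n_b <- config$n_background
  n_x <- config$n_excluded
  members <- data.table(
    user_id = c(sprintf("P%05d", seq_len(n_p)),
                sprintf("B%05d", seq_len(n_b)),
                sprintf("X%03d", seq_len(n_x))),
    is_trial_participant = rep(c(TRUE, FALSE, FALSE), c(n_p, n_b, n_x)),
    is_excluded = rep(c(FALSE, FALSE, TRUE), c(n_p, n_b, n_x))
  )
  members[, registration_day := c(runif(n_p, 0, config$enrollment_days),
                                  runif(n_b, -180, config$enrollment_days),
                                  runif(pmax(n_x, 0), -180, 0))]
  members[, window_start := registration_day]
  members[, window_end := fifelse(is_trial_participant,
                                  registration_day + config$study_days,
                                  horizon)]
  members[, window_len := window_end - window_start]

  ## heavy-tailed activity multipliers, mean 1
  mlog <- -config$rate_sdlog^2 / 2
  nm <- nrow(members)
  members[, view_mult := rlnorm(nm, mlog, config$rate_sdlog)]
  members[, post_mult := rlnorm(nm, mlog, config$rate_sdlog)]
  members[, is_lurker := runif(nm) < config$lurker_fraction]

  ## -- pass A: top-level posts -------------------------------------------
  posters <- members[is_lurker == FALSE]
  n_posts <- if (nrow(posters))
    1L + rpois(nrow(posters),
               config$post_rate * posters$post_mult * posters$window_len)
  else integer(0)
  posts <- posters[rep(seq_len(.N), n_posts),
                   .(user_id, window_start, window_end)]
  if (nrow(posts)) {
    posts[, time := runif(.N, window_start, window_end)]
    posts[, channel := sample(CN_CHANNELS, .N, replace = TRUE,
                              prob = config$channel_mix)]
    setorder(posts, time)
    posts[, content_id := sprintf("c%07d", seq_len(.N))]
    posts[, thread_id := content_id]
  } else {
    posts <- data.table(user_id = character(), window_start = numeric(),
                        window_end = numeric(), time = numeric(),
                        channel = character(), content_id = character(),
                        thread_id = character())
  }

  ## PM recipients: uniform among other members
  pm_idx <- which(posts$channel == "pm")
  if (length(pm_idx) && nm >= 2) {
    rec <- sample.int(nm, length(pm_idx), replace = TRUE)
    senders <- match(posts$user_id[pm_idx], members$user_id)
    while (any(bad <- rec == senders))
      rec[bad] <- sample.int(nm, sum(bad), replace = TRUE)
    posts[pm_idx, recipient := members$user_id[rec]]
  } else {
    posts[, recipient := NA_character_]
    if (length(pm_idx)) posts <- posts[channel != "pm"]  # no one to receive
  }

  ## -- pass B: browsing views of non-PM content --------------------------
  pool <- posts[channel != "pm"]
  n_views <- rpois(nm, config$view_rate * members$view_mult *
                     members$window_len)
  views <- members[rep(seq_len(.N), n_views),
                   .(viewer = user_id, window_start, window_end)]
  if (nrow(views) && nrow(pool)) {
    views[, time := runif(.N, window_start, window_end)]
    setorder(views, time)
    k <- findInterval(views$time, pool$time)
    views <- views[k > 0]
    k <- k[k > 0]
    idx <- floor(runif(nrow(views)) * k) + 1L
    views[, `:=`(content_id = pool$content_id[idx],
                 thread_id = pool$thread_id[idx],
                 channel = pool$channel[idx],
                 author_id = pool$user_id[idx])]
  } else {
    views <- data.table(viewer = character(), time = numeric(),
                        content_id = character(), thread_id = character(),
                        channel = character(), author_id = character())
  }
  views <- views[, .(viewer, time, content_id, thread_id, channel,
                     author_id)]

  ## PM receipt views
  pms <- posts[channel == "pm" & !is.na(recipient)]
  if (nrow(pms)) {
    pms[, read := runif(.N) < config$pm_read_prob]
    pm_views <- pms[read == TRUE,
                    .(viewer = recipient,
                      time = time + rexp(sum(read), rate = 1),
                      content_id, thread_id, channel,
                      author_id = user_id)]
    pm_views <- pm_views[time <= horizon]
    views <- rbindlist(list(views, pm_views), use.names = TRUE)
  }

  ## -- pass C: in-thread responses ---------------------------------------
  lurker_ids <- members[is_lurker == TRUE, user_id]
  can_reply <- !(views$viewer %in% lurker_ids) &
    views$viewer != views$author_id
  do_reply <- can_reply & runif(nrow(views)) < config$reply_prob
  responses <- views[do_reply,
                     .(user_id = viewer, channel, thread_id,
                       parent_content = content_id,
                       parent_author = author_id,
                       time = time + runif(sum(do_reply), 1, 10) / 1440)]
  responses <- responses[time <= horizon]
  if (nrow(responses)) {
    setorder(responses, time)
    responses[, content_id := sprintf("r%07d", seq_len(.N))]
  } else {
    responses[, content_id := character(0)]
  }

  ## -- pass D: author revisits of responses ------------------------------
  revisit <- responses[runif(.N) < config$author_revisit_prob &
                         parent_author != user_id]
  revisits <- revisit[, .(viewer = parent_author,
                          time = time + rexp(.N, rate = 0.5),
                          content_id, thread_id, channel,
                          author_id = user_id)]
  revisits <- revisits[time <= horizon]

  ## -- assemble event log -------------------------------------------------
  authored <- rbindlist(list(
    posts[, .(user_id, time, action = fifelse(channel == "pm", "send_pm",
                                              "post"),
              channel, content_id, thread_id, author_id = user_id)],
    responses[, .(user_id, time, action = "respond", channel, content_id,
                  thread_id, author_id = user_id)]
  ), use.names = TRUE)
  viewed <- rbindlist(list(views, revisits), use.names = TRUE)[
    , .(user_id = viewer, time, action = "view", channel, content_id,
        thread_id, author_id)]
  events <- rbindlist(list(authored, viewed), use.names = TRUE)
  setorder(events, time, content_id, action, user_id)
  events[, seq := seq_len(.N)]
  events[, timestamp := days_to_time(time)]
  events[, time := NULL]
  setcolorder(events, c("user_id", "timestamp", "action", "channel",
                        "content_id", "thread_id", "author_id", "seq"))

  ## -- roster with baseline covariates ------------------------------------
  roster <- members[, .(user_id, is_trial_participant, is_excluded,
                        registration_time = days_to_time(registration_day))]
  roster[, `:=`(age = NA_real_, female = NA_integer_,
                some_college = NA_integer_, employed_ft = NA_integer_,
                hispanic = NA_integer_, white = NA_integer_,
                ttfc_5min = NA_integer_, ftnd = NA_real_,
                cigs_per_day = NA_real_, quit_attempts = NA_real_,
                desire_quit = NA_real_, confidence_quit = NA_real_,
                tempt_social = NA_real_, tempt_negaffect = NA_real_,
                tempt_craving = NA_real_, piq_pos = NA_real_,
                piq_neg = NA_real_, extraversion = NA_real_,
                neurosis = NA_real_, openness = NA_real_,
                illness_smoking = NA_integer_, doctor_advice = NA_integer_,
                sns_profile = NA_integer_, intention_ex = NA_integer_,
                abstinent_30d = NA_integer_)]
  if (n_p > 0) {
    clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    pi <- which(roster$is_trial_participant)
    roster[pi, `:=`(
      age = clip(round(rnorm(n_p, 42.1, 13.2)), 18, 80),
      female = as.integer(runif(n_p) < 0.613),
      some_college = as.integer(runif(n_p) < 0.729),
      employed_ft = as.integer(runif(n_p) < 0.455),
      hispanic = as.integer(runif(n_p) < 0.061),
      white = as.integer(runif(n_p) < 0.802),
      ttfc_5min = as.integer(runif(n_p) < 0.381),
      ftnd = clip(round(rnorm(n_p, 5.2, 2.2)), 0, 10),
      cigs_per_day = clip(round(rnorm(n_p, 16.5, 8.4)), 1, 60),
      quit_attempts = rpois(n_p, 3),
      desire_quit = clip(round(rnorm(n_p, 4.55, 0.6)), 1, 5),
      confidence_quit = clip(round(rnorm(n_p, 3.3, 1.1)), 1, 5),
      tempt_social = clip(rnorm(n_p, 4.0, 0.8), 1, 5),
      tempt_negaffect = clip(rnorm(n_p, 4.5, 0.6), 1, 5),
      tempt_craving = clip(rnorm(n_p, 3.8, 0.8), 1, 5),
      piq_pos = clip(rnorm(n_p, 6.3, 5.0), 0, 20),
      piq_neg = clip(rnorm(n_p, 4.4, 4.6), 0, 20),
      extraversion = clip(round(rnorm(n_p, 8.6, 3.2)), 2, 14),
      neurosis = clip(round(rnorm(n_p, 8.3, 3.1)), 2, 14),
      openness = clip(round(rnorm(n_p, 10.8, 2.5)), 2, 14),
      illness_smoking = as.integer(runif(n_p) < 0.636),
      doctor_advice = as.integer(runif(n_p) < 0.623),
      sns_profile = as.integer(runif(n_p) < 0.898),
      intention_ex = as.integer(runif(n_p) < 0.977)
    )]
  }

  ## -- outcome from realized centrality trajectories ----------------------
  cov_transform <- list(age = c(center = 42.1, scale = 13.2),
                        confidence_quit = c(center = 3.3, scale = 1.1))
  truth <- list(outcome = config$outcome,
                covariate_transform = cov_transform,
                features = NULL)
  if (n_p > 0) {
    ties <- build_ties(events,
                       exclusions = members[is_excluded == TRUE, user_id])
    ties <- mark_awareness(ties, events)
    wc <- weekly_centralities(ties, roster,
                              n_weeks = config$study_days %/% 7L)
    feats <- sqrt_change_features(wc)
    feats <- feats[match(roster$user_id[pi], user_id)]
    feats[, age_z := (roster$age[pi] - 42.1) / 13.2]
    feats[, confidence_z := (roster$confidence_quit[pi] - 3.3) / 1.1]
    co <- config$outcome
    lp <- co$intercept +
      co$sqrt_in_week1 * feats$sqrt_in_week1 +
      co$sqrt_in_change * feats$sqrt_in_change +
      co$sqrt_outaware_week1 * feats$sqrt_outaware_week1 +
      co$sqrt_outaware_change * feats$sqrt_outaware_change +
      co$age_z * feats$age_z +
      co$confidence_z * feats$confidence_z
    abst <- rbinom(n_p, 1, plogis(lp))
    responded <- rbinom(n_p, 1, config$response_prob)
    roster[pi, abstinent_30d := as.integer(abst * responded)]
    feats[, abstinent_30d := roster$abstinent_30d[pi]]
    truth$features <- feats[]
  }

  list(events = events[], roster = roster[], truth = truth)
}
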