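#' Configuration for the synthetic community generator
#'
#' Bundles every knob of the synthetic clickstream/cohort generator with
#' validation. Defaults describe a mid-sized online cessation community
#' observed over a 12-week study window: a trial cohort of 2,657 smokers
#' embedded in a larger background membership, heavy-tailed reading and
#' posting activity with a majority of lurkers, threaded content across
#' five communication channels, and a binary 30-day abstinence outcome
#' generated from a logistic model on square-root scale centrality
#' features plus baseline covariates.
#'
#' @param n_participants number of trial participants in the cohort.
#' @param n_background number of background (non-trial) community members.
#'   Participant degrees count ties to the whole community, so background
#'   members are first-class nodes.
#' @param n_excluded number of staff/bot accounts; they generate events but
#'   are excluded from all network denominators.
#' @param study_days per-participant observation window in days
#'   (84 = 12 weeks).
#' @param enrollment_days length of the enrollment window over which
#'   participant registrations are spread uniformly.
#' @param channel_mix named proportions over the posting channels
#'   `blog`, `group`, `wall`, `board`, `pm`; must sum to 1.
#' @param view_rate,post_rate baseline per-user event rates (events per
#'   active day). Individual rates are `rate * m_i` with
#'   `m_i ~ Lognormal(-sdlog^2/2, sdlog)` so the population mean multiplier
#'   is 1; the log-normal tail reproduces the strongly right-skewed degree
#'   distributions typical of such communities.
#' @param rate_sdlog log-scale standard deviation of the activity
#'   multipliers (heaviness of the tail).
#' @param lurker_fraction probability that a member never posts (posting
#'   rate forced to zero); reading is unaffected.
#' @param reply_prob probability that a reader responds in-thread after
#'   viewing a content item.
#' @param author_revisit_prob probability that the author whose content was
#'   responded to later views the response (the second leg of the
#'   awareness chain).
#' @param pm_read_prob probability that the recipient of a private message
#'   reads it.
#' @param outcome named list defining the logistic outcome model:
#'   `intercept`, coefficients `sqrt_in_week1`, `sqrt_in_change`,
#'   `sqrt_outaware_week1`, `sqrt_outaware_change` on the unscaled
#'   square-root centrality features, and `age_z`, `confidence_z` on
#'   standardized baseline covariates.
#' @param response_prob probability a participant answers the 3-month
#'   survey; non-responders are coded as smokers (outcome 0).
#' @param seed integer seed; identical config + seed reproduces the event
#'   log and cohort exactly.
#'
#' @return an object of class `generator_config` (a validated named list).
#' @seealso [generate_community()], [read_generator_config()]
#' @export
generator_config <- function(n_participants = 2657,
                             n_background = 5000,
                             n_excluded = 5,
                             study_days = 84,
                             enrollment_days = 120,
                             channel_mix = c(blog = 0.35, group = 0.30,
                                             wall = 0.10, board = 0.15,
                                             pm = 0.10),
                             view_rate = 0.15,
                             post_rate = 0.08,
                             rate_sdlog = 1.4,
                             lurker_fraction = 0.66,
                             reply_prob = 0.15,
                             author_revisit_prob = 0.6,
                             pm_read_prob = 0.8,
                             outcome = list(intercept = -2.2,
                                            sqrt_in_week1 = 0,
                                            sqrt_in_change = log(1.19),
                                            sqrt_outaware_week1 = 0,
                                            sqrt_outaware_change = log(1.29),
                                            age_z = log(0.85),
                                            confidence_z = log(1.3)),
                             response_prob = 1,
                             seed = 1L) {
  cfg <- list(n_participants = n_participants, n_background = n_background,
              n_excluded = n_excluded, study_days = study_days,
              enrollment_days = enrollment_days, channel_mix = channel_mix,
              view_rate = view_rate, post_rate = post_rate,
              rate_sdlog = rate_sdlog, lurker_fraction = lurker_fraction,
              reply_prob = reply_prob,
              author_revisit_prob = author_revisit_prob,
              pm_read_prob = pm_read_prob, outcome = outcome,
              response_prob = response_prob, seed = as.integer(seed))
  validate_generator_config(cfg)
}

CN_CHANNELS <- c("blog", "group", "wall", "board", "pm")
CN_ACTIONS <- c("view", "post", "respond", "send_pm")
CN_OUTCOME_TERMS <- c("intercept", "sqrt_in_week1", "sqrt_in_change",
                      "sqrt_outaware_week1", "sqrt_outaware_change",
                      "age_z", "confidence_z")

validate_generator_config <- function(cfg) {
  chk_count <- function(field, min = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min ||
        v != as.integer(v))
      cn_stop("invalid generator config: '", field,
              "' must be a single integer >= ", min,
              class = "cessnet_config_error")
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      cn_stop("invalid generator config: '", field,
              "' must be a probability in [0, 1]",
              class = "cessnet_config_error")
  }
  for (f in c("n_participants", "n_background", "n_excluded"))
    chk_count(f)
  for (f in c("study_days", "enrollment_days")) chk_count(f, min = 1)
  for (f in c("lurker_fraction", "reply_prob", "author_revisit_prob",
              "pm_read_prob", "response_prob"))
    chk_prob(f)
  for (f in c("view_rate", "post_rate", "rate_sdlog")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      cn_stop("invalid generator config: '", f, "' must be >= 0",
              class = "cessnet_config_error")
  }
  mix <- cfg$channel_mix
  if (!is.numeric(mix) || is.null(names(mix)) ||
      !setequal(names(mix), CN_CHANNELS))
    cn_stop("invalid generator config: 'channel_mix' must be named over {",
            paste(CN_CHANNELS, collapse = ", "), "}",
            class = "cessnet_config_error")
  if (any(mix < 0 | mix > 1) || abs(sum(mix) - 1) > 1e-8)
    cn_stop("invalid generator config: 'channel_mix' proportions must lie",
            " in [0,1] and sum to 1", class = "cessnet_config_error")
  cfg$channel_mix <- mix[CN_CHANNELS]
  out <- cfg$outcome
  if (!is.list(out) || !all(CN_OUTCOME_TERMS %in% names(out)) ||
      !all(vapply(out[CN_OUTCOME_TERMS], function(x)
        is.numeric(x) && length(x) == 1 && !is.na(x), logical(1))))
    cn_stop("invalid generator config: 'outcome' must supply numeric ",
            paste(CN_OUTCOME_TERMS, collapse = ", "),
            class = "cessnet_config_error")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    cn_stop("invalid generator config: 'seed' must be a single integer",
            class = "cessnet_config_error")
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  cohort: %d participants + %d background members (%d excluded accounts)\n",
              x$n_participants, x$n_background, x$n_excluded))
  cat(sprintf("  window: %d study days, %d enrollment days\n",
              x$study_days, x$enrollment_days))
  cat(sprintf("  activity: view %.3g/day, post %.3g/day, sdlog %.2f, lurkers %.0f%%\n",
              x$view_rate, x$post_rate, x$rate_sdlog,
              100 * x$lurker_fraction))
  cat(sprintf("  interaction: reply %.2f, author revisit %.2f, pm read %.2f\n",
              x$reply_prob, x$author_revisit_prob, x$pm_read_prob))
  co <- x$outcome
  cat(sprintf("  outcome: logit = %.2f + %.3f*sqrt_in_wk1 + %.3f*sqrt_in_chg + %.3f*sqrt_oa_wk1 + %.3f*sqrt_oa_chg + covariates\n",
              co$intercept, co$sqrt_in_week1, co$sqrt_in_change,
              co$sqrt_outaware_week1, co$sqrt_outaware_change))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Read / write a generator configuration as YAML
#'
#' @param path file path.
#' @return `read_generator_config()` returns a validated
#'   [generator_config()]; `write_generator_config()` returns `path`
#'   invisibly.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- generator_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown))
    cn_stop("unknown generator config field(s): ",
            paste(unknown, collapse = ", "),
            class = "cessnet_config_error")
  cfg <- utils::modifyList(unclass(base), raw)
  if (!is.null(raw$channel_mix)) cfg$channel_mix <- unlist(raw$channel_mix)
  cfg$seed <- as.integer(cfg$seed)
  validate_generator_config(cfg)
}

#' @rdname read_generator_config
#' @param config a [generator_config()].
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- unclass(config)
  x$channel_mix <- as.list(x$channel_mix)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}
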