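#' Segment page views into sessions (30-minute inactivity rule)
#'
#' Groups each user's `view` events into sessions: a gap of *more than*
#' 30 minutes between consecutive page views ends the session, so a gap of
#' exactly 30 minutes does not split. Session duration is the time elapsed
#' between the first and the last page view of the session, hence a
#' single-view session has duration zero. Only view events define
#' sessions; posting is assumed to co-occur with a page view.
#'
#' @param events event `data.table`; may contain any mix of users and
#'   actions. Within each user, events must be time-ordered (ties resolved
#'   by `seq` if present) or an error is raised.
#' @param gap_minutes inactivity threshold in minutes (default 30).
#' @return `data.table` with one row per session: `user_id`, `session_id`
#'   (1-based per user), `start_time`, `end_time`, `n_page_views`,
#'   `duration_min`.
#' @export
sessionize <- function(events, gap_minutes = 30) {
  ev <- as.data.table(events)[action == "view"]
  if (nrow(ev) == 0)
    return(data.table(user_id = character(), session_id = integer(),
                      start_time = as_time(character()),
                      end_time = as_time(character()),
                      n_page_views = integer(), duration_min = numeric()))
  if (is.null(ev$seq)) ev[, seq := seq_len(.N)]
  ev <- ev[order(user_id, seq)]
  unsorted <- ev[, any(diff(as.numeric(timestamp)) < 0), by = user_id]
  if (any(unsorted$V1))
    cn_stop("sessionize(): events are not time-sorted for user(s) ",
            paste(head(unsorted[V1 == TRUE, user_id], 3), collapse = ", "),
            class = "cessnet_contract_error")
  ev[, gap := c(Inf, diff(as.numeric(timestamp))), by = user_id]
  ev[, session_id := cumsum(gap > gap_minutes * 60), by = user_id]
  ev[, .(start_time = timestamp[1],
         end_time = timestamp[.N],
         n_page_views = .N,
         duration_min = as.numeric(difftime(timestamp[.N], timestamp[1],
                                            units = "mins"))),
     by = .(user_id, session_id)]
}

#' Per-user website utilization profiles
#'
#' Computes individual utilization and engagement metrics over each
#' member's first `window_days` days after registration: return visits
#' (session count), time on site (sum of session durations, minutes),
#' days logged in (distinct calendar days with at least one event), page
#' views, and per-channel passive/active engagement counts. `total_posts`
#' counts authored messages (posts and in-thread responses) in the blog,
#' group-discussion and message-board channels; wall posts and private
#' messages are tallied separately and do not count toward `total_posts`.
#' Profile views are wall-channel views (the wall is the member profile
#' page); "PMs received" is the number of private messages the member
#' read.
#'
#' @param events event `data.table` for the whole community.
#' @param roster roster with `user_id` and `registration_time`; one
#'   profile is returned per roster row (excluded accounts keep their
#'   profile but are flagged upstream).
#' @param window_days length of the extraction window (default 84 days =
#'   12 weeks, aligning with the weekly centrality window).
#' @return `data.table` with one row per roster member; all counts are 0
#'   for members without events.
#' @export
utilization <- function(events, roster, window_days = 84) {
  ev <- as.data.table(events)
  ro <- as.data.table(roster)
  if (anyNA(ro$registration_time))
    cn_stop("utilization(): roster has missing registration_time",
            class = "cessnet_contract_error")
  ev <- ev[user_id %in% ro$user_id]
  ev[ro, reg := i.registration_time, on = "user_id"]
  ev <- ev[timestamp >= reg & timestamp < reg + window_days * 86400]

  ses <- sessionize(ev)
  ses_sum <- ses[, .(return_visits = .N,
                     time_on_site = sum(duration_min)), by = user_id]

  cnt <- function(expr) {
    e <- ev[eval(expr), .N, by = user_id]
    setNames(e$N[match(ro$user_id, e$user_id)], ro$user_id)
  }
  z <- function(x) fifelse(is.na(x), 0L, as.integer(x))

  days_in <- ev[, .(days_logged_in = uniqueN(as.Date(timestamp, tz = CN_TZ))),
                by = user_id]

  prof <- data.table(user_id = ro$user_id)
  prof[, return_visits := z(ses_sum$return_visits[
    match(user_id, ses_sum$user_id)])]
  prof[, time_on_site := {
    v <- ses_sum$time_on_site[match(user_id, ses_sum$user_id)]
    fifelse(is.na(v), 0, v)
  }]
  prof[, days_logged_in := z(days_in$days_logged_in[
    match(user_id, days_in$user_id)])]
  prof[, total_page_views := z(cnt(quote(action == "view")))]
  prof[, sn_page_views := total_page_views]
  ## passive engagement
  prof[, profiles_viewed := z(cnt(quote(action == "view" &
                                          channel == "wall")))]
  prof[, blog_posts_read := z(cnt(quote(action == "view" &
                                          channel == "blog")))]
  prof[, pms_received := z(cnt(quote(action == "view" & channel == "pm")))]
  ## active engagement
  prof[, blog_posts := z(cnt(quote(action == "post" & channel == "blog")))]
  prof[, blog_comments := z(cnt(quote(action == "respond" &
                                        channel == "blog")))]
  prof[, group_posts := z(cnt(quote(action %in% c("post", "respond") &
                                      channel == "group")))]
  prof[, board_posts := z(cnt(quote(action %in% c("post", "respond") &
                                      channel == "board")))]
  prof[, wall_posts := z(cnt(quote(action %in% c("post", "respond") &
                                     channel == "wall")))]
  prof[, pms_sent := z(cnt(quote(action %in% c("send_pm", "respond") &
                                   channel == "pm")))]
  ## posts definition: blogs + group discussions + message board;
  ## excludes private messages and wall posts
  prof[, total_posts := blog_posts + blog_comments + group_posts +
         board_posts]
  prof[]
}
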