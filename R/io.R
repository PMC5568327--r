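#' Write and read click-event logs
#'
#' The on-disk format is UTF-8 tab-delimited text with header row and
#' columns exactly `user_id`, `timestamp` (ISO-8601, UTC, second
#' resolution), `action` (`view`, `post`, `respond`, `send_pm`), `channel`
#' (`blog`, `group`, `wall`, `board`, `pm`), `content_id`, `thread_id`,
#' `author_id`. Rows are stored in event order; on reading, the sequence
#' number `seq` is re-derived as the row number, so a write/read
#' round-trip is the identity.
#'
#' @param events event `data.table` as produced by [generate_community()].
#' @param path file path.
#' @return `write_event_log()` returns `path` invisibly;
#'   `read_event_log()` returns the event `data.table`.
#' @export
write_event_log <- function(events, path) {
  ev <- as.data.table(events)
  out <- ev[, .(user_id,
                timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                   tz = "UTC"),
                action, channel, content_id, thread_id, author_id)]
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

CN_EVENT_COLS <- c("user_id", "timestamp", "action", "channel",
                   "content_id", "thread_id", "author_id")

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  ev <- fread(path, sep = "\t", colClasses = "character",
              header = TRUE)
  if (!identical(names(ev), CN_EVENT_COLS))
    cn_stop("malformed event log '", path, "': expected columns ",
            paste(CN_EVENT_COLS, collapse = ", "),
            class = "cessnet_parse_error")
  bad <- which(!(ev$action %in% CN_ACTIONS))
  if (length(bad))
    cn_stop("malformed event log '", path, "': unknown action '",
            ev$action[bad[1]], "' at line ", bad[1] + 1L,
            class = "cessnet_parse_error")
  bad <- which(!(ev$channel %in% CN_CHANNELS))
  if (length(bad))
    cn_stop("malformed event log '", path, "': unknown channel '",
            ev$channel[bad[1]], "' at line ", bad[1] + 1L,
            class = "cessnet_parse_error")
  ts <- as.POSIXct(ev$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  bad <- which(is.na(ts) & nzchar(ev$timestamp))
  if (length(bad) || anyNA(ts))
    cn_stop("malformed event log '", path, "': unparseable timestamp at ",
            "line ", (if (length(bad)) bad[1] else which(is.na(ts))[1]) + 1L,
            class = "cessnet_parse_error")
  ev[, timestamp := ts]
  ev[, seq := seq_len(.N)]
  ev[]
}

#' Write and read participant rosters
#'
#' Tab-delimited text; `registration_time` is ISO-8601 UTC, logical flags
#' are 0/1, missing covariates are empty fields. Column dictionary: member
#' id and flags (`user_id`, `is_trial_participant`, `is_excluded`),
#' `registration_time`, baseline covariates (demographics, smoking
#' history, psychosocial scores), and the coded outcome `abstinent_30d`.
#'
#' @param roster roster `data.table` as produced by [generate_community()].
#' @param path file path.
#' @return `write_roster()` returns `path` invisibly; `read_roster()`
#'   returns the roster `data.table`.
#' @export
write_roster <- function(roster, path) {
  ro <- copy(as.data.table(roster))
  ro[, registration_time := format(registration_time,
                                   "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  ro[, is_trial_participant := as.integer(is_trial_participant)]
  ro[, is_excluded := as.integer(is_excluded)]
  fwrite(ro, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_roster
#' @export
read_roster <- function(path) {
  ro <- fread(path, sep = "\t", header = TRUE, na.strings = "")
  need <- c("user_id", "is_trial_participant", "is_excluded",
            "registration_time")
  if (!all(need %in% names(ro)))
    cn_stop("malformed roster '", path, "': missing column(s) ",
            paste(setdiff(need, names(ro)), collapse = ", "),
            class = "cessnet_parse_error")
  ro[, registration_time := as.POSIXct(registration_time,
                                       format = "%Y-%m-%dT%H:%M:%SZ",
                                       tz = "UTC")]
  ro[, is_trial_participant := as.logical(is_trial_participant)]
  ro[, is_excluded := as.logical(is_excluded)]
  ro[, user_id := as.character(user_id)]
  ro[]
}
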