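#' Build the directed reading-tie network from clickstream events
#'
#' A directed tie points from a content author to a reader: the tie
#' source→target is formed the first time `target` views a content item
#' authored by `source` in one of the included channels. At most one tie
#' exists per ordered pair — degree counts distinct members, not
#' documents. Message-board events are excluded by default (the board's
#' clickstream does not identify reading unambiguously), as are wall
#' events; ties aggregate over blogs, group discussions and private
#' messages. Events touching excluded (staff/bot) accounts never form
#' ties, and self-views do not form ties.
#'
#' @param events event `data.table` (see [generate_community()] for the
#'   schema); a `seq` column is used to break timestamp ties and is
#'   derived from row order if absent.
#' @param channels channels whose views form ties.
#' @param exclusions character vector of excluded account ids.
#' @return `data.table` of ties: `source`, `target`, `formed_at`,
#'   `channel` (channel of first formation), `formed_seq`, `aware`
#'   (all `FALSE` until [mark_awareness()]), `aware_at`.
#' @export
build_ties <- function(events, channels = c("blog", "group", "pm"),
                       exclusions = character()) {
  ev <- as.data.table(events)
  if (is.null(ev$seq)) ev <- copy(ev)[, seq := seq_len(.N)]

  ## data integrity: every view must reference content authored earlier
  contents <- ev[action %in% c("post", "respond", "send_pm"),
                 .(content_id, created_seq = seq)]
  vw <- ev[action == "view"]
  if (nrow(vw)) {
    vw[contents, created_seq := i.created_seq, on = "content_id"]
    if (anyNA(vw$created_seq))
      cn_stop("build_ties(): view event references unknown content '",
              vw[is.na(created_seq), content_id][1], "'",
              class = "cessnet_integrity_error")
    if (any(vw$created_seq >= vw$seq))
      cn_stop("build_ties(): view event precedes creation of content '",
              vw[created_seq >= seq, content_id][1], "'",
              class = "cessnet_integrity_error")
  }

  q <- vw[channel %in% channels & author_id != user_id &
            !(user_id %in% exclusions) & !(author_id %in% exclusions)]
  if (nrow(q) == 0)
    return(data.table(source = character(), target = character(),
                      formed_at = as_time(character()),
                      channel = character(), formed_seq = integer(),
                      aware = logical(), aware_at = as_time(character())))
  setorder(q, seq)
  ties <- q[, .(formed_at = timestamp[1], channel = channel[1],
                formed_seq = seq[1]),
            by = .(source = author_id, target = user_id)]
  ties[, aware := FALSE]
  ties[, aware_at := as_time(NA)]
  ties[]
}

#' Flag awareness on out-going ties
#'
#' A tie source→target (Mary→John) is *aware* when the clickstream shows
#' the full chain: (1) John read content by Mary in some thread, then
#' responded or commented in that same thread, and (2) Mary subsequently
#' viewed John's response. Ordering is strict in event-sequence terms
#' (read before response before the author's view of it). `aware_at` is
#' the earliest qualifying time at which the author saw the response.
#' Only events in the tie-forming channels participate in the chain.
#'
#' @param ties output of [build_ties()].
#' @param events the full event `data.table`.
#' @param channels channels in which the chain may occur (defaults to the
#'   tie-forming channels).
#' @return `ties` with `aware`/`aware_at` filled in.
#' @export
mark_awareness <- function(ties, events,
                           channels = c("blog", "group", "pm")) {
  ties <- copy(as.data.table(ties))
  if (nrow(ties) == 0) return(ties)
  ev <- as.data.table(events)
  if (is.null(ev$seq)) ev <- copy(ev)[, seq := seq_len(.N)]
  ev <- ev[channel %in% channels]

  reads <- ev[action == "view",
              .(viewer = user_id, thread_id, content_id,
                content_author = author_id, rseq = seq, rtime = timestamp)]
  resp <- ev[action == "respond",
             .(responder = user_id, thread_id, resp_content = content_id,
               resp_seq = seq)]
  if (nrow(resp) == 0) return(ties)

  ## (1) responder had read someone else's content in the same thread,
  ## before responding
  chain1 <- resp[reads,
                 on = .(responder = viewer, thread_id),
                 nomatch = NULL, allow.cartesian = TRUE,
                 .(responder, thread_id, resp_content, resp_seq,
                   content_author, rseq)]
  chain1 <- chain1[rseq < resp_seq & content_author != responder]
  if (nrow(chain1) == 0) return(ties)
  chain1 <- unique(chain1[, .(source = content_author, target = responder,
                              resp_content, resp_seq)])

  ## (2) that author later viewed the response
  author_views <- reads[, .(source = viewer, resp_content = content_id,
                            vseq = rseq, vtime = rtime)]
  aware_links <- chain1[author_views, on = .(source, resp_content),
                        nomatch = NULL, allow.cartesian = TRUE]
  aware_links <- aware_links[vseq > resp_seq]
  if (nrow(aware_links) == 0) return(ties)
  aw <- aware_links[, .(aware_at = min(vtime)), by = .(source, target)]

  ties[aw, `:=`(aware = TRUE, aware_at = i.aware_at), on = .(source, target)]
  ## awareness applies only where a tie exists and never precedes it
  ties[aware == TRUE & aware_at < formed_at, aware_at := formed_at]
  ties[]
}
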