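#' Weekly cumulative centrality trajectories
#'
#' For each trial participant, computes cumulative in-degree, out-degree
#' and out-degree-aware at the end of each week relative to their own
#' registration: week `w` spans `[registration + 7*(w-1), registration +
#' 7*w)` days. Ties are cumulative, so each week's network contains all
#' ties formed in that week and earlier; in-degree counts distinct
#' authors whose content the participant read, out-degree counts distinct
#' readers of the participant's content, and out-degree-aware counts the
#' readers whose tie has become aware (response seen by the participant)
#' by the end of the week. Ties to and from background community members
#' count.
#'
#' @param ties tie `data.table` from [build_ties()] (after
#'   [mark_awareness()] if aware trajectories are needed).
#' @param roster roster; trajectories are computed for rows with
#'   `is_trial_participant == TRUE` and `is_excluded == FALSE` (or all
#'   rows when those columns are absent). Missing `registration_time` is
#'   an error.
#' @param n_weeks number of weekly snapshots (default 12).
#' @return `data.table` in long format: `user_id`, `week` (1..n_weeks),
#'   `in_degree`, `out_degree`, `out_degree_aware`; one row per
#'   participant-week, all-zero rows included.
#' @export
weekly_centralities <- function(ties, roster, n_weeks = 12) {
  ro <- as.data.table(roster)
  if (!is.null(ro$is_trial_participant)) ro <- ro[is_trial_participant == TRUE]
  if (!is.null(ro$is_excluded)) ro <- ro[is_excluded == FALSE]
  if (nrow(ro) == 0)
    return(data.table(user_id = character(), week = integer(),
                      in_degree = integer(), out_degree = integer(),
                      out_degree_aware = integer()))
  if (is.null(ro$registration_time) || anyNA(ro$registration_time))
    cn_stop("weekly_centralities(): participant missing registration_time",
            class = "cessnet_contract_error")
  tt <- as.data.table(ties)

  ## cumulative count matrix: participants x weeks
  cum_counts <- function(ids, times) {
    m <- matrix(0L, nrow(ro), n_weeks)
    keep <- ids %in% ro$user_id & !is.na(times)
    ids <- ids[keep]; times <- times[keep]
    if (length(ids)) {
      reg <- ro$registration_time[match(ids, ro$user_id)]
      wk <- pmax(1, ceiling(as.numeric(difftime(times, reg,
                                                units = "days")) / 7))
      keep2 <- wk <= n_weeks
      if (any(keep2)) {
        ui <- match(ids[keep2], ro$user_id)
        tab <- table(factor(ui, levels = seq_len(nrow(ro))),
                     factor(wk[keep2], levels = seq_len(n_weeks)))
        m <- t(apply(unclass(tab), 1, cumsum))
        storage.mode(m) <- "integer"
      }
    }
    m
  }
  m_in <- cum_counts(tt$target, tt$formed_at)
  m_out <- cum_counts(tt$source, tt$formed_at)
  aware_tt <- tt[aware == TRUE]
  m_oa <- cum_counts(aware_tt$source, aware_tt$aware_at)

  data.table(user_id = rep(ro$user_id, each = n_weeks),
             week = rep(seq_len(n_weeks), nrow(ro)),
             in_degree = as.integer(t(m_in)),
             out_degree = as.integer(t(m_out)),
             out_degree_aware = as.integer(t(m_oa)))
}

#' Square-root scale network predictor set
#'
#' Derives the four network predictors used in the abstinence models from
#' a weekly centrality trajectory: the week-1 value and the change over
#' weeks 2–12, both on the square-root scale. The change is computed as
#' `sqrt(week-12 cumulative) - sqrt(week-1 cumulative)`, so accumulating
#' nine ties after week 1 from a zero start corresponds to 3 square-root
#' units. Values are left unstandardized.
#'
#' @param series long `data.table` from [weekly_centralities()].
#' @return `data.table` with one row per participant: `user_id`,
#'   `sqrt_in_week1`, `sqrt_in_change`, `sqrt_outaware_week1`,
#'   `sqrt_outaware_change`.
#' @export
sqrt_change_features <- function(series) {
  s <- as.data.table(series)
  if (nrow(s) == 0)
    return(data.table(user_id = character(), sqrt_in_week1 = numeric(),
                      sqrt_in_change = numeric(),
                      sqrt_outaware_week1 = numeric(),
                      sqrt_outaware_change = numeric()))
  last_wk <- max(s$week)
  s[order(week),
    .(sqrt_in_week1 = sqrt(in_degree[1]),
      sqrt_in_change = sqrt(in_degree[.N]) - sqrt(in_degree[1]),
      sqrt_outaware_week1 = sqrt(out_degree_aware[1]),
      sqrt_outaware_change = sqrt(out_degree_aware[.N]) -
        sqrt(out_degree_aware[1])),
    by = user_id]
}
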