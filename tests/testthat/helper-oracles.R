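# Independent brute-force oracles and small fixture builders.
# Everything here is deliberately naive (loops, dense matrices) so the
# oracles share no code path with the package implementation.

suppressMessages(library(data.table))

ORIGIN <- as.POSIXct("2012-03-01 00:00:00", tz = "UTC")

# Build an event table from minutes-since-origin; fills schema defaults.
mk_events <- function(user_id, minutes, action = "view", channel = "blog",
                      content_id = NA_character_, thread_id = content_id,
                      author_id = NA_character_) {
  n <- length(minutes)
  dt <- data.table(
    user_id = rep_len(user_id, n),
    timestamp = ORIGIN + round(rep_len(minutes, n) * 60),
    action = rep_len(action, n),
    channel = rep_len(channel, n),
    content_id = rep_len(as.character(content_id), n),
    thread_id = rep_len(as.character(thread_id), n),
    author_id = rep_len(as.character(author_id), n))
  setorder(dt, timestamp)
  dt[, seq := seq_len(.N)]
  dt[]
}

mk_roster <- function(user_id, reg_minutes = 0, participant = TRUE,
                      excluded = FALSE, abstinent = NA_integer_) {
  n <- length(user_id)
  data.table(user_id = user_id,
             registration_time = ORIGIN + round(rep_len(reg_minutes, n) * 60),
             is_trial_participant = rep_len(participant, n),
             is_excluded = rep_len(excluded, n),
             abstinent_30d = rep_len(as.integer(abstinent), n))
}

## ---- sessionization oracle: O(n^2) interval check -------------------------
# Two views i <= j are in the same session iff every consecutive gap
# between them is <= gap seconds; sessions are the equivalence classes.
oracle_sessions <- function(times_sec, gap = 1800) {
  n <- length(times_sec)
  if (n == 0) return(integer(0))
  same <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ok <- TRUE
    if (j > i) for (k in (i + 1):j)
      if (times_sec[k] - times_sec[k - 1] > gap) ok <- FALSE
    same[i, j] <- same[j, i] <- ok
  }
  id <- integer(n); id[1] <- 1L
  for (i in seq_len(n)[-1])
    id[i] <- if (same[i - 1, i]) id[i - 1] else id[i - 1] + 1L
  # sanity: the labelling must reproduce the pairwise relation
  stopifnot(all((outer(id, id, "==")) == same))
  id
}

## ---- naive tie construction and awareness --------------------------------
# Plain-loop re-derivation of the tie rules for small logs.
oracle_ties <- function(events, channels = c("blog", "group", "pm"),
                        exclusions = character()) {
  ev <- as.data.frame(events)[order(events$seq), ]
  ties <- list()
  for (r in seq_len(nrow(ev))) {
    e <- ev[r, ]
    if (e$action != "view") next
    if (!(e$channel %in% channels)) next
    if (e$author_id == e$user_id) next
    if (e$user_id %in% exclusions || e$author_id %in% exclusions) next
    key <- paste(e$author_id, e$user_id, sep = "->")
    if (is.null(ties[[key]]))
      ties[[key]] <- list(source = e$author_id, target = e$user_id,
                          formed_at = e$timestamp, channel = e$channel,
                          formed_seq = e$seq)
  }
  if (!length(ties))
    return(data.frame(source = character(), target = character(),
                      formed_at = ORIGIN[0], channel = character(),
                      formed_seq = integer()))
  do.call(rbind, lapply(ties, function(t)
    data.frame(source = t$source, target = t$target, formed_at = t$formed_at,
               channel = t$channel, formed_seq = t$formed_seq)))
}

oracle_aware <- function(ties, events, channels = c("blog", "group", "pm")) {
  if (nrow(ties) == 0) {
    ties$aware <- logical(0)
    ties$aware_at <- ORIGIN[0]
    return(ties)
  }
  ev <- as.data.frame(events)
  ev <- ev[ev$channel %in% channels, ]
  ties$aware <- FALSE
  ties$aware_at <- ties$formed_at + NA
  views <- ev[ev$action == "view", ]
  resps <- ev[ev$action == "respond", ]
  for (i in seq_len(nrow(ties))) {
    M <- ties$source[i]; J <- ties$target[i]
    best <- Inf; best_t <- NULL
    for (r in seq_len(nrow(resps))) {
      rs <- resps[r, ]
      if (rs$user_id != J) next
      # (1) J read content authored by M in this thread, before responding
      read_ok <- any(views$user_id == J & views$thread_id == rs$thread_id &
                       views$author_id == M & views$seq < rs$seq)
      if (!read_ok) next
      # (2) M viewed J's response afterwards
      mv <- views[views$user_id == M & views$content_id == rs$content_id &
                    views$seq > rs$seq, ]
      if (nrow(mv) && min(as.numeric(mv$timestamp)) < best) {
        best <- min(as.numeric(mv$timestamp))
        best_t <- mv$timestamp[which.min(as.numeric(mv$timestamp))]
      }
    }
    if (!is.null(best_t)) {
      ties$aware[i] <- TRUE
      ties$aware_at[i] <- best_t
    }
  }
  ties
}

# From-scratch weekly rebuild: cumulative distinct counterparties by the
# end of each week, recomputed independently per week.
oracle_weekly <- function(ties, roster, n_weeks = 12) {
  ro <- as.data.frame(roster)
  ro <- ro[ro$is_trial_participant & !ro$is_excluded, ]
  out <- NULL
  for (u in ro$user_id) {
    reg <- ro$registration_time[ro$user_id == u]
    for (w in seq_len(n_weeks)) {
      cutoff <- reg + w * 7 * 86400
      indeg <- length(unique(ties$source[ties$target == u &
                                           ties$formed_at < cutoff]))
      outdeg <- length(unique(ties$target[ties$source == u &
                                            ties$formed_at < cutoff]))
      oa <- length(unique(ties$target[ties$source == u & ties$aware &
                                        !is.na(ties$aware_at) &
                                        ties$aware_at < cutoff]))
      out <- rbind(out, data.frame(user_id = u, week = w, in_degree = indeg,
                                   out_degree = outdeg,
                                   out_degree_aware = oa))
    }
  }
  out
}

## ---- digraph structural oracles ------------------------------------------
# adj: dense 0/1 matrix, no self loops. Exhaustive reachability via
# repeated boolean products; shortest paths via matrix powers.
oracle_graph <- function(adj) {
  n <- nrow(adj)
  reach <- diag(n) > 0
  for (step in seq_len(n)) reach <- reach | ((reach %*% adj) > 0)
  scc <- reach & t(reach)
  comp <- match(apply(scc, 1, paste, collapse = ""),
                unique(apply(scc, 1, paste, collapse = "")))
  sizes <- tabulate(comp)
  lscc_size <- max(sizes)
  lscc <- which(comp == which.max(sizes))
  apl <- NA_real_
  if (lscc_size >= 2) {
    dist <- matrix(Inf, n, n)
    pw <- diag(n)
    for (k in seq_len(n)) {
      pw <- (pw %*% adj) > 0
      newly <- pw & !is.finite(dist)
      dist[newly] <- k
    }
    pairs <- expand.grid(i = lscc, j = lscc)
    pairs <- pairs[pairs$i != pairs$j, ]
    apl <- mean(dist[cbind(pairs$i, pairs$j)])
  }
  und <- ((adj + t(adj)) > 0) * 1
  diag(und) <- 0
  loc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(und[i, ] > 0)
    k <- length(nb)
    loc[i] <- if (k < 2) 0
    else sum(und[nb, nb]) / 2 / choose(k, 2)
  }
  deg <- rowSums(und)
  tri <- sum(diag(und %*% und %*% und)) / 6
  triples <- sum(choose(deg, 2))
  list(lscc_size = lscc_size, avg_path_length = apl,
       clustering_local_avg = mean(loc),
       transitivity_global = if (triples > 0) 3 * tri / triples
       else NaN)
}

# random digraph as a tie table + its adjacency matrix
random_digraph <- function(n_nodes, p_edge = NULL) {
  if (is.null(p_edge)) p_edge <- runif(1, 0.1, 0.5)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  adj <- matrix(rbinom(n_nodes^2, 1, p_edge), n_nodes, n_nodes)
  diag(adj) <- 0
  idx <- which(adj == 1, arr.ind = TRUE)
  ties <- data.table(source = nodes[idx[, 1]], target = nodes[idx[, 2]],
                     formed_at = ORIGIN + seq_len(nrow(idx)) * 60,
                     channel = "blog", formed_seq = seq_len(nrow(idx)),
                     aware = rbinom(nrow(idx), 1, 0.3) == 1)
  ties[, aware_at := fifelse(aware, formed_at + 3600, ORIGIN[NA])]
  # node order in igraph follows first appearance; keep both
  list(adj = adj, nodes = nodes, ties = ties[])
}

## ---- random small event logs for oracle equivalence -----------------------
random_event_log <- function(n_users = 4, n_steps = 40,
                             channels = c("blog", "group", "board")) {
  users <- sprintf("U%02d", seq_len(n_users))
  contents <- list()  # content_id -> list(author, thread, channel)
  rows <- list()
  t_min <- 0
  for (s in seq_len(n_steps)) {
    t_min <- t_min + sample(c(0, 1, 5, 20, 31, 60, 240), 1,
                            prob = c(.1, .3, .2, .15, .1, .1, .05))
    u <- sample(users, 1)
    act <- sample(c("post", "view", "respond"), 1, prob = c(.3, .5, .2))
    if (act == "post" || length(contents) == 0) {
      cid <- sprintf("c%03d", length(contents) + 1)
      ch <- sample(channels, 1)
      contents[[cid]] <- list(author = u, thread = cid, channel = ch)
      rows[[length(rows) + 1]] <- data.frame(
        user_id = u, minutes = t_min, action = "post", channel = ch,
        content_id = cid, thread_id = cid, author_id = u)
    } else if (act == "view") {
      cid <- sample(names(contents), 1)
      cc <- contents[[cid]]
      rows[[length(rows) + 1]] <- data.frame(
        user_id = u, minutes = t_min, action = "view", channel = cc$channel,
        content_id = cid, thread_id = cc$thread, author_id = cc$author)
    } else {
      cid <- sample(names(contents), 1)
      cc <- contents[[cid]]
      rid <- sprintf("r%03d", length(contents) + 1)
      contents[[rid]] <- list(author = u, thread = cc$thread,
                              channel = cc$channel)
      rows[[length(rows) + 1]] <- data.frame(
        user_id = u, minutes = t_min, action = "respond",
        channel = cc$channel, content_id = rid, thread_id = cc$thread,
        author_id = u)
    }
  }
  df <- do.call(rbind, rows)
  # keep insertion order on timestamp ties so content creation always
  # precedes its views in seq
  ev <- as.data.table(df)[, .(user_id,
                              timestamp = ORIGIN + round(minutes * 60),
                              action, channel, content_id, thread_id,
                              author_id)]
  ev[, seq := seq_len(.N)]
  ev[]
}

## ---- logistic sandwich oracle --------------------------------------------
oracle_sandwich <- function(X, y, beta) {
  p <- as.numeric(plogis(X %*% beta))
  A <- t(X) %*% (X * (p * (1 - p)))
  B <- t(X) %*% (X * (y - p)^2)
  solve(A) %*% B %*% solve(A)
}

## ---- Fisher exact oracle for 2 x k tables --------------------------------
# Enumerates all tables with the observed margins; p = total probability
# of tables no more probable than the observed one.
oracle_fisher_2xk <- function(tab) {
  stopifnot(nrow(tab) == 2)
  cs <- colSums(tab); rs <- rowSums(tab); N <- sum(tab)
  log_p <- function(t1) {  # t1 = first row
    t2 <- cs - t1
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
      sum(lfactorial(c(t1, t2)))
  }
  grids <- lapply(seq_along(cs), function(j) 0:min(rs[1], cs[j]))
  all_t1 <- as.matrix(expand.grid(grids))
  keep <- rowSums(all_t1) == rs[1]
  all_t1 <- all_t1[keep, , drop = FALSE]
  lp_obs <- log_p(tab[1, ])
  lps <- apply(all_t1, 1, log_p)
  sum(exp(lps[lps <= lp_obs + 1e-7]))
}
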