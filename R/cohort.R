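#' Classify participants by social-network engagement
#'
#' Partitions participants into three exhaustive, disjoint groups based on
#' two utilization metrics dichotomized at zero over the 3-month window:
#' *non-users* (no posts and no page views), *passive users* (page views
#' but no posts) and *active users* (both posts and page views). The
#' posts metric is `total_posts` (blogs + group discussions + message
#' board; private messages and wall posts excluded), so a member whose
#' only contributions are wall posts or PMs classifies as passive — a
#' documented consequence of the posts definition. The degenerate case of
#' posts without any page view is assigned to `active` and recorded in
#' the audit log attached to the result.
#'
#' @param profiles utilization profiles from [utilization()].
#' @return `data.table` with `user_id`, `total_posts`, `sn_page_views`
#'   and `group` (factor: `non_user`, `passive`, `active`); attribute
#'   `"audit"` lists degenerate assignments.
#' @export
classify_engagement <- function(profiles) {
  pr <- as.data.table(profiles)
  out <- pr[, .(user_id, total_posts, sn_page_views)]
  out[, group := fifelse(total_posts == 0 & sn_page_views == 0, "non_user",
                         fifelse(total_posts == 0, "passive", "active"))]
  out[, group := factor(group, levels = c("non_user", "passive", "active"))]
  audit <- out[total_posts > 0 & sn_page_views == 0, user_id]
  setattr(out, "audit",
          if (length(audit))
            sprintf("assigned to 'active' with posts but zero page views: %s",
                    paste(audit, collapse = ", "))
          else character())
  out[]
}

#' Abstinence by engagement group
#'
#' Tabulates, per engagement group: N, median (IQR) of posts and page
#' views, and the count and percentage abstinent at 3 months (percent =
#' 100 * abstinent / N, one decimal; survey non-response is already coded
#' as smoking upstream).
#'
#' @param roster roster with `abstinent_30d` (participants).
#' @param labels group labels from [classify_engagement()].
#' @return `data.frame` with one row per group (empty groups keep N = 0
#'   and an `NA` percentage, flagged in the `note` column).
#' @export
group_table <- function(roster, labels) {
  ro <- as.data.table(roster)
  lb <- as.data.table(labels)
  d <- lb[ro[, .(user_id, abstinent_30d)], on = "user_id", nomatch = NULL]
  d <- d[!is.na(group)]
  iqr_fmt <- function(x) {
    if (!length(x)) return(NA_character_)
    q <- quantile(x, c(.25, .5, .75), type = 7)
    sprintf("%g (%g-%g)", q[2], q[1], q[3])
  }
  res <- lapply(levels(d$group), function(gl) {
    g <- d[group == gl]
    n <- nrow(g)
    n_abst <- sum(g$abstinent_30d, na.rm = TRUE)
    data.frame(group = gl, N = n,
               posts_median_iqr = iqr_fmt(g$total_posts),
               views_median_iqr = iqr_fmt(g$sn_page_views),
               n_abstinent = n_abst,
               pct_abstinent = pct(n_abst, n),
               note = if (n == 0) "empty group" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Between-group comparisons of baseline and utilization variables
#'
#' Dispatches each variable to the conventional test: one-way ANOVA for
#' continuous baseline variables, chi-square for categorical baseline
#' variables, Kruskal-Wallis rank-sum for (skewed) utilization and
#' network metrics, and Fisher's exact test for sparse categorical
#' metrics (2 x k tables). Constant variables are skipped with a reason.
#'
#' @param data `data.frame`/`data.table` of participant-level variables.
#' @param labels group labels from [classify_engagement()] (matched by
#'   `user_id`).
#' @param types named character vector mapping variable names to one of
#'   `"continuous"`, `"categorical"`, `"utilization"`,
#'   `"sparse_categorical"`; variables not named are skipped.
#' @return `data.frame` with `variable`, `test`, `p_value`, `note`.
#' @export
compare_groups <- function(data, labels, types) {
  d <- as.data.table(data)
  lb <- as.data.table(labels)
  d <- d[lb[, .(user_id, group)], on = "user_id", nomatch = NULL]
  if (uniqueN(stats::na.omit(d$group)) < 2)
    cn_stop("compare_groups(): need at least 2 non-empty groups",
            class = "cessnet_contract_error")
  one <- function(v, type) {
    x <- d[[v]]
    g <- d$group
    ok <- !is.na(x) & !is.na(g)
    x <- x[ok]; g <- droplevels(g[ok])
    if (length(unique(x)) < 2)
      return(data.frame(variable = v, test = NA_character_,
                        p_value = NA_real_, note = "constant variable"))
    p <- switch(type,
      continuous = {
        fit <- anova(lm(x ~ g))
        fit[["Pr(>F)"]][1]
      },
      categorical = suppressWarnings(chisq.test(table(x, g))$p.value),
      utilization = kruskal.test(x, g)$p.value,
      sparse_categorical = fisher.test(table(x, g))$p.value,
      cn_stop("compare_groups(): unknown type '", type, "' for '", v, "'"))
    test_name <- switch(type, continuous = "one-way ANOVA",
                        categorical = "chi-square",
                        utilization = "Kruskal-Wallis",
                        sparse_categorical = "Fisher exact")
    data.frame(variable = v, test = test_name, p_value = p, note = "")
  }
  vars <- intersect(names(types), names(d))
  do.call(rbind, lapply(vars, function(v) one(v, types[[v]])))
}
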