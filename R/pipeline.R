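#' Run the full analysis pipeline on a synthetic community
#'
#' Orchestrates generate -> sessionize -> build network -> classify ->
#' model as one reproducible run: writes the event log, roster, sessions,
#' utilization profiles, edge list, weekly centrality series, group
#' table, group comparisons, per-group model reports (including
#' nine-tie odds-ratio extrapolations and cross-validated AUC), the
#' degree-distribution table, and a run log recording the seed, the
#' configuration and package/R versions. Re-running with the same
#' configuration reproduces byte-identical outputs. Any stage failure
#' aborts with the stage name and cause.
#'
#' Stages communicate through the documented delimited formats, so each
#' downstream stage can equally be invoked on files from a previous run.
#'
#' @param config a [generator_config()] or the path to its YAML form.
#' @param out_dir output directory (created if needed).
#' @param alpha stepwise entry/stay threshold.
#' @param folds cross-validation folds.
#' @param n_weeks weekly snapshots for the centrality series.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = generator_config(), out_dir,
                         alpha = 0.10, folds = 10, n_weeks = 12) {
  if (is.character(config)) config <- read_generator_config(config)
  stopifnot(inherits(config, "generator_config"))
  if (config$n_participants == 0)
    cn_stop("run_pipeline(): empty cohort (n_participants = 0)",
            class = "cessnet_config_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      cn_stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
              class = "cessnet_pipeline_error"))
  }
  p <- function(f) file.path(out_dir, f)

  sim <- stage("generate", generate_community(config))
  stage("write_inputs", {
    write_event_log(sim$events, p("events.tsv"))
    write_roster(sim$roster, p("roster.tsv"))
  })

  participants <- sim$roster[is_trial_participant == TRUE &
                               is_excluded == FALSE]
  sessions <- stage("sessions", {
    ev_part <- sim$events[user_id %in% participants$user_id]
    sessionize(ev_part)
  })
  profiles <- stage("utilization",
                    utilization(sim$events, participants,
                                window_days = config$study_days))
  stage("write_sessions", {
    s <- copy(sessions)
    s[, `:=`(start_time = format(start_time, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC"),
             end_time = format(end_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))]
    fwrite(s, p("sessions.tsv"), sep = "\t", quote = FALSE)
    fwrite(profiles, p("profiles.tsv"), sep = "\t", quote = FALSE)
  })

  ties <- stage("network", {
    tt <- build_ties(sim$events,
                     exclusions = sim$roster[is_excluded == TRUE, user_id])
    mark_awareness(tt, sim$events)
  })
  stage("write_network", write_edge_list(ties, p("edge_list.tsv")))
  centr <- stage("centrality",
                 weekly_centralities(ties, sim$roster, n_weeks = n_weeks))
  stage("write_centrality",
        fwrite(centr, p("centrality.tsv"), sep = "\t", quote = FALSE))
  summ <- stage("network_summary", network_summary(ties))
  stage("write_degree_table",
        fwrite(summ$degree_table, p("degree_distribution.tsv"),
               sep = "\t", quote = FALSE))

  labels <- stage("classify", classify_engagement(profiles))
  gtab <- stage("group_table", group_table(participants, labels))
  stage("write_groups",
        fwrite(gtab, p("group_table.tsv"), sep = "\t", quote = FALSE))

  baseline_types <- c(age = "continuous", ftnd = "continuous",
                      confidence_quit = "continuous",
                      desire_quit = "continuous",
                      tempt_social = "continuous",
                      tempt_negaffect = "continuous",
                      tempt_craving = "continuous",
                      extraversion = "continuous",
                      neurosis = "continuous", openness = "continuous",
                      piq_pos = "continuous", piq_neg = "continuous",
                      female = "categorical", some_college = "categorical",
                      employed_ft = "categorical", white = "categorical",
                      hispanic = "categorical", ttfc_5min = "categorical",
                      illness_smoking = "categorical",
                      doctor_advice = "categorical",
                      return_visits = "utilization",
                      time_on_site = "utilization",
                      days_logged_in = "utilization",
                      total_page_views = "utilization")
  comparisons <- stage("compare_groups", {
    d <- profiles[participants, on = "user_id"]
    compare_groups(d, labels, baseline_types)
  })
  stage("write_comparisons",
        fwrite(comparisons, p("group_comparisons.tsv"), sep = "\t",
               quote = FALSE))

  feats <- stage("features", sqrt_change_features(centr))
  models <- stage("models",
                  fit_group_models(participants, profiles, labels, feats,
                                   alpha = alpha, folds = folds,
                                   seed = config$seed))
  stage("write_models", {
    for (gname in names(models)) {
      m <- models[[gname]]
      fwrite(m$fit$table, p(sprintf("model_%s.tsv", gname)), sep = "\t",
             quote = FALSE)
      if (!is.null(m$or9))
        fwrite(m$or9, p(sprintf("model_%s_or9.tsv", gname)), sep = "\t",
               quote = FALSE)
    }
  })

  stage("run_log", {
    lines <- c("cessnet pipeline run",
               sprintf("seed: %d", config$seed),
               sprintf("cessnet version: %s",
                       as.character(utils::packageVersion("cessnet"))),
               sprintf("R version: %s.%s", R.version$major, R.version$minor),
               sprintf("alpha: %g, folds: %d, n_weeks: %d", alpha, folds,
                       n_weeks),
               "config:",
               utils::capture.output(utils::str(unclass(config))))
    writeLines(lines, p("run_log.txt"))
  })

  invisible(list(sim = sim, sessions = sessions, profiles = profiles,
                 ties = ties, centralities = centr, summary = summ,
                 labels = labels, group_table = gtab,
                 comparisons = comparisons, features = feats,
                 models = models))
}

#' Group-specific abstinence models with network terms
#'
#' For the passive and active groups: selects a reference model by
#' stepwise logistic regression over quartile-scaled baseline and
#' utilization covariates, adds the square-root scale network terms
#' (passive: in-degree week-1 and change only, as passive users have zero
#' out-degree by definition; active: all four terms), fits the model with
#' robust standard errors, extrapolates the change terms' odds ratios to
#' nine ties, and computes cross-validated and apparent AUC. Non-users
#' have no network exposure and are not modelled.
#'
#' @param participants participant roster rows (with covariates and
#'   outcome).
#' @param profiles utilization profiles.
#' @param labels engagement group labels.
#' @param features network predictor set from [sqrt_change_features()].
#' @param alpha stepwise threshold.
#' @param folds CV folds.
#' @param seed fold-assignment seed.
#' @param min_n smallest group size worth modelling.
#' @return named list (per modelled group) of lists with elements
#'   `fit` ([robust_logit()]), `terms`, `scaling`, `or9`, `auc`.
#' @export
fit_group_models <- function(participants, profiles, labels, features,
                             alpha = 0.10, folds = 10, seed = 1L,
                             min_n = 50L) {
  d <- as.data.table(participants)[as.data.table(profiles),
                                   on = "user_id", nomatch = NULL]
  d <- d[as.data.table(labels)[, .(user_id, group)], on = "user_id",
         nomatch = NULL]
  d <- d[as.data.table(features), on = "user_id", nomatch = NULL]

  scale_vars <- c("age", "ftnd", "confidence_quit", "desire_quit",
                  "tempt_social", "tempt_negaffect", "tempt_craving",
                  "extraversion", "neurosis", "openness", "piq_pos",
                  "piq_neg", "return_visits", "time_on_site",
                  "days_logged_in", "total_page_views")
  candidates <- c(scale_vars, "female", "some_college", "employed_ft",
                  "white", "hispanic", "ttfc_5min", "illness_smoking",
                  "doctor_advice", "sns_profile", "intention_ex")
  net_terms <- list(
    passive = c("sqrt_in_week1", "sqrt_in_change"),
    active = c("sqrt_in_week1", "sqrt_in_change", "sqrt_outaware_week1",
               "sqrt_outaware_change"))

  out <- list()
  for (gname in names(net_terms)) {
    g <- d[group == gname]
    if (nrow(g) < min_n || uniqueN(g$abstinent_30d) < 2) next
    sc <- scale_covariates(g, intersect(scale_vars, names(g)))
    gd <- sc$data
    ref <- stepwise_select(gd, "abstinent_30d",
                           intersect(candidates, names(gd)),
                           alpha = alpha)
    terms <- c(as.character(ref), net_terms[[gname]])
    f <- as.formula(paste("abstinent_30d ~",
                          paste(terms, collapse = " + ")))
    fit <- robust_logit(f, gd, group = gname)
    chg <- intersect(c("sqrt_in_change", "sqrt_outaware_change"), terms)
    or9 <- do.call(rbind, lapply(chg, function(tm)
      or_at_k_ties(fit, k = 9, term = tm)))
    auc <- tryCatch(cv_auc(f, gd, folds = folds, seed = seed),
                    error = function(e) NULL)
    out[[gname]] <- list(fit = fit, terms = terms, scaling = sc$scaling,
                         reference_terms = as.character(ref), or9 = or9,
                         auc = auc, stepwise_log = attr(ref, "log"))
  }
  out
}
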