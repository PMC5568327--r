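#' Quartile-based centering and scaling of covariates within groups
#'
#' Continuous baseline and website-utilization predictors are centered at
#' their group median and scaled by the distance from the median to the
#' group's third quartile, so a fitted coefficient measures the change in
#' log-odds per one-quartile increase above the group median. Quantiles
#' use linear interpolation between order statistics (R quantile type 7);
#' the scaled value of the group median is 0 and of the group Q3 is 1.
#' When the spread is degenerate (Q3 <= median) the predictor is centered
#' only and flagged unscalable. Network predictors are never passed here:
#' they stay on the square-root scale, unstandardized.
#'
#' @param data participant-level `data.frame`/`data.table`.
#' @param vars character vector of columns to scale.
#' @return a list: `data` (copy of `data` with the named columns replaced
#'   by their scaled values) and `scaling` (`data.frame` of per-variable
#'   `location`, `scale`, `scalable`).
#' @export
scale_covariates <- function(data, vars) {
  d <- copy(as.data.table(data))
  rows <- lapply(vars, function(v) {
    x <- d[[v]]
    if (!is.numeric(x))
      cn_stop("scale_covariates(): '", v, "' is not numeric")
    med <- unname(quantile(x, 0.5, type = 7, na.rm = TRUE))
    q3 <- unname(quantile(x, 0.75, type = 7, na.rm = TRUE))
    sc <- q3 - med
    scalable <- is.finite(sc) && sc > 0
    d[, (v) := if (scalable) (x - med) / sc else x - med]
    data.frame(variable = v, location = med,
               scale = if (scalable) sc else NA_real_,
               scalable = scalable)
  })
  list(data = d[], scaling = do.call(rbind, rows))
}

#' Stepwise reference-model selection on Wald p-values
#'
#' Chooses a group-specific reference model from candidate baseline and
#' website-utilization covariates by forward selection with backward
#' pruning, both judged on Wald p-values at threshold `alpha`: at each
#' step the smallest-p candidate enters if p < alpha, then any included
#' term whose p has risen to >= alpha is dropped (largest first); the
#' procedure iterates to a fixed point. Ties are broken by candidate
#' order, making the selection deterministic given the data. Candidates
#' whose trial fit fails to converge or separates are skipped and logged.
#' Network centrality terms are not candidates at this stage; they are
#' added to the selected reference model afterwards.
#'
#' @param data participant-level data containing `outcome` and candidates.
#' @param outcome name of the binary outcome column.
#' @param candidates character vector of candidate term names, in
#'   priority order.
#' @param alpha entry/stay significance threshold (default 0.10).
#' @param max_steps safety bound on selection iterations.
#' @return character vector of selected terms (possibly empty =
#'   intercept-only), with attribute `"log"` tracing each step.
#' @export
stepwise_select <- function(data, outcome, candidates, alpha = 0.10,
                            max_steps = 50L) {
  d <- as.data.table(data)
  if (!outcome %in% names(d))
    cn_stop("stepwise_select(): outcome '", outcome, "' not in data")
  candidates <- intersect(candidates, names(d))
  selected <- character()
  log <- character()

  wald_p <- function(terms, focus) {
    f <- as.formula(paste(outcome, "~",
                          if (length(terms)) paste(terms, collapse = " + ")
                          else "1"))
    sep_flag <- FALSE
    fit <- withCallingHandlers(
      glm(f, data = d, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w)))
          sep_flag <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (!fit$converged || sep_flag) return(NULL)
    ct <- summary(fit)$coefficients
    if (!(focus %in% rownames(ct)) || is.na(ct[focus, 4])) return(NULL)
    ct[focus, 4]
  }

  for (step in seq_len(max_steps)) {
    changed <- FALSE
    ## forward: best candidate not yet in the model
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      ps <- vapply(pool, function(v) {
        p <- wald_p(c(selected, v), v)
        if (is.null(p)) {
          log <<- c(log, sprintf("skip %s (non-convergence/separation)", v))
          NA_real_
        } else p
      }, numeric(1))
      if (any(!is.na(ps)) && min(ps, na.rm = TRUE) < alpha) {
        add <- pool[which.min(ps)]   # which.min ignores NA, first wins ties
        selected <- c(selected, add)
        log <- c(log, sprintf("add %s (p = %.4g)", add, min(ps, na.rm = TRUE)))
        changed <- TRUE
      }
    }
    ## backward: prune any term whose p rose to >= alpha
    repeat {
      if (!length(selected)) break
      ps <- vapply(selected, function(v) {
        p <- wald_p(selected, v)
        if (is.null(p)) NA_real_ else p
      }, numeric(1))
      worst <- which.max(ps)
      if (length(worst) && !all(is.na(ps)) &&
          max(ps, na.rm = TRUE) >= alpha) {
        drop <- selected[which.max(ps)]
        log <- c(log, sprintf("drop %s (p = %.4g)", drop,
                              max(ps, na.rm = TRUE)))
        selected <- setdiff(selected, drop)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  structure(selected, log = log)
}
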