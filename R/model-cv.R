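#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Wilcoxon rank statistic:
#' the probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half. Invariant under strictly
#' increasing transformations of the scores.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param outcome binary 0/1 outcome.
#' @return AUC in `[0, 1]`; `NA` when only one class is present.
#' @export
auc_rank <- function(scores, outcome) {
  outcome <- as.integer(outcome)
  n1 <- sum(outcome == 1L)
  n0 <- sum(outcome == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[outcome == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated and apparent AUC of a logistic model
#'
#' Assesses model predictiveness by the AUC, with ten-fold
#' cross-validation correcting the optimism of scoring the data the model
#' was trained on. Folds are assigned stratified by outcome; the model is
#' refit on nine folds, the held-out fold is scored, held-out scores are
#' pooled over folds and the AUC is computed once on the pooled scores.
#' If an assignment leaves a training fold with a single outcome class it
#' is re-randomized (bounded retries), then an error is raised.
#'
#' @param formula model formula.
#' @param data one row per participant.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold assignment, stored in the
#'   result.
#' @param max_retries re-randomization bound.
#' @return list with `cv_auc`, `apparent_auc`, `folds`, `seed`.
#' @export
cv_auc <- function(formula, data, folds = 10, seed = 1L,
                   max_retries = 20L) {
  d <- as.data.table(data)
  mf <- stats::model.frame(formula, data = d)
  y <- as.integer(stats::model.response(mf))
  n <- length(y)
  if (folds < 2 || n < 2 * folds)
    cn_stop("cv_auc(): need folds >= 2 and n >= 2 * folds",
            class = "cessnet_contract_error")
  d <- d[as.integer(rownames(mf))]

  set.seed(as.integer(seed))
  assign_folds <- function() {
    f <- integer(n)
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  }
  ok <- FALSE
  for (try in seq_len(max_retries)) {
    fold <- assign_folds()
    train_ok <- vapply(seq_len(folds), function(k)
      length(unique(y[fold != k])) == 2L, logical(1))
    if (all(train_ok) && all(tabulate(fold, folds) > 0)) { ok <- TRUE; break }
  }
  if (!ok)
    cn_stop("cv_auc(): could not build folds with both outcome classes in ",
            "every training set", class = "cessnet_cv_error")

  scores <- numeric(n)
  for (k in seq_len(folds)) {
    fit <- suppressWarnings(glm(formula, data = d[fold != k],
                                family = binomial()))
    scores[fold == k] <- suppressWarnings(
      predict(fit, newdata = d[fold == k], type = "response"))
  }
  full <- suppressWarnings(glm(formula, data = d, family = binomial()))
  list(cv_auc = auc_rank(scores, y),
       apparent_auc = auc_rank(fitted(full), y),
       folds = folds, seed = as.integer(seed))
}
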