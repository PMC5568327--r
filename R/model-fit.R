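#' Logistic abstinence model with robust (sandwich) standard errors
#'
#' Fits a logistic regression by maximum likelihood and reports sandwich
#' (robust) standard errors. With one record per independent subject this
#' reproduces a GEE fit with working-independence correlation exactly:
#' the point estimates are the ordinary logistic ML estimates and the
#' robust covariance is the heteroskedasticity-consistent (HC0) sandwich.
#' Odds ratios use 95% Wald intervals, `exp(coef +- 1.96 * robust SE)`.
#'
#' Group-specific model composition follows the study design: the passive
#' group's design matrix carries in-degree terms only (passive users have
#' zero out-degree by definition), while the active group's carries all
#' four square-root scale network terms.
#'
#' @param formula model formula (binary outcome on the left).
#' @param data participant-level data, one row per subject.
#' @param group optional label (e.g. `"passive"`, `"active"`) recorded in
#'   the fit.
#' @param conf_level confidence level for Wald intervals (default 0.95).
#' @return object of class `robust_logit`: the underlying `glm` fit, the
#'   robust covariance, and a coefficient table with `estimate`,
#'   `robust_se`, `z`, `p_value`, `or`, `lcl`, `ucl`.
#' @seealso [or_at_k_ties()], [cv_auc()]
#' @export
robust_logit <- function(formula, data, group = NULL, conf_level = 0.95) {
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep_flag <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    cn_stop("robust_logit(): IRLS did not converge after ", fit$iter,
            " iterations", class = "cessnet_fit_error")
  V <- sandwich::vcovHC(fit, type = "HC0")
  est <- coef(fit)
  ## aliased (e.g. constant) columns are dropped from the sandwich matrix;
  ## keep them in the table as NA rows
  se <- setNames(rep(NA_real_, length(est)), names(est))
  se[colnames(V)] <- sqrt(diag(V))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  z <- est / se
  tab <- data.frame(term = names(est), estimate = unname(est),
                    robust_se = unname(se), z = unname(z),
                    p_value = unname(2 * pnorm(-abs(z))),
                    or = unname(exp(est)),
                    lcl = unname(exp(est - zq * se)),
                    ucl = unname(exp(est + zq * se)),
                    stringsAsFactors = FALSE)
  structure(list(glm = fit, vcov = V, table = tab, group = group,
                 separation = sep_flag, conf_level = conf_level,
                 call = match.call()),
            class = "robust_logit")
}

#' @export
print.robust_logit <- function(x, digits = 3, ...) {
  cat("Logistic regression with robust (sandwich) standard errors\n")
  if (!is.null(x$group)) cat("Group:", x$group, "\n")
  cat("n =", stats::nobs(x$glm), "\n")
  if (x$separation)
    cat("warning: fitted probabilities of 0/1 occurred (possible separation)\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.robust_logit <- function(object, ...) {
  structure(list(table = object$table, group = object$group,
                 n = stats::nobs(object$glm),
                 aic = stats::AIC(object$glm),
                 separation = object$separation),
            class = "summary.robust_logit")
}

#' @export
print.summary.robust_logit <- function(x, digits = 3, ...) {
  cat("Robust logistic model", if (!is.null(x$group))
    paste0("(", x$group, " group)"), "- n =", x$n, "\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat("AIC (ML fit):", round(x$aic, 1), "\n")
  invisible(x)
}

#' @export
coef.robust_logit <- function(object, ...) coef(object$glm)

#' @export
vcov.robust_logit <- function(object, ...) object$vcov

#' @export
nobs.robust_logit <- function(object, ...) stats::nobs(object$glm)

#' @export
confint.robust_logit <- function(object, parm, level = 0.95, ...) {
  est <- coef(object$glm)
  se <- sqrt(diag(object$vcov))
  zq <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - zq * se, est + zq * se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2,
                                       1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.robust_logit <- function(object, newdata,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) predict(object$glm, type = type)
  else predict(object$glm, newdata = newdata, type = type)
}

#' @export
residuals.robust_logit <- function(object, ...) residuals(object$glm, ...)

#' @export
fitted.robust_logit <- function(object, ...) fitted(object$glm)

#' @export
simulate.robust_logit <- function(object, nsim = 1, seed = NULL, ...)
  simulate(object$glm, nsim = nsim, seed = seed, ...)

#' Forest plot of odds ratios
#'
#' @param x a `robust_logit` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.robust_logit <- function(x, ...) {
  tab <- x$table[x$table$term != "(Intercept)", ]
  if (!nrow(tab)) return(invisible(x))
  n <- nrow(tab)
  xlim <- range(c(tab$lcl, tab$ucl, 1))
  graphics::plot(tab$or, seq_len(n), log = "x", xlim = xlim,
                 ylim = c(0.5, n + 0.5), pch = 16, yaxt = "n",
                 xlab = "Odds ratio (95% CI, robust)", ylab = "", ...)
  graphics::segments(tab$lcl, seq_len(n), tab$ucl, seq_len(n))
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n), labels = tab$term, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}

#' Odds ratio of accumulating k ties
#'
#' The network predictors enter the model on the square-root scale, so a
#' per-unit odds ratio translates to the odds ratio of accumulating `k`
#' ties (from a zero start) by raising it to the power `sqrt(k)`:
#' `OR(k) = exp(coef * sqrt(k)) = OR^sqrt(k)`. Confidence limits are
#' transformed the same way (endpoint transformation). For `k = 9`,
#' `sqrt(k) = 3`, so a per-unit OR of 1.14 becomes `1.14^3 = 1.48`.
#'
#' @param object a per-unit odds ratio (single number) or a
#'   `robust_logit` fit.
#' @param k number of ties; must be >= 0.
#' @param ... method arguments.
#' @return `data.frame` with `k`, `or` and, when limits are available,
#'   `lcl`, `ucl`.
#' @export
or_at_k_ties <- function(object, k, ...) UseMethod("or_at_k_ties")

#' @rdname or_at_k_ties
#' @param lcl,ucl optional per-unit confidence limits.
#' @export
or_at_k_ties.numeric <- function(object, k, lcl = NULL, ucl = NULL, ...) {
  if (any(k < 0)) cn_stop("or_at_k_ties(): k must be >= 0",
                          class = "cessnet_domain_error")
  if (any(object <= 0)) cn_stop("or_at_k_ties(): odds ratio must be > 0",
                                class = "cessnet_domain_error")
  out <- data.frame(k = k, or = object^sqrt(k))
  if (!is.null(lcl)) out$lcl <- lcl^sqrt(k)
  if (!is.null(ucl)) out$ucl <- ucl^sqrt(k)
  out
}

#' @rdname or_at_k_ties
#' @param term name of a square-root scale network term in the fit.
#' @export
or_at_k_ties.robust_logit <- function(object, k, term, ...) {
  tab <- object$table
  if (!term %in% tab$term)
    cn_stop("or_at_k_ties(): term '", term, "' not in model")
  row <- tab[tab$term == term, ]
  out <- or_at_k_ties(row$or, k, lcl = row$lcl, ucl = row$ucl)
  out$term <- term
  out
}
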