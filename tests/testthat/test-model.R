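mk_series <- function(in1, in12, oa1 = 0, oa12 = 0) {
  data.table(user_id = "P1", week = 1:12,
             in_degree = as.integer(round(seq(in1, in12, length.out = 12))),
             out_degree = as.integer(round(seq(oa1, oa12,
                                               length.out = 12))),
             out_degree_aware = as.integer(round(seq(oa1, oa12,
                                                     length.out = 12))))
}

test_that("network predictors are week-1 value and change on the sqrt scale", {
  f <- sqrt_change_features(mk_series(4, 4))
  expect_equal(f$sqrt_in_week1, 2)
  expect_equal(f$sqrt_in_change, 0)

  # nine ties accumulated from zero correspond to 3 square-root units
  f2 <- sqrt_change_features(mk_series(0, 9))
  expect_equal(f2$sqrt_in_change, 3)

  f3 <- sqrt_change_features(mk_series(0, 0))
  expect_true(all(unlist(f3[, -1]) == 0))
})

test_that("quartile scaling centers at the median and scales by Q3 - median", {
  set.seed(3)
  # group with median 45 and Q3 53 (matching a typical age distribution)
  x <- c(rep(45, 11), rep(32, 5), rep(53, 6), rep(60, 2))
  d <- data.table(user_id = seq_along(x), age = x)
  sc <- scale_covariates(d, "age")
  med <- quantile(x, .5, type = 7); q3 <- quantile(x, .75, type = 7)
  expect_equal(sc$scaling$location, unname(med))
  expect_equal(sc$scaling$scale, unname(q3 - med))
  expect_equal(sc$data$age[1], 0)                      # the median maps to 0
  expect_equal(sc$data$age[x == 53][1],
               unname((53 - med) / (q3 - med)))
  # worked example: median 45, Q3 53 => age 29 scales to (29-45)/8 = -2
  d2 <- data.table(user_id = 1:2, age = c(53, 29))
  sc2 <- list(location = 45, scale = 8)
  expect_equal((d2$age - sc2$location) / sc2$scale, c(1, -2))
})

test_that("degenerate spread falls back to centering with a flag", {
  d <- data.table(user_id = 1:10, v = c(rep(1, 9), 100))
  sc <- scale_covariates(d, "v")
  expect_false(sc$scaling$scalable)
  expect_equal(sc$data$v, d$v - 1)
})

test_that("stepwise selection finds planted predictors and respects alpha", {
  set.seed(21)
  hits <- vapply(1:10, function(i) {
    n <- 1500
    d <- data.table(user_id = 1:n, strong = rnorm(n))
    for (j in 1:8) set(d, j = paste0("noise", j), value = rnorm(n))
    d[, y := rbinom(n, 1, plogis(-2 + 0.8 * strong))]
    sel <- stepwise_select(d, "y", c(paste0("noise", 1:8), "strong"),
                           alpha = 0.10)
    "strong" %in% sel
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # empty candidate set -> intercept-only model
  d <- data.table(user_id = 1:50, y = rbinom(50, 1, 0.3))
  expect_length(stepwise_select(d, "y", character(0)), 0)
})

test_that("pure-noise candidates enter at roughly the alpha rate", {
  set.seed(33)
  n_sel <- vapply(1:40, function(i) {
    n <- 400
    d <- data.table(user_id = 1:n, y = rbinom(n, 1, 0.3))
    for (j in 1:5) set(d, j = paste0("noise", j), value = rnorm(n))
    length(stepwise_select(d, "y", paste0("noise", 1:5), alpha = 0.10))
  }, numeric(1))
  # P(at least one of 5 null candidates < .10) ~ 1-(0.9)^5 ~ .41; the
  # backward step prunes some again. Loose calibration band.
  expect_lt(mean(n_sel > 0), 0.7)
  expect_gt(mean(n_sel > 0), 0.15)
})

test_that("robust covariance equals the hand-computed sandwich", {
  set.seed(4)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  d$y <- rbinom(n, 1, plogis(-1 + 0.5 * d$x1 - 0.3 * d$x2))
  fit <- robust_logit(y ~ x1 + x2, d)
  X <- cbind(1, d$x1, d$x2)
  V_oracle <- oracle_sandwich(X, d$y, coef(fit))
  expect_equal(unname(vcov(fit)), unname(V_oracle), tolerance = 1e-6)
  # for a correctly specified model the robust and model-based SEs agree
  # to within sampling noise
  se_model <- sqrt(diag(vcov(fit$glm)))
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(se_model),
               tolerance = 0.15)
})

test_that("OR table is internally consistent and CIs contain the OR", {
  set.seed(9)
  n <- 500
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-1.5 + 0.4 * d$x))
  fit <- robust_logit(y ~ x, d)
  tab <- fit$table
  expect_equal(tab$or, exp(tab$estimate))
  expect_true(all(tab$lcl < tab$or & tab$or < tab$ucl))
  expect_true(all(tab$or > 0))
  ci <- confint(fit)
  expect_equal(unname(exp(ci[, 1])), tab$lcl)
})

test_that("scaling a predictor rescales its coefficient and nothing else", {
  set.seed(12)
  n <- 400
  d <- data.frame(x = rnorm(n, 50, 10))
  d$y <- rbinom(n, 1, plogis(-1 + 0.05 * (d$x - 50)))
  f1 <- robust_logit(y ~ x, d)
  d2 <- transform(d, x = (x - 50) / 8)
  f2 <- robust_logit(y ~ x, d2)
  expect_equal(coef(f2)[["x"]], coef(f1)[["x"]] * 8, tolerance = 1e-6)
  expect_equal(fitted(f1), fitted(f2), tolerance = 1e-8)
})

test_that("null predictors give calibrated robust CIs", {
  set.seed(6)
  cover <- vapply(1:60, function(i) {
    n <- 400
    d <- data.frame(x = rnorm(n))
    d$y <- rbinom(n, 1, 0.25)
    tab <- robust_logit(y ~ x, d)$table
    tab$lcl[2] < 1 && 1 < tab$ucl[2]
  }, logical(1))
  expect_gt(mean(cover), 0.85)
})

test_that("odds ratios extrapolate to k ties by the sqrt-power rule", {
  # per-unit OR 1.14 at nine ties: 1.14^3 = 1.48
  r <- or_at_k_ties(1.14, k = 9)
  expect_equal(round(r$or, 2), 1.48)
  r2 <- or_at_k_ties(1.29, k = 9, lcl = 1.02, ucl = 1.63)
  expect_equal(round(r2$or, 2), 2.15)
  expect_equal(round(r2$ucl, 2), 4.33)
  # k = 0 gives OR exactly 1 for any fit
  expect_equal(or_at_k_ties(2.5, k = 0)$or, 1)
  expect_error(or_at_k_ties(1.2, k = -1), class = "cessnet_domain_error")
  # endpoint transformation commutes with exp: OR(k) = exp(coef*sqrt(k))
  expect_equal(or_at_k_ties(exp(0.2), 9)$or, exp(0.2 * 3))

  # method on a fitted model picks the term's row
  set.seed(2)
  d <- data.frame(x = abs(rnorm(300)))
  d$y <- rbinom(300, 1, plogis(-1 + 0.3 * d$x))
  fit <- robust_logit(y ~ x, d)
  r3 <- or_at_k_ties(fit, k = 9, term = "x")
  expect_equal(r3$or, fit$table$or[2]^3)
  expect_equal(r3$lcl, fit$table$lcl[2]^3)
})

test_that("AUC behaves as the rank statistic it is", {
  y <- c(rep(0, 50), rep(1, 50))
  expect_equal(auc_rank(y, y), 1)                 # scores = outcome
  expect_equal(auc_rank(-y, y), 0)
  set.seed(8)
  s <- rnorm(100)
  expect_equal(auc_rank(s, y), auc_rank(exp(s), y))   # monotone invariance
  expect_equal(auc_rank(s, y), auc_rank(rank(s), y))
  # cross-check against an independent implementation
  skip_if_not_installed("pROC")
  roc <- pROC::roc(y, s, levels = c(0, 1), direction = "<", quiet = TRUE)
  expect_equal(auc_rank(s, y), as.numeric(pROC::auc(roc)))
})

test_that("cross-validated AUC is honest about null models", {
  set.seed(14)
  n <- 1000
  d <- data.frame(x = rnorm(n), y = rbinom(n, 1, 0.3))
  res <- cv_auc(y ~ x, d, folds = 10, seed = 3)
  expect_lt(abs(res$cv_auc - 0.5), 0.06)
  expect_gte(res$apparent_auc, res$cv_auc - 0.02)
  # strong signal: both AUCs high, apparent >= cv on average
  d2 <- data.frame(x = rnorm(n))
  d2$y <- rbinom(n, 1, plogis(-1 + 2 * d2$x))
  res2 <- cv_auc(y ~ x, d2, folds = 10, seed = 3)
  expect_gt(res2$cv_auc, 0.7)
  # determinism given the seed
  expect_equal(cv_auc(y ~ x, d2, folds = 10, seed = 3)$cv_auc, res2$cv_auc)
})
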