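test_that("remission labeling uses the week-8 <= 7 boundary", {
  lab <- label_remission(c(7, 8, 0, 20), c(20, 20, 15, 16))
  expect_equal(lab$remitter, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(lab$eligible, c(TRUE, TRUE, FALSE, TRUE))
  expect_error(label_remission(c(5, NA), c(20, 20)), "missing week-8")
})

test_that("equivalent doses follow the conversion factors", {
  expect_equal(equivalent_dose("escitalopram", 15), 112.5)
  expect_equal(equivalent_dose("sertraline", 62.5), 93.75)
  expect_equal(equivalent_dose("venlafaxine", 100), 100)
  expect_equal(equivalent_dose(c("sertraline", "escitalopram"), c(10, 10)),
               c(15, 75))
  expect_error(equivalent_dose("fluoxetine", 20), "unknown drug")
  expect_error(equivalent_dose("sertraline", -5), "positive")
})

test_that("sample flow reproduces the analyzed counts", {
  pats <- sample_flow(80, c(movement = 4, incomplete = 1))
  expect_equal(pats$analyzed, 75)
  ctrl <- sample_flow(34, c(movement = 2, incomplete = 1))
  expect_equal(ctrl$analyzed, 31)
  expect_error(sample_flow(3, c(a = 5)), "more exclusions")
})

test_that("likelihood-ratio statistic matches a brute-force deviance oracle", {
  # 2x2 toy: remission by binarized connectivity, 15/20 vs 5/20
  y <- c(rep(1, 15), rep(0, 5), rep(1, 5), rep(0, 15))
  fc <- rep(c(1, 0), each = 20)
  fit <- fit_logistic_with_lr(y, covariates = NULL, fc = fc)
  # closed-form binomial log-likelihoods on the contingency table
  ll_sat <- function(k, n) {
    p <- k / n
    k * log(p) + (n - k) * log(1 - p)
  }
  ll_full <- ll_sat(15, 20) + ll_sat(5, 20)
  ll_red <- ll_sat(20, 40)
  expect_equal(fit$lr_chisq, 2 * (ll_full - ll_red), tolerance = 1e-6)
  expect_equal(fit$lr_df, 1L)
  # LR equals twice the log-likelihood difference of the two glm fits
  expect_equal(fit$lr_chisq,
               2 * (as.numeric(logLik(fit$fit_full)) -
                      as.numeric(logLik(fit$fit_reduced))),
               tolerance = 1e-6)
})

test_that("degenerate logistic inputs are flagged, not silently accepted", {
  set.seed(1)
  y <- rep(c(1, 0), each = 10)
  fit0 <- fit_logistic_with_lr(y, covariates = NULL, fc = rep(0, 20))
  expect_equal(fit0$lr_chisq, 0, tolerance = 1e-8)
  expect_equal(fit0$lr_df, 1L)

  sep <- fit_logistic_with_lr(y, covariates = NULL,
                              fc = c(rnorm(10, 5), rnorm(10, -5)))
  expect_true(sep$separation)
  expect_error(fit_logistic_with_lr(rep(1, 20), NULL, rnorm(20)),
               "single class")
  expect_error(fit_logistic_with_lr(c(0, 1), NULL, c(1, 2)), "n >= 10")
})

test_that("ROC analysis matches the pairwise-concordance oracle", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(n) + y * runif(1, 0, 2)
    roc <- roc_analysis(s, y)
    pos <- s[y == 1]; neg <- s[y == 0]
    conc <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(roc$auc, conc, tolerance = 1e-10)
    # label inversion maps AUC to 1 - AUC
    expect_equal(roc_analysis(s, 1 - y)$auc, 1 - roc$auc, tolerance = 1e-10)
    # invariance under strictly monotone transforms of the scores
    expect_equal(roc_analysis(exp(2 * s), y)$auc, roc$auc, tolerance = 1e-12)
  }
})

test_that("ROC handles perfect and degenerate scores", {
  y <- rep(c(0, 1), each = 10)
  s <- c(rnorm(10, -3), rnorm(10, 3))
  roc <- roc_analysis(s, y)
  expect_equal(roc$auc, 1)
  expect_equal(roc$operating_point$accuracy, 1)
  expect_equal(roc$operating_point$sensitivity, 1)
  expect_equal(roc$operating_point$specificity, 1)
  # curve is monotone in both coordinates
  o <- order(roc$curve$fpr, roc$curve$sensitivity)
  expect_true(all(diff(roc$curve$sensitivity[o]) >= 0))

  dg <- roc_analysis(rep(1, 20), y)
  expect_true(dg$degenerate)
  expect_equal(dg$auc, 0.5)
  expect_error(roc_analysis(rnorm(5), rep(1, 5)), "both classes")
})

test_that("LOOCV produces honest held-out scores without leakage", {
  set.seed(44)
  n <- 30
  y <- rbinom(n, 1, 0.5)
  fc <- rnorm(n) + y
  covs <- data.frame(age = rnorm(n, 30, 8))
  cv <- loocv_predict(y, covs, fc)
  expect_length(cv$scores, n)
  expect_true(all(!is.na(cv$scores)))

  # no leakage: fold i's model and standardization parameters are those of
  # the n-1 training subjects, reproducible from scratch
  for (i in c(4, 17)) {
    mu <- mean(fc[-i]); s <- sd(fc[-i])
    dtr <- data.frame(y = y[-i], age = covs$age[-i],
                      fc_z = (fc[-i] - mu) / s)
    fit <- glm(y ~ ., data = dtr, family = binomial())
    manual <- predict(fit, newdata = data.frame(age = covs$age[i],
                                                fc_z = (fc[i] - mu) / s),
                      type = "response")
    expect_equal(unname(manual), cv$scores[i], tolerance = 1e-8)
  }
  # and the held-out subject's own value never enters the training fit:
  # perturbing fc[i] leaves every *other* fold's training data unchanged
  # only through its own appearances there, so a perturbation confined to
  # prediction time must move score i alone when refitted manually
  mu <- mean(fc[-4]); s <- sd(fc[-4])
  dtr <- data.frame(y = y[-4], age = covs$age[-4], fc_z = (fc[-4] - mu) / s)
  fit <- glm(y ~ ., data = dtr, family = binomial())
  p_shift <- predict(fit, newdata = data.frame(age = covs$age[4],
                                               fc_z = (fc[4] + 50 - mu) / s),
                     type = "response")
  cv2 <- loocv_predict(y, covs, replace(fc, 4, fc[4] + 50))
  expect_equal(unname(p_shift), cv2$scores[4], tolerance = 1e-8)
})

test_that("cross-validated accuracy does not exceed apparent accuracy on average", {
  set.seed(70)
  diffs <- replicate(30, {
    n <- 40
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) return(NA_real_)
    fc <- rnorm(n)
    fit <- fit_logistic_with_lr(y, NULL, fc)
    app <- roc_analysis(predict(fit$fit_full, type = "response"), y,
                        "fixed_0.5")$operating_point$accuracy
    cv <- loocv_predict(y, NULL, fc)$accuracy_fixed
    app - cv
  })
  expect_gt(mean(diffs, na.rm = TRUE), 0)
})

test_that("specificity checks behave under null, planted, and redundant cases", {
  set.seed(88)
  n <- 75
  fc <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.1 * fc))        # odds ratio ~ 3 per SD
  chars <- data.frame(anxiety = rnorm(n, 7, 2),
                      bmi = rnorm(n, 26, 5),
                      constant = rep(1, n))
  tab <- specificity_checks(fc, y, chars)
  expect_equal(nrow(tab), 3)
  expect_true(tab$skipped[tab$characteristic == "constant"])
  # characteristics independent of connectivity: slopes near zero
  expect_true(all(abs(tab$slope[!tab$skipped]) < 0.5))
  # planted connectivity effect adds predictive power beyond characteristics
  expect_true(all(tab$lr_p[!tab$skipped] < 0.05))

  # characteristic identical to the predictor: no added value
  tab2 <- specificity_checks(fc, y, data.frame(same = fc))
  expect_gt(tab2$lr_p[1], 0.05)
  expect_lt(tab2$lr_chisq[1], 1)
})
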