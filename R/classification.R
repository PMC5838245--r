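#' Remission labeling from symptom scores
#'
#' A patient is a remitter when the week-8 17-item Hamilton depression
#' score is at most 7; trial eligibility additionally requires a baseline
#' score of at least 16.
#'
#' @param hrsd17_week8 week-8 score(s)
#' @param hrsd17_baseline baseline score(s)
#' @return data.frame with `remitter` (logical) and `eligible` (logical)
#' @export
label_remission <- function(hrsd17_week8, hrsd17_baseline) {
  if (any(is.na(hrsd17_week8)))
    stop("missing week-8 score: outcome cannot be labeled")
  data.frame(remitter = hrsd17_week8 <= 7,
             eligible = !is.na(hrsd17_baseline) & hrsd17_baseline >= 16)
}

#' Venlafaxine-equivalent antidepressant dose
#'
#' Conversion factors: escitalopram x 7.5, sertraline x 1.5,
#' venlafaxine x 1.
#'
#' @param drug character vector of drug arms
#' @param dose_mg prescribed dose in mg (> 0)
#' @return equivalent dose in mg
#' @export
equivalent_dose <- function(drug, dose_mg) {
  factors <- c(escitalopram = 7.5, sertraline = 1.5, venlafaxine = 1.0)
  unknown <- setdiff(unique(drug), names(factors))
  if (length(unknown)) stop("unknown drug arm(s): ",
                            paste(unknown, collapse = ", "))
  if (any(dose_mg <= 0)) stop("doses must be positive")
  unname(factors[drug] * dose_mg)
}

#' Sample-flow bookkeeping
#'
#' Computes analyzed sample sizes from enrollment counts and exclusion
#' tallies (e.g. excessive movement, incomplete scans).
#'
#' @param enrolled number scanned
#' @param exclusions named integer vector of exclusion counts
#' @return list with `enrolled`, `excluded`, `analyzed`
#' @export
sample_flow <- function(enrolled, exclusions = integer(0)) {
  excl <- sum(exclusions)
  if (excl > enrolled) stop("more exclusions than enrolled")
  list(enrolled = enrolled, excluded = excl, analyzed = enrolled - excl)
}

# fit logistic regression, trapping the separation warning
fit_logit <- function(formula, data) {
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  attr(fit, "separation") <- sep ||
    any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  fit
}

#' Hierarchical logistic regression with likelihood-ratio and Wald tests
#'
#' Fits a covariate-only logistic model of remission and a second model
#' adding the standardized connectivity predictor (mean centered, scaled by
#' its SD), and reports the deviance-difference likelihood-ratio statistic
#' and per-coefficient Wald z statistics. Complete separation is detected
#' and flagged rather than silently diverging.
#'
#' @param outcome logical/0-1 remission indicator
#' @param covariates data.frame of covariate columns (may be NULL/empty)
#' @param fc optional connectivity predictor (standardized internally)
#' @return list with `fit_reduced`, `fit_full`, `lr_chisq`, `lr_df`,
#'   `lr_p`, `wald` (coefficient table), `separation`
#' @export
fit_logistic_with_lr <- function(outcome, covariates = NULL, fc = NULL) {
  y <- as.numeric(outcome)
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (length(y) < 10) stop("need n >= 10")
  dat <- data.frame(y = y)
  if (!is.null(covariates) && NCOL(covariates) > 0)
    dat <- cbind(dat, as.data.frame(covariates))
  fit_red <- fit_logit(y ~ ., dat)
  if (is.null(fc)) {
    sm <- summary(fit_red)$coefficients
    return(list(fit_reduced = fit_red, fit_full = fit_red,
                lr_chisq = 0, lr_df = 0L, lr_p = NA_real_,
                wald = sm, separation = attr(fit_red, "separation")))
  }
  if (sd(fc) > 0) dat$fc_z <- as.numeric(scale(fc)) else dat$fc_z <- fc * 0
  fit_full <- fit_logit(y ~ ., dat)
  lr <- max(0, fit_red$deviance - fit_full$deviance)
  lr_df <- 1L                       # df = number of added parameters
  sm <- summary(fit_full)$coefficients
  wald <- cbind(sm, z = sm[, "Estimate"] / sm[, "Std. Error"])
  list(fit_reduced = fit_red, fit_full = fit_full,
       lr_chisq = lr, lr_df = lr_df,
       lr_p = stats::pchisq(lr, max(lr_df, 1), lower.tail = FALSE),
       wald = wald,
       separation = attr(fit_full, "separation") ||
         attr(fit_red, "separation"))
}

#' Receiver operating characteristic analysis
#'
#' Full threshold sweep over the scores; AUC by the trapezoid rule (equal
#' to pairwise concordance); operating point chosen by the Youden index
#' (default) or a fixed 0.5 cut on probability-scale scores.
#'
#' @param scores numeric classifier scores (higher = more likely positive)
#' @param outcomes logical/0-1 class labels
#' @param threshold_rule `"youden"` or `"fixed_0.5"`
#' @return object of class `roc_curve`: list with `curve` (data.frame of
#'   threshold, sensitivity, specificity, fpr), `auc`, `operating_point`
#'   (threshold, accuracy, sensitivity, specificity), `degenerate`
#' @export
roc_analysis <- function(scores, outcomes,
                         threshold_rule = c("youden", "fixed_0.5")) {
  threshold_rule <- match.arg(threshold_rule)
  y <- as.logical(outcomes)
  if (!any(y) || all(y)) stop("both classes must be present")
  degenerate <- sd(scores) == 0
  thr <- c(-Inf, sort(unique(scores)), Inf)
  npos <- sum(y); nneg <- sum(!y)
  sens <- vapply(thr, function(t) sum(scores >= t & y) / npos, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !y) / nneg, numeric(1))
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(sens)]) / 2)
  if (degenerate) auc <- 0.5
  op_thr <- if (threshold_rule == "youden") {
    thr[which.max(sens + spec - 1)]
  } else 0.5
  pred <- scores >= op_thr
  list2 <- list(threshold = op_thr,
                accuracy = mean(pred == y),
                sensitivity = sum(pred & y) / npos,
                specificity = sum(!pred & !y) / nneg)
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec, fpr = fpr),
                 auc = auc, operating_point = list2,
                 degenerate = degenerate),
            class = "roc_curve")
}

#' Leave-one-out cross-validated classification
#'
#' For each subject, the hierarchical logistic model (including the
#' connectivity centering/scaling parameters) is refitted on the remaining
#' n - 1 subjects and applied to the held-out subject; the ROC analysis is
#' then run on the n held-out scores. Accuracy is reported at the fixed
#' 0.5 probability cut (no threshold optimization on test scores).
#'
#' Pooled leave-one-out probability scores carry a well-known pessimistic
#' AUC bias: the fitted intercept tracks the training fold's class
#' balance, which is anti-correlated with the held-out label, so under the
#' null the pooled-score AUC drops far below 0.5. The ROC here therefore
#' uses prior-corrected scores - the held-out linear predictor minus the
#' training fold's base-rate logit - which removes that fold-dependent
#' shift; raw held-out probabilities are kept for the accuracy figures.
#'
#' @param outcome logical/0-1 remission labels
#' @param covariates data.frame of covariates (or NULL)
#' @param fc connectivity predictor (or NULL for a covariate-only model)
#' @return list with `scores` (held-out probabilities),
#'   `scores_corrected` (prior-corrected link-scale scores), `roc`
#'   (Youden-rule curve on the corrected scores), `accuracy_fixed`,
#'   `sensitivity_fixed`, `specificity_fixed`, `n_flagged` (folds with a
#'   single-class training set)
#' @export
loocv_predict <- function(outcome, covariates = NULL, fc = NULL) {
  y <- as.numeric(outcome)
  n <- length(y)
  if (n < 10) stop("need n >= 10")
  has_cov <- !is.null(covariates) && NCOL(covariates) > 0
  covariates <- if (has_cov) as.data.frame(covariates) else NULL
  scores <- rep(NA_real_, n)
  scores_adj <- rep(NA_real_, n)
  flagged <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) { flagged <- flagged + 1L; next }
    dtr <- data.frame(y = ytr)
    dte <- data.frame(y = y[i])
    if (has_cov) {
      dtr <- cbind(dtr, covariates[-i, , drop = FALSE])
      dte <- cbind(dte, covariates[i, , drop = FALSE])
    }
    if (!is.null(fc)) {
      mu <- mean(fc[-i]); s <- sd(fc[-i])
      if (s == 0) s <- 1
      dtr$fc_z <- (fc[-i] - mu) / s     # training-fold parameters only
      dte$fc_z <- (fc[i] - mu) / s
    }
    fit <- fit_logit(y ~ ., dtr)
    eta <- predict(fit, newdata = dte, type = "link")
    scores[i] <- stats::plogis(eta)
    scores_adj[i] <- eta - stats::qlogis(mean(ytr))
  }
  ok <- !is.na(scores)
  roc <- roc_analysis(scores_adj[ok], y[ok])
  pred <- scores[ok] >= 0.5
  yy <- as.logical(y[ok])
  list(scores = scores, scores_corrected = scores_adj, roc = roc,
       accuracy_fixed = mean(pred == yy),
       sensitivity_fixed = sum(pred & yy) / sum(yy),
       specificity_fixed = sum(!pred & !yy) / sum(!yy),
       n_flagged = flagged)
}

#' Specificity (added-value) analyses of a connectivity predictor
#'
#' For each baseline characteristic: (1) the linear regression of
#' connectivity on the characteristic (slope and p), asking whether the
#' biomarker merely proxies the characteristic; (2) the likelihood-ratio
#' test of adding connectivity to a logistic remission model already
#' containing the characteristic, asking whether it adds predictive power.
#'
#' @param fc connectivity values
#' @param outcome remission labels
#' @param characteristics data.frame of baseline characteristic columns
#' @return data.frame with one row per characteristic: `slope`, `slope_p`,
#'   `lr_chisq`, `lr_p`, `skipped`
#' @export
specificity_checks <- function(fc, outcome, characteristics) {
  characteristics <- as.data.frame(characteristics)
  rows <- lapply(names(characteristics), function(nm) {
    x <- characteristics[[nm]]
    keep <- stats::complete.cases(x, fc, outcome)
    if (sd(x[keep]) == 0)
      return(data.frame(characteristic = nm, slope = NA, slope_p = NA,
                        lr_chisq = NA, lr_p = NA, skipped = TRUE))
    fitl <- lm(fc[keep] ~ x[keep])
    sm <- suppressWarnings(summary(fitl))$coefficients
    hl <- fit_logistic_with_lr(outcome[keep],
                               data.frame(x = x[keep]), fc[keep])
    data.frame(characteristic = nm, slope = sm[2, "Estimate"],
               slope_p = sm[2, "Pr(>|t|)"],
               lr_chisq = hl$lr_chisq, lr_p = hl$lr_p, skipped = FALSE)
  })
  do.call(rbind, rows)
}
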