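# tor_model(): the central fitting function. Fits the 11-covariate
# logistic model on a (development) cohort, derives the conjunction TOR
# rule by adjusted-OR thresholding, and exposes the usual modelling
# methods (print, summary, coef, predict, plot, residuals).

#' Derive a termination-of-resuscitation rule from a cohort
#'
#' Fits univariate and 11-covariate multivariable logistic regressions of
#' the chosen one-month outcome on the risk-coded prehospital covariates
#' ([odds_ratio_table()]), then selects as rule criteria every binary
#' covariate with adjusted odds ratio strictly above `threshold`
#' ([select_criteria()]). The resulting conjunction rule predicts the
#' outcome (termination indicated) when all criteria hold.
#'
#' @param data A registry data frame (the development cohort).
#' @param outcome Outcome the model is fitted on: `"death"` (one-month
#'   death; the rule-derivation outcome) or `"unfavorable"` (CPC 3-5).
#' @param threshold Adjusted-OR selection cutoff, default 2.0.
#' @param conf Confidence level for all intervals.
#' @param tol,max_iter IRLS controls, see [fit_logistic()].
#' @param name Name given to the derived rule.
#' @return An object of class `tor_model` with components `or_table`
#'   (class `or_table`), `rule` (class `tor_rule`), `fit` (the joint
#'   `tor_logit` fit), `outcome`, `threshold`, `n`, `call`.
#' @examples
#' cfg <- generator_config(n = 3000, seed = 7)
#' cohort <- generate_records(cfg)
#' m <- tor_model(cohort)
#' m$rule$criteria
#' table(predict(m, cohort))
#' @export
tor_model <- function(data, outcome = c("death", "unfavorable"),
                      threshold = 2.0, conf = 0.95, tol = 1e-8,
                      max_iter = 50L, name = "derived TOR") {
  outcome <- match.arg(outcome)
  ot <- odds_ratio_table(data, outcome = outcome, conf = conf,
                         tol = tol, max_iter = max_iter)
  rule <- tor_rule(name, select_criteria(ot, threshold))
  structure(list(
    or_table = ot, rule = rule, fit = attr(ot, "fit"),
    outcome = outcome, threshold = threshold, conf = conf,
    n = nrow(data), call = match.call()
  ), class = "tor_model")
}

#' @export
print.tor_model <- function(x, ...) {
  cat("TOR rule model (outcome: one-month ", x$outcome, ", n = ",
      format(x$n, big.mark = ","), ")\n", sep = "")
  cat("Criteria selected at adjusted OR >", x$threshold, ":\n")
  sel <- x$or_table[match(x$rule$criteria, x$or_table$variable), ]
  for (i in seq_len(nrow(sel))) {
    cat(sprintf("  %-30s adjusted OR %.2f (%.2f to %.2f)\n",
                sel$variable[i], sel$adjusted_or[i], sel$adjusted_low[i],
                sel$adjusted_high[i]))
  }
  invisible(x)
}

#' @export
summary.tor_model <- function(object, ...) {
  structure(list(model = object), class = "summary.tor_model")
}

#' @export
print.summary.tor_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\n")
  print(m$or_table)
  cat("\nJoint fit: converged =", m$fit$converged, "in", m$fit$iterations,
      "IRLS iterations, log-likelihood", format(m$fit$log_likelihood), "\n")
  invisible(x)
}

#' @export
coef.tor_model <- function(object, ...) coef(object$fit)

#' @export
vcov.tor_model <- function(object, ...) vcov(object$fit)

#' Predict from a TOR rule model
#'
#' @param object A [tor_model()].
#' @param newdata Registry records (or a predictor data frame).
#' @param type `"tor"` (logical: rule fulfilled, termination indicated),
#'   `"score"` (criteria count, ordinal), or `"response"` (fitted
#'   probability of the outcome from the joint logistic model).
#' @param ... Unused.
#' @return A vector with one element per record.
#' @export
predict.tor_model <- function(object, newdata,
                              type = c("tor", "score", "response"), ...) {
  type <- match.arg(type)
  switch(type,
    tor = apply_rule(object$rule, newdata),
    score = criteria_count(object$rule, newdata),
    response = {
      X <- cbind("(Intercept)" = 1, predictor_matrix(newdata))
      predict(object$fit, newdata = X, type = "response")
    })
}

#' @export
residuals.tor_model <- function(object, ...) residuals(object$fit, ...)

#' Plot the criteria-count ROC curve of a TOR rule model
#'
#' @param x A [tor_model()].
#' @param newdata Registry records to evaluate on (e.g. a validation
#'   cohort).
#' @param outcome Outcome to plot against; defaults to the model's.
#' @param ... Passed to [graphics::plot()].
#' @return The [roc_auc()] result, invisibly.
#' @export
plot.tor_model <- function(x, newdata, outcome = x$outcome, ...) {
  res <- roc_auc(newdata, x$rule, outcome = outcome, conf = x$conf)
  graphics::plot(res$roc$fpr, res$roc$tpr, type = "b",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("%s: AUC %.3f (%.3f to %.3f)",
                                x$rule$name, res$auc, res$low, res$high),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(res)
}
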