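# Diagnostic evaluation of a TOR rule: 2x2 contingency table, sensitivity /
# specificity / PPV / NPV with Wilson score intervals, criteria-count
# ROC/AUC, and the futility misclassification rate (1 - PPV).

#' Construct a 2x2 contingency table
#'
#' Counts of rule fulfillment crossed with outcome status: `tp` fulfilled &
#' outcome-positive, `fp` fulfilled & outcome-negative, `fn` not fulfilled &
#' positive, `tn` not fulfilled & negative. "Positive test" means the rule
#' is fulfilled (termination indicated); "positive outcome" means death (or
#' an unfavorable neurological outcome).
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `contingency_2x2`.
#' @seealso [contingency()] to count from per-patient records.
#' @export
contingency_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "contingency_2x2")
}

#' Cross-tabulate rule fulfillment against outcome
#'
#' @param rule A [tor_rule()].
#' @param records A non-empty registry data frame.
#' @param outcome `"death"` or `"unfavorable"`.
#' @return A [contingency_table()] whose counts sum to `nrow(records)`.
#' @export
contingency <- function(rule, records, outcome = c("death", "unfavorable")) {
  outcome <- match.arg(outcome)
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  fulfilled <- apply_rule(rule, records)
  oc <- to_outcomes(records)
  pos <- if (outcome == "death") oc$death_1m else oc$unfavorable_1m
  contingency_table(
    tp = sum(fulfilled & pos), fp = sum(fulfilled & !pos),
    fn = sum(!fulfilled & pos), tn = sum(!fulfilled & !pos)
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("rule fulfilled", "not fulfilled"),
                              c("outcome+", "outcome-")))
  print(m)
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials; must be positive.
#' @param conf Confidence level, default 0.95.
#' @return `c(low, high)`, both inside `[0, 1]`.
#' @examples
#' round(wilson_interval(4113, 4555), 3)  # c(0.894, 0.911)
#' @export
wilson_interval <- function(successes, n, conf = 0.95) {
  if (n <= 0) stop("wilson_interval requires n > 0", call. = FALSE)
  if (successes < 0 || successes > n) {
    stop("successes must lie in 0..n", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(low = max(0, (centre - half) / denom),
    high = min(1, (centre + half) / denom))
}

.metric_row <- function(num, den, conf) {
  if (den == 0L) {
    return(c(estimate = NA_real_, low = NA_real_, high = NA_real_))
  }
  ci <- wilson_interval(num, den, conf)
  c(estimate = num / den, low = unname(ci[1]), high = unname(ci[2]))
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each with
#' a Wilson score confidence interval, plus the fraction of patients
#' fulfilling the rule and the futility misclassification rate `1 - PPV`
#' (outcome-negative patients among those the rule marks futile).
#'
#' A metric whose denominator is zero is reported as an explicit undefined
#' marker (`NA` with the metric named in the `undefined` field and a
#' message), never silently as 0.
#'
#' @param table A [contingency_table()].
#' @param conf Confidence level for the Wilson intervals.
#' @return An object of class `tor_diag`: a list with a `metrics` data
#'   frame (`metric`, `estimate`, `low`, `high`), `fulfilled_fraction`,
#'   `misclassification`, `undefined` (character vector of undefined
#'   metrics) and the input counts.
#' @export
diagnostic_metrics <- function(table, conf = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  rows <- rbind(
    sensitivity = .metric_row(table$tp, table$tp + table$fn, conf),
    specificity = .metric_row(table$tn, table$tn + table$fp, conf),
    ppv         = .metric_row(table$tp, table$tp + table$fp, conf),
    npv         = .metric_row(table$tn, table$tn + table$fn, conf)
  )
  metrics <- data.frame(metric = rownames(rows), rows, row.names = NULL)
  undefined <- metrics$metric[is.na(metrics$estimate)]
  if (length(undefined) > 0L) {
    message("undefined metric(s) (zero denominator): ",
            paste(undefined, collapse = ", "))
  }
  total <- table$tp + table$fp + table$fn + table$tn
  structure(list(
    metrics = metrics,
    fulfilled_fraction = if (total > 0) (table$tp + table$fp) / total else NA_real_,
    misclassification = if (table$tp + table$fp > 0)
      table$fp / (table$tp + table$fp) else NA_real_,
    undefined = undefined,
    counts = unlist(table[c("tp", "fp", "fn", "tn")]),
    conf = conf
  ), class = "tor_diag")
}

#' @export
print.tor_diag <- function(x, ...) {
  cat("Diagnostic performance (", 100 * x$conf, "% CI)\n", sep = "")
  cat(sprintf("  counts: tp=%d fp=%d fn=%d tn=%d\n",
              x$counts["tp"], x$counts["fp"], x$counts["fn"], x$counts["tn"]))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$estimate[i])) {
      cat(sprintf("  %-12s undefined\n", m$metric[i]))
    } else {
      cat(sprintf("  %-12s %.3f (%.3f to %.3f)\n", m$metric[i],
                  m$estimate[i], m$low[i], m$high[i]))
    }
  }
  cat(sprintf("  fulfilled    %.1f%%\n", 100 * x$fulfilled_fraction))
  if (!is.na(x$misclassification)) {
    cat(sprintf("  misclassification (1 - PPV)  %.1f%%\n",
                100 * x$misclassification))
  }
  invisible(x)
}

#' Futility misclassification rate
#'
#' The proportion of outcome-negative patients (survivors, or favorable
#' outcomes) among those fulfilling the rule: `fp / (tp + fp)`, identically
#' `1 - PPV`. Undefined (`NA`) when no patient fulfills the rule.
#'
#' @param table A [contingency_table()].
#' @return A proportion, or `NA` if undefined.
#' @export
misclassification_rate <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (table$tp + table$fp == 0L) {
    message("misclassification undefined: no patient fulfills the rule")
    return(NA_real_)
  }
  table$fp / (table$tp + table$fp)
}

# Mann-Whitney AUC with Hanley-McNeil variance approximation
.auc_rank <- function(score, positive, conf) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop("ROC requires both outcome classes present", call. = FALSE)
  }
  r <- rank(score)
  auc <- (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = auc, low = max(0, auc - z * se), high = min(1, auc + z * se),
       se = se, n_pos = n1, n_neg = n0)
}

#' ROC curve and AUC over the criteria-count score
#'
#' Builds the receiver operating characteristic over thresholds of the
#' ordinal criteria-count score (0..number of criteria) and computes the
#' area under it by the trapezoidal rule, which for this discrete score
#' equals the rank statistic `P(score_pos > score_neg) + P(equal)/2`
#' (Mann-Whitney). The confidence interval uses the Hanley-McNeil variance
#' approximation for a rank-based AUC.
#'
#' @param records A registry data frame containing both outcome classes.
#' @param rule A [tor_rule()].
#' @param outcome `"death"` or `"unfavorable"`.
#' @param conf Confidence level.
#' @return A list with `auc`, `low`, `high`, `se`, the per-threshold ROC
#'   points (`roc`, a data frame of 1-specificity and sensitivity), and
#'   class counts.
#' @export
roc_auc <- function(records, rule, outcome = c("death", "unfavorable"),
                    conf = 0.95) {
  outcome <- match.arg(outcome)
  score <- criteria_count(rule, records)
  oc <- to_outcomes(records)
  pos <- if (outcome == "death") oc$death_1m else oc$unfavorable_1m
  res <- .auc_rank(score, pos, conf)
  k <- length(rule$criteria)
  pts <- t(vapply(seq(0, k + 1), function(thr) {
    pred <- score >= thr
    c(fpr = sum(pred & !pos) / res$n_neg, tpr = sum(pred & pos) / res$n_pos)
  }, c(fpr = 0, tpr = 0)))
  res$roc <- data.frame(threshold = seq(0, k + 1), pts)
  res
}
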