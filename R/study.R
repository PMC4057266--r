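# Full study replay: simulate a cohort, split into development and
# validation periods, derive the rule on the development group, and
# evaluate the derived and BLS comparator rules on both outcomes in both
# groups. A fixture mode evaluates published aggregate 2x2 tables through
# the same code path.

#' Evaluate a set of 2x2 tables
#'
#' Applies [diagnostic_metrics()] to each table of a named list. This is
#' the single evaluation code path shared by the synthetic-cohort pipeline
#' and the published-aggregate fixture mode.
#'
#' @param tables Named list of [contingency_table()] objects.
#' @param conf Confidence level.
#' @return Named list of `tor_diag` objects.
#' @export
evaluate_tables <- function(tables, conf = 0.95) {
  stopifnot(is.list(tables))
  lapply(tables, diagnostic_metrics, conf = conf)
}

#' Replay the published study results from aggregate counts
#'
#' Runs the evaluation module over the six published 2x2 tables
#' ([published_contingency_tables()]), reproducing the published
#' sensitivity, specificity, PPV, NPV (with Wilson intervals) and futility
#' misclassification rates without any per-record data.
#'
#' @param conf Confidence level.
#' @return A named list of `tor_diag` objects, one per published table.
#' @export
replay_published_study <- function(conf = 0.95) {
  evaluate_tables(published_contingency_tables(), conf = conf)
}

.study_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("study pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full study pipeline on a synthetic cohort
#'
#' Deterministically from the configuration seed: generates a cohort,
#' splits it into development and validation periods, derives the TOR rule
#' on the development group (11-covariate logistic model, adjusted-OR
#' threshold), and evaluates the derived rule and the BLS comparator rule
#' against one-month death and unfavorable neurological outcome in both
#' groups, including criteria-count ROC/AUC. Each stage logs its record
#' counts; stage errors abort with the stage named.
#'
#' @param config A [generator_config()].
#' @param threshold Adjusted-OR selection cutoff.
#' @param dev_years,val_years Development / validation calendar years.
#' @param conf Confidence level.
#' @return An object of class `tor_study`: list with `summaries`
#'   (per-group `cohort_summary`), `model` (the fitted [tor_model()]),
#'   `rules`, `evaluations` (per rule x outcome x group: list with
#'   `table`, `metrics`, `auc`), and `provenance` (seed, n, threshold,
#'   package version).
#' @export
run_study <- function(config = generator_config(), threshold = 2.0,
                      dev_years = 2005:2008, val_years = 2009,
                      conf = 0.95) {
  cohort <- .study_stage("simulate", generate_records(config))
  message("run_study: generated ", nrow(cohort), " records")
  split <- .study_stage("split",
                        split_by_period(cohort, dev_years, val_years))
  message("run_study: development n = ", nrow(split$development),
          ", validation n = ", nrow(split$validation))
  model <- .study_stage("derive", tor_model(split$development,
                                            outcome = "death",
                                            threshold = threshold,
                                            conf = conf))
  message("run_study: derived rule criteria: ",
          paste(model$rule$criteria, collapse = ", "))
  rules <- list(derived = model$rule, bls = bls_tor_rule())
  groups <- list(development = split$development,
                 validation = split$validation)
  evaluations <- list()
  for (rn in names(rules)) {
    for (oc in c("death", "unfavorable")) {
      for (gn in names(groups)) {
        key <- paste(rn, oc, gn, sep = "_")
        evaluations[[key]] <- .study_stage(paste("validate", key), {
          tab <- contingency(rules[[rn]], groups[[gn]], outcome = oc)
          list(table = tab,
               metrics = diagnostic_metrics(tab, conf = conf),
               auc = roc_auc(groups[[gn]], rules[[rn]], outcome = oc,
                             conf = conf))
        })
      }
    }
  }
  structure(list(
    summaries = lapply(groups, summarize_cohort),
    model = model,
    rules = rules,
    evaluations = evaluations,
    provenance = list(seed = config$seed, n = config$n,
                      threshold = threshold,
                      package_version = as.character(
                        utils::packageVersion("torrule")))
  ), class = "tor_study")
}

#' @export
print.tor_study <- function(x, ...) {
  cat("TOR study replay (seed ", x$provenance$seed, ", n = ",
      format(x$provenance$n, big.mark = ","), ")\n\n", sep = "")
  print(x$model)
  cat("\nRule performance:\n")
  for (key in names(x$evaluations)) {
    ev <- x$evaluations[[key]]
    m <- ev$metrics$metrics
    get <- function(nm) m$estimate[m$metric == nm]
    cat(sprintf(
      "  %-28s sens %.3f  spec %.3f  ppv %.3f  npv %.3f  auc %.3f\n",
      key, get("sensitivity"), get("specificity"), get("ppv"), get("npv"),
      ev$auc$auc))
  }
  invisible(x)
}
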