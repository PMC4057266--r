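# Conjunction termination-of-resuscitation rules: construction, criteria
# selection by adjusted-odds-ratio threshold, and application to records.

#' Construct a termination-of-resuscitation rule
#'
#' A TOR rule is a named conjunction of binary risk-coded criteria:
#' resuscitation is classified futile (death predicted) exactly when every
#' criterion holds. Criteria must be binary model covariates (see
#' [binary_predictors()]); continuous covariates are never rule criteria.
#'
#' @param name Rule name.
#' @param criteria Non-empty character vector of binary predictor names.
#' @return An object of class `tor_rule`.
#' @seealso [select_criteria()], [bls_tor_rule()], [ed_tor_rule()]
#' @export
tor_rule <- function(name, criteria) {
  if (length(criteria) == 0L) {
    stop("a TOR rule needs at least one criterion", call. = FALSE)
  }
  bad <- setdiff(criteria, .binary_predictor_fields)
  if (length(bad) > 0L) {
    stop("invalid rule criterion(s): ", paste(bad, collapse = ", "),
         "; criteria must be binary model covariates", call. = FALSE)
  }
  structure(list(name = name, criteria = unique(criteria)),
            class = "tor_rule")
}

#' @export
print.tor_rule <- function(x, ...) {
  cat("TOR rule '", x$name, "': terminate when ALL of\n", sep = "")
  cat(paste0("  - ", x$criteria, collapse = "\n"), "\n")
  invisible(x)
}

#' Select rule criteria from an odds-ratio table
#'
#' Returns the binary covariates whose adjusted odds ratio for the outcome
#' is strictly greater than the threshold, ordered by descending adjusted
#' OR. This is the rule-derivation step: with the default threshold of 2.0
#' on the one-month-death model it yields the three-criterion rule
#' (no prehospital ROSC, unshockable initial rhythm, unwitnessed by
#' bystanders). Ties at the threshold are excluded ("strictly greater"),
#' and continuous covariates are never candidates.
#'
#' @param ortable An [or_table] (from [odds_ratio_table()] or published
#'   values via [or_table()]).
#' @param threshold Positive adjusted-OR cutoff; default 2.0.
#' @return Character vector of selected criteria, descending adjusted OR.
#' @export
select_criteria <- function(ortable, threshold = 2.0) {
  stopifnot(inherits(ortable, "or_table"), threshold > 0)
  cand <- ortable[ortable$variable %in% .binary_predictor_fields, ]
  keep <- cand[!is.na(cand$adjusted_or) & cand$adjusted_or > threshold, ]
  if (nrow(keep) == 0L) {
    stop("no criteria selected: no binary covariate has adjusted OR > ",
         threshold, call. = FALSE)
  }
  keep$variable[order(keep$adjusted_or, decreasing = TRUE)]
}

# accept either raw registry records or an already-derived predictor frame
.as_predictor_frame <- function(x) {
  if (all(.registry_fields %in% names(x))) to_predictors(x) else as.data.frame(x)
}

#' Apply a rule to patients
#'
#' @description
#' `apply_rule()` returns, per patient, whether every criterion of the rule
#' is satisfied (conjunction; `TRUE` means termination indicated, i.e.
#' death predicted). `criteria_count()` returns the number of satisfied
#' criteria, an ordinal score in `0..length(criteria)` used for the ROC
#' analysis; it equals `length(criteria)` exactly when `apply_rule()` is
#' `TRUE`.
#'
#' @param rule A [tor_rule()].
#' @param x Registry records or a predictor data frame ([to_predictors()]).
#' @return `apply_rule()`: a logical vector; `criteria_count()`: an integer
#'   vector.
#' @export
apply_rule <- function(rule, x) {
  stopifnot(inherits(rule, "tor_rule"))
  p <- .as_predictor_frame(x)
  missing_crit <- setdiff(rule$criteria, names(p))
  if (length(missing_crit) > 0L) {
    stop("unknown rule criterion(s): ",
         paste(missing_crit, collapse = ", "), call. = FALSE)
  }
  Reduce(`&`, lapply(rule$criteria, function(cr) as.logical(p[[cr]])))
}

#' @rdname apply_rule
#' @export
criteria_count <- function(rule, x) {
  stopifnot(inherits(rule, "tor_rule"))
  p <- .as_predictor_frame(x)
  missing_crit <- setdiff(rule$criteria, names(p))
  if (length(missing_crit) > 0L) {
    stop("unknown rule criterion(s): ",
         paste(missing_crit, collapse = ", "), call. = FALSE)
  }
  Reduce(`+`, lapply(rule$criteria, function(cr) as.integer(p[[cr]])))
}

#' The prehospital basic-life-support TOR rule
#'
#' The established three-criterion prehospital comparator rule: arrest
#' unwitnessed by EMS personnel, no shock delivered, and no prehospital
#' return of spontaneous circulation. "No shock given" maps to the
#' registry's prehospital-defibrillation field (EMS or public AED).
#'
#' @return A [tor_rule()].
#' @export
bls_tor_rule <- function() {
  tor_rule("BLS TOR", c("unwitnessed_by_ems",
                        "no_prehospital_defibrillation",
                        "no_prehospital_rosc"))
}

#' The emergency-department TOR rule
#'
#' The three-criterion rule for emergency department physicians derived
#' from the nationwide cohort: no prehospital return of spontaneous
#' circulation, unshockable initial rhythm, and arrest unwitnessed by
#' bystanders (the covariates with adjusted odds ratio above 2.0 for
#' one-month death).
#'
#' @return A [tor_rule()].
#' @export
ed_tor_rule <- function() {
  tor_rule("new TOR", c("no_prehospital_rosc",
                        "unshockable_initial_rhythm",
                        "unwitnessed_by_bystander"))
}
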