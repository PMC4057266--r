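# Published aggregate results of the nationwide Japanese OHCA cohort
# (2005-2009), usable as first-class inputs: the per-rule 2x2 contingency
# tables, the adjusted odds-ratio columns of the 11-covariate models, and
# the overall outcome counts. These let the evaluation and rule-selection
# code run on the published aggregates without any per-record data.

#' Published 2x2 contingency tables of the nationwide cohort
#'
#' The six published rule-performance cross-tabulations: the derived
#' emergency-department rule against one-month death and against
#' unfavorable neurological outcome, each in the development (2005-2008,
#' n = 390,577) and validation (2009, n = 105,030) groups, and the BLS
#' comparator rule against both outcomes in the validation group.
#'
#' @return A named list of [contingency_table()] objects; names have the
#'   form `<rule>_<outcome>_<group>` with rule `ed` (emergency-department
#'   rule) or `bls`, outcome `death` or `unfavorable`, group `development`
#'   or `validation`.
#' @export
published_contingency_tables <- function() {
  list(
    ed_death_development        = contingency_table(tp = 221167, fp = 1856,
                                                    fn = 154512, tn = 13042),
    ed_death_validation         = contingency_table(tp = 59763, fp = 442,
                                                    fn = 40712, tn = 4113),
    ed_unfavorable_development  = contingency_table(tp = 222642, fp = 381,
                                                    fn = 161691, tn = 5863),
    ed_unfavorable_validation   = contingency_table(tp = 60132, fp = 73,
                                                    fn = 42751, tn = 2074),
    bls_death_validation        = contingency_table(tp = 84723, fp = 1005,
                                                    fn = 15752, tn = 3550),
    bls_unfavorable_validation  = contingency_table(tp = 85575, fp = 153,
                                                    fn = 17308, tn = 1994)
  )
}

#' Published odds-ratio table of the 11-covariate model
#'
#' The published crude and adjusted odds ratios (with 95% CIs) of the
#' 11-covariate logistic models fitted on the development group, for
#' one-month death or for unfavorable neurological outcome (CPC 3-5).
#' Feeding the death table to [select_criteria()] with threshold 2.0
#' reproduces the derived three-criterion rule.
#'
#' @param outcome `"death"` or `"unfavorable"`.
#' @return An [or_table] data frame in model covariate order.
#' @export
published_or_table <- function(outcome = c("death", "unfavorable")) {
  outcome <- match.arg(outcome)
  v <- predictor_names()
  if (outcome == "death") {
    tab <- or_table(
      variable = v,
      crude_or      = c(1.02, 1.40, 4.70, 3.51, 1.13, 1.38, 10.4, 7.50, 43.4, 1.10, 1.02),
      crude_low     = c(1.02, 1.35, 4.54, 3.33, 1.10, 1.34, 10.0, 7.25, 41.8, 1.10, 1.01),
      crude_high    = c(1.02, 1.45, 4.88, 3.68, 1.17, 1.43, 10.8, 7.76, 45.0, 1.11, 1.02),
      adjusted_or   = c(1.01, 1.00, 2.18, 1.69, 1.01, 0.93, 2.76, 1.54, 25.8, 1.05, 1.03),
      adjusted_low  = c(1.01, 0.96, 2.09, 1.59, 0.97, 0.89, 2.54, 1.41, 24.7, 1.04, 1.02),
      adjusted_high = c(1.01, 1.05, 2.28, 1.81, 1.06, 0.97, 3.01, 1.67, 26.9, 1.06, 1.03)
    )
  } else {
    tab <- or_table(
      variable = v,
      crude_or      = c(1.03, 0.53, 7.04, 5.10, 1.29, 3.00, 21.6, 15.2, 80.2, 1.13, 1.02),
      crude_low     = c(1.03, 0.50, 6.61, 4.77, 1.23, 2.83, 20.5, 14.4, 75.5, 1.12, 1.02),
      crude_high    = c(1.03, 0.56, 7.50, 5.44, 1.36, 3.19, 22.7, 16.0, 85.2, 1.14, 1.02),
      adjusted_or   = c(1.03, 0.90, 2.01, 2.68, 1.11, 1.84, 3.38, 1.42, 38.4, 1.05, 1.02),
      adjusted_low  = c(1.02, 0.84, 1.87, 2.46, 1.04, 1.71, 2.98, 1.24, 35.9, 1.04, 1.02),
      adjusted_high = c(1.03, 0.96, 2.17, 2.93, 1.18, 1.99, 3.84, 1.61, 41.0, 1.06, 1.03)
    )
  }
  attr(tab, "outcome") <- outcome
  tab
}

#' Published cohort-level outcome counts
#'
#' Aggregate size and one-month outcome counts of the full cohort and of
#' the development and validation groups, for consistency checks of
#' summary percentages (e.g. overall survival 19,453 / 495,607 = 3.93%).
#'
#' @return A data frame with one row per group.
#' @export
published_cohort_counts <- function() {
  data.frame(
    group = c("all", "development", "validation"),
    n = c(495607L, 390577L, 105030L),
    survivors = c(19453L, 14898L, 4555L),
    cpc12 = c(8391L, 6244L, 2147L)
  )
}
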