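# Seeded synthetic Utstein-style cohort generator. Covariate marginals
# follow the published nationwide validation-year cohort; one-month death
# follows a logistic model whose coefficients are the published adjusted
# odds ratios, with the intercept calibrated to the published death rate.

#' Configuration for the synthetic registry generator
#'
#' Builds the full parameter set for [generate_records()]. The defaults
#' reproduce the validation-year (2009) characteristics of the nationwide
#' Japanese out-of-hospital cardiac arrest cohort: marginal prevalences of
#' the prehospital covariates, age and time distributions given as median
#' (first and third quartile), the adjusted odds ratios of the 11-covariate
#' one-month-death model as true effects, and an intercept calibrated so
#' the cohort death rate matches the published 95.66%.
#'
#' Covariate dependence is a shallow causal chain: bystander-witnessed
#' status raises the bystander-CPR probability; a shockable initial rhythm
#' raises the defibrillation probability; defibrillation raises the
#' prehospital-ROSC probability. Each link stores the child probability
#' given the parent is TRUE; the probability given FALSE is solved from the
#' configured marginal so marginal prevalences are preserved. Witness
#' status is drawn as a three-way category (bystander / EMS / unwitnessed),
#' making the two witness indicators mutually exclusive. All remaining
#' covariates are independent.
#'
#' @param n Number of records to generate.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param prevalences Named vector of marginal prevalences for the binary
#'   registry covariates.
#' @param conditional_links List of `(parent, child, p_given_true)` triples
#'   defining the dependence chain (see Details).
#' @param or_vector Named vector of true odds ratios for the 11 risk-coded
#'   model covariates, in [predictor_names()] order (per year / per minute
#'   for the continuous covariates).
#' @param intercept Log-odds intercept of the outcome model, or `NULL`
#'   (default) to calibrate it to `target_death_rate` on first use.
#' @param target_death_rate Population-averaged one-month death probability
#'   the intercept is calibrated to when `intercept` is `NULL`.
#' @param age_distribution Named vector `c(median, q1, q3)` in years; ages
#'   are drawn from a reflected log-normal matched to these quantiles,
#'   rounded to whole years and truncated to 18..110.
#' @param time_distributions List with elements `call_to_response` and
#'   `transport_gap`, each `c(median, q1, q3)` in minutes, both log-normal;
#'   call-to-hospital time is the response time plus the transport gap, so
#'   hospital arrival never precedes scene arrival.
#' @param cpc_split Probabilities over Cerebral Performance Categories 1..4
#'   for survivors (non-survivors are CPC 5 by definition). The default
#'   puts 47% of survivors in CPC 1-2, matching the published 2.04%
#'   favorable / 4.34% survival ratio.
#' @param years Calendar years the cohort spans.
#' @param year_weights Sampling weights over `years`; the default splits
#'   78.8% / 21.2% between 2005-2008 and 2009 as in the published cohort.
#' @return An object of class `generator_config` (a named list).
#' @seealso [generate_records()], [calibrate_intercept()]
#' @export
generator_config <- function(
  n = 10000L,
  seed = 1L,
  prevalences = c(
    male                       = 0.580,
    witnessed_by_bystander     = 0.385,
    witnessed_by_ems           = 0.050,
    bystander_cpr              = 0.487,
    cardiac_etiology           = 0.570,
    shockable_initial_rhythm   = 0.078,
    prehospital_defibrillation = 0.107,
    prehospital_rosc           = 0.061
  ),
  conditional_links = list(
    list(parent = "witnessed_by_bystander", child = "bystander_cpr",
         p_given_true = 0.60),
    list(parent = "shockable_initial_rhythm",
         child = "prehospital_defibrillation", p_given_true = 0.85),
    list(parent = "prehospital_defibrillation", child = "prehospital_rosc",
         p_given_true = 0.20)
  ),
  or_vector = c(
    age                           = 1.01,
    male                          = 1.00,
    unwitnessed_by_bystander      = 2.18,
    unwitnessed_by_ems            = 1.69,
    no_bystander_cpr              = 1.01,
    noncardiac_etiology           = 0.93,
    unshockable_initial_rhythm    = 2.76,
    no_prehospital_defibrillation = 1.54,
    no_prehospital_rosc           = 25.8,
    call_to_response_min          = 1.05,
    call_to_hospital_min          = 1.03
  ),
  intercept = NULL,
  target_death_rate = 0.9566,
  age_distribution = c(median = 77, q1 = 65, q3 = 85),
  time_distributions = list(
    call_to_response = c(median = 7, q1 = 5, q3 = 9),
    transport_gap    = c(median = 23, q1 = 19, q3 = 28)
  ),
  cpc_split = c(0.28, 0.19, 0.23, 0.30),
  years = 2005:2009,
  year_weights = c(0.197, 0.197, 0.197, 0.197, 0.212)
) {
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    prevalences = prevalences, conditional_links = conditional_links,
    or_vector = or_vector, intercept = intercept,
    target_death_rate = target_death_rate,
    age_distribution = age_distribution,
    time_distributions = time_distributions,
    cpc_split = cpc_split, years = years,
    year_weights = year_weights / sum(year_weights)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n < 0L) stop("n must be non-negative", call. = FALSE)
  if (any(cfg$prevalences < 0 | cfg$prevalences > 1)) {
    stop("generator configuration error: prevalences must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(cfg$or_vector <= 0)) {
    stop("generator configuration error: odds ratios must be positive",
         call. = FALSE)
  }
  if (!setequal(names(cfg$or_vector), .predictor_fields)) {
    stop("or_vector must name exactly the 11 model covariates", call. = FALSE)
  }
  if (abs(sum(cfg$cpc_split) - 1) > 1e-8 || any(cfg$cpc_split < 0)) {
    stop("cpc_split must be non-negative and sum to 1", call. = FALSE)
  }
  for (lk in cfg$conditional_links) {
    if (lk$p_given_true < 0 || lk$p_given_true > 1) {
      stop("conditional link probability outside [0, 1]", call. = FALSE)
    }
    p_false <- .link_p_false(cfg, lk)
    if (p_false < 0 || p_false > 1) {
      stop("conditional link (", lk$parent, " -> ", lk$child,
           ") incompatible with configured marginals: implied P(child | !parent) = ",
           signif(p_false, 4), call. = FALSE)
    }
  }
  invisible(cfg)
}

# solve P(child | parent FALSE) from the child's marginal
.link_p_false <- function(cfg, lk) {
  w <- cfg$prevalences[[lk$parent]]
  m <- cfg$prevalences[[lk$child]]
  (m - w * lk$p_given_true) / (1 - w)
}

# reflected log-normal age sampler matched to median and quartiles,
# truncated to [18, 110] by resampling
.sample_ages <- function(dist, n) {
  offset <- 100
  q <- offset - c(dist[["q3"]], dist[["median"]], dist[["q1"]])
  meanlog <- log(q[2])
  sdlog <- (log(q[3]) - log(q[1])) / (2 * stats::qnorm(0.75))
  age <- round(offset - stats::rlnorm(n, meanlog, sdlog))
  bad <- which(age < 18 | age > 110)
  while (length(bad) > 0L) {
    age[bad] <- round(offset - stats::rlnorm(length(bad), meanlog, sdlog))
    bad <- bad[age[bad] < 18 | age[bad] > 110]
  }
  age
}

.sample_lognormal <- function(dist, n) {
  meanlog <- log(dist[["median"]])
  sdlog <- (log(dist[["q3"]]) - log(dist[["q1"]])) / (2 * stats::qnorm(0.75))
  stats::rlnorm(n, meanlog, sdlog)
}

# Draw covariates (not outcomes) for n patients; assumes RNG already seeded.
# Returns the partial registry data frame plus the 11-column design matrix.
.sample_covariates <- function(cfg, n) {
  pv <- cfg$prevalences
  # three-way witness category keeps the two indicators mutually exclusive
  u <- stats::runif(n)
  witnessed_by_bystander <- u < pv[["witnessed_by_bystander"]]
  witnessed_by_ems <- !witnessed_by_bystander &
    u < pv[["witnessed_by_bystander"]] + pv[["witnessed_by_ems"]]

  df <- data.frame(
    year = sample(cfg$years, n, replace = TRUE, prob = cfg$year_weights),
    age = .sample_ages(cfg$age_distribution, n),
    male = stats::runif(n) < pv[["male"]],
    witnessed_by_bystander = witnessed_by_bystander,
    witnessed_by_ems = witnessed_by_ems,
    bystander_cpr = NA,
    cardiac_etiology = stats::runif(n) < pv[["cardiac_etiology"]],
    shockable_initial_rhythm = stats::runif(n) < pv[["shockable_initial_rhythm"]],
    prehospital_defibrillation = NA,
    prehospital_rosc = NA
  )
  for (lk in cfg$conditional_links) {
    p <- ifelse(df[[lk$parent]], lk$p_given_true, .link_p_false(cfg, lk))
    df[[lk$child]] <- stats::runif(n) < p
  }
  # any chain child left unset (link removed from config) falls back to its marginal
  for (f in c("bystander_cpr", "prehospital_defibrillation", "prehospital_rosc")) {
    if (anyNA(df[[f]])) df[[f]] <- stats::runif(n) < pv[[f]]
  }
  df$call_to_response_min <- .sample_lognormal(
    cfg$time_distributions$call_to_response, n)
  df$call_to_hospital_min <- df$call_to_response_min +
    .sample_lognormal(cfg$time_distributions$transport_gap, n)
  df
}

#' Calibrate the outcome-model intercept to a target death rate
#'
#' Finds the log-odds intercept at which the population-averaged one-month
#' death probability — the mean of `plogis(intercept + x' log(OR))` over the
#' configured covariate distribution — equals the target. The mean death
#' probability is strictly increasing in the intercept, so a bracketing
#' bisection converges; the covariate sample used for the average is drawn
#' deterministically from the configuration seed.
#'
#' @param config A [generator_config()].
#' @param target_death_rate Target population-averaged death probability in
#'   (0, 1); defaults to the configured value.
#' @param tol Absolute tolerance on the achieved mean death probability.
#' @param n_calib Size of the covariate sample the average is taken over.
#' @param max_iter Bisection iteration cap.
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(config,
                                target_death_rate = config$target_death_rate,
                                tol = 1e-4, n_calib = 50000L,
                                max_iter = 200L) {
  stopifnot(inherits(config, "generator_config"))
  if (target_death_rate <= 0 || target_death_rate >= 1) {
    stop("target_death_rate must lie strictly inside (0, 1)", call. = FALSE)
  }
  # private RNG stream so calibration never perturbs generation
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed((config$seed %% 1000003L) + 424243L)
  df <- .sample_covariates(config, n_calib)
  eta0 <- as.vector(predictor_matrix(df) %*% log(config$or_vector[.predictor_fields]))

  mean_p <- function(b0) mean(stats::plogis(b0 + eta0))
  lo <- -40; hi <- 40
  if (mean_p(lo) > target_death_rate || mean_p(hi) < target_death_rate) {
    stop("calibration bracket [-40, 40] does not contain the target rate",
         call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f <- mean_p(mid)
    if (abs(f - target_death_rate) < tol) return(mid)
    if (f < target_death_rate) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "intercept calibration did not converge within %d iterations (bracket [%.6f, %.6f])",
    max_iter, lo, hi), call. = FALSE)
}

#' Generate a synthetic Utstein-style cohort
#'
#' Draws `n` registry records reproducibly from `seed`: covariates from the
#' configured marginals and dependence chain, one-month death per record
#' from the logistic model `logit(p) = intercept + sum(log(OR_j) x_j)` over
#' the 11 risk-coded covariates, CPC 1..4 for survivors from `cpc_split`
#' and CPC 5 for non-survivors. If the configuration's intercept is `NULL`
#' it is calibrated first (see [calibrate_intercept()]).
#'
#' @param config A [generator_config()].
#' @param n Number of records; defaults to `config$n`. `n = 0` yields an
#'   empty collection.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A validated registry data frame (see [registry_fields()]).
#' @export
generate_records <- function(config, n = config$n, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  n <- as.integer(n)
  if (n == 0L) {
    empty <- as.data.frame(stats::setNames(
      rep(list(logical(0)), length(.registry_fields)), .registry_fields))
    return(empty)
  }
  intercept <- config$intercept
  if (is.null(intercept)) intercept <- calibrate_intercept(config)

  set.seed(seed)
  df <- .sample_covariates(config, n)
  eta <- intercept +
    as.vector(predictor_matrix(df) %*% log(config$or_vector[.predictor_fields]))
  death <- stats::runif(n) < stats::plogis(eta)
  cpc <- rep(5L, n)
  n_surv <- sum(!death)
  if (n_surv > 0L) {
    cpc[!death] <- sample(1:4, n_surv, replace = TRUE, prob = config$cpc_split)
  }
  df$prehospital_rosc <- as.logical(df$prehospital_rosc)
  out <- data.frame(patient_id = sprintf("P%08d", seq_len(n)), df,
                    stringsAsFactors = FALSE)
  out$one_month_survival <- !death
  out$cpc <- cpc
  out <- out[, .registry_fields]
  validate_registry(out, study_years = config$years)
}

#' Summarize a cohort's baseline characteristics
#'
#' Produces a baseline-characteristics summary in the style of a registry
#' Table 1: count and percentage for each binary covariate, median and
#' quartiles for age and times, and one-month survival and favorable
#' neurological outcome (CPC 1-2) rates.
#'
#' @param records A non-empty registry data frame.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("cannot summarize an empty cohort", call. = FALSE)
  }
  n <- nrow(records)
  bin <- c("male", "witnessed_by_bystander", "witnessed_by_ems",
           "bystander_cpr", "cardiac_etiology", "shockable_initial_rhythm",
           "prehospital_defibrillation", "prehospital_rosc")
  counts <- vapply(records[bin], function(v) sum(as.logical(v)), integer(1))
  q3 <- function(v) stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
  out <- list(
    n = n,
    binary = data.frame(field = bin, count = counts,
                        percent = 100 * counts / n, row.names = NULL),
    age = q3(records$age),
    call_to_response_min = q3(records$call_to_response_min),
    call_to_hospital_min = q3(records$call_to_hospital_min),
    survival_percent = 100 * sum(records$one_month_survival) / n,
    cpc12_percent = 100 * sum(records$cpc <= 2) / n
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n = ", format(x$n, big.mark = ","), ")\n", sep = "")
  b <- x$binary
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-28s %9s (%.1f%%)\n", b$field[i],
                format(b$count[i], big.mark = ","), b$percent[i]))
  }
  fq <- function(v) sprintf("%.0f (%.0f to %.0f)", v[1], v[2], v[3])
  cat("  age, years                  ", fq(x$age), "\n")
  cat("  call-to-response, min       ", fq(x$call_to_response_min), "\n")
  cat("  call-to-hospital, min       ", fq(x$call_to_hospital_min), "\n")
  cat(sprintf("  one-month survival           %.2f%%\n", x$survival_percent))
  cat(sprintf("  CPC 1-2 at one month         %.2f%%\n", x$cpc12_percent))
  invisible(x)
}
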