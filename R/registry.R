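# Utstein-style registry schema, validation, delimited I/O, and the
# mapping from raw records to risk-direction-coded model covariates.

.registry_fields <- c(
  "patient_id", "year", "age", "male",
  "witnessed_by_bystander", "witnessed_by_ems", "bystander_cpr",
  "cardiac_etiology", "shockable_initial_rhythm",
  "prehospital_defibrillation",
  "call_to_response_min", "call_to_hospital_min",
  "prehospital_rosc", "one_month_survival", "cpc"
)

.registry_bool_fields <- c(
  "male", "witnessed_by_bystander", "witnessed_by_ems", "bystander_cpr",
  "cardiac_etiology", "shockable_initial_rhythm",
  "prehospital_defibrillation", "prehospital_rosc", "one_month_survival"
)

# The 11 model covariates, in the order they enter the multivariable fit.
# Booleans are risk-direction coded: absence of the favourable feature is 1.
.predictor_fields <- c(
  "age", "male",
  "unwitnessed_by_bystander", "unwitnessed_by_ems", "no_bystander_cpr",
  "noncardiac_etiology", "unshockable_initial_rhythm",
  "no_prehospital_defibrillation", "no_prehospital_rosc",
  "call_to_response_min", "call_to_hospital_min"
)

.binary_predictor_fields <- setdiff(
  .predictor_fields, c("age", "call_to_response_min", "call_to_hospital_min")
)

# map risk-coded predictor name -> (registry field, negated?)
.predictor_map <- list(
  age                           = list(field = "age", negate = FALSE),
  male                          = list(field = "male", negate = FALSE),
  unwitnessed_by_bystander      = list(field = "witnessed_by_bystander", negate = TRUE),
  unwitnessed_by_ems            = list(field = "witnessed_by_ems", negate = TRUE),
  no_bystander_cpr              = list(field = "bystander_cpr", negate = TRUE),
  noncardiac_etiology           = list(field = "cardiac_etiology", negate = TRUE),
  unshockable_initial_rhythm    = list(field = "shockable_initial_rhythm", negate = TRUE),
  no_prehospital_defibrillation = list(field = "prehospital_defibrillation", negate = TRUE),
  no_prehospital_rosc           = list(field = "prehospital_rosc", negate = TRUE),
  call_to_response_min          = list(field = "call_to_response_min", negate = FALSE),
  call_to_hospital_min          = list(field = "call_to_hospital_min", negate = FALSE)
)

#' Registry and predictor field names
#'
#' @description
#' `registry_fields()` returns the column names of the Utstein-style record
#' schema (one row per arrest). `predictor_names()` returns the 11 model
#' covariates in the order they enter the multivariable logistic model;
#' `binary_predictors()` returns the subset eligible as rule criteria
#' (continuous covariates are never rule criteria).
#'
#' @return A character vector of field names.
#' @export
registry_fields <- function() .registry_fields

#' @rdname registry_fields
#' @export
predictor_names <- function() .predictor_fields

#' @rdname registry_fields
#' @export
binary_predictors <- function() .binary_predictor_fields

#' Validate a collection of registry records
#'
#' Checks the schema and the per-record invariants: age at least 18 years,
#' CPC in 1..5 with CPC 5 if and only if death at one month, non-negative
#' response and transport times with hospital arrival no earlier than scene
#' arrival, and (optionally) calendar year inside the study period. Missing
#' values invalidate a row.
#'
#' @param records A data frame with the columns of [registry_fields()].
#' @param study_years Optional integer vector of admissible calendar years.
#' @param on_invalid `"abort"` (default) raises an error naming the offending
#'   rows; `"skip"` drops invalid rows with a message.
#' @return The validated (possibly row-filtered) data frame, invisibly
#'   classed as before.
#' @export
validate_registry <- function(records, study_years = NULL,
                              on_invalid = c("abort", "skip")) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.registry_fields, names(records))
  if (length(missing_cols) > 0L) {
    stop("registry schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) return(records)

  for (f in .registry_bool_fields) {
    v <- records[[f]]
    if (is.numeric(v)) {
      bad <- !(v %in% c(0, 1)) & !is.na(v)
      if (any(bad)) {
        stop("registry value error in column '", f, "', row(s) ",
             paste(utils::head(which(bad), 5L), collapse = ", "),
             ": booleans must be 0/1", call. = FALSE)
      }
      records[[f]] <- as.logical(v)
    } else if (!is.logical(v)) {
      stop("registry value error: column '", f, "' must be logical or 0/1",
           call. = FALSE)
    }
  }

  problems <- character(0)
  flag <- function(bad, what) {
    bad <- which(bad | is.na(bad))
    if (length(bad) > 0L) {
      problems <<- c(problems, sprintf(
        "row %s: %s", paste(utils::head(bad, 5L), collapse = ","), what))
    }
    bad
  }
  bad_rows <- integer(0)
  bad_rows <- c(bad_rows, flag(records$age < 18, "age below 18"))
  bad_rows <- c(bad_rows, flag(!(records$cpc %in% 1:5), "cpc outside 1..5"))
  bad_rows <- c(bad_rows, flag(
    (records$cpc == 5) != (!records$one_month_survival),
    "cpc 5 must coincide with one-month death"))
  bad_rows <- c(bad_rows, flag(records$call_to_response_min < 0,
                               "negative call-to-response time"))
  bad_rows <- c(bad_rows, flag(
    records$call_to_hospital_min < records$call_to_response_min,
    "hospital arrival before scene arrival"))
  if (!is.null(study_years)) {
    bad_rows <- c(bad_rows, flag(!(records$year %in% study_years),
                                 "year outside study period"))
  }
  for (f in setdiff(.registry_fields, "patient_id")) {
    bad_rows <- c(bad_rows, flag(is.na(records[[f]]),
                                 paste0("missing value in ", f)))
  }

  bad_rows <- sort(unique(bad_rows))
  if (length(bad_rows) > 0L) {
    if (on_invalid == "abort") {
      stop("invalid registry record(s): ",
           paste(utils::head(problems, 10L), collapse = "; "), call. = FALSE)
    }
    message("dropping ", length(bad_rows), " invalid registry record(s)")
    records <- records[-bad_rows, , drop = FALSE]
    rownames(records) <- NULL
  }
  records
}

#' Read an Utstein-style registry file
#'
#' Reads a delimited text file with a mandatory header row naming every
#' schema field (see [registry_fields()]); booleans are serialized as 0/1.
#' Every row is validated; row order is preserved. An empty file (header
#' only) yields an empty collection.
#'
#' @param path Path to the delimited file.
#' @param delimiter Field delimiter, default comma.
#' @inheritParams validate_registry
#' @return A data frame of validated registry records.
#' @seealso [write_registry()], [validate_registry()]
#' @export
read_registry <- function(path, delimiter = ",", study_years = NULL,
                          on_invalid = c("abort", "skip")) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  df <- df[, intersect(c(.registry_fields, names(df)), names(df)), drop = FALSE]
  validate_registry(df, study_years = study_years, on_invalid = on_invalid)
}

#' Write an Utstein-style registry file
#'
#' Inverse of [read_registry()]: comma-delimited UTF-8 with a header row,
#' booleans as 0/1. Writing then re-reading is the identity on valid records.
#'
#' @param records A validated registry data frame.
#' @param path Output path.
#' @param delimiter Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path, delimiter = ",") {
  records <- validate_registry(records)
  out <- records[, .registry_fields, drop = FALSE]
  for (f in .registry_bool_fields) out[[f]] <- as.integer(out[[f]])
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive the risk-direction-coded model covariates
#'
#' Maps registry records to the 11 covariates of the logistic model. Each
#' boolean covariate is the logical negation of the corresponding favourable
#' registry field (e.g. `no_prehospital_rosc = !prehospital_rosc`), so that
#' a value of 1 always codes the risk direction; age and the two times are
#' carried over unchanged (per year, per minute).
#'
#' @param records A registry data frame (see [registry_fields()]).
#' @return A data frame with the columns of [predictor_names()], one row per
#'   record, in record order.
#' @export
to_predictors <- function(records) {
  stopifnot(is.data.frame(records))
  out <- lapply(.predictor_map, function(m) {
    v <- records[[m$field]]
    if (is.null(v)) stop("missing registry field: ", m$field, call. = FALSE)
    if (m$negate) !as.logical(v) else v
  })
  as.data.frame(out, optional = TRUE)
}

#' Numeric design matrix of the model covariates
#'
#' @param records A registry data frame.
#' @return A numeric matrix (0/1 for the boolean covariates) with one column
#'   per entry of [predictor_names()].
#' @export
predictor_matrix <- function(records) {
  p <- to_predictors(records)
  m <- vapply(p, as.numeric, numeric(nrow(p)))
  if (nrow(p) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(p)))
  m
}

#' Derive the one-month outcome labels
#'
#' @param records A registry data frame.
#' @return A data frame with `death_1m` (no survival at one month) and
#'   `unfavorable_1m` (Cerebral Performance Category 3, 4 or 5). Death
#'   always implies an unfavorable outcome since CPC 5 is death.
#' @export
to_outcomes <- function(records) {
  stopifnot(is.data.frame(records))
  data.frame(
    death_1m = !as.logical(records$one_month_survival),
    unfavorable_1m = records$cpc >= 3
  )
}

#' Split a cohort into development and validation periods
#'
#' Assigns each record to the development or validation group by calendar
#' year; records in neither set are dropped with a message reporting the
#' count.
#'
#' @param records A registry data frame.
#' @param dev_years Integer vector of development-period years.
#' @param val_years Integer vector of validation-period years; must be
#'   disjoint from `dev_years`.
#' @return A list with elements `development`, `validation` (data frames)
#'   and `n_dropped` (integer).
#' @export
split_by_period <- function(records, dev_years = 2005:2008,
                            val_years = 2009) {
  if (length(intersect(dev_years, val_years)) > 0L) {
    stop("development and validation year sets overlap: ",
         paste(intersect(dev_years, val_years), collapse = ", "),
         call. = FALSE)
  }
  in_dev <- records$year %in% dev_years
  in_val <- records$year %in% val_years
  n_dropped <- sum(!in_dev & !in_val)
  if (n_dropped > 0L) {
    message("split_by_period: dropping ", n_dropped,
            " record(s) outside both periods")
  }
  list(
    development = records[in_dev, , drop = FALSE],
    validation  = records[in_val, , drop = FALSE],
    n_dropped   = n_dropped
  )
}
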