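# Maximum-likelihood logistic regression via iteratively reweighted least
# squares with step-halving, and crude/adjusted odds-ratio tables with
# Wald confidence intervals on the log scale.

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of `P(y = 1) = plogis(x beta)`. Each IRLS step is
#' a Newton step on the log-likelihood; if a step does not increase the
#' log-likelihood it is halved (up to 30 times), so the likelihood ascends
#' monotonically. Convergence is declared when the score (gradient) norm
#' falls below `tol` times the effective sample size `max(1, sum(w))`,
#' where `w` are the IRLS weights; the raw score scales with n, so an
#' unscaled absolute tolerance would be unattainable in floating point on
#' large cohorts.
#'
#' The variance-covariance matrix is the inverse observed Fisher
#' information at the optimum. Perfect separation (coefficients diverging
#' beyond 30 on the log-odds scale, fitted probabilities pinned at 0/1) and
#' rank-deficient designs raise explicit errors.
#'
#' @param x Numeric design matrix, including an intercept column if one is
#'   wanted (see [odds_ratio_table()] for the usual front end).
#' @param y Outcome vector: logical or 0/1, one per row of `x`.
#' @param tol Convergence tolerance on the scaled score norm.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `tor_logit` with components `coefficients`,
#'   `vcov`, `converged`, `iterations`, `log_likelihood`, `ll_trace`,
#'   `fitted`, `y`, `n`.
#' @examples
#' x <- cbind(1, c(rep(1, 50), rep(0, 50)))
#' y <- c(rep(1, 40), rep(0, 10), rep(1, 20), rep(0, 30))
#' exp(coef(fit_logistic(x, y))[2])  # 2x2 cross-product odds ratio: 6
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 50L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) {
    stop("design matrix rows and outcome length differ", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (is.null(colnames(x))) {
    colnames(x) <- c("(Intercept)", paste0("x", seq_len(ncol(x) - 1L)))[seq_len(ncol(x))]
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    dropped <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop("rank-deficient design: collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  p <- ncol(x)
  beta <- numeric(p)
  loglik <- function(b) {
    eta <- drop(x %*% b)
    # numerically stable log(1 + exp(eta))
    sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
  }
  ll <- loglik(beta)
  ll_trace <- ll
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(x, y - mu))
    info <- crossprod(x, x * w)
    scale <- max(1, sum(w))
    if (sqrt(sum(score^2)) < tol * scale) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(info, score), error = function(e) {
      stop("separation detected: Fisher information is numerically singular",
           call. = FALSE)
    })
    # step-halving guarantees likelihood ascent
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 2^-30) {
        stop("IRLS step-halving failed to increase the likelihood",
             call. = FALSE)
      }
    }
    beta <- cand
    ll <- ll_new
    ll_trace <- c(ll_trace, ll)
    if (max(abs(beta)) > 30) {
      stop("separation detected: coefficient diverging beyond 30 on the ",
           "log-odds scale", call. = FALSE)
    }
    if (iter >= max_iter) break
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(x, x * (mu * (1 - mu)))
  vc <- solve(info)
  dimnames(vc) <- list(colnames(x), colnames(x))
  structure(list(
    coefficients = stats::setNames(beta, colnames(x)),
    vcov = vc,
    converged = converged,
    iterations = iter,
    log_likelihood = ll,
    ll_trace = ll_trace,
    fitted = mu,
    y = y,
    n = length(y)
  ), class = "tor_logit")
}

#' @export
coef.tor_logit <- function(object, ...) object$coefficients

#' @export
vcov.tor_logit <- function(object, ...) object$vcov

#' @export
logLik.tor_logit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
residuals.tor_logit <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted
  if (type == "pearson") {
    (y - mu) / sqrt(mu * (1 - mu))
  } else {
    sign(y - mu) * sqrt(-2 * (y * log(mu) + (1 - y) * log(1 - mu)))
  }
}

#' @export
predict.tor_logit <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- stats::qlogis(object$fitted)
  } else {
    newdata <- as.matrix(newdata)
    eta <- drop(newdata %*% object$coefficients)
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
print.tor_logit <- function(x, ...) {
  cat("Logistic regression (IRLS), n =", x$n, "\n")
  cat("Converged:", x$converged, "in", x$iterations, "iterations;",
      "log-likelihood", format(x$log_likelihood), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.tor_logit <- function(object, conf = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  b <- object$coefficients
  tab <- data.frame(
    estimate = b, se = se, z = b / se,
    p = 2 * stats::pnorm(-abs(b / se)),
    or = exp(b), or_low = exp(b - z * se), or_high = exp(b + z * se)
  )
  structure(list(table = tab, conf = conf, fit = object),
            class = "summary.tor_logit")
}

#' @export
print.summary.tor_logit <- function(x, ...) {
  cat("Logistic regression (IRLS), n =", x$fit$n, "\n\n")
  print(round(x$table, 4))
  invisible(x)
}

# closed-form 2x2 crude OR (exposed/unexposed x event/non-event)
.crude_or_2x2 <- function(exposed, event, conf) {
  a <- sum(exposed & event);  b <- sum(exposed & !event)
  cc <- sum(!exposed & event); d <- sum(!exposed & !event)
  if (min(a, b, cc, d) == 0L) return(NULL)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lor <- log(a) + log(d) - log(b) - log(cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  c(or = exp(lor), low = exp(lor - z * se), high = exp(lor + z * se))
}

#' Crude and adjusted odds-ratio table for the 11 model covariates
#'
#' For each of the 11 risk-coded covariates, computes the crude (univariate)
#' odds ratio — the 2x2 cross-product ratio for binary covariates, a
#' univariate per-unit logistic fit for age and the times — and the
#' adjusted odds ratio from the joint 11-covariate logistic model.
#' Confidence intervals are Wald intervals on the log-odds scale,
#' `exp(coefficient +/- z SE)`.
#'
#' A binary covariate with an empty 2x2 cell has no finite crude
#' maximum-likelihood estimate; it is reported as `NA` with a separation
#' warning rather than silently continuity-corrected.
#'
#' @param records A registry data frame.
#' @param outcome `"death"` (one-month death) or `"unfavorable"`
#'   (CPC 3-5 at one month).
#' @param conf Confidence level for the Wald intervals.
#' @param tol,max_iter Passed to [fit_logistic()].
#' @return An object of class `or_table`: a data frame with one row per
#'   covariate in model order and columns `variable`, `crude_or`,
#'   `crude_low`, `crude_high`, `adjusted_or`, `adjusted_low`,
#'   `adjusted_high`.
#' @export
odds_ratio_table <- function(records, outcome = c("death", "unfavorable"),
                             conf = 0.95, tol = 1e-8, max_iter = 50L) {
  outcome <- match.arg(outcome)
  X <- predictor_matrix(records)
  oc <- to_outcomes(records)
  y <- if (outcome == "death") oc$death_1m else oc$unfavorable_1m
  if (sum(y) == 0L || sum(!y) == 0L) {
    stop("outcome has a single class; odds ratios are undefined",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)

  crude <- matrix(NA_real_, nrow = length(.predictor_fields), ncol = 3,
                  dimnames = list(.predictor_fields, c("or", "low", "high")))
  for (v in .predictor_fields) {
    if (v %in% .binary_predictor_fields) {
      res <- .crude_or_2x2(X[, v] == 1, y, conf)
      if (is.null(res)) {
        res <- tryCatch({
          f <- fit_logistic(cbind("(Intercept)" = 1, X[, v, drop = FALSE]),
                            y, tol = tol, max_iter = max_iter)
          se <- sqrt(diag(f$vcov))[2]
          b <- coef(f)[2]
          c(or = exp(b), low = exp(b - z * se), high = exp(b + z * se))
        }, error = function(e) {
          warning("crude OR for '", v, "' is undefined (zero 2x2 cell / ",
                  "separation); reported as NA", call. = FALSE)
          c(or = NA_real_, low = NA_real_, high = NA_real_)
        })
      }
    } else {
      f <- fit_logistic(cbind("(Intercept)" = 1, X[, v, drop = FALSE]),
                        y, tol = tol, max_iter = max_iter)
      se <- sqrt(diag(f$vcov))[2]
      b <- coef(f)[2]
      res <- c(or = exp(b), low = exp(b - z * se), high = exp(b + z * se))
    }
    crude[v, ] <- res
  }

  joint <- fit_logistic(cbind("(Intercept)" = 1, X), y,
                        tol = tol, max_iter = max_iter)
  b <- coef(joint)[.predictor_fields]
  se <- sqrt(diag(joint$vcov))[.predictor_fields]
  out <- data.frame(
    variable = .predictor_fields,
    crude_or = crude[, "or"], crude_low = crude[, "low"],
    crude_high = crude[, "high"],
    adjusted_or = exp(b), adjusted_low = exp(b - z * se),
    adjusted_high = exp(b + z * se),
    row.names = NULL
  )
  structure(out, class = c("or_table", "data.frame"),
            outcome = outcome, conf = conf, fit = joint)
}

#' Construct an odds-ratio table from known values
#'
#' Builds an `or_table` directly from supplied odds ratios (for example a
#' published regression table), so rule selection can run on aggregate
#' inputs without per-record data.
#'
#' @param variable Covariate names (must be model covariates).
#' @param adjusted_or Adjusted odds ratios.
#' @param adjusted_low,adjusted_high Optional CI bounds.
#' @param crude_or,crude_low,crude_high Optional crude columns.
#' @return An `or_table` data frame.
#' @export
or_table <- function(variable, adjusted_or, adjusted_low = NA_real_,
                     adjusted_high = NA_real_, crude_or = NA_real_,
                     crude_low = NA_real_, crude_high = NA_real_) {
  bad <- setdiff(variable, .predictor_fields)
  if (length(bad) > 0L) {
    stop("unknown model covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(variable = variable, crude_or = crude_or,
                    crude_low = crude_low, crude_high = crude_high,
                    adjusted_or = adjusted_or, adjusted_low = adjusted_low,
                    adjusted_high = adjusted_high, row.names = NULL)
  structure(out, class = c("or_table", "data.frame"))
}

#' @export
print.or_table <- function(x, digits = 3, ...) {
  fmt <- function(or, lo, hi) {
    ifelse(is.na(or), "undefined",
           sprintf("%s (%s to %s)", signif(or, digits),
                   signif(lo, digits), signif(hi, digits)))
  }
  oc <- attr(x, "outcome")
  cat("Odds ratios", if (!is.null(oc)) paste0(" (outcome: ", oc, ")"),
      "\n", sep = "")
  df <- data.frame(
    variable = x$variable,
    crude = fmt(x$crude_or, x$crude_low, x$crude_high),
    adjusted = fmt(x$adjusted_or, x$adjusted_low, x$adjusted_high)
  )
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
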