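test_that("contingency counts match a per-record brute-force recount", {
  ed <- ed_tor_rule()
  for (seed in c(4, 14)) {
    cohort <- small_cohort(n = 400, seed = seed)
    tab <- contingency(ed, cohort, "death")
    # brute force: loop over records
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_len(nrow(cohort))) {
      f <- apply_rule(ed, cohort[i, ])
      d <- !cohort$one_month_survival[i]
      if (f && d) tp <- tp + 1L else if (f) fp <- fp + 1L
      else if (d) fn <- fn + 1L else tn <- tn + 1L
    }
    expect_identical(unlist(tab[c("tp", "fp", "fn", "tn")]),
                     c(tp = tp, fp = fp, fn = fn, tn = tn))
    expect_identical(tab$tp + tab$fp + tab$fn + tab$tn, nrow(cohort))
  }
})

test_that("a four-record cohort populates each contingency cell once", {
  recs <- make_records(
    make_record("fd", prehospital_rosc = FALSE, shockable_initial_rhythm = FALSE,
                witnessed_by_bystander = FALSE, one_month_survival = FALSE, cpc = 5),
    make_record("fa", prehospital_rosc = FALSE, shockable_initial_rhythm = FALSE,
                witnessed_by_bystander = FALSE, one_month_survival = TRUE, cpc = 2),
    make_record("nd", one_month_survival = FALSE, cpc = 5),
    make_record("na", one_month_survival = TRUE, cpc = 1)
  )
  tab <- contingency(ed_tor_rule(), recs, "death")
  expect_identical(unlist(tab[c("tp", "fp", "fn", "tn")]),
                   c(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
})

test_that("degenerate tables surface undefined metrics, never silent zeros", {
  none_fulfilled <- contingency_table(tp = 0, fp = 0, fn = 5, tn = 5)
  expect_message(d <- diagnostic_metrics(none_fulfilled), "undefined.*ppv")
  expect_true("ppv" %in% d$undefined)
  expect_true(is.na(d$metrics$estimate[d$metrics$metric == "ppv"]))
  expect_message(expect_true(is.na(misclassification_rate(none_fulfilled))),
                 "no patient fulfills")
  expect_error(contingency_table(-1, 0, 0, 0), "non-negative")

  perfect <- diagnostic_metrics(contingency_table(10, 0, 0, 10))
  expect_equal(perfect$metrics$estimate, rep(1, 4))
})

test_that("misclassification is one minus PPV on arbitrary tables", {
  set.seed(5)
  for (i in 1:20) {
    cts <- rpois(4, 40) + 1L
    tab <- contingency_table(cts[1], cts[2], cts[3], cts[4])
    d <- diagnostic_metrics(tab)
    ppv <- d$metrics$estimate[d$metrics$metric == "ppv"]
    expect_equal(misclassification_rate(tab), 1 - ppv, tolerance = 1e-12)
    expect_equal(d$misclassification, 1 - ppv, tolerance = 1e-12)
  }
  expect_equal(misclassification_rate(contingency_table(10, 0, 3, 4)), 0)
})

test_that("predictive values, sensitivity and prevalence obey the odds identity", {
  set.seed(6)
  for (i in 1:20) {
    cts <- rpois(4, 25) + 1L
    d <- diagnostic_metrics(contingency_table(cts[1], cts[2], cts[3], cts[4]))
    g <- function(nm) d$metrics$estimate[d$metrics$metric == nm]
    prev <- (cts[1] + cts[3]) / sum(cts)
    lhs <- g("ppv") / (1 - g("ppv"))
    rhs <- g("sensitivity") / (1 - g("specificity")) * prev / (1 - prev)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("Wilson interval: bounds, boundaries and the registry exemplar", {
  ci <- wilson_interval(4113, 4555)
  expect_equal(unname(round(ci, 3)), c(0.894, 0.911))
  expect_identical(unname(wilson_interval(0, 50)[1]), 0)
  expect_lt(wilson_interval(50, 50)[1], 1)
  expect_identical(unname(wilson_interval(50, 50)[2]), 1)
  expect_error(wilson_interval(1, 0), "n > 0")
  expect_error(wilson_interval(5, 3), "0..n")
  set.seed(30)
  for (i in 1:50) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    ci <- wilson_interval(x, n)
    expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] <= x / n && x / n <= ci[2])
  }
})

test_that("Wilson interval coverage is near nominal at n = 500, p = 0.9", {
  # exact coverage by enumerating the binomial distribution
  n <- 500; p <- 0.9
  covered <- vapply(0:n, function(x) {
    ci <- wilson_interval(x, n)
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  coverage <- sum(dbinom(0:n, n, p)[covered])
  expect_gt(coverage, 0.93)
  expect_lt(coverage, 0.97)
})

test_that("criteria-count AUC equals all-pairs enumeration on a small cohort", {
  recs <- do.call(make_records, lapply(1:10, function(i) {
    make_record(patient_id = paste0("p", i),
                prehospital_rosc = i %% 2 == 0,
                shockable_initial_rhythm = i %% 3 == 0,
                witnessed_by_bystander = i %% 4 == 0,
                one_month_survival = i > 6, cpc = if (i > 6) 2L else 5L)
  }))
  ed <- ed_tor_rule()
  res <- roc_auc(recs, ed, "death")
  score <- criteria_count(ed, recs)
  dead <- !recs$one_month_survival
  pairs <- expand.grid(pos = which(dead), neg = which(!dead))
  auc_brute <- mean(ifelse(score[pairs$pos] > score[pairs$neg], 1,
                           ifelse(score[pairs$pos] == score[pairs$neg], 0.5, 0)))
  expect_equal(res$auc, auc_brute, tolerance = 1e-12)
  expect_true(res$low <= res$auc && res$auc <= res$high)
})

test_that("AUC sits at 0.5 for uninformative scores and 1 for separating ones", {
  set.seed(44)
  n <- 4000
  recs <- small_cohort(n = n, seed = 44)
  # scramble outcomes so the score is independent of death
  recs$one_month_survival <- sample(recs$one_month_survival)
  recs$cpc <- ifelse(recs$one_month_survival, 1L, 5L)
  res <- roc_auc(recs, ed_tor_rule(), "death")
  expect_equal(res$auc, 0.5, tolerance = 0.03)

  sep <- make_records(
    make_record("d", prehospital_rosc = FALSE, shockable_initial_rhythm = FALSE,
                witnessed_by_bystander = FALSE, one_month_survival = FALSE, cpc = 5),
    make_record("a", one_month_survival = TRUE, cpc = 1)
  )
  expect_equal(roc_auc(sep, ed_tor_rule(), "death")$auc, 1.0)

  all_dead <- sep[1, ]
  expect_error(roc_auc(all_dead, ed_tor_rule(), "death"), "both outcome classes")
})

test_that("one-point ROC identity: binary-rule AUC is (sensitivity + specificity) / 2", {
  cohort <- small_cohort(n = 2500, seed = 61)
  one_crit <- tor_rule("single", "no_prehospital_rosc")
  res <- roc_auc(cohort, one_crit, "death")
  d <- diagnostic_metrics(contingency(one_crit, cohort, "death"))
  g <- function(nm) d$metrics$estimate[d$metrics$metric == nm]
  expect_equal(res$auc, (g("sensitivity") + g("specificity")) / 2,
               tolerance = 1e-12)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  cohort <- small_cohort(n = 3000, seed = 23)
  ed <- ed_tor_rule()
  res <- roc_auc(cohort, ed, "death")
  score <- criteria_count(ed, cohort)
  ref <- pROC::auc(pROC::roc(!cohort$one_month_survival, score,
                             direction = "<", quiet = TRUE))
  expect_equal(res$auc, as.numeric(ref), tolerance = 1e-10)
})
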