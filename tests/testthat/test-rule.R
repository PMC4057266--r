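test_that("OR > 2 on the published death model selects the three-criterion rule", {
  sel <- select_criteria(published_or_table("death"), threshold = 2.0)
  expect_identical(sel, c("no_prehospital_rosc", "unshockable_initial_rhythm",
                          "unwitnessed_by_bystander"))
})

test_that("lowering the threshold to 1.5 adds two criteria in OR order", {
  sel <- select_criteria(published_or_table("death"), threshold = 1.5)
  expect_identical(sel, c("no_prehospital_rosc", "unshockable_initial_rhythm",
                          "unwitnessed_by_bystander", "unwitnessed_by_ems",
                          "no_prehospital_defibrillation"))
})

test_that("selection is strict, binary-only, and errors when empty", {
  expect_error(select_criteria(published_or_table("death"), threshold = 100),
               "no criteria selected")
  # tie at the threshold is excluded ("strictly greater")
  tied <- or_table(variable = c("no_prehospital_rosc", "unwitnessed_by_ems"),
                   adjusted_or = c(2.0, 3.0))
  expect_identical(select_criteria(tied, 2.0), "unwitnessed_by_ems")
  # continuous covariates are never candidates, however large their OR
  cont <- or_table(variable = c("call_to_response_min", "no_prehospital_rosc"),
                   adjusted_or = c(50, 3))
  expect_identical(select_criteria(cont, 2.0), "no_prehospital_rosc")
})

test_that("rule construction validates its criteria", {
  expect_error(tor_rule("x", character(0)), "at least one")
  expect_error(tor_rule("x", "age"), "binary")
  expect_error(tor_rule("x", "not_a_field"), "invalid rule criterion")
  expect_error(or_table("not_a_field", 3), "unknown model covariate")
})

test_that("rule application is a conjunction; count agrees with fulfillment", {
  ed <- ed_tor_rule()
  fulfilled <- make_record(prehospital_rosc = FALSE,
                           shockable_initial_rhythm = FALSE,
                           witnessed_by_bystander = FALSE,
                           one_month_survival = FALSE, cpc = 5)
  expect_true(apply_rule(ed, fulfilled))
  expect_identical(criteria_count(ed, fulfilled), 3L)

  with_rosc <- make_record(prehospital_rosc = TRUE,
                           shockable_initial_rhythm = FALSE,
                           witnessed_by_bystander = FALSE)
  expect_false(apply_rule(ed, with_rosc))

  only_unshockable <- make_record(prehospital_rosc = TRUE,
                                  shockable_initial_rhythm = FALSE,
                                  witnessed_by_bystander = TRUE)
  expect_identical(criteria_count(ed, only_unshockable), 1L)
  none <- make_record()
  expect_identical(criteria_count(ed, none), 0L)

  p <- to_predictors(fulfilled)
  expect_error(apply_rule(ed, p[, setdiff(names(p), "no_prehospital_rosc")]),
               "unknown rule criterion")
})

test_that("the BLS comparator rule uses EMS witness, shock and ROSC", {
  bls <- bls_tor_rule()
  expect_setequal(bls$criteria, c("unwitnessed_by_ems",
                                  "no_prehospital_defibrillation",
                                  "no_prehospital_rosc"))
  ems_witnessed <- make_record(witnessed_by_ems = TRUE,
                               prehospital_defibrillation = FALSE,
                               prehospital_rosc = FALSE)
  expect_false(apply_rule(bls, ems_witnessed))
  bls_positive <- make_record(witnessed_by_ems = FALSE,
                              prehospital_defibrillation = FALSE,
                              prehospital_rosc = FALSE)
  expect_true(apply_rule(bls, bls_positive))
})

test_that("the two rules can disagree: shocked, EMS-witnessed, ED-rule-positive", {
  rec <- make_record(prehospital_rosc = FALSE,
                     shockable_initial_rhythm = FALSE,  # rhythm recorded unshockable
                     prehospital_defibrillation = TRUE, # but a shock was delivered
                     witnessed_by_bystander = FALSE, witnessed_by_ems = TRUE)
  expect_true(apply_rule(ed_tor_rule(), rec))
  expect_false(apply_rule(bls_tor_rule(), rec))
})

test_that("count equals the criteria total exactly when the rule is fulfilled", {
  # enumerate all combinations of the five criteria underlying both rules
  crits <- union(ed_tor_rule()$criteria, bls_tor_rule()$criteria)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(crits)))
  names(combos) <- crits
  recs <- do.call(make_records, lapply(seq_len(nrow(combos)), function(i) {
    make_record(patient_id = paste0("c", i),
                prehospital_rosc = !combos$no_prehospital_rosc[i],
                shockable_initial_rhythm = !combos$unshockable_initial_rhythm[i],
                witnessed_by_bystander = !combos$unwitnessed_by_bystander[i],
                witnessed_by_ems = !combos$unwitnessed_by_ems[i],
                prehospital_defibrillation = !combos$no_prehospital_defibrillation[i])
  }))
  for (rule in list(ed_tor_rule(), bls_tor_rule())) {
    cnt <- criteria_count(rule, recs)
    expect_identical(apply_rule(rule, recs), cnt == length(rule$criteria))
    # brute-force count over the combination grid
    expected <- rowSums(combos[, rule$criteria])
    expect_identical(cnt, as.integer(expected))
  }
})

test_that("adding a criterion never enlarges the fulfilled set", {
  cohort <- small_cohort(n = 3000, seed = 19)
  base <- tor_rule("base", c("no_prehospital_rosc"))
  grown <- tor_rule("grown", c("no_prehospital_rosc",
                               "unshockable_initial_rhythm"))
  grown2 <- tor_rule("grown2", c("no_prehospital_rosc",
                                 "unshockable_initial_rhythm",
                                 "unwitnessed_by_bystander"))
  f0 <- apply_rule(base, cohort)
  f1 <- apply_rule(grown, cohort)
  f2 <- apply_rule(grown2, cohort)
  expect_true(all(f1 <= f0))
  expect_true(all(f2 <= f1))

  sens_spec <- function(rule) {
    m <- diagnostic_metrics(contingency(rule, cohort, "death"))$metrics
    c(sens = m$estimate[m$metric == "sensitivity"],
      spec = m$estimate[m$metric == "specificity"])
  }
  s0 <- sens_spec(base); s1 <- sens_spec(grown); s2 <- sens_spec(grown2)
  expect_true(s1["sens"] <= s0["sens"] && s2["sens"] <= s1["sens"])
  expect_true(s1["spec"] >= s0["spec"] && s2["spec"] >= s1["spec"])
})
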