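# Hand-built registry records for small deterministic fixtures.
# Defaults describe an eligible arrest that fulfills neither rule.
make_record <- function(patient_id = "P1", year = 2009L, age = 70L,
                        male = TRUE, witnessed_by_bystander = TRUE,
                        witnessed_by_ems = FALSE, bystander_cpr = TRUE,
                        cardiac_etiology = TRUE,
                        shockable_initial_rhythm = TRUE,
                        prehospital_defibrillation = TRUE,
                        call_to_response_min = 7,
                        call_to_hospital_min = 30,
                        prehospital_rosc = TRUE,
                        one_month_survival = TRUE, cpc = 1L) {
  data.frame(patient_id = patient_id, year = year, age = age, male = male,
             witnessed_by_bystander = witnessed_by_bystander,
             witnessed_by_ems = witnessed_by_ems,
             bystander_cpr = bystander_cpr,
             cardiac_etiology = cardiac_etiology,
             shockable_initial_rhythm = shockable_initial_rhythm,
             prehospital_defibrillation = prehospital_defibrillation,
             call_to_response_min = call_to_response_min,
             call_to_hospital_min = call_to_hospital_min,
             prehospital_rosc = prehospital_rosc,
             one_month_survival = one_month_survival, cpc = cpc,
             stringsAsFactors = FALSE)
}

make_records <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# small seeded synthetic cohort shared across tests
small_cohort <- function(n = 2000, seed = 42, ...) {
  cfg <- generator_config(n = n, seed = seed, ...)
  suppressMessages(generate_records(cfg))
}
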