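test_that("eligibility removes the young and the baseline-impaired", {
  co <- mk_cohort(
    mk_quiet_resident("R1", 3),                      # eligible
    mk_quiet_resident("R2", 3, age = 60),            # too young
    mk_quiet_resident("R3", 3, adl = 6),             # physically impaired
    mk_quiet_resident("R4", 3, cps = 5),             # cognitively impaired
    mk_quiet_resident("R5", 3, cps = 6))             # comatose
  phys <- apply_eligibility(co, "physical")
  expect_setequal(unique(phys$table$resident_id), c("R1", "R4", "R5"))
  cog <- apply_eligibility(co, "cognitive")
  expect_setequal(unique(cog$table$resident_id), c("R1", "R3"))
  mort <- apply_eligibility(co, "mortality")
  expect_setequal(unique(mort$table$resident_id),
                  c("R1", "R3", "R4", "R5"))

  rep <- phys$report
  expect_equal(rep$n_input, 5)
  expect_equal(rep$n_excluded_age, 1)
  expect_equal(rep$n_excluded_prior_impairment_physical, 1)
  expect_equal(rep$n_excluded_prior_impairment_cognitive, 2)
  expect_equal(rep$n_at_risk_physical, 3)
  expect_equal(rep$n_at_risk_cognitive, 2)
})

test_that("eligibility arithmetic is subtraction from the input count", {
  rep <- eligibility_report(1000, 10, 30, 90)
  expect_equal(rep$n_at_risk_physical, 960)
  expect_equal(rep$n_at_risk_cognitive, 900)
  expect_error(eligibility_report(10, -1, 0, 0), "nonnegative")
})

test_that("residents without an admission assessment are rejected", {
  co <- rbind(mk_quiet_resident("R1", 3),
              mk_row("R2", 1), mk_row("R2", 2))
  expect_error(apply_eligibility(co, "mortality"), "R2")
})

test_that("empty input yields an empty report", {
  co <- mk_quiet_resident("R1", 2)[0, ]
  out <- apply_eligibility(co, "physical")
  expect_equal(nrow(out$table), 0)
  expect_equal(out$report$n_input, 0)
  expect_equal(out$report$n_at_risk_physical, 0)
})

test_that("the permanence rule finds the first crossing never reversed", {
  r1 <- detect_permanent_impairment(c(4, 5, 6, 6, 6), "adl_eq_6")
  expect_equal(r1$onset_index, 3)
  expect_true(r1$permanent)

  ## the first crossing is reversed by an improvement; the re-crossing counts
  r2 <- detect_permanent_impairment(c(4, 6, 5, 6, 6), "adl_eq_6")
  expect_equal(r2$onset_index, 4)
  expect_true(r2$permanent)

  r3 <- detect_permanent_impairment(c(3, 4, 4), "cps_ge_5")
  expect_true(is.na(r3$onset_index))
  expect_false(r3$permanent)

  ## CPS threshold is >= 5
  r4 <- detect_permanent_impairment(c(3, 5, 6, 5), "cps_ge_5")
  expect_equal(r4$onset_index, 2)

  expect_error(detect_permanent_impairment(c(2, 7), "adl_eq_6"), "0..6")
  expect_error(detect_permanent_impairment(integer(0), "adl_eq_6"), "empty")
})

test_that("a final-observation crossing is permanent unless confirmation is required", {
  lax <- detect_permanent_impairment(c(4, 5, 6), "adl_eq_6")
  expect_equal(lax$onset_index, 3)
  strict <- detect_permanent_impairment(c(4, 5, 6), "adl_eq_6",
                                        require_confirmation = TRUE)
  expect_false(strict$permanent)
  confirmed <- detect_permanent_impairment(c(4, 6, 6), "adl_eq_6",
                                           require_confirmation = TRUE)
  expect_equal(confirmed$onset_index, 2)
})

test_that("events are attributed to the exposure window preceding the outcome window", {
  ## transfer in period 0 (day 50), death in period 1 (day 150): the k = 0
  ## row is exposed and carries the death event
  co <- rbind(mk_row("R1", 0, transfer = 1),
              mk_row("R1", 1, died = 1))
  pp <- build_person_periods(co, "mortality")
  expect_equal(nrow(pp), 1)
  expect_equal(pp$exposed, 1)
  expect_equal(pp$event_code, "death")
  expect_equal(pp$event, 1)
  expect_equal(c(pp$start, pp$stop), c(0, 92))

  ## no transfers, administratively censored: 20 unexposed rows
  co2 <- mk_quiet_resident("R2", 20)
  pp2 <- build_person_periods(co2, "mortality")
  expect_equal(nrow(pp2), 20)
  expect_true(all(pp2$exposed == 0))
  expect_equal(pp2$event_code[20], "censored")
  expect_equal(pp2$censor_reason[20], "administrative")

  ## discharged in period 1 without return: censored at that period's end
  co3 <- rbind(mk_row("R3", 0), mk_row("R3", 1, disch = 1))
  pp3 <- build_person_periods(co3, "mortality")
  expect_equal(nrow(pp3), 2)
  expect_equal(pp3$event_code[2], "censored")
  expect_equal(pp3$censor_reason[2], "discharge")
})

test_that("impairment onset truncates follow-up and respects competing death", {
  ## ADL hits 6 at the period-2 assessment: onset window 2, event on row 1
  co <- rbind(mk_row("R1", 0, adl = 4, transfer = 1),
              mk_row("R1", 1, adl = 5, transfer = 1),
              mk_row("R1", 2, adl = 6),
              mk_row("R1", 3, adl = 6, died = 1))
  pp <- build_person_periods(co, "physical")
  expect_equal(nrow(pp), 2)
  expect_equal(pp$event_code[2], "physical_impairment")

  ## mortality analysis keeps the impairment path and runs to the death
  ppm <- build_person_periods(co, "mortality")
  expect_equal(nrow(ppm), 3)
  expect_equal(ppm$event_code[3], "death")

  ## death before any crossing is a competing terminal event
  co2 <- rbind(mk_row("R2", 0, adl = 4), mk_row("R2", 1, adl = 5, died = 1))
  pp2 <- build_person_periods(co2, "physical")
  expect_equal(pp2$event_code[nrow(pp2)], "death")
  expect_equal(pp2$event[nrow(pp2)], 0)

  ## same-window tie: impairment precedence by default, switchable
  co3 <- rbind(mk_row("R3", 0, adl = 5), mk_row("R3", 1, adl = 6, died = 1))
  tie1 <- build_person_periods(co3, "physical")
  expect_equal(tie1$event_code[nrow(tie1)], "physical_impairment")
  tie2 <- build_person_periods(co3, "physical", impairment_precedence = FALSE)
  expect_equal(tie2$event_code[nrow(tie2)], "death")
})

test_that("non-contiguous period indices are rejected", {
  co <- rbind(mk_row("R1", 0), mk_row("R1", 2))
  expect_error(build_person_periods(co, "mortality"), "non-contiguous")
})

test_that("person-time is conserved and terminal rows are unique", {
  sim <- simulate_cohort(ltc_sim_config(n_homes = 4,
                                        residents_per_home = 60, seed = 13))
  for (oc in c("physical", "cognitive", "mortality")) {
    el <- apply_eligibility(sim$cohort, oc)
    pp <- build_person_periods(el$table, oc)
    expect_true(all(pp$stop - pp$start == 92))
    expect_equal(sum(pp$stop - pp$start), 92 * nrow(pp))
    expect_equal(person_years(pp), 92 * nrow(pp) / 365.25)
    terminal <- pp$event_code != "none"
    expect_equal(sum(terminal), length(unique(pp$resident_id)))
    last <- !duplicated(pp$resident_id, fromLast = TRUE)
    expect_true(all(terminal == last))
  }
})

test_that("construction matches an independent per-resident rule scanner", {
  for (seed in c(3, 17)) {
    sim <- simulate_cohort(ltc_sim_config(n_homes = 2,
                                          residents_per_home = 5,
                                          seed = seed))
    for (oc in c("physical", "cognitive", "mortality")) {
      el <- apply_eligibility(sim$cohort, oc)
      pp <- build_person_periods(el$table, oc)
      want <- oracle_person_periods(el$table, oc)
      got <- pp_signature(pp)
      expect_equal(got$n_rows, want$n_rows, info = oc)
      expect_equal(got$terminal, want$terminal, info = oc)
      expect_equal(got$exposure,
                   substr(want$exposure, 1, nchar(got$exposure)), info = oc)
    }
  }
})

test_that("tightening the age threshold never increases at-risk counts", {
  sim <- simulate_cohort(ltc_sim_config(n_homes = 3,
                                        residents_per_home = 50, seed = 23))
  base <- apply_eligibility(sim$cohort, "physical")$report
  older <- sim$cohort
  keep <- unique(older$resident_id[older$period_index == 0 &
                                     older$age_at_admission >= 75])
  stricter <- apply_eligibility(older[older$resident_id %in% keep, ],
                                "physical")$report
  expect_lte(stricter$n_at_risk_physical, base$n_at_risk_physical)
})
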