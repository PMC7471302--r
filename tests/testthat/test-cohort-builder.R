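wwindow <- c("2006-01-01", "2015-12-31")
wwash <- c("2002-01-01", "2005-12-31")

test_that("the six-patient toy table exercises every exclusion once", {
  toy <- toy_claims_six()
  cohort <- build_cohort(toy$claims, toy$demographics,
                         window = wwindow, washout = wwash)
  ledger <- cohort$ledger
  expect_equal(unname(ledger["candidates"]), 6L)
  expect_equal(unname(ledger["prevalent_washout"]), 1L)
  expect_equal(unname(ledger["no_hospitalization"]), 1L)
  expect_equal(unname(ledger["no_imaging"]), 1L)
  expect_equal(unname(ledger["inaccurate_age"]), 1L)
  expect_equal(unname(ledger["inconsistent_dx"]), 1L)
  expect_equal(unname(ledger["retained"]), 1L)
  expect_equal(cohort$patients$patient_id, "F")
  expect_equal(cohort$patients$subtype, "CI")
  expect_equal(cohort$patients$event, 1L)
})

test_that("an empty claims table yields an empty cohort and zero ledger", {
  toy <- toy_claims_six()
  cohort <- build_cohort(toy$claims[0, ], toy$demographics,
                         window = wwindow, washout = wwash)
  expect_equal(nrow(cohort$patients), 0L)
  expect_true(all(cohort$ledger == 0L))
})

test_that("ledger conservation holds on synthetic cohorts", {
  lt <- study_lt()
  scen <- synthetic_scenario(seed = 31, n_patients = 250,
                             washout_noise_rate = 0.25,
                             nonhosp_rate = 0.3, no_imaging_rate = 0.1)
  sim <- generate_cohort(scen, lt)
  cohort <- build_cohort(sim, window = c(scen$admin_start, scen$admin_end))
  l <- cohort$ledger
  expect_equal(unname(l["candidates"]),
               unname(l["retained"] + sum(l[c(
                 "prevalent_washout", "no_hospitalization", "no_imaging",
                 "inaccurate_age", "inconsistent_dx"
               )])))
})

test_that("a clean scenario retains every generated patient", {
  lt <- study_lt()
  scen <- clean_scenario(seed = 32, n = 150)
  sim <- generate_cohort(scen, lt)
  cohort <- build_cohort(sim, window = c(scen$admin_start, scen$admin_end))
  expect_equal(nrow(cohort$patients), 150L)
})

test_that("washout_noise_rate = 1 removes the whole cohort", {
  lt <- study_lt()
  scen <- synthetic_scenario(seed = 33, n_patients = 60,
                             washout_noise_rate = 1)
  sim <- generate_cohort(scen, lt)
  cohort <- build_cohort(sim, window = c(scen$admin_start, scen$admin_end))
  expect_equal(nrow(cohort$patients), 0L)
  expect_equal(unname(cohort$ledger["prevalent_washout"]), 60L)
})

test_that("rebuilding from the retained patients reproduces the cohort", {
  lt <- study_lt()
  scen <- synthetic_scenario(seed = 34, n_patients = 120,
                             washout_noise_rate = 0.2, nonhosp_rate = 0.2)
  sim <- generate_cohort(scen, lt)
  first <- build_cohort(sim, window = c(scen$admin_start, scen$admin_end))
  kept_claims <- sim$claims[sim$claims$patient_id %in%
                              first$patients$patient_id, ]
  second <- build_cohort(kept_claims, sim$demographics,
                         window = c(scen$admin_start, scen$admin_end),
                         washout = c(scen$washout_start, scen$washout_end))
  expect_equal(second$patients, first$patients)
  expect_equal(unname(second$ledger["retained"]),
               unname(first$ledger["retained"]))
})

test_that("every retained patient carries exactly one subtype", {
  lt <- study_lt()
  sim <- generate_cohort(synthetic_scenario(seed = 35, n_patients = 200),
                         lt)
  cohort <- build_cohort(sim, window = c("2006-01-01", "2015-12-31"))
  expect_true(all(cohort$patients$subtype %in%
                    c("SAH", "ICH", "NIH", "CI")))
  expect_equal(sum(table(cohort$patients$subtype)),
               nrow(cohort$patients))
  # generator's subtype assignment survives the rebuild
  truth <- sim$patients$subtype[match(cohort$patients$patient_id,
                                      sim$patients$patient_id)]
  expect_equal(cohort$patients$subtype, truth)
})

test_that("malformed diagnosis codes are skipped with a warning", {
  toy <- toy_claims_six()
  bad <- rbind(toy$claims, claim_row("F", "2010-09-01", "outpatient",
                                     "???"))
  expect_warning(
    cohort <- build_cohort(bad, toy$demographics, window = wwindow,
                           washout = wwash),
    "skipped"
  )
  expect_equal(unname(cohort$ledger["retained"]), 1L)
})

test_that("outpatient comparators need three distinct visit dates", {
  claims <- rbind(
    claim_row("X", "2010-01-01", "outpatient", "I63.1"),
    claim_row("X", "2010-02-01", "outpatient", "I63.1"),
    claim_row("X", "2010-03-01", "outpatient", "I63.1"),
    claim_row("Y", "2010-01-01", "outpatient", "I63.1"),
    claim_row("Y", "2010-02-01", "outpatient", "I63.1"),
    # Z: three claim lines but only one distinct date
    claim_row("Z", "2010-01-01", "outpatient", "I63.1"),
    claim_row("Z", "2010-01-01", "outpatient", "I63.2"),
    claim_row("Z", "2010-01-01", "outpatient", "I63.3")
  )
  got <- flag_outpatient_comparators(claims, c("X", "Y", "Z"))
  expect_equal(got, "X")
  expect_equal(flag_outpatient_comparators(claims, character()),
               character())
})

test_that("comorbidity flags use strict precedence over the index date", {
  toy <- toy_claims_six()
  claims <- rbind(
    toy$claims,
    claim_row("F", "2010-07-31", "outpatient", "I10.9"),  # day before
    claim_row("F", "2010-08-01", "outpatient", "E11.9")   # index day
  )
  cohort <- build_cohort(claims, toy$demographics, window = wwindow,
                         washout = wwash)
  cohort <- flag_comorbidities(claims, cohort)
  expect_true(cohort$patients$hypertension)
  expect_false(cohort$patients$diabetes)

  bad_map <- cohort$config$comorbidity_map
  bad_map$hypertension <- NULL
  expect_error(flag_comorbidities(claims, cohort, code_map = bad_map),
               "hypertension")
})

test_that("per-condition prevalence counts disjoint conditions", {
  claims <- rbind(
    claim_row("P1", "2010-03-01", "inpatient", "I63.0", "HA401"),
    claim_row("P1", "2009-01-01", "outpatient", "I10.0"),
    claim_row("P2", "2010-03-01", "inpatient", "I63.0", "HA401"),
    claim_row("P2", "2009-01-01", "outpatient", "E11.0"),
    claim_row("P3", "2010-03-01", "inpatient", "I63.0", "HA401"),
    claim_row("P3", "2009-01-01", "outpatient", "E78.5")
  )
  demo <- rbind(demo_row("P1"), demo_row("P2"), demo_row("P3"))
  cohort <- build_cohort(claims, demo, window = wwindow, washout = wwash)
  cohort <- flag_comorbidities(claims, cohort)
  p <- cohort$patients
  expect_equal(mean(p$hypertension), 1 / 3)
  expect_equal(mean(p$diabetes), 1 / 3)
  expect_equal(mean(p$hyperlipidemia), 1 / 3)
  expect_equal(mean(p$tia), 0)
})

test_that("severity index is the clipped linear score", {
  cfg <- ssi_config(intercept = 4.1,
                    coefficients = c(icu_admission = 2.0,
                                     mechanical_ventilation = 4.5))
  zeros <- c(icu_admission = 0, mechanical_ventilation = 0)
  expect_equal(compute_ssi(zeros, cfg), 4.1)
  one <- c(icu_admission = 1, mechanical_ventilation = 0)
  expect_equal(compute_ssi(one, cfg), 6.1)

  # random indicator matrix against a brute-force dot product
  set.seed(42)
  coefs <- stats::setNames(runif(5, -1, 5), paste0("p", 1:5))
  cfg2 <- ssi_config(intercept = 4.1, coefficients = coefs,
                     score_min = -100, score_max = 100)
  x <- matrix(rbinom(50, 3, 0.4), nrow = 10,
              dimnames = list(NULL, paste0("p", 1:5)))
  manual <- 4.1 + vapply(seq_len(10), function(i) {
    sum(x[i, ] * coefs)
  }, numeric(1L))
  expect_equal(compute_ssi(x, cfg2), manual, tolerance = 1e-12)

  # clipping at the score range
  big <- c(icu_admission = 100, mechanical_ventilation = 100)
  expect_equal(compute_ssi(big, cfg), 27.11)

  expect_warning(
    s <- compute_ssi(c(icu_admission = 1, mechanical_ventilation = 0,
                       unknown = 3), cfg),
    "unknown"
  )
  expect_equal(s, 6.1)
  expect_error(compute_ssi(c(icu_admission = 1), cfg),
               "mechanical_ventilation")
})

test_that("hemorrhagic strokes score higher on the severity index", {
  lt <- study_lt()
  sim <- generate_cohort(synthetic_scenario(seed = 36, n_patients = 600),
                         lt)
  cohort <- build_cohort(sim, window = c("2006-01-01", "2015-12-31"))
  ssi <- compute_ssi(derive_ssi_indicators(sim$claims, cohort),
                     cohort$config$ssi)
  by_subtype <- tapply(ssi, cohort$patients$subtype, mean)
  expect_gt(by_subtype["SAH"], by_subtype["CI"])
})
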