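test_that("constant-hazard life tables reproduce the requested q", {
  lt <- const_lt(0.5, 2000, 2002, max_age = 90)
  df <- as.data.frame(lt)
  expect_true(all(df$qx[df$age < 90] == 0.5))
  expect_true(all(df$qx[df$age == 90] == 1))
})

test_that("Gompertz life tables are strictly increasing in age", {
  lt <- generate_life_table(2006, 2008)
  for (s in c("F", "M")) {
    for (y in c("2006", "2008")) {
      q <- lt$qx[s, y, as.character(0:109)]
      expect_true(all(diff(q) > 0))
    }
  }
  # females lighter mortality, later years lighter than earlier
  expect_true(all(lt$qx["F", "2006", 30:100] <
                    lt$qx["M", "2006", 30:100]))
  expect_true(all(lt$qx["M", "2008", 30:100] <
                    lt$qx["M", "2006", 30:100]))
})

test_that("life-table generation validates its hazard parameters", {
  expect_error(generate_life_table(2010, 2005), "first_year")
  expect_error(generate_life_table(2000, 2001, max_age = 80), "85")
  expect_error(
    generate_life_table(2000, 2001,
                        hazard_shape = list(model = "gompertz", b = -1)),
    "monotone"
  )
  expect_error(
    generate_life_table(2000, 2001,
                        hazard_shape = list(model = "constant", q = 1.2)),
    "constant"
  )
})

test_that("life-table CSV round-trips exactly", {
  lt <- generate_life_table(2006, 2007, max_age = 90)
  path <- tempfile(fileext = ".csv")
  write_life_table(lt, path)
  lt2 <- read_life_table(path)
  expect_equal(lt2$qx, lt$qx)
  unlink(path)
})

test_that("same seed and parameters reproduce identical outputs", {
  lt <- study_lt()
  scen <- clean_scenario(seed = 11, n = 80)
  a <- generate_cohort(scen, lt)
  b <- generate_cohort(scen, lt)
  expect_identical(a$claims, b$claims)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$truth$death_month, b$truth$death_month)
  lt_a <- generate_life_table(2006, 2008)
  lt_b <- generate_life_table(2006, 2008)
  expect_identical(lt_a$qx, lt_b$qx)
})

test_that("every patient receives exactly one index event", {
  lt <- study_lt()
  scen <- synthetic_scenario(seed = 3, n_patients = 150,
                             washout_noise_rate = 0.3,
                             nonhosp_rate = 0.3, no_imaging_rate = 0.2)
  sim <- generate_cohort(scen, lt)
  idx <- sim$claims[substr(sim$claims$primary_dx, 1, 3) %in%
                      c("I60", "I61", "I62", "I63") &
                      sim$claims$date >= scen$index_start, ]
  first <- tapply(idx$date, idx$patient_id, min)
  expect_equal(length(unique(sim$claims$patient_id)), 150L)
  expect_equal(nrow(sim$patients), 150L)
})

test_that("ground truth is self-consistent", {
  lt <- study_lt()
  scen <- clean_scenario(seed = 5, n = 200, mult = 2)
  sim <- generate_cohort(scen, lt)
  tr <- sim$truth
  # stated invariant: true LE equals the integral of the true curve
  expect_equal(tr$LE, reference_life_expectancy(tr$curve),
               tolerance = 1e-6)
  expect_equal(tr$EYLL, tr$LE_ref - tr$LE, tolerance = 1e-9)
  # empirical survival of drawn death months converges to the true
  # curve as n grows (KS distance decreasing across decades of n)
  ks <- vapply(c(100, 1000, 10000), function(n) {
    scen_n <- clean_scenario(seed = 5, n = n, mult = 2)
    sim_n <- generate_cohort(scen_n, lt)
    dm <- sim_n$truth$death_month
    months <- sim_n$truth$curve$month
    emp <- vapply(months, function(m) mean(dm > m), numeric(1L))
    max(abs(emp - sim_n$truth$curve$surv))
  }, numeric(1L))
  expect_true(ks[3] < ks[1])
  expect_true(ks[3] < 0.05)
})

test_that("suppression flags shape the emitted claim lines", {
  lt <- study_lt()
  scen <- synthetic_scenario(seed = 9, n_patients = 200,
                             washout_noise_rate = 0.4,
                             nonhosp_rate = 0.3, no_imaging_rate = 0.5)
  sim <- generate_cohort(scen, lt)
  p <- sim$patients
  wash <- sim$claims[sim$claims$date <= scen$washout_end &
                       substr(sim$claims$primary_dx, 1, 2) == "I6", ]
  expect_setequal(unique(wash$patient_id),
                  p$patient_id[p$washout_flag])
  idx <- sim$claims[sim$claims$setting == "inpatient", ]
  expect_true(all(!p$nonhosp_flag[match(idx$patient_id, p$patient_id)]))
})

test_that("terminal cost surge raises mean costs near death", {
  lt <- study_lt()
  scen <- clean_scenario(seed = 21, n = 300, mult = 3)
  sim <- generate_cohort(scen, lt)
  p <- sim$patients
  costs <- sim$claims[sim$claims$insurer_paid > 0, ]
  rel_month <- floor(as.numeric(costs$date -
    p$index_date[match(costs$patient_id, p$patient_id)]) / 30.4375)
  to_death <- p$death_month[match(costs$patient_id, p$patient_id)] -
    rel_month
  surge <- to_death <= scen$cost_spec$surge_window
  expect_gt(mean(costs$insurer_paid[surge]),
            2 * mean(costs$insurer_paid[!surge]))
})

test_that("census denominators follow the band widths and growth", {
  lt <- study_lt()
  cen <- generate_census(lt, 1000, periods = "2006-2007")
  first <- cen[cen$age_group == "18-24", ]
  expect_true(all(first$population == 7000))
  expect_true(all(cen$population[cen$age_group == "25-29"] == 5000))
  expect_equal(sort(unique(cen$age_group)),
               sort(age_bands_18_84()$age_group))

  cen2 <- generate_census(lt, 1000,
                          periods = c("2006-2007", "2008-2009"))
  expect_equal(cen2$population[cen2$period == "2006-2007"],
               cen2$population[cen2$period == "2008-2009"])

  shrink <- generate_census(lt, 1000,
                            periods = c("2006-2007", "2008-2009",
                                        "2010-2011"),
                            annual_growth = -0.02)
  by_period <- tapply(shrink$population, shrink$period, sum)
  expect_true(all(diff(by_period[sort(names(by_period))]) < 0))

  expect_error(generate_census(lt, 1000, periods = character()),
               "period")
  expect_error(generate_census(lt, -5, periods = "2006-2007"),
               "positive")
})

test_that("scenario validation rejects malformed inputs", {
  expect_error(synthetic_scenario(subtype_weights = c(SAH = 0.5, ICH = 0.5,
                                                      NIH = 0, CI = 0.2)),
               "sum to 1")
  expect_error(synthetic_scenario(sex_ratio_male = 1.4), "proportions")
  expect_error(synthetic_scenario(washout_noise_rate = -0.1),
               "proportions")
  expect_error(excess_hazard_spec(c(2, -1), breaks = c(0, 6)),
               "non-negative")
  expect_error(excess_hazard_spec(c(2, 1), breaks = c(3, 6)), "month 0")
  expect_error(synthetic_scenario(washout_start = "2007-01-01",
                                  washout_end = "2008-01-01"),
               "washout")
})
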