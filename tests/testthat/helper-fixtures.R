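# Fixtures shared across the suite; everything is built in code.

# Constant-q life table over a small year span (closed-form checks).
const_lt <- function(q, first_year = 2000, last_year = 2020,
                     max_age = 110) {
  generate_life_table(first_year, last_year, max_age = max_age,
                      hazard_shape = list(model = "constant", q = q))
}

# Gompertz life table covering the default study window; memoised
# since several files need it and it is deterministic.
study_lt <- local({
  lt <- NULL
  function() {
    if (is.null(lt)) lt <<- generate_life_table(2002, 2016)
    lt
  }
})

# Bare patient table for survival estimation.
patient_table <- function(time_months, event) {
  data.frame(time_months = time_months, event = event,
             stringsAsFactors = FALSE)
}

# Brute-force product-limit estimator: direct product over distinct
# event times, deaths before censorings within a time. Independent of
# the survival package.
brute_km <- function(time, event, at) {
  vapply(at, function(t0) {
    s <- 1
    for (u in sort(unique(time[event == 1 & time <= t0]))) {
      n_at_risk <- sum(time > u | (time == u))
      d <- sum(time == u & event == 1)
      s <- s * (1 - d / n_at_risk)
    }
    s
  }, numeric(1L))
}

# Claim-line row constructor.
claim_row <- function(id, date, setting = "inpatient", dx = "I63.9",
                      proc = "", insurer = 0, copay = 0) {
  data.frame(patient_id = id, date = as.Date(date), setting = setting,
             primary_dx = dx, procedure_codes = proc,
             insurer_paid = insurer, copay = copay,
             stringsAsFactors = FALSE)
}

demo_row <- function(id, sex = "M", birth_year = 1950,
                     insurance = "employed", residence = "seoul",
                     death = NA) {
  data.frame(patient_id = id, sex = sex, birth_year = birth_year,
             insurance_type = insurance, residence = residence,
             death_date = as.Date(death), stringsAsFactors = FALSE)
}

# The six-patient toy claims table: one patient per exclusion
# criterion plus one clean. All index events in 2010.
toy_claims_six <- function() {
  claims <- rbind(
    # A: prevalent case (washout I69 record)
    claim_row("A", "2010-03-01", "inpatient", "I60.1", "HA401"),
    claim_row("A", "2004-07-10", "outpatient", "I69.4"),
    # B: outpatient-only event
    claim_row("B", "2010-04-01", "outpatient", "I61.0", "HA401"),
    # C: admitted but no imaging
    claim_row("C", "2010-05-01", "inpatient", "I62.0"),
    # D: aged 17 at index
    claim_row("D", "2010-06-01", "inpatient", "I63.3", "HE101"),
    # E: inconsistent index-date diagnoses (I60 and I63)
    claim_row("E", "2010-07-01", "inpatient", "I60.0", "HA401"),
    claim_row("E", "2010-07-01", "inpatient", "I63.8", "HA401"),
    # F: clean
    claim_row("F", "2010-08-01", "inpatient", "I63.0", "HE101")
  )
  demographics <- rbind(
    demo_row("A", birth_year = 1950),
    demo_row("B", birth_year = 1948),
    demo_row("C", birth_year = 1955),
    demo_row("D", birth_year = 1993),
    demo_row("E", birth_year = 1940),
    demo_row("F", birth_year = 1952, death = "2013-02-01")
  )
  list(claims = claims, demographics = demographics)
}

# Small clean scenario (no suppression, ages capped at 84 so the
# builder's age rule never triggers) used where exact conservation is
# asserted.
clean_scenario <- function(seed = 1, n = 120, mult = 1,
                           index_end = "2006-12-31") {
  w <- default_age_weights()
  w[as.integer(names(w)) > 84] <- 0
  synthetic_scenario(
    seed = seed, n_patients = n, age_weights = w,
    excess_hazard = excess_hazard_spec(mult, 0),
    index_start = "2006-01-01", index_end = index_end
  )
}
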