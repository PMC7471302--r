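#' Synthetic claims-cohort scenario
#'
#' Bundles every knob of the synthetic claims generator: cohort size
#' and demographics, stroke-subtype mix, the excess hazard the disease
#' adds over life-table mortality, the monthly cost process (with a
#' terminal surge before death), the administrative observation window,
#' and the rates at which realistic "dirt" is injected (washout-period
#' stroke codes, events without an admission, events without imaging).
#' The generated cohort carries known ground truth, so downstream
#' estimates can be checked against the generating process.
#'
#' @param seed Integer RNG seed; identical scenarios reproduce
#'   byte-identical outputs.
#' @param n_patients Number of index events to generate.
#' @param age_weights Named non-negative weights over single years of
#'   age 18..100 at index.
#' @param sex_ratio_male Proportion male in \[0, 1\].
#' @param subtype_weights Proportions over SAH/ICH/NIH/CI summing to 1.
#' @param excess_hazard An [excess_hazard_spec()]; the default is no
#'   excess (referent mortality).
#' @param cost_spec List with monthly mean costs in KRW for the insurer
#'   and copayment streams, a terminal surge multiplier applied to the
#'   last `surge_window` months before death, and the lognormal noise
#'   `sdlog`.
#' @param admin_start,admin_end Administrative observation window.
#' @param index_start,index_end Calendar range in which index events
#'   occur (defaults to the administrative window).
#' @param washout_start,washout_end Pre-window span scanned for
#'   prevalent-case codes.
#' @param washout_noise_rate Proportion of patients given a spurious
#'   I60-I69 record inside the washout span (these patients are
#'   intended to be excluded downstream).
#' @param nonhosp_rate Proportion of index events generated without an
#'   inpatient admission record.
#' @param no_imaging_rate Proportion generated without a CT/MRI
#'   procedure code.
#' @param comorbidity_rates Named per-condition probabilities of a
#'   pre-index claim line; `NULL` uses built-in stroke-like defaults.
#' @return A `synthetic_scenario` object.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_patients = 1000L,
                               age_weights = default_age_weights(),
                               sex_ratio_male = 0.54,
                               subtype_weights = c(SAH = 0.084, ICH = 0.145,
                                                   NIH = 0.036, CI = 0.735),
                               excess_hazard = excess_hazard_spec(1, 0),
                               cost_spec = list(insurer = 400000,
                                                copay = 90000,
                                                surge_multiplier = 3,
                                                surge_window = 6,
                                                sdlog = 0.5),
                               admin_start = "2006-01-01",
                               admin_end = "2015-12-31",
                               index_start = admin_start,
                               index_end = admin_end,
                               washout_start = "2002-01-01",
                               washout_end = "2005-12-31",
                               washout_noise_rate = 0,
                               nonhosp_rate = 0,
                               no_imaging_rate = 0,
                               comorbidity_rates = NULL) {
  props <- c(sex_ratio_male = sex_ratio_male,
             washout_noise_rate = washout_noise_rate,
             nonhosp_rate = nonhosp_rate,
             no_imaging_rate = no_imaging_rate)
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]: ",
         paste(names(props)[props < 0 | props > 1], collapse = ", "))
  }
  if (abs(sum(subtype_weights) - 1) > 1e-9) {
    stop("`subtype_weights` must sum to 1")
  }
  if (!setequal(names(subtype_weights), c("SAH", "ICH", "NIH", "CI"))) {
    stop("`subtype_weights` must be named SAH, ICH, NIH, CI")
  }
  if (n_patients < 1L) stop("`n_patients` must be positive")
  if (!identical(names(age_weights), as.character(18:100)) ||
      any(age_weights < 0) || sum(age_weights) <= 0) {
    stop("`age_weights` must be non-negative weights named 18..100")
  }
  stopifnot(inherits(excess_hazard, "excess_hazard_spec"))
  for (fld in c("insurer", "copay", "surge_multiplier",
                "surge_window", "sdlog")) {
    if (is.null(cost_spec[[fld]]) || cost_spec[[fld]] < 0) {
      stop("cost_spec$", fld, " must be present and non-negative")
    }
  }
  if (cost_spec$surge_multiplier < 1) {
    stop("the terminal surge multiplier must be >= 1")
  }
  dates <- lapply(list(admin_start, admin_end, index_start, index_end,
                       washout_start, washout_end), as_date)
  if (dates[[5L]] >= dates[[1L]] && dates[[6L]] >= dates[[1L]]) {
    stop("the washout span must precede the administrative window")
  }
  if (dates[[1L]] > dates[[2L]] || dates[[3L]] > dates[[4L]]) {
    stop("calendar ranges must be ordered start <= end")
  }
  if (dates[[3L]] < dates[[1L]] || dates[[4L]] > dates[[2L]]) {
    stop("the index range must lie inside the administrative window")
  }
  if (is.null(comorbidity_rates)) {
    comorbidity_rates <- c(
      hypertension = 0.64, hyperlipidemia = 0.48, diabetes = 0.36,
      ihd = 0.18, copd = 0.10, atrial_fibrillation = 0.09,
      tia = 0.07, chf = 0.06, ckd = 0.024
    )
  }
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         age_weights = age_weights, sex_ratio_male = sex_ratio_male,
         subtype_weights = subtype_weights, excess_hazard = excess_hazard,
         cost_spec = cost_spec,
         admin_start = dates[[1L]], admin_end = dates[[2L]],
         index_start = dates[[3L]], index_end = dates[[4L]],
         washout_start = dates[[5L]], washout_end = dates[[6L]],
         washout_noise_rate = washout_noise_rate,
         nonhosp_rate = nonhosp_rate, no_imaging_rate = no_imaging_rate,
         comorbidity_rates = comorbidity_rates),
    class = "synthetic_scenario"
  )
}

#' @rdname synthetic_scenario
#' @export
default_age_weights <- function() {
  # overall stroke cohort age mix: band shares spread uniformly within
  # 18-44 / 45-54 / 55-64 / 65-74 / 75-84 and a thinning 85+ tail
  ages <- 18:100
  w <- numeric(length(ages))
  band <- function(lo, hi, share) {
    sel <- ages >= lo & ages <= hi
    w[sel] <<- share / sum(sel)
  }
  band(18, 44, 0.067)
  band(45, 54, 0.151)
  band(55, 64, 0.205)
  band(65, 74, 0.282)
  band(75, 84, 0.247)
  band(85, 100, 0.048)
  names(w) <- ages
  w
}

SUBTYPE_CODES <- c(SAH = "I60", ICH = "I61", NIH = "I62", CI = "I63")

# Comorbidity ICD-10 prefixes shared between the generator and the
# default cohort-builder configuration.
COMORBIDITY_CODES <- list(
  atrial_fibrillation = "I48",
  chf = "I50",
  ckd = "N18",
  copd = c("J43", "J44"),
  diabetes = c("E10", "E11", "E12", "E13", "E14"),
  hyperlipidemia = "E78",
  hypertension = c("I10", "I11", "I12", "I13", "I15"),
  ihd = c("I20", "I21", "I22", "I23", "I24", "I25"),
  tia = "G45"
)

# Severity-marker procedure codes emitted during the index admission;
# probabilities differ by subtype so hemorrhagic strokes score higher
# on the severity index. Synthetic placeholder codes.
SSI_MARKER_PROBS <- list(
  ICUADM = c(SAH = 0.75, ICH = 0.65, NIH = 0.50, CI = 0.20),
  MVENT = c(SAH = 0.45, ICH = 0.35, NIH = 0.25, CI = 0.08),
  NGTUBE = c(SAH = 0.35, ICH = 0.40, NIH = 0.30, CI = 0.15)
)

#' Generate a synthetic claims cohort with known ground truth
#'
#' Draws demographics and an index event per patient, simulates the
#' uncensored death month from the life-table hazard combined with the
#' scenario's excess hazard (monthly constant-hazard discretisation,
#' h_month = -log(1 - q_annual)/12), and emits the claim lines the
#' cohort builder needs to reconstruct the intended cohort: an index
#' admission line with the subtype ICD-10 code, an imaging procedure
#' line (unless suppressed), pre-index comorbidity lines, monthly cost
#' lines until death or administrative censoring (lognormal noise
#' around the scenario means, with a terminal surge in the last months
#' before death), and washout-period noise lines for the configured
#' fraction of patients.
#'
#' @param scenario A [synthetic_scenario()].
#' @param lt A [life_table()] covering every age/year reachable.
#' @param max_age Simulation horizon in years of age.
#' @return A `synthetic_cohort` list with elements `claims` (claim-line
#'   table), `demographics` (one row per patient, including death
#'   date), `patients` (true per-patient attributes and suppression
#'   flags), and `truth` (a `ground_truth` object: uncensored death
#'   months, the cohort's true lifetime survival curve, true LE /
#'   referent LE / EYLL, and true discounted lifetime costs).
#' @export
generate_cohort <- function(scenario, lt, max_age = 110) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(lt, "life_table"))
  set.seed(scenario$seed)
  n <- scenario$n_patients
  ages <- as.integer(names(scenario$age_weights))
  age <- sample(ages, n, replace = TRUE, prob = scenario$age_weights)
  sex <- ifelse(stats::runif(n) < scenario$sex_ratio_male, "M", "F")
  subtype <- sample(names(scenario$subtype_weights), n, replace = TRUE,
                    prob = scenario$subtype_weights)
  span <- as.numeric(scenario$index_end - scenario$index_start)
  index_date <- scenario$index_start +
    floor(stats::runif(n) * (span + 1))
  index_year <- year_of(index_date)

  # uncensored death month per patient via inverse-CDF sampling of the
  # matched monthly hazard path with excess applied
  u <- stats::runif(n)
  death_month <- integer(n)
  key <- paste(sex, age, index_year, sep = "|")
  for (g in sort(unique(key))) {
    sel <- key == g
    parts <- strsplit(g, "|", fixed = TRUE)[[1L]]
    h <- monthly_hazard_path(lt, parts[1L], as.integer(parts[2L]),
                             as.integer(parts[3L]), max_age = max_age)
    h <- apply_excess(h, scenario$excess_hazard)
    s_cum <- exp(-cumsum(h))
    death_month[sel] <- sim_death_month(s_cum, u[sel])
  }

  potential_months <- days_to_months(scenario$admin_end - index_date)
  died <- death_month <= potential_months
  followup_months <- ifelse(died, death_month, potential_months)
  death_date <- as.Date(rep(NA, n))
  death_date[died] <- pmin(
    index_date[died] + round((death_month[died] - 0.5) * DAYS_PER_MONTH),
    scenario$admin_end
  )

  washout_flag <- stats::runif(n) < scenario$washout_noise_rate
  nonhosp_flag <- stats::runif(n) < scenario$nonhosp_rate
  no_imaging_flag <- stats::runif(n) < scenario$no_imaging_rate
  # patients breaching the builder's age-accuracy rule (born more than
  # 85 years before the window start) are not part of the intended
  # cohort, so ground truth is computed without them
  age_ok <- (index_year - age) >= year_of(scenario$admin_start) - 85L
  insurance_type <- sample(
    c("self-employed", "employed", "medical-aid"), n,
    replace = TRUE, prob = c(0.34, 0.56, 0.10)
  )
  residence <- sample(
    c("seoul", "metropolitan", "non-metropolitan"), n,
    replace = TRUE, prob = c(0.16, 0.24, 0.60)
  )
  pid <- sprintf("P%06d", seq_len(n))

  demographics <- data.frame(
    patient_id = pid, sex = sex, birth_year = index_year - age,
    insurance_type = insurance_type, residence = residence,
    death_date = death_date, stringsAsFactors = FALSE
  )

  claims <- list()
  dx_suffix <- function(k) sprintf(".%d", sample(0:9, k, replace = TRUE))

  # index admission (or outpatient-only event when suppressed), with
  # imaging and severity-marker procedure codes
  proc <- ifelse(no_imaging_flag, "",
                 sample(c("HA401", "HE101"), n, replace = TRUE))
  for (code in names(SSI_MARKER_PROBS)) {
    p <- SSI_MARKER_PROBS[[code]][subtype]
    hit <- stats::runif(n) < p & !nonhosp_flag
    proc <- ifelse(hit, ifelse(proc == "", code,
                               paste(proc, code, sep = ";")), proc)
  }
  claims$index <- data.frame(
    patient_id = pid, date = index_date,
    setting = ifelse(nonhosp_flag, "outpatient", "inpatient"),
    primary_dx = paste0(SUBTYPE_CODES[subtype], dx_suffix(n)),
    procedure_codes = proc,
    insurer_paid = 0, copay = 0, stringsAsFactors = FALSE
  )

  # washout-period stroke/sequelae noise
  if (any(washout_flag)) {
    k <- sum(washout_flag)
    wspan <- as.numeric(scenario$washout_end - scenario$washout_start)
    claims$washout <- data.frame(
      patient_id = pid[washout_flag],
      date = scenario$washout_start + floor(stats::runif(k) * (wspan + 1)),
      setting = "outpatient",
      primary_dx = paste0("I6", sample(0:9, k, replace = TRUE),
                          dx_suffix(k)),
      procedure_codes = "", insurer_paid = 0, copay = 0,
      stringsAsFactors = FALSE
    )
  }

  # pre-index comorbidity history
  como <- list()
  for (cond in names(scenario$comorbidity_rates)) {
    hit <- stats::runif(n) < scenario$comorbidity_rates[[cond]]
    if (!any(hit)) next
    k <- sum(hit)
    lag_days <- 1L + floor(stats::runif(k) *
      pmax(1, as.numeric(index_date[hit] - scenario$washout_start) - 1))
    codes <- COMORBIDITY_CODES[[cond]]
    como[[cond]] <- data.frame(
      patient_id = pid[hit], date = index_date[hit] - lag_days,
      setting = "outpatient",
      primary_dx = paste0(sample(codes, k, replace = TRUE), dx_suffix(k)),
      procedure_codes = "", insurer_paid = 0, copay = 0,
      stringsAsFactors = FALSE
    )
  }
  claims$comorbidity <- do.call(rbind, como)

  # monthly cost lines until death or administrative censoring
  n_lines <- followup_months
  if (sum(n_lines) > 0) {
    cpid <- rep(pid, n_lines)
    month_idx <- unlist(lapply(n_lines, function(k) seq_len(k) - 1L),
                        use.names = FALSE)
    cdate <- rep(index_date, n_lines) +
      floor(month_idx * DAYS_PER_MONTH)
    in_surge <- month_idx >= rep(death_month, n_lines) -
      scenario$cost_spec$surge_window
    mult <- ifelse(in_surge, scenario$cost_spec$surge_multiplier, 1)
    sdlog <- scenario$cost_spec$sdlog
    draw <- function(mu) {
      stats::rlnorm(length(mu), meanlog = log(mu) - sdlog^2 / 2,
                    sdlog = sdlog)
    }
    claims$costs <- data.frame(
      patient_id = cpid, date = cdate,
      setting = sample(c("outpatient", "pharmacy"), length(cpid),
                       replace = TRUE, prob = c(0.7, 0.3)),
      primary_dx = paste0(rep(SUBTYPE_CODES[subtype], n_lines),
                          dx_suffix(length(cpid))),
      procedure_codes = "",
      insurer_paid = draw(mult * scenario$cost_spec$insurer),
      copay = draw(mult * scenario$cost_spec$copay),
      stringsAsFactors = FALSE
    )
  }

  claims <- do.call(rbind, claims)
  claims <- claims[order(claims$patient_id, claims$date,
                         claims$setting, claims$primary_dx), ]
  rownames(claims) <- NULL

  patients <- data.frame(
    patient_id = pid, sex = sex, age = age, year = index_year,
    subtype = subtype, index_date = index_date,
    death_month = death_month, followup_months = followup_months,
    died = died, washout_flag = washout_flag,
    nonhosp_flag = nonhosp_flag, no_imaging_flag = no_imaging_flag,
    age_ok = age_ok,
    stringsAsFactors = FALSE
  )

  clean <- !(washout_flag | nonhosp_flag | no_imaging_flag) & age_ok
  # ground truth describes the intended (retainable) cohort; with no
  # clean patient left there is nothing to describe
  truth <- if (any(clean)) {
    ground_truth(patients[clean, , drop = FALSE], lt, scenario,
                 max_age = max_age)
  } else NULL

  structure(
    list(claims = claims, demographics = demographics,
         patients = patients, truth = truth, scenario = scenario),
    class = "synthetic_cohort"
  )
}

# Inverse-CDF draw of the death month: smallest m with S_cum[m] < u,
# where S_cum is the (decreasing) survival to the end of month m.
sim_death_month <- function(s_cum, u) {
  m_max <- length(s_cum)
  r <- rev(s_cum)
  pmin(m_max - findInterval(u, r) + 1L, m_max)
}

# Ground truth for the clean (unsuppressed) subset of a synthetic
# cohort: the analytic pooled lifetime survival curve under the
# scenario's excess hazard, the matched referent curve, their integrals
# (true LE, referent LE, EYLL), and the true expected discounted
# lifetime costs implied by the drawn death months and the noiseless
# cost process.
ground_truth <- function(patients, lt, scenario, max_age = 110,
                         discount_rates = c(0, 0.03, 0.05)) {
  if (nrow(patients) == 0L) {
    stop("ground truth undefined for an empty clean cohort")
  }
  truth_curve <- expected_survival(patients, lt, scenario$excess_hazard,
                                   max_age = max_age, provenance = "truth")
  ref_curve <- expected_survival(patients, lt, NULL, max_age = max_age,
                                 provenance = "referent-expected")
  le_true <- reference_life_expectancy(truth_curve)
  le_ref <- reference_life_expectancy(ref_curve)

  cs <- scenario$cost_spec
  t_death <- patients$death_month
  costs <- lapply(discount_rates, function(r) {
    horizon <- max(t_death)
    disc <- (1 + r)^(-(seq_len(horizon) - 1L) / 12)
    cum_disc <- c(0, cumsum(disc)) # cum_disc[m + 1] = sum over months 0..m-1
    base_part <- cum_disc[t_death + 1L]
    surge_lo <- pmax(t_death - cs$surge_window, 0L)
    surge_part <- (cs$surge_multiplier - 1) *
      (cum_disc[t_death + 1L] - cum_disc[surge_lo + 1L])
    c(insurer = cs$insurer * mean(base_part + surge_part),
      copay = cs$copay * mean(base_part + surge_part))
  })
  names(costs) <- paste0("rate_", discount_rates)

  structure(
    list(death_month = stats::setNames(t_death, patients$patient_id),
         curve = truth_curve, ref_curve = ref_curve,
         LE = le_true, LE_ref = le_ref, EYLL = le_ref - le_true,
         lifetime_costs = costs, discount_rates = discount_rates),
    class = "ground_truth"
  )
}

#' Generate census denominators
#'
#' Person-count denominators per sex, 5-year-style age group (18-24,
#' then 5-year bands up to 80-84) and two-year period, from a base
#' population per single year of age with an optional annual growth
#' rate (negative for a shrinking population).
#'
#' @param lt A [life_table()]; used to check that ages 18-84 are
#'   covered by the mortality source the cohort was drawn against.
#' @param base_population Scalar population per sex and single year of
#'   age in the first period, or a data frame with columns `sex`,
#'   `age`, `population`.
#' @param periods Character vector of two-year periods, e.g.
#'   `"2006-2007"`.
#' @param annual_growth Annual multiplicative growth rate applied
#'   between periods (0 keeps the population constant).
#' @return Data frame with columns `sex`, `age_group`, `period`,
#'   `population`.
#' @export
generate_census <- function(lt, base_population = 1000,
                            periods, annual_growth = 0) {
  if (missing(periods) || length(periods) == 0L) {
    stop("at least one period is required")
  }
  if (max(lt$ages) < 84 || min(lt$ages) > 18) {
    stop("life table must cover ages 18-84")
  }
  bands <- age_bands_18_84()
  ages <- 18:84
  if (is.data.frame(base_population)) {
    need <- c("sex", "age", "population")
    if (!all(need %in% names(base_population))) {
      stop("`base_population` data frame needs columns sex, age, population")
    }
    base <- base_population
  } else {
    if (base_population <= 0) stop("`base_population` must be positive")
    base <- expand.grid(sex = c("F", "M"), age = ages,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    base$population <- base_population
  }
  if (any(base$population <= 0)) {
    stop("`base_population` must be positive")
  }
  base <- base[base$age >= 18 & base$age <= 84, , drop = FALSE]
  start_years <- as.integer(substr(periods, 1L, 4L))
  out <- list()
  for (pi in seq_along(periods)) {
    scale <- (1 + annual_growth)^(start_years[pi] - start_years[1L])
    b <- base
    b$age_group <- bands$age_group[
      findInterval(b$age, bands$lower)
    ]
    agg <- stats::aggregate(population ~ sex + age_group, data = b, FUN = sum)
    agg$population <- agg$population * scale
    agg$period <- periods[pi]
    out[[pi]] <- agg[, c("sex", "age_group", "period", "population")]
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
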