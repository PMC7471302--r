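#' Cohort-builder configuration
#'
#' Code sets and windows used to reconstruct the index cohort from raw
#' claim lines: the CT/MRI procedure codes satisfying the imaging
#' requirement, the ICD-10 prefixes defining the nine comorbidities,
#' the severity-index predictors with their marker procedure codes, and
#' the episode windows. The shipped code lists are synthetic
#' placeholders matching what the bundled generator emits; users
#' analysing real claims substitute their own lists (e.g. via
#' [read_cohort_config()]).
#'
#' @param imaging_codes Procedure codes counting as CT/MRI evidence.
#' @param comorbidity_map Named list of ICD-10 prefixes per condition;
#'   must cover exactly the nine conditions.
#' @param ssi An [ssi_config()].
#' @param ssi_codes Named list mapping each severity predictor to the
#'   procedure codes that switch its indicator on.
#' @param admission_window_days Days after the first diagnosis within
#'   which the index admission must start.
#' @param imaging_window_days Days after the index admission within
#'   which an imaging record must occur.
#' @param first_stay_days Span after the index date treated as the
#'   first hospital stay when deriving severity indicators.
#' @param min_age Minimum age at index.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(imaging_codes = c("HA401", "HA402", "HE101", "HE102"),
                          comorbidity_map = COMORBIDITY_CODES,
                          ssi = ssi_config(),
                          ssi_codes = list(icu_admission = "ICUADM",
                                           mechanical_ventilation = "MVENT",
                                           nasogastric_tube = "NGTUBE"),
                          admission_window_days = 30,
                          imaging_window_days = 30,
                          first_stay_days = 30,
                          min_age = 18) {
  structure(
    list(imaging_codes = imaging_codes, comorbidity_map = comorbidity_map,
         ssi = ssi, ssi_codes = ssi_codes,
         admission_window_days = admission_window_days,
         imaging_window_days = imaging_window_days,
         first_stay_days = first_stay_days, min_age = min_age),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @param path Path to a YAML file with any subset of the
#'   `cohort_config()` fields; missing fields keep their defaults.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- cohort_config()
  for (nm in intersect(names(raw), setdiff(names(base), "ssi"))) {
    base[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$ssi)) {
    base$ssi <- ssi_config(
      intercept = raw$ssi$intercept %||% 4.1,
      coefficients = unlist(raw$ssi$coefficients),
      score_min = raw$ssi$score_min %||% 4.1,
      score_max = raw$ssi$score_max %||% 27.11
    )
  }
  base
}

STROKE_CODES <- c("I60", "I61", "I62", "I63")
STROKE_ANY_CODES <- paste0("I6", 0:9)

dx3 <- function(x) substr(x, 1L, 3L)

has_procedure <- function(proc_field, codes) {
  if (length(codes) == 0L) return(rep(FALSE, length(proc_field)))
  pat <- paste0("(^|;)(", paste(codes, collapse = "|"), ")($|;)")
  grepl(pat, proc_field)
}

#' Build the index cohort from raw claim lines
#'
#' Reproduces the inclusion/exclusion cascade used to assemble a valid
#' first-ever-stroke cohort from claims: candidates are patients whose
#' first I60-I63 primary-diagnosis record falls inside the observation
#' window; they are then excluded, in order, if they carry any I60-I69
#' record during the washout span (prevalent case or sequela), lack an
#' inpatient admission near the index diagnosis, lack CT/MRI imaging
#' evidence, have inaccurate age information (below `min_age`, or born
#' before `min_birth_year`), or carry inconsistent stroke diagnoses on
#' the index date (primary I60-I63 codes mapping to more than one
#' subtype). The exclusion ledger records the count removed at each
#' step; input candidates always equal retained plus the ledger sum.
#'
#' @param claims Claim-line table (or a `synthetic_cohort`): columns
#'   `patient_id`, `date`, `setting`, `primary_dx`, `procedure_codes`
#'   (";"-separated), `insurer_paid`, `copay`.
#' @param demographics One row per patient: `patient_id`, `sex`,
#'   `birth_year`, `insurance_type`, `residence`, `death_date`.
#' @param window Length-2 calendar range of the observation window.
#' @param washout Length-2 calendar range scanned for prevalent cases;
#'   must precede the window.
#' @param config A [cohort_config()].
#' @param min_birth_year Patients born earlier are treated as having
#'   inaccurate age information; defaults to 85 years before the window
#'   start.
#' @return A `claims_cohort` list: `patients` (one PatientRecord row
#'   per retained patient with index date, subtype, follow-up and event
#'   indicator), `costs` (monthly insurer/copay sums per patient from
#'   the index month, binned on the 30.4375-day grid), `ledger` (named
#'   exclusion counts), and `excluded_no_hosp` (ids removed for lacking
#'   hospitalization, the input to [flag_outpatient_comparators()]).
#' @export
build_cohort <- function(claims, demographics = NULL,
                         window = c("2006-01-01", "2015-12-31"),
                         washout = c("2002-01-01", "2005-12-31"),
                         config = cohort_config(),
                         min_birth_year = NULL) {
  if (inherits(claims, "synthetic_cohort")) {
    demographics <- claims$demographics
    claims <- claims$claims
  }
  if (is.null(demographics)) stop("`demographics` is required")
  window <- as_date(window)
  washout <- as_date(washout)
  if (washout[2L] >= window[1L]) {
    stop("the washout span must precede the observation window")
  }
  if (is.null(min_birth_year)) {
    min_birth_year <- year_of(window[1L]) - 85L
  }

  empty <- function(ledger) {
    structure(
      list(
        patients = data.frame(
          patient_id = character(), sex = character(),
          birth_year = integer(), age_at_index = integer(),
          index_date = as.Date(character()), subtype = character(),
          insurance_type = character(), residence = character(),
          death_date = as.Date(character()), event = integer(),
          time_days = numeric(), time_months = integer(),
          stringsAsFactors = FALSE
        ),
        costs = data.frame(patient_id = character(), month = integer(),
                           insurer = numeric(), copay = numeric(),
                           stringsAsFactors = FALSE),
        ledger = ledger, excluded_no_hosp = character(),
        window = window, washout = washout, config = config
      ),
      class = "claims_cohort"
    )
  }
  ledger <- c(candidates = 0L, prevalent_washout = 0L,
              no_hospitalization = 0L, no_imaging = 0L,
              inaccurate_age = 0L, inconsistent_dx = 0L, retained = 0L)
  if (nrow(claims) == 0L) return(empty(ledger))

  claims$date <- as_date(claims$date)
  ok_dx <- grepl("^[A-Z][0-9]{2}", claims$primary_dx)
  if (any(!ok_dx)) {
    warning(sum(!ok_dx), " claim line(s) with unrecognisable ICD-10 ",
            "codes were skipped")
    claims <- claims[ok_dx, , drop = FALSE]
  }
  if (nrow(claims) == 0L) return(empty(ledger))
  claims$dx3 <- dx3(claims$primary_dx)

  stroke <- claims[claims$dx3 %in% STROKE_CODES, , drop = FALSE]
  in_window <- stroke$date >= window[1L] & stroke$date <= window[2L]
  sw <- stroke[in_window, , drop = FALSE]
  if (nrow(sw) == 0L) return(empty(ledger))
  first_dx <- tapply(as.numeric(sw$date), sw$patient_id, min)
  # a candidate's *first ever* stroke record must be the in-window one;
  # earlier records can only predate the window, where the washout scan
  # below catches them (records before the washout span do too)
  first_any <- tapply(as.numeric(stroke$date), stroke$patient_id, min)
  candidates <- names(first_dx)
  index_date <- as.Date(as.numeric(first_dx[candidates]),
                        origin = "1970-01-01")
  names(index_date) <- candidates
  ledger["candidates"] <- length(candidates)

  any_stroke <- claims[claims$dx3 %in% STROKE_ANY_CODES, , drop = FALSE]
  in_washout <- any_stroke$date >= washout[1L] &
    any_stroke$date <= washout[2L]
  washout_ids <- unique(any_stroke$patient_id[in_washout])
  pre_window_ids <- candidates[
    as.numeric(first_any[candidates]) < as.numeric(window[1L])
  ]
  fail_washout <- candidates %in% union(washout_ids, pre_window_ids)

  # inpatient admission near the index diagnosis
  inp <- stroke[stroke$setting == "inpatient", , drop = FALSE]
  inp <- inp[inp$patient_id %in% candidates, , drop = FALSE]
  rel <- as.numeric(inp$date) -
    as.numeric(index_date[inp$patient_id])
  inp_ok <- inp[rel >= 0 & rel <= config$admission_window_days, ,
                drop = FALSE]
  admit_date <- tapply(as.numeric(inp_ok$date), inp_ok$patient_id, min)
  has_hosp <- candidates %in% names(admit_date)

  # imaging within the window after the index admission
  img_lines <- claims[has_procedure(claims$procedure_codes,
                                    config$imaging_codes), , drop = FALSE]
  img_lines <- img_lines[img_lines$patient_id %in% names(admit_date), ,
                         drop = FALSE]
  rel_img <- as.numeric(img_lines$date) -
    as.numeric(admit_date[img_lines$patient_id])
  img_ids <- unique(img_lines$patient_id[
    rel_img >= 0 & rel_img <= config$imaging_window_days
  ])
  has_imaging <- candidates %in% img_ids

  demo <- demographics[match(candidates, demographics$patient_id), ,
                       drop = FALSE]
  age_at_index <- year_of(index_date) - demo$birth_year
  age_ok <- !is.na(age_at_index) & age_at_index >= config$min_age &
    demo$birth_year >= min_birth_year

  # subtype consistency on the index date
  on_index <- sw[as.numeric(sw$date) ==
                   as.numeric(first_dx[sw$patient_id]), , drop = FALSE]
  n_subtypes <- tapply(on_index$dx3, on_index$patient_id,
                       function(x) length(unique(x)))
  consistent <- n_subtypes[candidates] == 1L
  subtype <- tapply(on_index$dx3, on_index$patient_id,
                    function(x) x[1L])[candidates]

  alive <- rep(TRUE, length(candidates))
  drop_step <- function(fail, name) {
    k <- alive & fail
    ledger[name] <<- sum(k)
    alive <<- alive & !k
  }
  drop_step(fail_washout, "prevalent_washout")
  no_hosp_ids <- candidates[alive & !has_hosp]
  drop_step(!has_hosp, "no_hospitalization")
  drop_step(!has_imaging, "no_imaging")
  drop_step(!age_ok, "inaccurate_age")
  drop_step(!consistent, "inconsistent_dx")
  ledger["retained"] <- sum(alive)

  keep <- candidates[alive]
  if (length(keep) == 0L) {
    res <- empty(ledger)
    res$excluded_no_hosp <- no_hosp_ids
    return(res)
  }
  demo_k <- demographics[match(keep, demographics$patient_id), ,
                         drop = FALSE]
  idx <- index_date[keep]
  death <- as_date(demo_k$death_date)
  event <- as.integer(!is.na(death) & death <= window[2L])
  end_date <- as.Date(ifelse(event == 1L, death, window[2L]),
                      origin = "1970-01-01")
  time_days <- as.numeric(end_date - idx)
  if (any(time_days < 0)) {
    stop("death/censoring precedes the index date for patient(s) ",
         paste(utils::head(keep[time_days < 0], 3L), collapse = ", "))
  }

  patients <- data.frame(
    patient_id = keep, sex = demo_k$sex, birth_year = demo_k$birth_year,
    age_at_index = year_of(idx) - demo_k$birth_year,
    index_date = idx, subtype = names(SUBTYPE_CODES)[
      match(subtype[keep], SUBTYPE_CODES)
    ],
    insurance_type = demo_k$insurance_type, residence = demo_k$residence,
    death_date = death, event = event, time_days = time_days,
    time_months = days_to_months(time_days),
    stringsAsFactors = FALSE
  )
  patients$index_year <- year_of(patients$index_date)
  rownames(patients) <- NULL

  # monthly cost vectors: all claim lines (any setting) from the index
  # date onward, binned by 30.4375-day months, both payment streams
  cc <- claims[claims$patient_id %in% keep, , drop = FALSE]
  rel_days <- as.numeric(cc$date) - as.numeric(index_date[cc$patient_id])
  cc <- cc[rel_days >= 0, , drop = FALSE]
  rel_days <- rel_days[rel_days >= 0]
  month <- as.integer(floor(rel_days / DAYS_PER_MONTH))
  grp <- paste(cc$patient_id, month, sep = "|")
  ins <- rowsum(cc$insurer_paid, grp)
  cop <- rowsum(cc$copay, grp)
  parts <- strsplit(rownames(ins), "|", fixed = TRUE)
  costs <- data.frame(
    patient_id = vapply(parts, `[`, "", 1L),
    month = as.integer(vapply(parts, `[`, "", 2L)),
    insurer = as.numeric(ins), copay = as.numeric(cop),
    stringsAsFactors = FALSE
  )
  costs <- costs[order(costs$patient_id, costs$month), ]
  rownames(costs) <- NULL

  structure(
    list(patients = patients, costs = costs, ledger = ledger,
         excluded_no_hosp = no_hosp_ids, window = window,
         washout = washout, config = config),
    class = "claims_cohort"
  )
}

#' @export
print.claims_cohort <- function(x, ...) {
  cat("<claims_cohort>", nrow(x$patients), "patients retained\n")
  print(x$ledger)
  invisible(x)
}

#' Outpatient-managed comparison group
#'
#' Among patients excluded for lacking a hospital admission, identifies
#' those with at least three outpatient visits (distinct service dates)
#' carrying a stroke diagnosis code -- the outpatient-managed
#' comparison group reported alongside the index cohort.
#'
#' @param claims Claim-line table.
#' @param patient_ids Ids of the patients excluded for lacking
#'   hospitalization (e.g. `cohort$excluded_no_hosp`).
#' @return Character vector of qualifying patient ids.
#' @export
flag_outpatient_comparators <- function(claims, patient_ids) {
  if (length(patient_ids) == 0L) return(character())
  cl <- claims[claims$patient_id %in% patient_ids &
                 claims$setting == "outpatient" &
                 dx3(claims$primary_dx) %in% STROKE_CODES, , drop = FALSE]
  if (nrow(cl) == 0L) return(character())
  n_dates <- tapply(as.numeric(as_date(cl$date)), cl$patient_id,
                    function(d) length(unique(d)))
  sort(names(n_dates)[n_dates >= 3L])
}

#' Flag pre-index comorbidities
#'
#' Sets one boolean flag per condition, true iff the patient has at
#' least one claim whose primary diagnosis starts with one of the
#' condition's ICD-10 prefixes strictly before the index date (and on
#' or after `lookback_start` if given).
#'
#' @param claims Claim-line table.
#' @param cohort A `claims_cohort` from [build_cohort()].
#' @param code_map Named list of ICD-10 prefixes; must cover exactly
#'   the nine conditions (atrial_fibrillation, chf, ckd, copd,
#'   diabetes, hyperlipidemia, hypertension, ihd, tia).
#' @param lookback_start Optional earliest date considered.
#' @return The cohort with one logical column per condition added to
#'   `$patients`.
#' @export
flag_comorbidities <- function(claims, cohort,
                               code_map = cohort$config$comorbidity_map,
                               lookback_start = NULL) {
  required <- c("atrial_fibrillation", "chf", "ckd", "copd", "diabetes",
                "hyperlipidemia", "hypertension", "ihd", "tia")
  if (!setequal(names(code_map), required)) {
    missing <- setdiff(required, names(code_map))
    extra <- setdiff(names(code_map), required)
    stop("`code_map` must cover exactly the nine conditions",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")))
  }
  pats <- cohort$patients
  cl <- claims[claims$patient_id %in% pats$patient_id, , drop = FALSE]
  cl$date <- as_date(cl$date)
  idx <- pats$index_date[match(cl$patient_id, pats$patient_id)]
  before <- cl$date < idx
  if (!is.null(lookback_start)) {
    before <- before & cl$date >= as_date(lookback_start)
  }
  cl <- cl[before, , drop = FALSE]
  for (cond in required) {
    prefixes <- code_map[[cond]]
    pat <- paste0("^(", paste(prefixes, collapse = "|"), ")")
    ids <- unique(cl$patient_id[grepl(pat, cl$primary_dx)])
    pats[[cond]] <- pats$patient_id %in% ids
  }
  cohort$patients <- pats
  cohort
}

#' Stroke severity index configuration
#'
#' A claims-based linear severity score: intercept plus a weighted sum
#' of first-hospital-stay service-use indicators, clipped to the score
#' range \[4.1, 27.11\] (higher = more severe). The published
#' coefficient set is not publicly printed, so the defaults are
#' synthetic placeholder weights; analyses of real claims should
#' supply the validated coefficients.
#'
#' @param intercept Baseline score when every indicator is zero.
#' @param coefficients Named weights, one per service-use predictor.
#' @param score_min,score_max Clipping bounds of the score.
#' @return An `ssi_config` object.
#' @export
ssi_config <- function(intercept = 4.1,
                       coefficients = c(icu_admission = 3.2,
                                        mechanical_ventilation = 4.5,
                                        nasogastric_tube = 2.1),
                       score_min = 4.1, score_max = 27.11) {
  if (score_min >= score_max) stop("`score_min` must be below `score_max`")
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    stop("`coefficients` must be a named vector")
  }
  structure(
    list(intercept = intercept, coefficients = coefficients,
         score_min = score_min, score_max = score_max),
    class = "ssi_config"
  )
}

#' Compute the stroke severity index
#'
#' `score = intercept + sum(coefficient * indicator)`, clipped to the
#' configured range. Indicator columns present in the data but absent
#' from the configuration are ignored with a warning; every configured
#' predictor must be present.
#'
#' @param indicators Named numeric vector (one patient) or a matrix /
#'   data frame with one column per predictor.
#' @param config An [ssi_config()].
#' @return Numeric score(s).
#' @export
compute_ssi <- function(indicators, config = ssi_config()) {
  if (is.vector(indicators) && !is.list(indicators)) {
    indicators <- matrix(indicators, nrow = 1L,
                         dimnames = list(NULL, names(indicators)))
  }
  indicators <- as.matrix(indicators)
  preds <- names(config$coefficients)
  extra <- setdiff(colnames(indicators), preds)
  if (length(extra) > 0L) {
    warning("ignoring indicator(s) absent from the configuration: ",
            paste(extra, collapse = ", "))
  }
  missing <- setdiff(preds, colnames(indicators))
  if (length(missing) > 0L) {
    stop("indicator(s) required by the configuration are missing: ",
         paste(missing, collapse = ", "))
  }
  raw <- config$intercept +
    as.numeric(indicators[, preds, drop = FALSE] %*%
                 config$coefficients[preds])
  clip(raw, config$score_min, config$score_max)
}

#' Derive first-stay severity indicators from claims
#'
#' Builds the indicator matrix feeding [compute_ssi()]: one column per
#' configured predictor, true iff any claim during the patient's first
#' stay (`first_stay_days` after the index date) carries one of the
#' predictor's marker procedure codes.
#'
#' @param claims Claim-line table.
#' @param cohort A `claims_cohort`.
#' @param config A [cohort_config()].
#' @return Logical matrix, one row per retained patient.
#' @export
derive_ssi_indicators <- function(claims, cohort,
                                  config = cohort$config) {
  pats <- cohort$patients
  cl <- claims[claims$patient_id %in% pats$patient_id, , drop = FALSE]
  cl$date <- as_date(cl$date)
  idx <- pats$index_date[match(cl$patient_id, pats$patient_id)]
  rel <- as.numeric(cl$date - idx)
  cl <- cl[rel >= 0 & rel <= config$first_stay_days, , drop = FALSE]
  out <- matrix(
    FALSE, nrow = nrow(pats), ncol = length(config$ssi_codes),
    dimnames = list(pats$patient_id, names(config$ssi_codes))
  )
  for (pred in names(config$ssi_codes)) {
    hit <- has_procedure(cl$procedure_codes, config$ssi_codes[[pred]])
    out[unique(cl$patient_id[hit]), pred] <- TRUE
  }
  out
}
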