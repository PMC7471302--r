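#' Monte-Carlo matched-referent survival
#'
#' Simulates, for every patient in the cohort, `n_replicates` referent
#' lifetimes from the life table matched on sex, completed age and
#' calendar year at index -- the survival the patients would have
#' experienced absent the disease. Each referent walks the table
#' forward month by month (age and calendar year advance together;
#' monthly hazard `-log(1 - q)/12`; calendar years beyond the table's
#' last year reuse the last column). The pooled empirical survival of
#' all simulated lifetimes is returned on the monthly grid, truncated
#' at the first month where it falls below `eps` or the closing age is
#' reached. Deterministic given the seed. Only the patients'
#' demographics enter; their follow-up and vital status do not.
#'
#' @param cohort A `claims_cohort` or data frame with columns `sex`,
#'   `age_at_index` (or `age`) and `index_year` (or `year`).
#' @param lt A [life_table()] covering every (sex, age, index year).
#' @param n_replicates Referent lifetimes per patient (>= 1).
#' @param seed Integer seed.
#' @param eps Pooled-survival truncation threshold.
#' @param max_age Horizon cap in years of age.
#' @return A [survival_curve()] tagged `"referent-MC"`; `n_risk` holds
#'   the number of simulated referents still alive, and the attribute
#'   `mean_lifetime_years` the raw mean of the simulated lifetimes.
#' @export
monte_carlo_reference <- function(cohort, lt, n_replicates = 100,
                                  seed = 1, eps = 1e-6, max_age = 110) {
  pats <- if (inherits(cohort, "claims_cohort")) cohort$patients else cohort
  if (nrow(pats) == 0L) stop("empty cohort")
  if (n_replicates < 1L) stop("`n_replicates` must be at least 1")
  age <- pats$age_at_index %||% pats$age
  year <- pats$index_year %||% pats$year
  if (is.null(age) || is.null(year)) {
    stop("cohort must carry age at index and index calendar year")
  }
  key <- paste(pats$sex, age, year, sep = "|")
  groups <- sort(unique(key))
  counts <- table(key)[groups]

  set.seed(as.integer(seed))
  horizon <- 0L
  deaths_by_group <- vector("list", length(groups))
  total_months <- 0
  n_total <- 0L
  for (gi in seq_along(groups)) {
    parts <- strsplit(groups[gi], "|", fixed = TRUE)[[1L]]
    h <- monthly_hazard_path(lt, parts[1L], as.integer(parts[2L]),
                             as.integer(parts[3L]), max_age = max_age)
    s_cum <- exp(-cumsum(h))
    k <- as.integer(counts[gi]) * as.integer(n_replicates)
    dm <- sim_death_month(s_cum, stats::runif(k))
    deaths_by_group[[gi]] <- tabulate(dm, nbins = length(h))
    total_months <- total_months + sum(dm)
    n_total <- n_total + k
    horizon <- max(horizon, length(h))
  }
  deaths <- numeric(horizon)
  for (d in deaths_by_group) deaths[seq_along(d)] <- deaths[seq_along(d)] + d
  surv <- 1 - cumsum(deaths) / n_total
  surv <- c(1, surv)

  cut <- which(surv < eps)
  last <- if (length(cut)) min(cut) else length(surv)
  surv <- surv[1:last]
  curve <- survival_curve(
    0:(last - 1L), surv,
    n_risk = round(n_total * surv),
    provenance = "referent-MC"
  )
  attr(curve, "mean_lifetime_years") <- total_months / n_total / 12
  attr(curve, "n_simulated") <- n_total
  curve
}

#' One-sample log-rank test of excess mortality
#'
#' Compares the cohort's observed number of deaths with the number
#' expected if every patient had experienced the mortality of their
#' sex-, age- and calendar-year-matched life-table referent over the
#' same follow-up: `E = sum_i H_ref,i(t_i)` (cumulative referent
#' hazard at each patient's censoring or death month) and
#' `Z = (O - E) / sqrt(E)`. A large positive Z says the cohort
#' carries genuine excess mortality; values near zero say its
#' survival is indistinguishable from the referent population, in
#' which case extrapolating a logit-ratio trend would only amplify
#' sampling drift (see [rolling_over_extrapolate()]).
#'
#' @param cohort A `claims_cohort` or patient data frame with `sex`,
#'   `age_at_index`/`age`, `index_year`/`year`, `time_months`,
#'   `event`.
#' @param lt A [life_table()].
#' @param max_age Horizon cap in years of age.
#' @return List with `observed`, `expected` and `z`.
#' @export
excess_mortality_test <- function(cohort, lt, max_age = 110) {
  pats <- if (inherits(cohort, "claims_cohort")) cohort$patients else cohort
  age <- pats$age_at_index %||% pats$age
  year <- pats$index_year %||% pats$year
  time <- as.integer(pats$time_months)
  key <- paste(pats$sex, age, year, sep = "|")
  expected <- 0
  for (g in sort(unique(key))) {
    sel <- key == g
    parts <- strsplit(g, "|", fixed = TRUE)[[1L]]
    h <- monthly_hazard_path(lt, parts[1L], as.integer(parts[2L]),
                             as.integer(parts[3L]), max_age = max_age)
    # the final path month carries an infinite closing hazard and is
    # never part of observed person-time
    cum_h <- c(0, cumsum(h[-length(h)]))
    expected <- expected +
      sum(cum_h[pmin(time[sel], length(h) - 1L) + 1L])
  }
  observed <- sum(pats$event == 1L)
  list(observed = observed, expected = expected,
       z = (observed - expected) / sqrt(max(expected, 1e-12)))
}
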