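#' Age bands for the cumulative incidence rate
#'
#' The thirteen age groups entering the lifetime-risk calculation: a
#' first 7-year band 18-24, then 5-year bands up to 80-84. Ages 85+
#' are deliberately excluded: at those ages the small populations and
#' case counts would let noisy rates dominate the cumulative sum.
#'
#' @return Data frame with `age_group`, `lower`, `upper`, `width`.
#' @export
age_bands_18_84 <- function() {
  lower <- c(18, seq(25, 80, by = 5))
  upper <- c(24, seq(29, 84, by = 5))
  data.frame(
    age_group = paste0(lower, "-", upper),
    lower = lower, upper = upper,
    width = upper - lower + 1,
    stringsAsFactors = FALSE
  )
}

assign_age_band <- function(age) {
  bands <- age_bands_18_84()
  idx <- findInterval(age, bands$lower)
  out <- rep(NA_character_, length(age))
  ok <- !is.na(age) & age >= 18 & age <= 84
  out[ok] <- bands$age_group[idx[ok]]
  out
}

#' Tabulate new cases by sex, age band and calendar year
#'
#' Counts index events per stratum from a cohort's patient table,
#' restricted to ages 18-84 at index (the range the CIR uses). Carries
#' the subtype through when present.
#'
#' @param patients Patient table with `sex`, `age_at_index` (or
#'   `age`), `index_year` (or `year`), optionally `subtype`.
#' @return Data frame `sex` (, `subtype`), `age_group`, `year`,
#'   `cases`.
#' @export
count_new_cases <- function(patients) {
  age <- patients$age_at_index %||% patients$age
  year <- patients$index_year %||% patients$year
  band <- assign_age_band(age)
  keep <- !is.na(band)
  df <- data.frame(
    sex = patients$sex[keep], age_group = band[keep],
    year = year[keep], stringsAsFactors = FALSE
  )
  if (!is.null(patients$subtype)) df$subtype <- patients$subtype[keep]
  agg <- stats::aggregate(
    list(cases = rep(1L, nrow(df))),
    by = df[, setdiff(names(df), "cases"), drop = FALSE], FUN = sum
  )
  agg
}

period_of_year <- function(year, periods) {
  starts <- as.integer(substr(periods, 1L, 4L))
  ends <- as.integer(substr(periods, 6L, 9L))
  out <- rep(NA_character_, length(year))
  for (i in seq_along(periods)) {
    out[year >= starts[i] & year <= ends[i]] <- periods[i]
  }
  out
}

#' Age- and sex-specific incidence rates
#'
#' Annualised incidence per stratum: yearly case counts are scaled up
#' by the sampling fraction of the corresponding year (the sample-to-
#' population factor), pooled into the census periods, and divided by
#' the period population times the period length in years.
#'
#' @param cases Data frame `sex` (, `subtype`), `age_group`, `year`,
#'   `cases`.
#' @param census Data frame `sex`, `age_group`, `period`,
#'   `population` (person counts), periods formatted `"YYYY-YYYY"`.
#' @param sampling Sampling fraction: a single number in (0, 1] or a
#'   data frame `year`, `fraction`.
#' @return An `incidence_table` data frame: stratum columns, scaled
#'   `cases`, `population`, band `width`, annualised `ir`.
#' @export
incidence_rates <- function(cases, census, sampling = 1) {
  bands <- age_bands_18_84()
  if (is.data.frame(sampling)) {
    frac <- sampling$fraction[match(cases$year, sampling$year)]
    if (anyNA(frac)) {
      stop("sampling fraction missing for year(s) ",
           paste(unique(cases$year[is.na(frac)]), collapse = ", "))
    }
  } else {
    frac <- rep(sampling, nrow(cases))
  }
  if (any(frac <= 0 | frac > 1)) {
    stop("sampling fractions must lie in (0, 1]")
  }
  periods <- sort(unique(census$period))
  period_years <- as.integer(substr(periods, 6L, 9L)) -
    as.integer(substr(periods, 1L, 4L)) + 1L
  names(period_years) <- periods

  cases$scaled <- cases$cases / frac
  cases$period <- period_of_year(cases$year, periods)
  if (anyNA(cases$period)) {
    stop("case year(s) outside the census periods: ",
         paste(unique(cases$year[is.na(cases$period)]), collapse = ", "))
  }
  by_cols <- intersect(c("subtype", "sex", "age_group", "period"),
                       names(cases))
  agg <- stats::aggregate(list(cases = cases$scaled),
                          by = cases[, by_cols, drop = FALSE], FUN = sum)

  strata <- census
  if ("subtype" %in% by_cols) {
    subtypes <- unique(agg$subtype)
    strata <- do.call(rbind, lapply(subtypes, function(st) {
      s <- census
      s$subtype <- st
      s
    }))
  }
  out <- merge(strata, agg, by = by_cols, all.x = TRUE)
  out$cases[is.na(out$cases)] <- 0
  if (any(out$cases > 0 & out$population <= 0)) {
    stop("cases observed in a stratum with zero population")
  }
  out$width <- bands$width[match(out$age_group, bands$age_group)]
  if (anyNA(out$width)) {
    stop("unknown age group(s): ",
         paste(unique(out$age_group[is.na(out$width)]), collapse = ", "))
  }
  out$ir <- out$cases / (out$population *
                           period_years[out$period])
  ord <- order(
    if ("subtype" %in% names(out)) out$subtype else rep("", nrow(out)),
    out$sex, out$period,
    match(out$age_group, bands$age_group)
  )
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' Lifetime risk: cumulative incidence rate over ages 18-84
#'
#' For every stratum (sex x period, and subtype when present),
#' `CIR = 1 - exp(-sum_i IR_i * w_i)` over the thirteen age bands,
#' with `w_i` the band width in years. Reported alongside as
#' "one in N" with N rounded to the nearest integer.
#'
#' @param table An `incidence_table` from [incidence_rates()] (or any
#'   data frame with `sex`, `age_group`, `period`, `ir`, `width`).
#' @return Data frame (`subtype`,) `sex`, `period`, `cir`, `one_in_n`,
#'   with attribute `variant`.
#' @export
cir_18_84 <- function(table) {
  bands <- age_bands_18_84()
  by_cols <- intersect(c("subtype", "sex", "period"), names(table))
  key <- do.call(paste, c(table[by_cols], sep = "|"))
  out <- lapply(sort(unique(key)), function(k) {
    sub <- table[key == k, , drop = FALSE]
    missing <- setdiff(bands$age_group, sub$age_group)
    if (length(missing) > 0L) {
      stop("stratum ", k, " is missing age band(s): ",
           paste(missing, collapse = ", "))
    }
    cir <- 1 - exp(-sum(sub$ir * sub$width))
    row <- sub[1L, by_cols, drop = FALSE]
    row$cir <- cir
    row$one_in_n <- if (cir > 0) round(1 / cir) else NA_real_
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "variant") <- attr(table, "variant") %||% "unadjusted"
  out
}

#' Prevalence-adjusted incidence table
#'
#' Sensitivity analysis subtracting known prevalent cases from the
#' population denominators (numerators untouched), which inflates the
#' rates and yields an upper bound on the CIR.
#'
#' @param table An `incidence_table`.
#' @param prevalence Data frame `sex`, `age_group`, `period`,
#'   `prevalence` (person counts); strata absent default to 0.
#' @param variant Label stored on the result.
#' @return The adjusted `incidence_table`.
#' @export
prevalence_adjust <- function(table, prevalence,
                              variant = "prevalence-adjusted") {
  period_years <- vapply(strsplit(table$period, "-"), function(p) {
    as.integer(p[2L]) - as.integer(p[1L]) + 1L
  }, integer(1L))
  m <- merge(
    as.data.frame(table), prevalence,
    by = intersect(c("sex", "age_group", "period"), names(prevalence)),
    all.x = TRUE, sort = FALSE
  )
  m$prevalence[is.na(m$prevalence)] <- 0
  if (any(m$prevalence > m$population)) {
    stop("prevalent cases exceed the population in some stratum")
  }
  # merge() may reorder; recompute on the merged frame
  key_t <- do.call(paste, c(table[c("sex", "age_group", "period")],
                            sep = "|"))
  key_m <- do.call(paste, c(m[c("sex", "age_group", "period")],
                            sep = "|"))
  m <- m[match(key_t, key_m), , drop = FALSE]
  out <- as.data.frame(table)
  out$population <- m$population - m$prevalence
  out$ir <- out$cases / (out$population * period_years)
  out$ir[out$population == 0 & out$cases == 0] <- 0
  rownames(out) <- NULL
  class(out) <- c("incidence_table", "data.frame")
  attr(out, "variant") <- variant
  out
}

#' Micro-simulation oracle for the CIR formula
#'
#' Brute-force check of the closed-form lifetime risk: simulate
#' individuals ageing from 18 to 84 under the per-band constant annual
#' hazards `IR_i` and report the fraction ever experiencing the event.
#' Converges to `1 - exp(-sum IR_i w_i)` as n grows.
#'
#' @param ir Per-band annual rates (length 13, ordered as
#'   [age_bands_18_84()]), or a one-stratum `incidence_table`.
#' @param n_individuals Number of simulated individuals (>= 1e4).
#' @param seed Integer seed.
#' @return Proportion ever experiencing the event.
#' @export
cir_micro_oracle <- function(ir, n_individuals = 1e5, seed = 1) {
  if (is.data.frame(ir)) {
    bands <- age_bands_18_84()
    ir <- ir$ir[match(bands$age_group, ir$age_group)]
  }
  bands <- age_bands_18_84()
  if (length(ir) != nrow(bands) || anyNA(ir)) {
    stop("`ir` must supply a rate for each of the 13 bands")
  }
  if (n_individuals < 1e4) {
    stop("at least 10^4 individuals are required for a stable oracle")
  }
  set.seed(as.integer(seed))
  p_band <- 1 - exp(-ir * bands$width)
  event <- rep(FALSE, n_individuals)
  for (b in seq_along(p_band)) {
    event <- event | (stats::runif(n_individuals) < p_band[b])
  }
  mean(event)
}

# Note on subtype in prevalence_adjust: adjustment keys on
# sex/age_group/period, applying the same denominator correction to
# every subtype's table, as prevalence sources report totals.
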