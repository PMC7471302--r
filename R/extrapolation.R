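#' Logit survival-ratio series
#'
#' The working series of the extrapolation algorithm:
#' `W(m) = logit(S_index(m) / S_ref(m))` on the months where the index
#' cohort's survival is still positive. The ratio is clipped into
#' `[1e-12, 1 - 1e-12]` before the logit so the transform is always
#' finite; month 0, where both curves equal 1 by construction, carries
#' no information and is not part of the series.
#'
#' Each point additionally carries an `informative` flag: points whose
#' ratio had to be clipped at a boundary are measurements of "at least
#' as good as the referent" (or extinct), not of the excess hazard,
#' and the extrapolation fit treats them accordingly (see
#' [rolling_over_extrapolate()]).
#'
#' @param index Index-cohort [survival_curve()] (Kaplan-Meier over
#'   follow-up).
#' @param ref Referent [survival_curve()]; must cover the index grid.
#' @param clip_lo,clip_hi Clipping bounds applied to the ratio.
#' @return A `logit_ratio_series` with fields `month`, `W` and
#'   `informative`.
#' @export
logit_ratio <- function(index, ref, clip_lo = 1e-12,
                        clip_hi = 1 - 1e-12) {
  last_pos <- max(index$month[index$surv > 0])
  if (last_pos < 1L) {
    stop("index survival reaches 0 immediately; no ratio series exists")
  }
  if (max(ref$month) < last_pos) {
    stop("grids misaligned: referent curve ends at month ",
         max(ref$month), " but the index curve is positive to month ",
         last_pos)
  }
  months <- 1:last_pos
  s_idx <- curve_surv_at(index, months)
  s_ref <- curve_surv_at(ref, months)
  r_raw <- s_idx / s_ref
  r <- clip(r_raw, clip_lo, clip_hi)
  informative <- r_raw > clip_lo & r_raw < clip_hi
  structure(
    list(month = months, W = stats::qlogis(r), ratio = r_raw,
         informative = informative,
         followup_end = max(index$month)),
    class = "logit_ratio_series"
  )
}

#' Rolling-over extrapolation of index-cohort survival
#'
#' Extends the index cohort's survival to the referent's lifetime
#' horizon by iterating one month at a time: fit an ordinary
#' least-squares line of W on month over the trailing `window` points
#' (observed plus previously extrapolated), predict W at the next
#' month, reconstruct survival there as `expit(W) * S_ref`, clip it at
#' the previous value so the curve stays non-increasing, append the
#' predicted point and roll forward. Over follow-up the returned curve
#' coincides exactly with the Kaplan-Meier estimate.
#'
#' Two fitting modes exist. In `"linear"` mode (the default) the OLS
#' line has intercept and slope, and each fit uses only the
#' informative points of its window (boundary-clipped points measure
#' "no detectable excess", not the excess trend; a window with fewer
#' than two informative points falls back to all its points, whose
#' boundary-dominated constant fit reproduces the referent curve). In
#' `"constant"` mode no trend is fitted: the raw survival ratio is
#' carried forward at its average level over the trailing window (the
#' raw, unclipped ratio, so sampling noise around a true ratio of 1
#' stays symmetric and no spurious lifetime loss accumulates).
#' Linear extrapolation of the logit-ratio trend is only warranted
#' when the cohort actually displays excess mortality over its
#' referents; for a cohort statistically indistinguishable from them
#' the "trend" is sampling drift, and amplifying it over decades
#' collapses the tail. [estimate_lifetime()] and
#' [validate_extrapolation()] therefore select the mode with the
#' one-sample log-rank test of [excess_mortality_test()].
#'
#' @param series A [logit_ratio()] series.
#' @param ref Referent [survival_curve()] extending to the lifetime
#'   horizon.
#' @param index The index-cohort [survival_curve()] the series was
#'   built from.
#' @param window Number of trailing points in each fit; default uses
#'   the whole observed series.
#' @param horizon Last month to extrapolate to; defaults to the
#'   referent's horizon.
#' @param trend `"linear"` (fit and continue the logit-ratio trend) or
#'   `"constant"` (carry the ratio level forward).
#' @return A [survival_curve()] on months 0..`horizon`, tagged
#'   `"index-KM"` over follow-up and `"extrapolated"` beyond.
#' @export
rolling_over_extrapolate <- function(series, ref, index, window = NULL,
                                     horizon = NULL,
                                     trend = c("linear", "constant")) {
  trend <- match.arg(trend)
  stopifnot(inherits(series, "logit_ratio_series"))
  n_obs <- length(series$month)
  window <- as.integer(window %||% n_obs)
  if (window < 2L) stop("`window` must be at least 2 points")
  if (n_obs < window) {
    stop("the observed series has ", n_obs,
         " points, fewer than the window (", window, ")")
  }
  horizon <- as.integer(horizon %||% max(ref$month))
  if (horizon > max(ref$month)) {
    stop("referent curve ends at month ", max(ref$month),
         ", before the requested horizon ", horizon)
  }
  km_end <- series$followup_end
  if (horizon < km_end) {
    stop("referent horizon is shorter than the observed follow-up")
  }

  surv_out <- numeric(horizon + 1L)
  prov <- rep("index-KM", horizon + 1L)
  obs_months <- 0:km_end
  surv_out[obs_months + 1L] <- curve_surv_at(index, obs_months)

  start <- km_end + 1L
  if (start <= horizon) {
    if (surv_out[km_end + 1L] <= 0) {
      # cohort extinct within follow-up: nothing left to extrapolate
      surv_out[(start:horizon) + 1L] <- 0
    } else {
      mm <- c(series$month, numeric(horizon - km_end))
      ww <- c(series$W, numeric(horizon - km_end))
      rr <- c(series$ratio, numeric(horizon - km_end))
      usable <- c(series$informative, rep(TRUE, horizon - km_end))
      k <- length(series$month)
      ref_surv <- curve_surv_at(ref, start:horizon)
      prev <- surv_out[km_end + 1L]
      for (m in start:horizon) {
        sel <- (k - window + 1L):k
        if (trend == "linear") {
          keep <- sel[usable[sel]]
          if (length(keep) >= 2L) sel <- keep
          line <- ols_line(mm[sel], ww[sel])
          w_hat <- line[1L] + line[2L] * m
          r_hat <- stats::plogis(w_hat)
        } else {
          r_hat <- mean(rr[sel])
          w_hat <- stats::qlogis(clip(r_hat, 1e-12, 1 - 1e-12))
        }
        s_hat <- min(r_hat * ref_surv[m - start + 1L], prev)
        surv_out[m + 1L] <- s_hat
        prev <- s_hat
        k <- k + 1L
        mm[k] <- m
        ww[k] <- w_hat
        rr[k] <- r_hat
      }
    }
    prov[(start:horizon) + 1L] <- "extrapolated"
  }
  survival_curve(0:horizon, surv_out, provenance = prov)
}

#' Life expectancy and expected years of life lost
#'
#' Integrates the extrapolated lifetime curve of the index cohort and
#' the matched-referent curve (trapezoidal rule on the monthly grid,
#' years = months / 12). EYLL is their difference: the expected years
#' of life a case loses relative to the age-, sex- and calendar-year-
#' matched reference population.
#'
#' @param index_lifetime Extrapolated index [survival_curve()].
#' @param ref Referent [survival_curve()].
#' @param eps Extinction tolerance; both curves must have fallen below
#'   it, otherwise the integrals would be silently truncated.
#' @return A `lifetime_estimate` list with `LE`, `LE_ref` and `EYLL`
#'   (years).
#' @export
le_eyll <- function(index_lifetime, ref, eps = 1e-6) {
  le <- reference_life_expectancy(index_lifetime, eps = eps)
  le_ref <- reference_life_expectancy(ref, eps = eps)
  structure(
    list(LE = le, LE_ref = le_ref, EYLL = le_ref - le),
    class = "lifetime_estimate"
  )
}

#' One-call lifetime estimation for a cohort
#'
#' Convenience wrapper running the full survival chain: Kaplan-Meier
#' over follow-up, Monte-Carlo referents from the life table, the
#' logit survival-ratio rolling-over extrapolation, and the LE / EYLL
#' integrals. By default the chain runs within sex-by-age-band strata
#' and pools the stratum curves by size: the logit-ratio trend of a
#' wide age mixture decelerates as its frailer members die off
#' (selection), so extrapolating the pooled mixture overstates the
#' lifetime loss, while within near-homogeneous strata the trend is
#' stable. Whether any trend is extrapolated at all is decided once
#' per cohort by the excess-mortality test (see
#' [rolling_over_extrapolate()]).
#'
#' @param cohort A `claims_cohort` or a patient data frame with
#'   `sex`, `age_at_index`, `index_year`, `time_months`, `event`.
#' @param lt A [life_table()].
#' @param n_replicates Referent replicates per patient.
#' @param seed Seed for the referent simulation.
#' @param window Trailing rolling window in months (36 by default: a
#'   trailing fit tracks the current excess-hazard regime, whereas the
#'   full-history line inherits the steep early post-diagnosis
#'   decline; `NULL` uses the whole observed series).
#' @param trend_z Threshold on the [excess_mortality_test()] Z
#'   statistic above which the logit-ratio trend is extrapolated
#'   linearly; below it the ratio level is carried forward (see
#'   [rolling_over_extrapolate()]).
#' @param stratify Run the chain within sex-by-age-band strata
#'   (default) or on the pooled cohort.
#' @param eps,max_age Passed to [monte_carlo_reference()].
#' @return A `lifetime_estimate` with the curves attached
#'   (`$index_curve`, `$ref_curve`) and the excess-mortality test
#'   (`$excess_test`).
#' @export
estimate_lifetime <- function(cohort, lt, n_replicates = 100, seed = 1,
                              window = 36, trend_z = 2,
                              stratify = TRUE, eps = 1e-6,
                              max_age = 110) {
  pats <- if (inherits(cohort, "claims_cohort")) cohort$patients else cohort
  xt <- excess_mortality_test(pats, lt, max_age = max_age)
  trend <- if (xt$z > trend_z) "linear" else "constant"
  curves <- extrapolate_stratified(
    pats, lt, n_replicates = n_replicates, seed = seed,
    window = window, trend = trend, stratify = stratify,
    eps = eps, max_age = max_age
  )
  est <- le_eyll(curves$index_curve, curves$ref_curve, eps = eps)
  est$index_curve <- curves$index_curve
  est$ref_curve <- curves$ref_curve
  est$excess_test <- xt
  est$n_strata <- curves$n_strata
  est
}

# Strata for the extrapolation: sex crossed with age bands, with
# adjacent bands merged (per sex) until every stratum holds at least
# `min_stratum` patients. Survival within a stratum must be near-
# homogeneous for the pooled logit-ratio trend to extrapolate cleanly
# (the ratio of a wide age mixture decelerates as its frailer members
# die off, and a linear trend fitted to the mixture over-extrapolates
# the decline), but strata too small make the trend fit noise.
stratum_key <- function(pats, min_stratum = 200L) {
  age <- pats$age_at_index %||% pats$age
  breaks <- c(-Inf, 44, 54, 64, 74, 84, Inf)
  band <- as.integer(cut(age, breaks = breaks))
  key <- character(nrow(pats))
  for (s in unique(pats$sex)) {
    sel <- pats$sex == s
    counts <- tabulate(band[sel], nbins = 6L)
    group <- integer(6L)
    g <- 1L
    acc <- 0L
    for (b in 1:6) {
      group[b] <- g
      acc <- acc + counts[b]
      if (acc >= min_stratum && b < 6L) {
        g <- g + 1L
        acc <- 0L
      }
    }
    # a trailing group below the minimum joins its predecessor
    if (acc < min_stratum && g > 1L) {
      group[group == g] <- g - 1L
    }
    key[sel] <- paste(s, group[band[sel]])
  }
  key
}

# Run referent simulation + KM + rolling-over extrapolation per
# stratum and pool the curves by stratum size. `horizon = NULL`
# extrapolates each stratum to its referent horizon (lifetime);
# a stratum extinct before its horizon contributes zeros beyond.
extrapolate_stratified <- function(pats, lt, n_replicates, seed,
                                   window, trend, stratify = TRUE,
                                   horizon = NULL, eps = 1e-6,
                                   max_age = 110) {
  key <- if (stratify) stratum_key(pats) else rep("all", nrow(pats))
  groups <- sort(unique(key))
  curves <- vector("list", length(groups))
  refs <- vector("list", length(groups))
  wts <- numeric(length(groups))
  h_max <- 0L
  for (gi in seq_along(groups)) {
    sub <- pats[key == groups[gi], , drop = FALSE]
    ref <- monte_carlo_reference(sub, lt, n_replicates = n_replicates,
                                 seed = seed + gi, eps = eps,
                                 max_age = max_age)
    km <- kaplan_meier(sub)
    h_g <- horizon %||% max(ref$month)
    w_g <- if (is.null(window)) NULL else {
      min(window, sum(km$surv[km$month >= 1L] > 0))
    }
    if (!is.null(w_g) && w_g < 2L) w_g <- 2L
    if (max(km$surv[km$month >= 1L]) <= 0) {
      # stratum extinct within follow-up: its lifetime curve is the
      # KM steps followed by zeros
      s <- km$surv[match(0:h_g, km$month)]
      s[is.na(s)] <- 0
      ext <- survival_curve(0:h_g, s)
    } else {
      series <- logit_ratio(km, ref)
      ext <- rolling_over_extrapolate(series, ref, km, window = w_g,
                                      horizon = h_g, trend = trend)
    }
    curves[[gi]] <- ext
    refs[[gi]] <- ref
    wts[gi] <- nrow(sub)
    h_max <- max(h_max, max(ext$month), max(ref$month))
  }
  pool <- function(lst, provenance) {
    s <- numeric(h_max + 1L)
    for (gi in seq_along(lst)) {
      v <- lst[[gi]]$surv[match(0:h_max, lst[[gi]]$month)]
      v[is.na(v)] <- 0
      s <- s + wts[gi] * v
    }
    survival_curve(0:h_max, s / sum(wts), provenance = provenance)
  }
  list(index_curve = pool(curves, "extrapolated"),
       ref_curve = pool(refs, "referent-MC"),
       n_strata = length(groups))
}

#' Bootstrap standard errors for lifetime estimates
#'
#' Resamples patients with replacement, reruns an arbitrary
#' estimation closure on each resample (the referent simulation seed
#' is offset per replicate so referent noise is independent across
#' replicates), and reports the sample standard deviation of every
#' returned quantity. Replicates that fail are recorded and skipped;
#' more than `max_fail` of them failing is an error.
#'
#' @param cohort Patient data frame (or `claims_cohort`).
#' @param statistic Function `(patients, replicate_seed) ->` named
#'   numeric vector.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed Master seed; replicate seeds derive from it.
#' @param max_fail Tolerated failure fraction.
#' @return List with `se` (named vector), `replicates` (B x q matrix)
#'   and `n_failed`.
#' @export
bootstrap_se <- function(cohort, statistic, B = 100, seed = 1,
                         max_fail = 0.1) {
  pats <- if (inherits(cohort, "claims_cohort")) cohort$patients else cohort
  if (B < 2L) stop("`B` must be at least 2")
  n <- nrow(pats)
  rep_seeds <- (as.integer(seed) %% 1000000L) * 1000L + seq_len(B)
  rows <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    rows[[b]] <- tryCatch(
      statistic(pats[idx, , drop = FALSE], rep_seeds[b]),
      error = function(e) NULL
    )
  }
  ok <- !vapply(rows, is.null, logical(1L))
  if (mean(!ok) > max_fail) {
    stop(sum(!ok), " of ", B, " bootstrap replicates failed")
  }
  mat <- do.call(rbind, rows[ok])
  list(se = apply(mat, 2L, stats::sd), replicates = mat,
       n_failed = sum(!ok))
}

#' Short-horizon validation of the extrapolation
#'
#' Empirical check mirroring a split-sample design: censor every
#' follow-up at `fit_months`, extrapolate to `test_months`, and
#' compare the extrapolated restricted mean survival with the
#' Kaplan-Meier restricted mean computed from the full data, as
#' `relative_bias = (extrapolated - observed) / observed`.
#'
#' @param cohort Patient data frame or `claims_cohort`.
#' @param lt A [life_table()].
#' @param fit_months Months of follow-up made available to the fit.
#' @param test_months Horizon of the comparison (>= `fit_months`).
#' @param n_replicates,seed,window,trend_z,stratify,max_age Passed
#'   through to the referent simulation and stratified extrapolation
#'   (see [estimate_lifetime()]).
#' @return A `validation_result` list with `extrapolated`, `observed`
#'   (restricted means in years) and `relative_bias`.
#' @export
validate_extrapolation <- function(cohort, lt, fit_months = 60,
                                   test_months = 120,
                                   n_replicates = 100, seed = 1,
                                   window = 36, trend_z = 2,
                                   stratify = TRUE, max_age = 110) {
  pats <- if (inherits(cohort, "claims_cohort")) cohort$patients else cohort
  if (test_months < fit_months) {
    stop("`test_months` must be at least `fit_months`")
  }
  if (max(pats$time_months) < test_months) {
    stop("no patient was followed to ", test_months,
         " months; the observed restricted mean is not estimable")
  }
  km_full <- kaplan_meier(pats, max_months = test_months)
  observed <- restricted_mean(km_full, test_months)

  if (test_months == fit_months) {
    return(structure(
      list(extrapolated = observed, observed = observed,
           relative_bias = 0),
      class = "validation_result"
    ))
  }
  cens <- pats
  cens$event <- ifelse(cens$time_months <= fit_months, cens$event, 0L)
  cens$time_months <- pmin(cens$time_months, fit_months)
  if (!any(cens$time_months > 0)) {
    stop("no follow-up remains after censoring at ", fit_months)
  }
  xt <- excess_mortality_test(cens, lt, max_age = max_age)
  curves <- extrapolate_stratified(
    cens, lt, n_replicates = n_replicates, seed = seed,
    window = window, trend = if (xt$z > trend_z) "linear" else "constant",
    stratify = stratify, horizon = test_months, max_age = max_age
  )
  extrapolated <- restricted_mean(curves$index_curve, test_months)
  structure(
    list(extrapolated = extrapolated, observed = observed,
         relative_bias = (extrapolated - observed) / observed),
    class = "validation_result"
  )
}
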