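#' Observed monthly mean costs
#'
#' Per month since index, the mean insurer-paid and copayment cost
#' among the patients still under observation (alive and uncensored)
#' that month; a patient whose follow-up ends at month t contributes
#' to months 0..t-1. Months with nobody under observation are absent.
#'
#' @param cohort A `claims_cohort` (uses `$costs` and
#'   `$patients$time_months`), or a list with those two elements.
#' @return A `cost_profile` data frame: `month`, `insurer`, `copay`,
#'   `n_contributing`, `provenance` (`"observed"`).
#' @export
monthly_mean_costs <- function(cohort) {
  costs <- cohort$costs
  pats <- cohort$patients
  if (is.null(costs) || is.null(pats)) {
    stop("`cohort` must carry `costs` and `patients`")
  }
  if (any(costs$insurer < 0) || any(costs$copay < 0)) {
    stop("negative costs are invalid")
  }
  time <- stats::setNames(pats$time_months, pats$patient_id)
  horizon <- max(time)
  if (horizon < 1L) stop("no observed person-time")
  months <- 0:(horizon - 1L)
  n_contrib <- vapply(months, function(m) sum(time > m), numeric(1L))

  keep <- costs$month < time[costs$patient_id]
  cc <- costs[keep, , drop = FALSE]
  ins <- rep(0, length(months))
  cop <- rep(0, length(months))
  if (nrow(cc) > 0L) {
    si <- rowsum(cc$insurer, cc$month)
    sc <- rowsum(cc$copay, cc$month)
    idx <- match(as.integer(rownames(si)), months)
    ins[idx] <- as.numeric(si)
    cop[idx] <- as.numeric(sc)
  }
  out <- data.frame(
    month = months,
    insurer = ifelse(n_contrib > 0, ins / n_contrib, NA_real_),
    copay = ifelse(n_contrib > 0, cop / n_contrib, NA_real_),
    n_contributing = n_contrib,
    provenance = "observed",
    stringsAsFactors = FALSE
  )
  out <- out[out$n_contributing > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cost_profile", "data.frame")
  out
}

#' Extrapolate monthly mean costs beyond follow-up
#'
#' Extends the observed cost profile to the lifetime horizon with the
#' same rolling-over scheme as the survival extrapolation, applied on
#' the `log(1 + cost)` scale to keep costs positive: fit an OLS line
#' over the trailing `window` points (observed plus previously
#' extrapolated), predict the next month, transform back, floor at 0,
#' roll forward. This lets the trend observed toward the end of
#' follow-up -- typically rising as more survivors approach the end of
#' life -- continue smoothly.
#'
#' @param profile A `cost_profile` from [monthly_mean_costs()].
#' @param lifetime The extrapolated lifetime [survival_curve()]; its
#'   horizon defines the last cost month (`horizon - 1`).
#' @param window Trailing points per fit; default the whole observed
#'   profile.
#' @return The profile extended to the horizon, extrapolated months
#'   tagged `"extrapolated"` with `n_contributing = 0`.
#' @export
extrapolate_costs <- function(profile, lifetime, window = NULL) {
  n_obs <- nrow(profile)
  window <- as.integer(window %||% n_obs)
  if (window < 2L) stop("`window` must be at least 2 points")
  if (n_obs < window) {
    stop("observed cost profile has fewer points than the window")
  }
  horizon <- max(lifetime$month)
  if (max(profile$month) >= horizon - 1L) return(profile)
  new_months <- seq.int(max(profile$month) + 1L, horizon - 1L)

  extrap_stream <- function(y_obs) {
    mm <- c(profile$month, new_months)
    yy <- c(log1p(y_obs), numeric(length(new_months)))
    k <- n_obs
    for (i in seq_along(new_months)) {
      sel <- (k - window + 1L):k
      line <- ols_line(mm[sel], yy[sel])
      y_hat <- line[1L] + line[2L] * new_months[i]
      k <- k + 1L
      yy[k] <- y_hat
    }
    pmax(expm1(yy[(n_obs + 1L):k]), 0)
  }
  ext <- data.frame(
    month = new_months,
    insurer = extrap_stream(profile$insurer),
    copay = extrap_stream(profile$copay),
    n_contributing = 0,
    provenance = "extrapolated",
    stringsAsFactors = FALSE
  )
  out <- rbind(as.data.frame(profile), ext)
  rownames(out) <- NULL
  class(out) <- c("cost_profile", "data.frame")
  out
}

#' Survival-weighted discounted lifetime cost
#'
#' Lifetime expected cost per case: the monthly mean costs weighted by
#' the probability of still being alive and discounted at an annual
#' rate compounded monthly,
#' `sum_m S(m) * cost(m) * (1 + r)^(-m/12)`, per payment stream.
#'
#' @param profile A `cost_profile` covering months 0..horizon-1.
#' @param lifetime The lifetime [survival_curve()] sharing the grid.
#' @param annual_rate Annual discount rate (default 3%; 0% and 5% are
#'   the usual sensitivity settings).
#' @return List with `insurer`, `copay`, `total`, `copay_share` and
#'   `annual_rate`.
#' @export
lifetime_cost <- function(profile, lifetime, annual_rate = 0.03) {
  if (annual_rate < 0) stop("`annual_rate` must be non-negative")
  horizon <- max(lifetime$month)
  if (!identical(as.integer(profile$month),
                 as.integer(0:(horizon - 1L)))) {
    stop("grid mismatch: the cost profile must cover months 0..",
         horizon - 1L, " of the lifetime curve")
  }
  s <- curve_surv_at(lifetime, profile$month)
  disc <- (1 + annual_rate)^(-profile$month / 12)
  insurer <- sum(s * profile$insurer * disc)
  copay <- sum(s * profile$copay * disc)
  total <- insurer + copay
  list(
    insurer = insurer, copay = copay, total = total,
    copay_share = if (total > 0) copay / total else NA_real_,
    annual_rate = annual_rate
  )
}

#' Convert KRW amounts to USD
#'
#' @param amount Amount(s) in KRW.
#' @param rate KRW per USD; the 2015 average exchange rate 1,131.2 is
#'   the default.
#' @return Amount(s) in USD.
#' @export
convert_currency <- function(amount, rate = 1131.2) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a positive number (KRW per USD)")
  }
  amount / rate
}
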