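#' Kaplan-Meier survival of the index cohort on the monthly grid
#'
#' Product-limit estimate of the cohort's survival from the index
#' month, evaluated at every month of follow-up. Follow-up durations
#' are taken in integer months (see `time_months` on the cohort's
#' patient table: days snapped to 30.4375-day months by interval
#' membership); within a month, deaths are handled before censorings
#' (the usual product-limit tie convention). Events recorded at month
#' 0 (death on the index day) drop the curve immediately after time 0,
#' so the stored S(0) remains 1 and the drop shows at month 1.
#'
#' @param cohort A `claims_cohort` from [build_cohort()], or any data
#'   frame with columns `time_months` and `event` (1 = died,
#'   0 = censored).
#' @param max_months Optional grid horizon; defaults to the largest
#'   observed follow-up (the curve is flat beyond the last event).
#' @return A [survival_curve()] with per-month numbers at risk.
#' @export
kaplan_meier <- function(cohort, max_months = NULL) {
  pats <- if (inherits(cohort, "claims_cohort")) cohort$patients else cohort
  if (!all(c("time_months", "event") %in% names(pats))) {
    stop("`cohort` must carry `time_months` and `event`")
  }
  n <- nrow(pats)
  if (n == 0L) stop("cannot estimate survival from zero patients")
  time <- as.numeric(pats$time_months)
  event <- as.integer(pats$event)
  if (any(time < 0)) stop("negative follow-up durations")
  if (all(time == 0) && all(event == 0)) {
    stop("all patients censored at time 0: survival is unidentifiable")
  }
  # time-0 records are placed just after 0 so S(0) = 1 by construction
  time[time == 0] <- 0.5
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  horizon <- as.integer(max_months %||% max(ceiling(time)))
  sm <- summary(fit, times = 0:horizon, extend = TRUE)
  survival_curve(0:horizon, sm$surv, n_risk = sm$n.risk,
                 provenance = "index-KM")
}
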