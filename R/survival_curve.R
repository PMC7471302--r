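#' Survival curve on a monthly grid
#'
#' Container shared by every stage of the pipeline: the index cohort's
#' Kaplan-Meier estimate, the Monte-Carlo referent curve, and the
#' extrapolated lifetime curve are all `survival_curve` objects -- a
#' data frame with one row per month from 0 (the index date) to the
#' horizon, a survival probability `surv`, the number at risk `n_risk`
#' (`NA` where not meaningful, e.g. analytic curves), and a per-point
#' `provenance` tag (`"index-KM"`, `"referent-MC"`, `"extrapolated"`,
#' `"truth"`, ...).
#'
#' @param month Integer vector of contiguous months starting at 0.
#' @param surv Survival probabilities; must start at 1, lie in
#'   \[0, 1\] and be non-increasing.
#' @param n_risk Optional number at risk per month.
#' @param provenance Character tag, recycled to the grid length.
#' @return A `survival_curve` (also a `data.frame`).
#' @examples
#' survival_curve(0:3, c(1, 0.9, 0.8, 0.8))
#' @export
survival_curve <- function(month, surv, n_risk = NULL, provenance = "index-KM") {
  month <- as.integer(month)
  if (length(month) != length(surv)) {
    stop("`month` and `surv` must have the same length")
  }
  if (length(month) < 1L || month[1L] != 0L) {
    stop("a survival curve must start at month 0")
  }
  if (length(month) > 1L && any(diff(month) != 1L)) {
    stop("a survival curve must live on a contiguous monthly grid")
  }
  if (abs(surv[1L] - 1) > 1e-9) stop("S(0) must equal 1")
  if (any(surv < -1e-9 | surv > 1 + 1e-9)) {
    stop("survival probabilities must lie in [0, 1]")
  }
  if (any(diff(surv) > 1e-9)) stop("a survival curve must be non-increasing")
  if (is.null(n_risk)) n_risk <- rep(NA_real_, length(month))
  provenance <- rep_len(as.character(provenance), length(month))
  out <- data.frame(
    month = month,
    surv = clip(surv, 0, 1),
    n_risk = as.numeric(n_risk),
    provenance = provenance,
    stringsAsFactors = FALSE
  )
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' @export
print.survival_curve <- function(x, ...) {
  horizon <- max(x$month)
  cat(sprintf(
    "<survival_curve> %d months, S(end) = %.3g, provenance: %s\n",
    horizon, x$surv[nrow(x)], paste(unique(x$provenance), collapse = " + ")
  ))
  invisible(x)
}

# Survival probability at the requested months (must be on the grid).
curve_surv_at <- function(curve, months) {
  idx <- match(as.integer(months), curve$month)
  if (anyNA(idx)) {
    stop("months ", paste(months[is.na(idx)], collapse = ", "),
         " are not on the curve's grid")
  }
  curve$surv[idx]
}

#' Restricted mean survival time
#'
#' Trapezoidal integral of the survival curve from month 0 to
#' `horizon_months`, returned in years (months / 12).
#'
#' @param curve A [survival_curve()].
#' @param horizon_months Integration horizon; must not exceed the grid.
#' @return Restricted mean survival in years.
#' @export
restricted_mean <- function(curve, horizon_months) {
  horizon_months <- as.integer(horizon_months)
  if (horizon_months < 0L) stop("`horizon_months` must be non-negative")
  if (horizon_months > max(curve$month)) {
    stop("horizon ", horizon_months, " lies beyond the curve's grid (",
         max(curve$month), " months)")
  }
  trapz_unit(curve$surv[curve$month <= horizon_months]) / 12
}

#' Life expectancy from a lifetime survival curve
#'
#' Trapezoidal integral of the full curve in years. The curve must have
#' effectively reached zero (`S(end) < eps`), otherwise the integral
#' would be silently truncated and the result is an error.
#'
#' @param ref A [survival_curve()] extending to its lifetime horizon.
#' @param eps Tail tolerance below which the cohort counts as extinct.
#' @return Life expectancy in years.
#' @export
reference_life_expectancy <- function(ref, eps = 1e-6) {
  if (ref$surv[nrow(ref)] >= eps) {
    stop("curve has not reached the extinction tolerance (S(end) = ",
         signif(ref$surv[nrow(ref)], 3), " >= ", eps,
         "); integrating it would truncate the mean")
  }
  trapz_unit(ref$surv) / 12
}

#' Write / read a survival curve as CSV
#'
#' Plain-text interchange format shared by the referent and index
#' curves: columns `month`, `surv`, `n_risk`, `provenance`.
#'
#' @param curve A [survival_curve()].
#' @param path File path.
#' @return `read_survival_curve` returns a [survival_curve()].
#' @export
write_survival_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_curve
#' @export
read_survival_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  survival_curve(df$month, df$surv, df$n_risk, df$provenance)
}
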