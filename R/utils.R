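# Internal helpers shared across modules.

# Average Gregorian month; all follow-up is binned on this grid.
DAYS_PER_MONTH <- 30.4375

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Trapezoidal integral of a vector sampled on a unit (monthly) grid.
trapz_unit <- function(y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) / 2)
}

# Snap a follow-up duration in days to the monthly grid by interval
# membership: a duration inside (m-1, m] months maps to month m; day 0
# maps to month 0.
days_to_months <- function(days) {
  as.integer(ceiling(as.numeric(days) / DAYS_PER_MONTH))
}

as_date <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}

year_of <- function(d) as.integer(format(as_date(d), "%Y"))

# Ordinary least squares of y on x returning c(intercept, slope); a
# degenerate design (constant x or fewer than 2 points) is an error,
# constant y yields slope 0.
ols_line <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("at least two points are required to fit a trend")
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stop("degenerate design: all time points identical")
  b <- sum((x - mx) * (y - my)) / sxx
  c(intercept = my - b * mx, slope = b)
}
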