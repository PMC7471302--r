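#' Life table of annual conditional death probabilities
#'
#' A rectangular table q(sex, calendar year, age) of conditional annual
#' death probabilities, the referent mortality source for the whole
#' pipeline. The closing age must carry q = 1 so every simulated
#' lifetime terminates.
#'
#' @param qx 3-dimensional array `[sex, year, age]` with dimnames; all
#'   values in \[0, 1\] and q = 1 at the last age.
#' @return A `life_table` object.
#' @export
life_table <- function(qx) {
  dn <- dimnames(qx)
  if (length(dim(qx)) != 3L || is.null(dn)) {
    stop("`qx` must be a [sex, year, age] array with dimnames")
  }
  if (anyNA(qx) || any(qx < 0 | qx > 1)) {
    stop("all death probabilities must lie in [0, 1] with no gaps")
  }
  last_age <- dim(qx)[3L]
  if (any(qx[, , last_age] != 1)) {
    stop("the table must close with q = 1 at the final age")
  }
  structure(
    list(
      qx = qx,
      sexes = dn[[1L]],
      years = as.integer(dn[[2L]]),
      ages = as.integer(dn[[3L]])
    ),
    class = "life_table"
  )
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf(
    "<life_table> sexes: %s; years %d-%d; ages %d-%d (closing q = 1)\n",
    paste(x$sexes, collapse = "/"), min(x$years), max(x$years),
    min(x$ages), max(x$ages)
  ))
  invisible(x)
}

#' Generate a synthetic complete life table
#'
#' Stands in for a national complete (single-year-of-age) life table.
#' Two hazard shapes are supported: `"constant"` (the same q in every
#' cell, useful for closed-form checks) and `"gompertz"`, a
#' Gompertz-Makeham law `h(age) = makeham + a * exp(b * age)` with a
#' female proportional reduction and an annual secular improvement
#' factor, giving a realistically ageing population with life
#' expectancy near 80 years under the defaults.
#'
#' @param first_year,last_year Calendar span of the table.
#' @param max_age Closing age (q = 1 there); at least 85.
#' @param hazard_shape List describing the hazard model, e.g.
#'   `list(model = "constant", q = 0.5)` or
#'   `list(model = "gompertz", a = 6e-5, b = 0.092, makeham = 5e-4,
#'   female_factor = 0.55, annual_improvement = 0.01)`.
#' @return A [life_table()] covering ages 0..`max_age` for sexes F/M.
#' @export
generate_life_table <- function(first_year, last_year, max_age = 110,
                                hazard_shape = list(model = "gompertz")) {
  first_year <- as.integer(first_year)
  last_year <- as.integer(last_year)
  if (first_year > last_year) stop("`first_year` must not exceed `last_year`")
  if (max_age < 85) stop("`max_age` must be at least 85")
  model <- hazard_shape$model %||% "gompertz"
  years <- first_year:last_year
  ages <- 0:max_age
  sexes <- c("F", "M")
  qx <- array(
    NA_real_, dim = c(2L, length(years), length(ages)),
    dimnames = list(sexes, years, ages)
  )
  if (model == "constant") {
    q0 <- hazard_shape$q
    if (is.null(q0) || q0 < 0 || q0 > 1) {
      stop("constant model requires `q` in [0, 1]")
    }
    qx[, , ] <- q0
  } else if (model == "gompertz") {
    a <- hazard_shape$a %||% 6e-5
    b <- hazard_shape$b %||% 0.092
    makeham <- hazard_shape$makeham %||% 5e-4
    female_factor <- hazard_shape$female_factor %||% 0.55
    improvement <- hazard_shape$annual_improvement %||% 0.01
    if (a <= 0 || b <= 0) {
      stop("Gompertz parameters must satisfy a > 0 and b > 0 ",
           "(otherwise the hazard is not monotone in age)")
    }
    if (makeham < 0 || female_factor <= 0 ||
        improvement < 0 || improvement >= 1) {
      stop("makeham must be >= 0, female_factor > 0 and ",
           "annual_improvement in [0, 1)")
    }
    for (s in sexes) {
      sex_a <- if (s == "F") a * female_factor else a
      for (yi in seq_along(years)) {
        h <- (makeham + sex_a * exp(b * ages)) *
          (1 - improvement)^(years[yi] - first_year)
        qx[s, yi, ] <- 1 - exp(-h)
      }
    }
  } else {
    stop("unknown hazard model: ", model)
  }
  qx[, , length(ages)] <- 1
  life_table(qx)
}

#' @export
as.data.frame.life_table <- function(x, ...) {
  grid <- expand.grid(
    sex = x$sexes, year = x$years, age = x$ages,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$qx <- as.vector(x$qx)
  grid
}

#' Life table CSV IO
#'
#' Columns `sex`, `year`, `age`, `qx`; the table must be rectangular
#' (every sex x year x age cell present).
#'
#' @param lt A [life_table()].
#' @param path File path.
#' @return `read_life_table` returns a [life_table()].
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "year", "age", "qx")
  if (!all(need %in% names(df))) {
    stop("life table CSV must have columns ", paste(need, collapse = ", "))
  }
  sexes <- sort(unique(df$sex))
  years <- sort(unique(df$year))
  ages <- sort(unique(df$age))
  if (nrow(df) != length(sexes) * length(years) * length(ages)) {
    stop("life table CSV is not rectangular over sex x year x age")
  }
  qx <- array(
    NA_real_, dim = c(length(sexes), length(years), length(ages)),
    dimnames = list(sexes, years, ages)
  )
  qx[cbind(
    match(df$sex, sexes), match(df$year, years), match(df$age, ages)
  )] <- df$qx
  life_table(qx)
}

# Monthly hazard path for one (sex, starting age, starting calendar
# year): annual q converted under the constant-hazard-within-year
# assumption h_month = -log(1 - q)/12, age and calendar year advancing
# together. Calendar years beyond the table's last year reuse the last
# available column (explicit carry-forward); a starting year before the
# table is an error. A final infinite-hazard month is appended past the
# closing age so every walk terminates.
monthly_hazard_path <- function(lt, sex, age, year, max_age = 110) {
  age <- as.integer(age)
  year <- as.integer(year)
  if (!sex %in% lt$sexes) {
    stop("life table does not cover sex '", sex, "'")
  }
  if (year < min(lt$years)) {
    stop("life table does not cover calendar year ", year,
         " for sex ", sex, ", age ", age,
         " (years before ", min(lt$years), " are not carried backward)")
  }
  top <- min(max_age, max(lt$ages))
  if (age < min(lt$ages) || age > top) {
    stop("life table does not cover age ", age, " for sex ", sex,
         ", year ", year)
  }
  path_ages <- age:top
  path_years <- pmin(year + seq_along(path_ages) - 1L, max(lt$years))
  q <- lt$qx[cbind(
    match(sex, lt$sexes),
    match(path_years, lt$years),
    match(path_ages, lt$ages)
  )]
  h <- -log(1 - pmin(q, 1 - 1e-12)) / 12
  c(rep(h, each = 12L), Inf)
}

#' Piecewise-constant excess hazard specification
#'
#' Describes how the index cohort's mortality departs from the
#' life-table referent on the monthly grid. In `"multiplicative"` mode
#' the referent monthly hazard is multiplied by the interval value (1 =
#' no excess); in `"additive"` mode a non-negative monthly hazard is
#' added. Intervals are defined by their starting month (0-based, month
#' 0 = the index month); the last interval extends to the horizon.
#'
#' @param values Multipliers (or additive monthly hazards) per interval.
#' @param breaks Starting month of each interval; must begin at 0 and
#'   be strictly increasing.
#' @param mode `"multiplicative"` (default) or `"additive"`.
#' @return An `excess_hazard_spec` object.
#' @examples
#' # acute excess fading to a moderate chronic excess
#' excess_hazard_spec(c(10, 4, 2, 1.4), breaks = c(0, 3, 12, 24))
#' @export
excess_hazard_spec <- function(values, breaks = 0,
                               mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  if (length(values) != length(breaks)) {
    stop("`values` and `breaks` must have the same length")
  }
  if (breaks[1L] != 0 || any(diff(breaks) <= 0)) {
    stop("`breaks` must start at month 0 and be strictly increasing")
  }
  if (any(values < 0)) {
    stop("excess hazard values must be non-negative")
  }
  structure(
    list(values = as.numeric(values), breaks = as.numeric(breaks),
         mode = mode),
    class = "excess_hazard_spec"
  )
}

# Excess value applying to each of the monthly intervals 1..n_months
# (interval m spans (m-1, m] months after index).
excess_per_month <- function(excess, n_months) {
  if (is.null(excess)) return(rep(1, n_months))
  idx <- findInterval(seq_len(n_months) - 1L, excess$breaks)
  excess$values[idx]
}

apply_excess <- function(h, excess) {
  if (is.null(excess)) return(h)
  e <- excess_per_month(excess, length(h))
  if (excess$mode == "multiplicative") h * e else h + e
}

#' Analytic pooled survival of a matched group
#'
#' Expected (infinite-replicate) survival curve of a set of
#' individuals, each matched on sex, completed age and calendar year to
#' the life table, optionally subject to an excess hazard. This is the
#' noiseless counterpart of [monte_carlo_reference()] and the source of
#' ground-truth curves for the synthetic-data module.
#'
#' @param patients Data frame with columns `sex`, `age`, `year`
#'   (calendar year at index).
#' @param lt A [life_table()].
#' @param excess Optional [excess_hazard_spec()].
#' @param max_age Horizon cap in years of age.
#' @param provenance Tag stored on the returned curve.
#' @return A [survival_curve()].
#' @export
expected_survival <- function(patients, lt, excess = NULL, max_age = 110,
                              provenance = "referent-expected") {
  if (nrow(patients) == 0L) stop("no patients supplied")
  key <- paste(patients$sex, patients$age, patients$year, sep = "|")
  groups <- sort(unique(key))
  counts <- table(key)[groups]
  horizon <- 0L
  surv_list <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    parts <- strsplit(groups[gi], "|", fixed = TRUE)[[1L]]
    h <- monthly_hazard_path(lt, parts[1L], as.integer(parts[2L]),
                             as.integer(parts[3L]), max_age = max_age)
    h <- apply_excess(h, excess)
    surv_list[[gi]] <- exp(-cumsum(h))
    horizon <- max(horizon, length(h))
  }
  pooled <- numeric(horizon)
  for (gi in seq_along(groups)) {
    s <- surv_list[[gi]]
    pooled[seq_along(s)] <- pooled[seq_along(s)] + counts[gi] * s
  }
  pooled <- pooled / nrow(patients)
  survival_curve(0:horizon, c(1, pooled), provenance = provenance)
}
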