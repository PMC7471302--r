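cost_cohort <- function(times, events, cost_rows) {
  list(
    patients = data.frame(
      patient_id = paste0("P", seq_along(times)),
      time_months = times, event = events, stringsAsFactors = FALSE
    ),
    costs = cost_rows
  )
}

cost_rows <- function(ids, months, insurer, copay = insurer / 4) {
  data.frame(patient_id = ids, month = months, insurer = insurer,
             copay = copay, stringsAsFactors = FALSE)
}

test_that("monthly means average over patients under observation", {
  co <- cost_cohort(
    times = c(3, 3), events = c(0, 0),
    cost_rows(c("P1", "P2"), c(0, 0), c(100, 300))
  )
  prof <- monthly_mean_costs(co)
  expect_equal(prof$insurer[prof$month == 0], 200)
  # months without any cost line still average to zero over those
  # under observation
  expect_equal(prof$insurer[prof$month == 2], 0)
  expect_equal(prof$n_contributing, c(2, 2, 2))
})

test_that("patients contribute only while under observation", {
  co <- cost_cohort(
    times = c(5, 10), events = c(0, 0),
    cost_rows(c("P1", "P1", "P2", "P2"), c(4, 5, 4, 5), c(80, 80, 40, 40))
  )
  prof <- monthly_mean_costs(co)
  # month 4: both observed -> (80 + 40) / 2; month 5: P1 censored at 5
  expect_equal(prof$insurer[prof$month == 4], 60)
  expect_equal(prof$insurer[prof$month == 5], 40)
  expect_equal(prof$n_contributing[prof$month == 5], 1)
  expect_error(monthly_mean_costs(cost_cohort(
    3, 0, cost_rows("P1", 0, -5)
  )), "negative")
})

test_that("random tables match a brute-force per-month average", {
  set.seed(11)
  n <- 40
  times <- sample(1:24, n, replace = TRUE)
  ids <- paste0("P", 1:n)
  rows <- do.call(rbind, lapply(1:n, function(i) {
    m <- 0:(times[i] - 1)
    cost_rows(rep(ids[i], length(m)), m, runif(length(m), 0, 1000))
  }))
  co <- list(patients = data.frame(patient_id = ids, time_months = times,
                                   event = rbinom(n, 1, 0.5)),
             costs = rows)
  prof <- monthly_mean_costs(co)
  for (m in c(0, 5, 12, 20)) {
    under <- ids[times > m]
    if (length(under) == 0) next
    manual <- sum(rows$insurer[rows$month == m &
                                 rows$patient_id %in% under]) /
      length(under)
    expect_equal(prof$insurer[prof$month == m], manual,
                 tolerance = 1e-9)
  }
})

test_that("constant observed costs extrapolate as the same constant", {
  prof <- monthly_mean_costs(cost_cohort(
    rep(24, 5), rep(0, 5),
    cost_rows(rep(paste0("P", 1:5), each = 24),
              rep(0:23, times = 5), rep(150, 120), rep(30, 120))
  ))
  curve <- survival_curve(0:60, c(1, 0.99^(1:60)))
  ext <- extrapolate_costs(prof, curve)
  new <- ext[ext$provenance == "extrapolated", ]
  expect_equal(nrow(new), 36)
  expect_true(all(abs(new$insurer - 150) < 1e-9))
  expect_true(all(abs(new$copay - 30) < 1e-9))
})

test_that("log-linear cost growth continues its closed-form line", {
  months <- 0:23
  y <- expm1(log1p(100) + 0.02 * months)  # exact line on log1p scale
  prof <- structure(
    data.frame(month = months, insurer = y, copay = y / 2,
               n_contributing = 10, provenance = "observed",
               stringsAsFactors = FALSE),
    class = c("cost_profile", "data.frame")
  )
  curve <- survival_curve(0:36, rep(c(1, 0.9), c(1, 36)))
  ext <- extrapolate_costs(prof, curve)
  want <- expm1(log1p(100) + 0.02 * (24:35))
  expect_equal(ext$insurer[ext$month %in% 24:35], want,
               tolerance = 1e-6)
  expect_error(extrapolate_costs(prof, curve, window = 1), "window")
})

test_that("zero observed costs stay zero when extrapolated", {
  prof <- monthly_mean_costs(cost_cohort(
    rep(12, 3), rep(0, 3),
    cost_rows(rep(paste0("P", 1:3), each = 12),
              rep(0:11, times = 3), rep(0, 36), rep(0, 36))
  ))
  curve <- survival_curve(0:24, c(1, 0.95^(1:24)))
  ext <- extrapolate_costs(prof, curve)
  expect_true(all(ext$insurer == 0))
  expect_true(all(ext$copay == 0))
})

test_that("rectangular survival with flat costs integrates in closed form", {
  curve <- survival_curve(0:12, c(rep(1, 12), 0))
  prof <- structure(
    data.frame(month = 0:11, insurer = 100, copay = 25,
               n_contributing = 1, provenance = "observed",
               stringsAsFactors = FALSE),
    class = c("cost_profile", "data.frame")
  )
  undisc <- lifetime_cost(prof, curve, annual_rate = 0)
  expect_equal(undisc$insurer, 1200)
  expect_equal(undisc$copay, 300)
  expect_equal(undisc$total, 1500)
  expect_equal(undisc$copay_share, 0.2)

  # 12-term scalar oracle at 5%
  disc <- lifetime_cost(prof, curve, annual_rate = 0.05)
  oracle <- sum(100 * 1.05^(-(0:11) / 12))
  expect_equal(disc$insurer, oracle, tolerance = 1e-12)
})

test_that("discounting is monotone and streams add exactly", {
  lt <- study_lt()
  scen <- clean_scenario(seed = 51, n = 150, mult = 2)
  sim <- generate_cohort(scen, lt)
  co <- build_cohort(sim, window = c(scen$admin_start, scen$admin_end))
  est <- estimate_lifetime(co, lt, n_replicates = 50, seed = 51)
  prof <- extrapolate_costs(monthly_mean_costs(co), est$index_curve)
  res <- lapply(c(0, 0.03, 0.05), function(r) {
    lifetime_cost(prof, est$index_curve, annual_rate = r)
  })
  totals <- vapply(res, `[[`, numeric(1L), "total")
  expect_true(all(diff(totals) < 0))
  for (r in res) {
    expect_equal(r$total, r$insurer + r$copay)
  }
  # survival-weighting bound
  smax <- sum(curve_surv_at(est$index_curve,
                            prof$month))
  expect_lte(res[[1]]$insurer, max(prof$insurer) * smax)
  expect_error(lifetime_cost(prof[-3, ], est$index_curve), "mismatch")
})

test_that("currency conversion divides by the KRW per USD rate", {
  expect_equal(convert_currency(1131.2, 1131.2), 1)
  expect_equal(convert_currency(0), 0)
  expect_equal(convert_currency(2262400, 1131.2), 2000)
  expect_error(convert_currency(100, 0), "positive")
  expect_error(convert_currency(100, -2), "positive")
})
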