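flat_ref <- function(h = 200, monthly = 0.99) {
  survival_curve(0:h, monthly^(0:h), provenance = "referent-MC")
}

test_that("the logit series maps hand-built ratios correctly", {
  ref <- flat_ref(60)
  idx <- survival_curve(0:24, 0.8 * c(1 / 0.8, ref$surv[2:25]))
  # identical curves: the ratio sits at the clip boundary, the series
  # is constant, and every point is flagged uninformative
  same <- logit_ratio(survival_curve(0:24, ref$surv[1:25]), ref)
  expect_true(all(same$W == same$W[1]))
  expect_true(all(!same$informative))

  # ratio exactly one half everywhere -> W = 0
  half <- survival_curve(0:24, c(1, 0.5 * ref$surv[2:25]))
  w_half <- logit_ratio(half, ref)
  expect_equal(w_half$W, rep(0, 24), tolerance = 1e-12)
  expect_true(all(w_half$informative))

  # ratio 0.8 -> W = -ln 4 is the logit of 0.8... check the scalar
  r08 <- survival_curve(0:24, c(1, 0.8 * ref$surv[2:25]))
  w08 <- logit_ratio(r08, ref)
  expect_equal(w08$W, rep(log(0.8 / 0.2), 24), tolerance = 1e-12)
  expect_equal(w08$W[1], log(4), tolerance = 1e-12)

  short_ref <- survival_curve(0:10, ref$surv[1:11])
  expect_error(logit_ratio(r08, short_ref), "misaligned")
})

test_that("a constant series extrapolates as expit(W) times the referent", {
  ref <- flat_ref(120)
  idx <- survival_curve(0:36, c(1, 0.8 * ref$surv[2:37]))
  ser <- logit_ratio(idx, ref)
  ext <- rolling_over_extrapolate(ser, ref, idx)
  expect_equal(max(ext$month), 120)
  # over follow-up the curve is exactly the index curve
  expect_equal(curve_surv_at(ext, 0:36), idx$surv)
  # beyond: expit(logit(0.8)) * S_ref = 0.8 * S_ref
  expect_equal(curve_surv_at(ext, 37:120),
               0.8 * curve_surv_at(ref, 37:120), tolerance = 1e-9)
  expect_equal(unique(ext$provenance[ext$month > 36]), "extrapolated")
})

test_that("a linear series continues its closed-form line", {
  ref <- flat_ref(120, monthly = 1 - 1e-9)  # essentially flat referent
  a <- 2
  b <- -0.05
  w_true <- a + b * (1:36)
  idx_surv <- c(1, stats::plogis(w_true) * curve_surv_at(ref, 1:36))
  idx <- survival_curve(0:36, idx_surv)
  ser <- logit_ratio(idx, ref)
  expect_equal(ser$W, w_true, tolerance = 1e-6)
  ext <- rolling_over_extrapolate(ser, ref, idx)
  want <- stats::plogis(a + b * (37:120)) * curve_surv_at(ref, 37:120)
  expect_equal(curve_surv_at(ext, 37:120), want, tolerance = 1e-6)
})

test_that("constant mode carries the ratio level forward", {
  ref <- flat_ref(120)
  idx <- survival_curve(0:36, c(1, 0.9 * ref$surv[2:37]))
  ser <- logit_ratio(idx, ref)
  ext <- rolling_over_extrapolate(ser, ref, idx, trend = "constant")
  expect_equal(curve_surv_at(ext, 37:120),
               0.9 * curve_surv_at(ref, 37:120), tolerance = 1e-9)
})

test_that("extrapolation guards its preconditions", {
  ref <- flat_ref(120)
  idx <- survival_curve(0:36, c(1, 0.8 * ref$surv[2:37]))
  ser <- logit_ratio(idx, ref)
  expect_error(rolling_over_extrapolate(ser, ref, idx, window = 1),
               "at least 2")
  expect_error(rolling_over_extrapolate(ser, ref, idx, window = 50),
               "fewer")
  expect_error(rolling_over_extrapolate(ser, ref, idx, horizon = 300),
               "before the requested horizon")
  short_ref <- survival_curve(0:20, ref$surv[1:21])
  expect_error(logit_ratio(idx, short_ref), "misaligned")
})

test_that("the extrapolated curve stays monotone within [0, 1]", {
  lt <- study_lt()
  for (s in 1:5) {
    scen <- clean_scenario(seed = 60 + s, n = 150,
                           mult = sample(c(1, 1.5, 3), 1))
    sim <- generate_cohort(scen, lt)
    co <- build_cohort(sim, window = c(scen$admin_start, scen$admin_end))
    est <- estimate_lifetime(co, lt, n_replicates = 30, seed = s)
    surv <- est$index_curve$surv
    expect_true(all(diff(surv) <= 1e-12))
    expect_true(all(surv >= 0 & surv <= 1))
    # over follow-up the pooled curve matches the pooled KM where the
    # cohort is unstratified
    est_pooled <- estimate_lifetime(co, lt, n_replicates = 30, seed = s,
                                    stratify = FALSE)
    km <- kaplan_meier(co$patients)
    expect_equal(curve_surv_at(est_pooled$index_curve, km$month),
                 km$surv, tolerance = 1e-12)
  }
})

test_that("LE / EYLL arithmetic and the validation formula hold", {
  ref <- survival_curve(0:241, c(rep(1, 240), 0.5, 0))
  idx <- survival_curve(0:241, c(rep(1, 180), rep(0.5, 60), 0.25, 0))
  est <- le_eyll(idx, ref)
  expect_equal(est$EYLL, est$LE_ref - est$LE, tolerance = 1e-12)
  same <- le_eyll(ref, ref)
  expect_equal(same$EYLL, 0)
  expect_error(le_eyll(survival_curve(0:10, rep(1, 11)), ref),
               "extinction")

  # relative bias is (extrapolated - observed) / observed
  lt <- study_lt()
  scen <- clean_scenario(seed = 71, n = 400, mult = 2)
  sim <- generate_cohort(scen, lt)
  co <- build_cohort(sim, window = c(scen$admin_start, scen$admin_end))
  v <- validate_extrapolation(co, lt, fit_months = 60, test_months = 120,
                              n_replicates = 50, seed = 71)
  expect_equal(v$relative_bias,
               (v$extrapolated - v$observed) / v$observed)
  # fit horizon equal to the test horizon is a no-op
  v0 <- validate_extrapolation(co, lt, fit_months = 120,
                               test_months = 120, n_replicates = 10,
                               seed = 71)
  expect_equal(v0$relative_bias, 0)
  expect_error(
    validate_extrapolation(co, lt, fit_months = 60, test_months = 600),
    "not estimable"
  )
})

test_that("bootstrap SEs behave on degenerate and forced resamples", {
  lt <- study_lt()
  # identical patients: no resampling variance in survival times
  pats <- data.frame(
    patient_id = paste0("P", 1:40), sex = "M", age_at_index = 70,
    index_year = 2006, time_months = 24, event = 1L
  )
  stat <- function(p, s) {
    c(rm = restricted_mean(kaplan_meier(p, max_months = 24), 24))
  }
  bs <- bootstrap_se(pats, stat, B = 10, seed = 1)
  expect_equal(unname(bs$se["rm"]), 0)
  expect_equal(bs$n_failed, 0L)

  # a statistic blind to the resample has exactly zero SE
  bs2 <- bootstrap_se(pats, function(p, s) c(k = 1), B = 2, seed = 1)
  expect_equal(unname(bs2$se["k"]), 0)
  expect_error(bootstrap_se(pats, stat, B = 1), "at least 2")
  expect_error(
    bootstrap_se(pats, function(p, s) stop("boom"), B = 10, seed = 1),
    "failed"
  )
})

test_that("bootstrap SE shrinks roughly as one over root n", {
  lt <- study_lt()
  ses <- vapply(c(100, 400), function(n) {
    scen <- clean_scenario(seed = 81, n = n, mult = 2)
    sim <- generate_cohort(scen, lt)
    co <- build_cohort(sim, window = c(scen$admin_start, scen$admin_end))
    stat <- function(p, s) {
      c(rm = restricted_mean(kaplan_meier(p, max_months = 60), 60))
    }
    bootstrap_se(co, stat, B = 40, seed = 5)$se["rm"]
  }, numeric(1L))
  ratio <- ses[1] / ses[2]
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
})
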