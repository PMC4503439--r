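profile_of <- function(times, conc, lloq = 0, route = "iv_bolus",
                       dose = NA_real_) {
  conc_profile("s1", times, conc, lloq = lloq, route = route, dose = dose)
}

test_that("trapezoid AUC matches closed forms", {
  flat <- profile_of(c(0, 60), c(10, 10))
  expect_equal(auc_trapezoid(flat, "linear"), 600)
  expect_equal(auc_trapezoid(flat, "linear_up_log_down"), 600)
  down <- profile_of(c(0, 60), c(10, 5))
  expect_equal(auc_trapezoid(down, "linear_up_log_down"),
               5 * 60 / log(2), tolerance = 1e-12)
  expect_equal(auc_trapezoid(down, "linear"), 450)
  # dense mono-exponential vs analytic integral
  t <- seq(0, 1000, by = 1)
  p <- profile_of(t, exp(-0.01 * t))
  analytic <- (1 - exp(-10)) / 0.01
  expect_equal(auc_trapezoid(p, "linear_up_log_down"), analytic,
               tolerance = 0.001)
})

test_that("AUC is additive, monotone, and log-down bounded by linear", {
  set.seed(31)
  for (i in 1:10) {
    t <- sort(c(0, runif(8, 1, 360)))
    c1 <- exp(-0.008 * t) * runif(9, 0.5, 1.5)
    p <- profile_of(t, c1)
    mid <- t[5]
    expect_equal(auc_trapezoid(p, "linear"),
                 auc_trapezoid(p, "linear", t_end = mid) +
                   sum(admekit:::auc_segments(t[5:9], c1[5:9], "linear")$auc),
                 tolerance = 1e-10)
    # monotone in concentrations
    p2 <- profile_of(t, c1 * 1.3)
    expect_gt(auc_trapezoid(p2, "linear"), auc_trapezoid(p, "linear"))
    # log-down never exceeds linear
    expect_lte(auc_trapezoid(p, "linear_up_log_down"),
               auc_trapezoid(p, "linear") + 1e-12)
  }
  expect_error(auc_trapezoid(profile_of(c(0, 60, 120), c(1, 2, 3)),
                             t_end = 30),
               class = "admekit_bad_t_end")
})

test_that("terminal slope is recovered exactly on a clean exponential", {
  t <- c(0, 30, 60, 120, 240, 360, 480)
  p <- profile_of(t, 2 * exp(-0.00315 * t))
  fit <- fit_lambda_z(p, route = "iv_bolus")
  expect_equal(fit$lambda_z, 0.00315, tolerance = 1e-10)
  expect_equal(fit$t_half, log(2) / 0.00315, tolerance = 1e-10)
  expect_equal(fit$t_half, 220.04, tolerance = 1e-4)
  expect_identical(fit$npoints, 7L)  # tie broken toward more points
})

test_that("ascending profiles have no estimable terminal phase", {
  p <- profile_of(c(0, 30, 60, 120), c(1, 2, 3, 4))
  expect_warning(fit <- fit_lambda_z(p, route = "iv_bolus"),
                 class = "admekit_lambda_z_not_estimable")
  expect_true(is.na(fit$lambda_z))
  # NCA still reports auc_last with extrapolated quantities absent
  pd <- profile_of(c(0, 30, 60, 120), c(1, 2, 3, 4), route = "iv_bolus",
                   dose = 5)
  suppressWarnings(r <- nca_single(pd))
  expect_gt(r$auc_last, 0)
  expect_true(is.na(r$auc_inf) && is.na(r$cl) && is.na(r$vss))
})

test_that("terminal slope tolerates moderate proportional noise", {
  set.seed(1)
  relerr <- replicate(100, {
    t <- seq(0, 700, length.out = 8)
    co <- 2 * exp(-0.003 * t) * (1 + rnorm(8, 0, 0.1))
    p <- profile_of(t, pmax(co, 1e-6))
    abs(fit_lambda_z(p, route = "iv_bolus")$lambda_z / 0.003 - 1)
  })
  expect_lt(median(relerr), 0.15)
  expect_lt(mean(relerr > 0.4), 0.1)
})

test_that("NCA recovers generating CL and Vss from dense noise-free bolus data", {
  set.seed(42)
  for (i in 1:20) {
    cl <- runif(1, 10, 60); v1 <- runif(1, 500, 3000)
    q <- runif(1, 5, 40); v2 <- runif(1, 1000, 6000)
    beta <- exponents_oracle(cl, v1, q, v2)$beta
    sched <- seq(0, 10 * log(2) / beta, by = 1)
    spec <- pk_population_spec(cl = cl, v1 = v1, q = q, v2 = v2,
                               omega = 0, sigma_prop = 0, lloq = 0,
                               schedule = sched, n_subjects = 1)
    r <- nca_single(simulate_iv_profiles(spec, dose = 10)[[1]])
    expect_equal(r$cl, cl, tolerance = 0.02)
    expect_equal(r$vss, v1 + v2, tolerance = 0.05)
  }
})

test_that("NCA on the sparse study schedule recovers the disposition model", {
  spec <- pk_population_spec(omega = 0, sigma_prop = 0, n_subjects = 1)
  r <- nca_single(simulate_iv_profiles(spec, dose = 5)[[1]])
  beta <- exponents_oracle(31.4, 1000, 15, 3304)$beta
  expect_equal(r$cl, 31.4, tolerance = 0.05)
  expect_equal(r$t_half, log(2) / beta, tolerance = 0.10)
  expect_lt(r$auc_extrap_pct, 20)
  expect_gte(r$auc_inf, r$auc_last)
  expect_equal(r$vss, r$cl * r$mrt, tolerance = 1e-12)
})

test_that("Cmax and Tmax are read from observed points and CL partitions exactly", {
  t <- c(0, 15, 60, 120, 240, 360)
  co <- c(0, 0.02, 0.05, 0.03, 0.012, 0.005)
  p <- conc_profile("s1", t, co, lloq = 0, route = "oral", dose = 10)
  r <- nca_single(p)
  expect_identical(r$tmax, 60)
  expect_identical(r$cmax, 0.05)
  # renal/non-renal clearance partition on an iv profile
  spec <- one_cpt_spec()
  p_iv <- simulate_iv_profiles(spec, dose = 5)[[1]]
  ex <- excretion_record(p_iv$subject_id, ae_0_24_pct = 0.839,
                         gi_24_pct = 3.44)
  r_iv <- nca_single(p_iv, excretion = ex)
  expect_equal(r_iv$cl_nr, r_iv$cl - r_iv$cl_r, tolerance = 1e-15)
  expect_equal(r_iv$cl_r,
               0.00839 * 5000 / r_iv$auc_inf, tolerance = 1e-12)
  # nca_table joins excretion by subject
  tab <- nca_table(list(p_iv), excretion = ex)
  expect_equal(tab$cl_r, r_iv$cl_r)
})

test_that("bioavailability and dose normalization follow their definitions", {
  expect_equal(bioavailability(7.80, 10, 340, 10), 2.29, tolerance = 0.005)
  expect_equal(bioavailability(100, 10, 100, 10), 100)
  expect_equal(bioavailability(37.3, 50, 340, 10), 2.19, tolerance = 0.005)
  expect_error(bioavailability(0, 10, 340, 10), class = "admekit_bad_auc")
  expect_equal(dose_normalize(169, 5), 33.8)
  expect_equal(dose_normalize(7.7, 1), 7.7)
  expect_equal(dose_normalize(0.709, 100), 0.00709)
  expect_error(dose_normalize(1, 0), class = "admekit_bad_dose")
})
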