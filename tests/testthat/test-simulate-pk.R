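test_that("bolus simulation reproduces the closed-form one-compartment curve", {
  spec <- one_cpt_spec(cl = 31.4, v = 4304)
  p <- simulate_iv_profiles(spec, dose = 5)[[1]]
  expect_equal(p$conc[1], 5000 / 4304, tolerance = 1e-12)
  k <- 31.4 / 4304
  expect_equal(p$conc, p$conc[1] * exp(-k * p$times), tolerance = 1e-12)
  expect_s3_class(p, "conc_profile")
  expect_identical(p$route, "iv_bolus")
})

test_that("two-compartment exponents agree with an independent polyroot oracle", {
  set.seed(101)
  for (i in 1:10) {
    cl <- runif(1, 5, 60); v1 <- runif(1, 300, 3000)
    q <- runif(1, 1, 50); v2 <- runif(1, 500, 6000)
    m <- admekit:::two_cpt_exponents(cl, v1, q, v2)
    o <- exponents_oracle(cl, v1, q, v2)
    expect_equal(m$alpha, o$alpha, tolerance = 1e-10)
    expect_equal(m$beta, o$beta, tolerance = 1e-10)
    # bolus curve integrates to dose/CL (mass balance)
    f <- function(t) conc_iv_2cpt(t, 10, cl, v1, q, v2)
    expect_equal(integrate(f, 0, Inf)$value, 10 * 1000 / cl,
                 tolerance = 1e-6)
  }
})

test_that("simulation rejects invalid dose and schedule", {
  spec <- one_cpt_spec()
  expect_error(simulate_iv_profiles(spec, dose = -5),
               class = "admekit_bad_dose")
  expect_error(pk_population_spec(schedule = c(5, 10)),
               class = "admekit_bad_schedule")
  expect_error(pk_population_spec(schedule = c(0, 10, 10)),
               class = "admekit_bad_schedule")
  expect_error(pk_population_spec(cl = -1), class = "admekit_bad_spec")
  expect_error(pk_population_spec(f_true = 1.2), class = "admekit_bad_spec")
})

test_that("population geometric mean matches the closed-form Monte-Carlo oracle", {
  # With independent log-normal CL and V1 (log-SD omega), the geometric
  # mean of a one-compartment bolus curve is C0 * exp(-t k e^{omega^2}):
  # E[log C(t)] = log C0 - t * E[k_i], E[k_i] = k * e^{omega^2}.
  spec <- pk_population_spec(cl = 31.4, v1 = 4304, q = 0, v2 = 1,
                             omega = 0.3, sigma_prop = 0.1,
                             n_subjects = 500, seed = 11)
  profs <- simulate_iv_profiles(spec, dose = 5)
  c60 <- vapply(profs, function(p) p$conc[p$times == 60], numeric(1))
  gm <- exp(mean(log(c60)))
  k <- 31.4 / 4304
  oracle <- (5000 / 4304) * exp(-60 * k * exp(0.3^2))
  expect_equal(gm, oracle, tolerance = 0.03)
  # at t = 1 min the variability correction is negligible, so the
  # geometric mean also matches the noise-free curve
  c1 <- vapply(profs, function(p) p$conc[p$times == 1], numeric(1))
  expect_equal(exp(mean(log(c1))), (5000 / 4304) * exp(-k),
               tolerance = 0.03)
})

test_that("oral absorption-rate limit converges to the scaled bolus curve", {
  spec <- one_cpt_spec(cl = 31.4, v = 1000)
  t <- amg_schedule("iv_bolus")[-1]
  oral <- conc_oral_2cpt(t, dose = 10, cl = 31.4, v1 = 1000, q = 0, v2 = 1,
                         ka = 1e3, f = 0.0229)
  bolus <- conc_iv_2cpt(t, dose = 10 * 0.0229, cl = 31.4, v1 = 1000,
                        q = 0, v2 = 1)
  expect_equal(oral, bolus, tolerance = 0.01)
})

test_that("oral AUC to infinity equals F * dose / CL (mass balance)", {
  f <- function(t) conc_oral_2cpt(t, dose = 10, cl = 31.4, v1 = 1000,
                                  q = 15, v2 = 3304, ka = 0.03, f = 0.0229)
  expect_equal(integrate(f, 0, Inf)$value, 0.0229 * 10 * 1000 / 31.4,
               tolerance = 1e-6)
})

test_that("oral Tmax matches the closed form and the numeric-solver oracle", {
  ka <- 0.05; ke <- 31.4 / 1000
  closed <- log(ka / ke) / (ka - ke)
  curve_fn <- function(t) conc_oral_2cpt(t, dose = 10, cl = 31.4,
                                         v1 = 1000, q = 0, v2 = 1,
                                         ka = ka, f = 0.0229)
  numeric_tmax <- optimize(curve_fn, c(0, 360), maximum = TRUE)$maximum
  expect_equal(numeric_tmax, closed, tolerance = 1e-4)
  # densely sampled noise-free profile peaks at the same time
  spec <- pk_population_spec(cl = 31.4, v1 = 1000, q = 0, v2 = 1,
                             ka = ka, f_true = 0.0229, omega = 0,
                             sigma_prop = 0, lloq = 0,
                             schedule = seq(0, 360, by = 0.25),
                             n_subjects = 1)
  p <- simulate_oral_profiles(spec, dose = 10)[[1]]
  expect_equal(p$times[which.max(p$conc)], closed, tolerance = 0.01)
})

test_that("ka colliding with a disposition exponent is perturbed with a warning", {
  expect_warning(
    conc_oral_2cpt(60, dose = 10, cl = 31.4, v1 = 1000, q = 0, v2 = 1,
                   ka = 31.4 / 1000, f = 1),
    class = "admekit_degenerate_ka"
  )
})

test_that("LLOQ censoring flags, never drops, and is monotone in the limit", {
  spec <- one_cpt_spec(lloq = 0.1)  # C(360) ~ 0.084 ug/mL falls below
  p <- simulate_iv_profiles(spec, dose = 5)[[1]]
  expect_length(p$times, length(amg_schedule("iv_bolus")))
  expect_true(any(p$censored))
  expect_true(all(is.na(p$conc[p$censored])))
  # raising the LLOQ never increases the number of quantifiable points
  lloqs <- c(0, 1e-4, 1e-3, 1e-2, 0.1, 1)
  counts <- vapply(lloqs, function(l) {
    sp <- one_cpt_spec(lloq = l)
    sum(!simulate_iv_profiles(sp, dose = 5)[[1]]$censored)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("identical spec and seed reproduce identical output", {
  spec <- pk_population_spec(n_subjects = 4, seed = 99)
  a <- simulate_iv_profiles(spec, dose = 10)
  b <- simulate_iv_profiles(spec, dose = 10)
  expect_identical(a, b)
  ex1 <- simulate_excretion(spec, dose = 10)
  ex2 <- simulate_excretion(spec, dose = 10)
  expect_identical(ex1, ex2)
})

test_that("excretion recoveries center on the true fractions", {
  spec0 <- pk_population_spec(fe_true = 0.00839, gi_true = 0,
                              excretion_cv = 0, n_subjects = 3)
  ex <- simulate_excretion(spec0, dose = 5)
  expect_equal(ex$ae_0_24_pct, rep(0.839, 3))
  expect_equal(ex$gi_24_pct, rep(0, 3))
  expect_equal(ex$urine_amount_ug, rep(0.00839 * 5000, 3))
  # law of large numbers at n = 1000
  spec1 <- pk_population_spec(fe_true = 0.005, excretion_cv = 0.6,
                              n_subjects = 1000, seed = 21)
  ex1 <- simulate_excretion(spec1)
  expect_equal(mean(ex1$ae_0_24_pct), 0.5, tolerance = 0.1)
  expect_true(all(ex1$ae_0_24_pct >= 0))
})
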