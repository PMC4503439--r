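# Per-segment AUC and AUMC between consecutive quantifiable points.
# Log-down segments ((C1 - C2) * dt / ln(C1/C2)) are used only when both
# concentrations are positive and strictly decreasing; everything else is
# linear. On flat segments the two methods coincide exactly.
auc_segments <- function(times, concs, method) {
  n <- length(times)
  if (n < 2L) return(list(auc = numeric(0), aumc = numeric(0)))
  t1 <- times[-n]; t2 <- times[-1]
  c1 <- concs[-n]; c2 <- concs[-1]
  dt <- t2 - t1
  lin_auc <- dt * (c1 + c2) / 2
  lin_aumc <- dt * (t1 * c1 + t2 * c2) / 2
  if (method == "linear") return(list(auc = lin_auc, aumc = lin_aumc))
  logdown <- c1 > 0 & c2 > 0 & c2 < c1
  lr <- log(c1[logdown] / c2[logdown])
  auc <- lin_auc
  aumc <- lin_aumc
  auc[logdown] <- dt[logdown] * (c1[logdown] - c2[logdown]) / lr
  aumc[logdown] <- dt[logdown] *
    (t1[logdown] * c1[logdown] - t2[logdown] * c2[logdown]) / lr +
    dt[logdown]^2 * (c1[logdown] - c2[logdown]) / lr^2
  list(auc = auc, aumc = aumc)
}

# Observed points used for AUC: quantifiable concentrations, with leading
# censored samples (pre-absorption BLQ) set to 0 so the rising limb is
# anchored; embedded and trailing censored points are dropped.
auc_points <- function(profile) {
  conc <- profile$conc
  cens <- profile$censored
  qidx <- which(!cens)
  if (length(qidx) == 0L) {
    abort_adme("profile has no quantifiable points", "admekit_all_censored")
  }
  lead <- which(cens & seq_along(cens) < qidx[1])
  keep <- sort(c(lead, qidx))
  conc[lead] <- 0
  list(times = profile$times[keep], conc = conc[keep])
}

#' Trapezoidal partial AUC of a concentration profile
#'
#' Area under the concentration-time curve from the first retained sample
#' to `t_end`, by the plain linear trapezoid or the linear-up/log-down
#' rule (log interpolation on segments where both concentrations are
#' positive and decreasing; the default for bolus decline). Censored
#' samples before the first quantifiable point enter as zeros; censored
#' points after it are excluded, and the area stops at the last
#' quantifiable sample at or before `t_end`.
#'
#' @param profile a [conc_profile()] with at least 2 quantifiable points.
#' @param method `"linear_up_log_down"` (default) or `"linear"`.
#' @param t_end end of the integration window, min; defaults to the last
#'   quantifiable time.
#' @return AUC in ug.min/mL.
#' @export
#' @examples
#' p <- conc_profile("m1", c(0, 60), c(10, 5), lloq = 0.001)
#' auc_trapezoid(p, method = "linear_up_log_down")  # 5 * 60 / log(2)
auc_trapezoid <- function(profile, method = c("linear_up_log_down", "linear"),
                          t_end = NULL) {
  method <- match.arg(method)
  pts <- auc_points(profile)
  if (length(pts$times) < 2L) {
    abort_adme("need at least 2 quantifiable points for AUC",
               "admekit_too_few_points")
  }
  t_end <- t_end %||% max(pts$times)
  if (t_end < pts$times[2]) {
    abort_adme("`t_end` precedes the second retained sample",
               "admekit_bad_t_end")
  }
  keep <- pts$times <= t_end
  seg <- auc_segments(pts$times[keep], pts$conc[keep], method)
  sum(seg$auc)
}

#' Fit the terminal elimination rate constant
#'
#' Unweighted least squares of log concentration against time over
#' candidate terminal windows: every suffix of at least 3 quantifiable
#' post-Cmax points (Cmax itself is included for an intravenous bolus and
#' excluded for the oral route). The window maximizing adjusted
#' R-squared is selected, ties broken toward more points, and the slope
#' must be negative; otherwise the half-life is flagged not estimable.
#'
#' @param profile a [conc_profile()].
#' @param route `"iv_bolus"` or `"oral"`; taken from the profile when
#'   `NULL`.
#' @return List: `lambda_z` (1/min, `NA` if not estimable), `npoints`,
#'   `r2adj`, `intercept` (log ug/mL), `t_half` (min), `clast_pred`
#'   (ug/mL, predicted at the last quantifiable time), `tlast` (min).
#' @export
fit_lambda_z <- function(profile, route = NULL) {
  route <- route %||% profile$route
  q <- quantifiable_points(profile)
  not_estimable <- function(msg) {
    warn_adme(msg, "admekit_lambda_z_not_estimable")
    list(lambda_z = NA_real_, npoints = NA_integer_, r2adj = NA_real_,
         intercept = NA_real_, t_half = NA_real_, clast_pred = NA_real_,
         tlast = if (length(q$times)) max(q$times) else NA_real_)
  }
  if (length(q$times) < 3L) {
    return(not_estimable("fewer than 3 quantifiable points"))
  }
  imax <- which.max(q$conc)
  start <- if (identical(route, "oral")) imax + 1L else imax
  t <- q$times[seq(start, length(q$times))]
  y <- log(q$conc[seq(start, length(q$times))])
  n <- length(t)
  if (n < 3L) return(not_estimable("fewer than 3 post-Cmax points"))
  # Vectorized suffix regressions via reverse cumulative sums: O(n) for
  # all candidate windows, needed for dense (minute-resolution) profiles.
  rcs <- function(x) rev(cumsum(rev(x)))
  St <- rcs(t); Sy <- rcs(y); Stt <- rcs(t^2); Sty <- rcs(t * y)
  Syy <- rcs(y^2)
  nj <- n - seq_len(n) + 1
  starts <- which(nj >= 3L)
  sxx <- nj * Stt - St^2
  sxy <- nj * Sty - St * Sy
  syy <- nj * Syy - Sy^2
  slope <- sxy / sxx
  r2 <- ifelse(syy > 0 & sxx > 0, sxy^2 / (sxx * syy), NA_real_)
  r2adj <- 1 - (1 - r2) * (nj - 1) / (nj - 2)
  ok <- seq_len(n) %in% starts & !is.na(r2adj) & slope < 0
  if (!any(ok)) {
    return(not_estimable("no candidate window with a negative terminal slope"))
  }
  # earliest start = most points; keep the longest window among ties
  best <- which(ok)[which.max(r2adj[ok] - 1e-10 * seq_along(which(ok)))]
  j <- best
  b <- slope[j]
  a <- (Sy[j] - b * St[j]) / nj[j]
  lambda_z <- -b
  tlast <- max(q$times)
  list(lambda_z = lambda_z, npoints = as.integer(nj[j]),
       r2adj = r2adj[j], intercept = a, t_half = log(2) / lambda_z,
       clast_pred = exp(a + b * tlast), tlast = tlast)
}

#' Non-compartmental analysis of one profile
#'
#' Computes the full set of non-compartmental parameters for one
#' subject: AUC to the last quantifiable sample and extrapolated to
#' infinity (using the predicted last concentration from the terminal
#' fit), AUMC and mean residence time, terminal half-life, clearance,
#' steady-state volume (IV bolus), Cmax/Tmax read from the observed
#' points without interpolation, renal and non-renal clearance when an
#' excretion record is supplied, and dose-normalized AUC and Cmax. When
#' the terminal slope is not estimable the extrapolated quantities are
#' `NA` but `auc_last` is still reported.
#'
#' @param profile a [conc_profile()].
#' @param dose dose in mg/kg; defaults to the dose recorded on the
#'   profile.
#' @param route `"iv_bolus"` or `"oral"`; defaults to the profile route.
#' @param excretion optional [excretion_record()] row for this subject
#'   (urinary recovery drives renal clearance).
#' @param auc_method trapezoid variant, as in [auc_trapezoid()].
#' @return A one-row tibble (class `nca_result`) with columns
#'   `subject_id`, `route`, `dose_mg_kg`, `auc_last`, `auc_inf`,
#'   `auc_extrap_pct`, `aumc_inf`, `lambda_z`, `lambda_z_npoints`,
#'   `lambda_z_r2adj`, `t_half`, `mrt`, `cl`, `vss`, `cmax`, `tmax`,
#'   `cl_r`, `cl_nr`, `dose_normalized_auc`, `dose_normalized_cmax`.
#' @export
nca_single <- function(profile, dose = NULL, route = NULL,
                       excretion = NULL,
                       auc_method = c("linear_up_log_down", "linear")) {
  auc_method <- match.arg(auc_method)
  dose <- dose %||% profile$dose
  route <- route %||% profile$route
  if (is.na(dose) || dose <= 0) {
    abort_adme("a positive dose (mg/kg) is required", "admekit_bad_dose")
  }
  if (is.na(route)) {
    abort_adme("profile route must be set for NCA", "admekit_bad_route")
  }
  q <- quantifiable_points(profile)
  if (length(q$times) < 3L) {
    abort_adme("need at least 3 quantifiable points for NCA",
               "admekit_too_few_points")
  }
  imax <- which.max(q$conc)
  cmax <- q$conc[imax]
  tmax <- q$times[imax]
  pts <- auc_points(profile)
  seg <- auc_segments(pts$times, pts$conc, auc_method)
  auc_last <- sum(seg$auc)
  aumc_last <- sum(seg$aumc)
  lz <- fit_lambda_z(profile, route)
  dose_ug_kg <- dose * 1000
  if (is.na(lz$lambda_z)) {
    auc_inf <- aumc_inf <- extrap <- mrt <- cl <- vss <- NA_real_
  } else {
    auc_inf <- auc_last + lz$clast_pred / lz$lambda_z
    aumc_inf <- aumc_last + lz$clast_pred * lz$tlast / lz$lambda_z +
      lz$clast_pred / lz$lambda_z^2
    extrap <- 100 * (auc_inf - auc_last) / auc_inf
    mrt <- if (identical(route, "iv_bolus")) aumc_inf / auc_inf else NA_real_
    cl <- if (identical(route, "iv_bolus")) dose_ug_kg / auc_inf else NA_real_
    vss <- if (identical(route, "iv_bolus")) cl * mrt else NA_real_
  }
  cl_r <- NA_real_
  if (!is.null(excretion) && !is.na(auc_inf)) {
    amount_ug_kg <- excretion$ae_0_24_pct / 100 * dose_ug_kg
    cl_r <- amount_ug_kg / auc_inf
  }
  cl_nr <- if (identical(route, "iv_bolus")) cl - cl_r else NA_real_
  out <- tibble::tibble(
    subject_id = profile$subject_id, route = route, dose_mg_kg = dose,
    auc_last = auc_last, auc_inf = auc_inf, auc_extrap_pct = extrap,
    aumc_inf = aumc_inf, lambda_z = lz$lambda_z,
    lambda_z_npoints = lz$npoints, lambda_z_r2adj = lz$r2adj,
    t_half = lz$t_half, mrt = mrt, cl = cl, vss = vss,
    cmax = cmax, tmax = tmax, cl_r = cl_r, cl_nr = cl_nr,
    dose_normalized_auc = dose_normalize(auc_inf, dose),
    dose_normalized_cmax = dose_normalize(cmax, dose)
  )
  class(out) <- c("nca_result", class(out))
  out
}

#' Non-compartmental analysis of a set of profiles
#'
#' Applies [nca_single()] to each profile, joining per-subject excretion
#' records by `subject_id` when supplied.
#'
#' @param profiles list of [conc_profile()] objects.
#' @param excretion optional [excretion_record()] tibble.
#' @inheritParams nca_single
#' @return Tibble with one [nca_single()] row per subject.
#' @export
nca_table <- function(profiles, excretion = NULL,
                      auc_method = c("linear_up_log_down", "linear")) {
  auc_method <- match.arg(auc_method)
  rows <- lapply(profiles, function(p) {
    ex <- NULL
    if (!is.null(excretion)) {
      hit <- excretion[excretion$subject_id == p$subject_id, ]
      if (nrow(hit) == 1L) ex <- hit
    }
    nca_single(p, excretion = ex, auc_method = auc_method)
  })
  dplyr::bind_rows(rows)
}

#' Absolute oral bioavailability
#'
#' `F% = 100 * (AUC_oral / dose_oral) / (AUC_iv / dose_iv)`; with equal
#' doses this reduces to the plain AUC ratio.
#'
#' @param auc_oral,auc_iv AUCs in ug.min/mL (> 0).
#' @param dose_oral,dose_iv doses in mg/kg (> 0).
#' @return Bioavailability in percent.
#' @export
#' @examples
#' bioavailability(7.80, 10, 340, 10)  # ~2.29
bioavailability <- function(auc_oral, dose_oral, auc_iv, dose_iv) {
  if (any(c(auc_oral, dose_oral, auc_iv, dose_iv) <= 0)) {
    abort_adme("AUCs and doses must be positive", "admekit_bad_auc")
  }
  100 * (auc_oral / dose_oral) / (auc_iv / dose_iv)
}

#' Dose-normalize a parameter
#'
#' Scales a dose-proportional parameter (AUC, Cmax) to a reference dose,
#' `value * ref_dose / dose`; applied per subject before group averaging.
#'
#' @param value parameter value.
#' @param dose administered dose, mg/kg (> 0).
#' @param ref_dose reference dose, mg/kg (default 1).
#' @return Normalized value.
#' @export
#' @examples
#' dose_normalize(169, 5)  # 33.8
dose_normalize <- function(value, dose, ref_dose = 1) {
  if (any(dose <= 0) || ref_dose <= 0) {
    abort_adme("doses must be positive", "admekit_bad_dose")
  }
  value * ref_dose / dose
}
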