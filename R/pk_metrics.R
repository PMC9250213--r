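# Derived pharmacokinetic quantities computed from posterior individual
# predictions: dense 1-minute prediction grids to 72 h, absorption half-life,
# Tmax/Cmax, trapezoidal AUC to infinity with a log-linear terminal
# extrapolation, dose normalisation to the 0.50 mmol reference arm, and the
# whole-blood -> plasma conversion by regression through the origin.

#' Reference dose (mmol) for dose normalisation
#'
#' Dose-normalised Cmax and AUC are expressed at the 0.50 mmol arm, i.e.
#' scaled by `0.5 / dose_mmol`, so the highest-dose arm is reported unchanged.
#' @export
DOSE_REFERENCE_MMOL <- 0.5

#' Dense prediction grid for a posterior estimate
#'
#' Concentrations at 1-minute spacing from administration to 72 h, computed
#' by default from the posterior-mean parameter vector (so Tmax, Cmax and
#' the absorption half-life all describe one internally consistent vector).
#' Alternatively the posterior-weighted mean of the per-support-point curves
#' can be requested.
#'
#' @param posterior A [posterior_individual()] estimate.
#' @param dose A [dose_event()].
#' @param curve `"posterior_mean"` (default) or `"weighted"`.
#' @return A `prediction_grid` data frame with `time_h` (0 to 72 by 1/60)
#'   and `conc_uM`.
#' @export
predict_grid <- function(posterior, dose, curve = c("posterior_mean", "weighted")) {
  if (!inherits(posterior, "posterior_estimate")) {
    stop("predict_grid: a posterior_estimate is required")
  }
  curve <- match.arg(curve)
  times <- prediction_times()
  conc <- if (curve == "posterior_mean") {
    solve_profile(posterior$posterior_mean, dose, times, posterior$structure)
  } else {
    w <- posterior$posterior_weights
    acc <- numeric(length(times))
    for (j in seq_along(w)) {
      if (w[j] <= 0) next
      p <- posterior$support[j, ]
      acc <- acc + w[j] * profile_stacked(p, times, rep(dose$amount, length(times)))
    }
    acc
  }
  structure(data.frame(time_h = times, conc_uM = pmax(conc, 0)),
            class = c("prediction_grid", "data.frame"))
}

prediction_times <- function(horizon_h = 72, step_h = 1 / 60) {
  seq(0, horizon_h, by = step_h)
}

#' Absorption half-life from the absorption rate constant
#'
#' Time for half the tracer amount in CSF to be cleared to blood:
#' `ln(2) / Ka`. This is the study's surrogate for CSF-to-blood clearance.
#'
#' @param ka Absorption rate constant (1/h), > 0.
#' @return Half-life in hours.
#' @export
t_half_abs <- function(ka) {
  if (any(!is.finite(ka)) || any(ka <= 0)) stop("t_half_abs: Ka must be > 0")
  log(2) / ka
}

#' Time and value of the maximum predicted concentration
#'
#' Argmax and max over the prediction grid; ties resolve to the earliest
#' grid time.
#'
#' @param grid A [predict_grid()] data frame.
#' @return Named list `t_max` (h) and `c_max` (uM).
#' @export
tmax_cmax <- function(grid) {
  i <- which.max(grid$conc_uM)
  list(t_max = grid$time_h[i], c_max = grid$conc_uM[i])
}

#' Area under the concentration-time curve from zero to infinity
#'
#' Trapezoidal integral over the 72 h prediction grid plus a terminal
#' extrapolation `C(72) / lambda_z`, with `lambda_z` the log-linear slope
#' fitted to the final 12 h of the grid. An all-zero curve returns 0 with no
#' terminal fit; a non-negative fitted slope likewise contributes no tail.
#'
#' @param grid A [predict_grid()] data frame.
#' @param tail_window_h Width of the terminal fitting window (h).
#' @return AUC in uM h.
#' @export
auc_0_inf <- function(grid, tail_window_h = 12) {
  auc <- pracma::trapz(grid$time_h, grid$conc_uM)
  t_end <- grid$time_h[nrow(grid)]
  c_last <- grid$conc_uM[nrow(grid)]
  if (c_last <= 0) return(auc)
  win <- grid$time_h >= t_end - tail_window_h & grid$conc_uM > 0
  if (sum(win) < 3) return(auc)
  fit <- stats::lm.fit(cbind(1, grid$time_h[win]), log(grid$conc_uM[win]))
  lambda_z <- -unname(fit$coefficients[2])
  if (!is.finite(lambda_z) || lambda_z <= 0) return(auc)
  auc + c_last / lambda_z
}

#' Normalise an exposure metric to the reference dose
#'
#' `value * (0.5 / dose_mmol)`: Cmax and AUC are rescaled to the 0.50 mmol
#' reference arm so dose arms are comparable under dose linearity.
#'
#' @param value Metric value (Cmax in uM or AUC in uM h).
#' @param dose_mmol Administered dose in mmol (> 0).
#' @return The dose-normalised value.
#' @export
dose_normalize <- function(value, dose_mmol) {
  if (any(!is.finite(dose_mmol)) || any(dose_mmol <= 0)) {
    stop("dose_normalize: dose_mmol must be > 0")
  }
  value * (DOSE_REFERENCE_MMOL / dose_mmol)
}

#' Plasma:whole-blood partition ratio by regression through the origin
#'
#' Fits `plasma = slope * whole_blood` with no intercept:
#' `slope = sum(x y) / sum(x^2)`. The reported R-squared is the adjusted
#' uncentred R-squared of the no-intercept model.
#'
#' @param pairs Data frame (or 2-column matrix) with whole-blood
#'   concentrations in the first column and plasma concentrations in the
#'   second (both uM); >= 2 pairs, not all whole-blood values zero.
#' @return A `ratio_fit` list: `slope`, `r_squared_adjusted`, `n_pairs`.
#' @export
fit_blood_plasma_ratio <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 2) stop("fit_blood_plasma_ratio: at least 2 pairs required")
  x <- pairs[[1]]; y <- pairs[[2]]
  if (all(x == 0)) stop("fit_blood_plasma_ratio: all whole-blood values are zero")
  slope <- sum(x * y) / sum(x^2)
  rss <- sum((y - slope * x)^2)
  tss <- sum(y^2)  # uncentred: the no-intercept null predicts 0
  n <- length(x)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * n / (n - 1)
  structure(list(slope = slope, r_squared_adjusted = r2_adj, n_pairs = n),
            class = "ratio_fit")
}

#' Convert observations to plasma-equivalent concentrations
#'
#' Whole-blood concentrations are multiplied by the fitted plasma:whole-blood
#' slope (plasma exceeds whole blood because the tracer is excluded from
#' erythrocytes); plasma observations pass through unchanged.
#'
#' @param observations Observation data frame (columns `conc_uM`, `matrix`).
#' @param ratio A [fit_blood_plasma_ratio()] fit, or a bare slope.
#' @return The data frame with whole-blood rows converted and relabelled.
#' @export
convert_matrix <- function(observations, ratio) {
  slope <- if (inherits(ratio, "ratio_fit")) ratio$slope else ratio
  stopifnot(is.finite(slope), slope > 0)
  wb <- observations$matrix == "whole_blood"
  observations$conc_uM[wb] <- observations$conc_uM[wb] * slope
  observations$matrix[wb] <- "plasma"
  observations
}

#' All derived pharmacokinetic metrics for one subject
#'
#' Assembles the absorption half-life (from the posterior-mean `Ka`), the
#' lag time (posterior-mean `Tlag`), Tmax and Cmax from the 1-minute
#' prediction grid, the trapezoidal AUC to infinity, and the dose-normalised
#' Cmax and AUC.
#'
#' @param posterior A [posterior_individual()] estimate.
#' @param dose A [dose_event()].
#' @param curve Prediction convention passed to [predict_grid()].
#' @return A `derived_metrics` list: `t_half_abs`, `t_max`, `c_max`, `t_lag`,
#'   `auc_0_inf`, `c_max_dn`, `auc_dn`.
#' @export
derive_all <- function(posterior, dose, curve = "posterior_mean") {
  grid <- predict_grid(posterior, dose, curve)
  pk <- tmax_cmax(grid)
  auc <- auc_0_inf(grid)
  dose_mmol <- dose$amount / 1000
  structure(list(
    t_half_abs = t_half_abs(posterior$posterior_mean[["Ka"]]),
    t_max = pk$t_max,
    c_max = pk$c_max,
    t_lag = posterior$posterior_mean[["Tlag"]],
    auc_0_inf = auc,
    c_max_dn = dose_normalize(pk$c_max, dose_mmol),
    auc_dn = dose_normalize(auc, dose_mmol)),
    class = "derived_metrics")
}

#' Tidy per-subject metrics table
#'
#' One row per subject with the standard export columns
#' `subject_id, group, dose_mmol, t_half_abs_h, t_max_h, c_max_uM, t_lag_h,
#' auc_uMh, c_max_dn_uM, auc_dn_uMh`.
#'
#' @param subjects List of [subject_record()] objects.
#' @param posteriors List of matching [posterior_individual()] estimates.
#' @param curve Prediction convention passed to [predict_grid()].
#' @return Data frame of derived metrics.
#' @export
derive_metrics_table <- function(subjects, posteriors, curve = "posterior_mean") {
  stopifnot(length(subjects) == length(posteriors))
  do.call(rbind, lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    m <- derive_all(posteriors[[i]], s$dose, curve)
    data.frame(subject_id = s$id, group = s$group,
               dose_mmol = s$dose$amount / 1000,
               t_half_abs_h = m$t_half_abs, t_max_h = m$t_max,
               c_max_uM = m$c_max, t_lag_h = m$t_lag,
               auc_uMh = m$auc_0_inf, c_max_dn_uM = m$c_max_dn,
               auc_dn_uMh = m$auc_dn)
  }))
}
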