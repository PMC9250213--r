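# End-to-end study pipeline: development/validation split, candidate-model
# selection by predictive error, per-group metric summaries, group and
# dose-arm statistics, and covariate correlations.

#' Development/validation split
#'
#' Subjects with more than six usable samples are allocated to the
#' development set; the remaining development slots (up to `dev_fraction`
#' of profiles, rounded to the nearest subject) are filled by a seeded
#' random draw. If the richly sampled subjects alone already exceed the
#' target, they all go to development and a warning is emitted.
#'
#' @param subjects List of [subject_record()] objects.
#' @param dev_fraction Fraction of profiles allocated to development.
#' @param seed Integer seed for the random fill.
#' @return List with `dev` and `validation` subject lists (disjoint,
#'   exhaustive).
#' @export
split_dev_validation <- function(subjects, dev_fraction = 0.8, seed = 1L) {
  n <- length(subjects)
  n_obs <- vapply(subjects, function(s) nrow(usable_observations(s)), 1L)
  target <- round(dev_fraction * n)
  forced <- which(n_obs > 6)
  if (length(forced) >= target) {
    if (length(forced) > target) {
      warning("split_dev_validation: subjects with > 6 samples already exceed ",
              "the development target; all allocated to development")
    }
    dev_idx <- forced
  } else {
    pool <- setdiff(seq_len(n), forced)
    extra <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
      sample(pool, target - length(forced))
    })
    dev_idx <- sort(c(forced, extra))
  }
  list(dev = subjects[dev_idx],
       validation = subjects[setdiff(seq_len(n), dev_idx)])
}

#' Goodness-of-fit diagnostics of posterior individual predictions
#'
#' Mean prediction error `mean(pred - obs)`, root mean squared error, the
#' relative RMSE in percent (over observations with `obs > 0`), the
#' observed-versus-predicted regression line, and the residual series with a
#' configurable relative-error band.
#'
#' @param subjects List of [subject_record()] objects.
#' @param posteriors Matching list of [posterior_individual()] estimates.
#' @param rel_band Relative-error band drawn around zero in the residual
#'   series (default 15%).
#' @return A `diagnostics_report` list: `mpe`, `rmse`, `rmse_pct`, `slope`,
#'   `r_squared`, `n_obs` and a `residuals` data frame (`subject_id`,
#'   `time_h`, `obs`, `pred`, `resid`, `within_band`).
#' @export
prediction_diagnostics <- function(subjects, posteriors, rel_band = 0.15) {
  stopifnot(length(subjects) == length(posteriors))
  rows <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    obs <- usable_observations(s)
    pred <- solve_profile(posteriors[[i]]$posterior_mean, s$dose, obs$time_h,
                          posteriors[[i]]$structure)
    data.frame(subject_id = s$id, time_h = obs$time_h,
               obs = obs$conc_uM, pred = pred)
  }))
  resid <- rows$pred - rows$obs
  pos <- rows$obs > 0
  mpe <- mean(resid)
  rmse <- sqrt(mean(resid^2))
  rmse_pct <- 100 * sqrt(mean((resid[pos] / rows$obs[pos])^2))
  fit <- stats::lm(obs ~ pred, data = rows)
  fit_summary <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  rows$resid <- resid
  rows$within_band <- abs(resid) <= rel_band * rows$obs
  structure(list(mpe = mpe, rmse = rmse, rmse_pct = rmse_pct,
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = fit_summary$r.squared,
                 n_obs = nrow(rows), residuals = rows),
            class = "diagnostics_report")
}

METRIC_COLUMNS <- c("t_half_abs_h", "t_max_h", "c_max_uM", "t_lag_h",
                    "auc_uMh", "c_max_dn_uM", "auc_dn_uMh")

#' Per-group mean, SD and CV of the derived metrics
#'
#' @param metrics Data frame from [derive_metrics_table()].
#' @param metric_cols Metric columns to summarise.
#' @return Data frame with `group`, `metric`, `n`, `mean`, `sd`, `cv_pct`
#'   (CV rounded to whole percent; 0 for single-subject groups).
#' @export
group_summary <- function(metrics, metric_cols = METRIC_COLUMNS) {
  metric_cols <- intersect(metric_cols, names(metrics))
  out <- list()
  for (g in unique(metrics$group)) {
    sub <- metrics[metrics$group == g, , drop = FALSE]
    for (m in metric_cols) {
      x <- sub[[m]]
      s <- if (length(x) > 1) stats::sd(x) else 0
      out[[length(out) + 1L]] <- data.frame(
        group = g, metric = m, n = length(x), mean = mean(x), sd = s,
        cv_pct = if (mean(x) > 0) round(100 * s / mean(x)) else NA_real_)
    }
  }
  do.call(rbind, out)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Group-versus-reference comparisons of the derived metrics
#'
#' Two-tailed independent-samples t-test of each non-reference group against
#' the reference, per metric, with the difference of means
#' (`group - reference`), its 95% confidence interval and significance stars
#' at 0.05/0.01/0.001. Welch's unequal-variance form is the default.
#'
#' @param metrics Data frame from [derive_metrics_table()].
#' @param reference_group Reference group label.
#' @param metric_cols Metric columns to compare.
#' @param var_equal Use the pooled-variance t-test instead of Welch's.
#' @return Data frame with `metric`, `group`, `reference`, `difference`,
#'   `ci_low`, `ci_high`, `p_value`, `stars` and both groups' mean/sd.
#' @export
compare_groups <- function(metrics, reference_group = "REF",
                           metric_cols = METRIC_COLUMNS, var_equal = FALSE) {
  metric_cols <- intersect(metric_cols, names(metrics))
  ref <- metrics[metrics$group == reference_group, , drop = FALSE]
  if (!nrow(ref)) stop("compare_groups: reference group '", reference_group, "' not found")
  out <- list()
  for (g in setdiff(unique(metrics$group), reference_group)) {
    sub <- metrics[metrics$group == g, , drop = FALSE]
    for (m in metric_cols) {
      x <- sub[[m]]; y <- ref[[m]]
      tt <- stats::t.test(x, y, var.equal = var_equal)
      out[[length(out) + 1L]] <- data.frame(
        metric = m, group = g, reference = reference_group,
        difference = mean(x) - mean(y),
        ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
        p_value = tt$p.value, stars = significance_stars(tt$p.value),
        mean_group = mean(x), sd_group = stats::sd(x),
        mean_ref = mean(y), sd_ref = stats::sd(y))
    }
  }
  do.call(rbind, out)
}

#' Exact test for a categorical contingency table
#'
#' Fisher's exact test on a 2 x k table of counts.
#'
#' @param counts Matrix (or coercible) of non-negative integer counts.
#' @return The exact p-value.
#' @export
categorical_test <- function(counts) {
  stats::fisher.test(as.matrix(counts))$p.value
}

#' Dose-linearity assessment across dose arms
#'
#' One-way ANOVA of each metric (dose-normalised where applicable) across
#' the 0.10/0.25/0.50 mmol arms, with pairwise mean differences and 95%
#' confidence intervals.
#'
#' @param metrics Data frame from [derive_metrics_table()].
#' @param metric_cols Metrics to assess; the default uses the
#'   dose-invariant ones (half-life, Tmax, lag) plus the dose-normalised
#'   exposure metrics.
#' @return List with `anova` (per-metric F and p) and `pairwise`
#'   (per metric and arm pair: difference, CI, p).
#' @export
dose_linearity_test <- function(metrics,
                                metric_cols = c("t_half_abs_h", "t_max_h",
                                                "t_lag_h", "c_max_dn_uM",
                                                "auc_dn_uMh")) {
  metric_cols <- intersect(metric_cols, names(metrics))
  arm <- factor(metrics$dose_mmol)
  if (nlevels(arm) < 2) stop("dose_linearity_test: need at least two dose arms")
  anova_rows <- list(); pair_rows <- list()
  for (m in metric_cols) {
    fit <- stats::aov(metrics[[m]] ~ arm)
    tab <- summary(fit)[[1]]
    anova_rows[[length(anova_rows) + 1L]] <- data.frame(
      metric = m, f_value = tab$`F value`[1], p_value = tab$`Pr(>F)`[1])
    lv <- levels(arm)
    for (i in seq_len(length(lv) - 1)) {
      for (j in seq(i + 1, length(lv))) {
        xi <- metrics[[m]][arm == lv[i]]; xj <- metrics[[m]][arm == lv[j]]
        if (length(xi) < 2 || length(xj) < 2) next
        tt <- stats::t.test(xj, xi)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          metric = m, arm_a = lv[j], arm_b = lv[i],
          difference = mean(xj) - mean(xi),
          ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
          p_value = tt$p.value)
      }
    }
  }
  list(anova = do.call(rbind, anova_rows),
       pairwise = if (length(pair_rows)) do.call(rbind, pair_rows) else NULL)
}

#' Pearson correlations between metrics and covariates
#'
#' Pearson's r with the Fisher-z 95% confidence interval and two-tailed
#' p-value for every (metric, covariate) pair, with significance stars at
#' 0.05 and 0.01.
#'
#' @param metrics Data frame of per-subject metrics.
#' @param covariates Data frame of per-subject covariates, same row order.
#' @param metric_cols,covariate_cols Columns to correlate.
#' @return Data frame with `metric`, `covariate`, `r`, `ci_low`, `ci_high`,
#'   `p_value`, `stars`, `n`.
#' @export
covariate_correlations <- function(metrics, covariates,
                                   metric_cols = METRIC_COLUMNS,
                                   covariate_cols = c("age", "height", "weight")) {
  metric_cols <- intersect(metric_cols, names(metrics))
  covariate_cols <- intersect(covariate_cols, names(covariates))
  out <- list()
  for (m in metric_cols) {
    for (cv in covariate_cols) {
      ok <- stats::complete.cases(metrics[[m]], covariates[[cv]])
      if (sum(ok) < 4) {
        out[[length(out) + 1L]] <- data.frame(
          metric = m, covariate = cv, r = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, p_value = NA_real_, stars = "", n = sum(ok))
        next
      }
      ct <- stats::cor.test(metrics[[m]][ok], covariates[[cv]][ok],
                            method = "pearson")
      p <- ct$p.value
      out[[length(out) + 1L]] <- data.frame(
        metric = m, covariate = cv, r = unname(ct$estimate),
        ci_low = ct$conf.int[1], ci_high = ct$conf.int[2], p_value = p,
        stars = ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")),
        n = sum(stats::complete.cases(metrics[[m]], covariates[[cv]])))
    }
  }
  do.call(rbind, out)
}

#' Per-subject covariate table
#'
#' @param subjects List of [subject_record()] objects.
#' @return Data frame with `subject_id`, `age`, `sex`, `height`, `weight`,
#'   `bmi`, `gfr` (NA where a covariate is absent).
#' @export
subject_covariate_df <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s) {
    cv <- s$covariates
    data.frame(subject_id = s$id,
               age = cv$age %||% NA_real_, sex = cv$sex %||% NA_character_,
               height = cv$height %||% NA_real_, weight = cv$weight %||% NA_real_,
               bmi = cv$bmi %||% NA_real_, gfr = cv$gfr %||% NA_real_)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Posterior predictive relative RMSE of a fitted model on held-out subjects.
validation_rmse_pct <- function(model, subjects) {
  posts <- lapply(subjects, posterior_individual, model = model)
  prediction_diagnostics(subjects, posts)$rmse_pct
}

#' Run the full analysis pipeline on a (synthetic) cohort
#'
#' Simulates a cohort (or accepts one), fits the whole-blood/plasma
#' conversion, splits development/validation, fits one- and two-compartment
#' candidates on the development set, selects the structure by validation
#' relative RMSE (ties broken by observed-versus-predicted R-squared, then
#' AIC), refits the selected structure on the complete dataset, computes
#' posterior individual estimates and derived metrics, and assembles group
#' summaries, group comparisons, dose-linearity ANOVA and covariate
#' correlations.
#'
#' @param config A [cohort_config()]; default [default_study_config()].
#' @param cohort Optional pre-simulated [simulate_cohort()] result.
#' @param structures Candidate structures to fit (default both); passing a
#'   single structure skips selection.
#' @param fit_args Named list of extra arguments passed to every
#'   [profile_ke_fit()] call (e.g. a smaller `ke_grid` or inner-fit budget
#'   for scaled-down runs).
#' @param out_dir Optional directory: when given, the standard CSV/JSON
#'   artifacts are written there.
#' @return List with the cohort, ratio fit, split, candidate fits and
#'   diagnostics, the selected structure, final model, posteriors, metrics
#'   table, and the statistical summaries.
#' @export
run_pipeline <- function(config = default_study_config(), cohort = NULL,
                         structures = c("two_compartment", "one_compartment"),
                         fit_args = list(), out_dir = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  subjects <- cohort$subjects

  pairs <- simulate_paired_blood(cohort)
  ratio <- fit_blood_plasma_ratio(pairs)
  subjects <- lapply(subjects, function(s) {
    s$observations <- convert_matrix(s$observations, ratio)
    s
  })

  split <- split_dev_validation(subjects, seed = config$seed)
  fit_structure <- function(subs, st) {
    do.call(profile_ke_fit,
            c(list(subjects = subs, error = config$noise, structure = st,
                   seed = config$seed), fit_args))
  }

  candidates <- list()
  for (st in structures) {
    dev_fit <- fit_structure(split$dev, st)
    score_subjects <- if (length(split$validation)) split$validation else split$dev
    posts <- lapply(score_subjects, posterior_individual, model = dev_fit$model)
    diag <- prediction_diagnostics(score_subjects, posts)
    candidates[[st]] <- list(fit = dev_fit, diagnostics = diag,
                             ic = information_criteria(dev_fit$model))
  }
  scores <- vapply(candidates, function(x) x$diagnostics$rmse_pct, numeric(1))
  best <- names(scores)[order(scores,
                              -vapply(candidates, function(x) x$diagnostics$r_squared, 1),
                              vapply(candidates, function(x) x$ic$AIC, 1))][1]

  final_fit <- fit_structure(subjects, best)
  final_model <- final_fit$model
  posteriors <- lapply(subjects, posterior_individual, model = final_model)
  final_diag <- prediction_diagnostics(subjects, posteriors)
  metrics <- derive_metrics_table(subjects, posteriors)
  covs <- subject_covariate_df(subjects)

  ref_metrics <- metrics[metrics$group == "REF", , drop = FALSE]
  ref_covs <- covs[match(ref_metrics$subject_id, covs$subject_id), , drop = FALSE]
  result <- list(
    cohort = cohort, ratio = ratio, split = split, candidates = candidates,
    selected_structure = best, model = final_model, final_fit = final_fit,
    diagnostics = final_diag, posteriors = posteriors, metrics = metrics,
    group_summary = group_summary(metrics),
    group_comparisons = compare_groups(metrics),
    dose_linearity = if (length(unique(metrics$dose_mmol)) > 1)
      dose_linearity_test(metrics) else NULL,
    covariate_correlations = if (nrow(ref_metrics) > 3 &&
                                 any(!is.na(ref_covs$age)))
      covariate_correlations(ref_metrics, ref_covs) else NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_conc_csv(subjects, file.path(out_dir, "concentrations.csv"))
    utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(result$group_summary, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(result$group_comparisons,
                     file.path(out_dir, "group_comparisons.csv"), row.names = FALSE)
    if (!is.null(result$covariate_correlations)) {
      utils::write.csv(result$covariate_correlations,
                       file.path(out_dir, "covariate_correlations.csv"),
                       row.names = FALSE)
    }
    write_population_model(final_model, file.path(out_dir, "population_model.json"))
  }
  result
}
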