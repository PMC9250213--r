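# Metrics tables built directly (no fitting) for the statistical layer.
toy_metrics <- function(groups, values, metric = "t_half_abs_h",
                        dose = 0.5) {
  df <- data.frame(subject_id = paste0("S", seq_along(values)),
                   group = groups, dose_mmol = dose)
  df[[metric]] <- values
  df
}

# Two values with a prescribed sample mean and SD.
two_point <- function(mean, sd) mean + sd / sqrt(2) * c(-1, 1)

test_that("development/validation split follows the richly-sampled-first rule", {
  p <- ref_params()
  rich <- lapply(1:9, function(i) make_subject(p, times = 1:8, id = paste0("R", i)))
  poor <- lapply(1:1, function(i) make_subject(p, times = 1:4, id = paste0("P", i)))
  expect_warning(sp <- split_dev_validation(c(rich, poor), 0.8, seed = 1),
                 "exceed")
  expect_gte(length(sp$dev), 9)

  sparse <- lapply(1:100, function(i) make_subject(p, times = c(1, 4, 12, 30),
                                                   id = paste0("S", i)))
  sp2 <- split_dev_validation(sparse, 0.8, seed = 2)
  expect_length(sp2$dev, 80)
  expect_length(sp2$validation, 20)
  expect_length(intersect(vapply(sp2$dev, function(s) s$id, ""),
                          vapply(sp2$validation, function(s) s$id, "")), 0)
  sp3 <- split_dev_validation(sparse, 0.8, seed = 2)
  expect_identical(vapply(sp2$dev, function(s) s$id, ""),
                   vapply(sp3$dev, function(s) s$id, ""))
})

test_that("prediction diagnostics match closed-form expectations and an oracle", {
  p <- ref_params()
  posts <- list(local({
    theta <- matrix(unclass(p), 1, 6, dimnames = list(NULL, names(p)))
    structure(list(subject_id = "S1", posterior_weights = 1, posterior_mean = p,
                   support = theta, structure = "two_compartment"),
              class = "posterior_estimate")
  }))
  s_perfect <- make_subject(p)
  d0 <- prediction_diagnostics(list(s_perfect), posts)
  expect_equal(d0$mpe, 0); expect_equal(d0$rmse, 0); expect_equal(d0$rmse_pct, 0)

  s_bias <- make_subject(p, times = c(4, 8, 24))
  s_bias$observations$conc_uM <- s_bias$observations$conc_uM - 0.1
  db <- prediction_diagnostics(list(s_bias), posts)
  expect_equal(db$mpe, 0.1, tolerance = 1e-12)
  expect_equal(db$rmse, 0.1, tolerance = 1e-12)

  set.seed(1)
  s_noisy <- make_subject(p, error = assay_error_model(0.01, 0.2))
  dn <- prediction_diagnostics(list(s_noisy), posts)
  pred <- solve_profile(p, s_noisy$dose, s_noisy$observations$time_h)
  obs <- s_noisy$observations$conc_uM
  expect_equal(dn$mpe, mean(pred - obs), tolerance = 1e-12)
  expect_equal(dn$rmse, sqrt(mean((pred - obs)^2)), tolerance = 1e-12)
  expect_equal(dn$rmse_pct, 100 * sqrt(mean(((pred - obs) / obs)^2)),
               tolerance = 1e-12)
  ols <- stats::lm(obs ~ pred)
  expect_equal(dn$slope, unname(stats::coef(ols)[2]), tolerance = 1e-12)
  expect_equal(dn$r_squared, summary(ols)$r.squared, tolerance = 1e-12)
})

test_that("group summaries report mean, SD and rounded CV per group", {
  m <- toy_metrics(c("REF", "REF", "IIH"), c(two_point(4.57, 3.31), 2.0))
  gs <- group_summary(m, "t_half_abs_h")
  ref <- gs[gs$group == "REF", ]
  expect_equal(ref$mean, 4.57)
  expect_equal(ref$sd, 3.31, tolerance = 1e-12)
  expect_equal(ref$cv_pct, 72)  # round(100 * 3.31 / 4.57)
  solo <- gs[gs$group == "IIH", ]
  expect_equal(solo$sd, 0)
  expect_equal(solo$cv_pct, 0)
})

test_that("group comparisons reproduce t-test arithmetic", {
  x <- c(3.1, 4.2, 5.0, 4.4, 3.8)
  y <- c(5.2, 6.1, 5.9, 6.8, 5.5)
  m <- toy_metrics(rep(c("REF", "IIH"), each = 5), c(x, y))
  cmp <- compare_groups(m, "REF", "t_half_abs_h")
  expect_equal(cmp$difference, mean(y) - mean(x), tolerance = 1e-12)
  # Welch oracle from the textbook formulas
  se <- sqrt(stats::var(x) / 5 + stats::var(y) / 5)
  df <- se^4 / ((stats::var(x) / 5)^2 / 4 + (stats::var(y) / 5)^2 / 4)
  tstat <- (mean(y) - mean(x)) / se
  expect_equal(cmp$p_value, 2 * stats::pt(-abs(tstat), df), tolerance = 1e-12)
  expect_equal(cmp$ci_low, (mean(y) - mean(x)) - stats::qt(0.975, df) * se,
               tolerance = 1e-12)
  expect_equal(cmp$ci_high, (mean(y) - mean(x)) + stats::qt(0.975, df) * se,
               tolerance = 1e-12)

  # identical groups: zero difference, p = 1
  m2 <- toy_metrics(rep(c("REF", "AC"), each = 5), c(x, x))
  cmp2 <- compare_groups(m2, "REF", "t_half_abs_h")
  expect_equal(cmp2$difference, 0)
  expect_equal(cmp2$p_value, 1)
})

test_that("the exact categorical test matches full enumeration", {
  expect_equal(categorical_test(matrix(c(5, 5, 5, 5), 2)), 1)
  tab <- matrix(c(10, 0, 0, 10), 2)
  # enumerate all tables with the observed margins
  probs <- vapply(0:10, function(k)
    stats::dhyper(k, 10, 10, 10), numeric(1))
  p_obs <- stats::dhyper(10, 10, 10, 10)
  oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  expect_equal(categorical_test(tab), oracle, tolerance = 1e-12)
  expect_equal(categorical_test(tab), categorical_test(tab[2:1, ]))
})

test_that("dose-linearity ANOVA matches the closed-form F statistic", {
  base <- c(0.61, 0.72, 0.66, 0.70, 0.68, 0.75)
  m <- toy_metrics(rep("REF", 18), rep(base, 3), metric = "c_max_dn_uM",
                   dose = rep(c(0.1, 0.25, 0.5), each = 6))
  dl <- dose_linearity_test(m, "c_max_dn_uM")
  expect_equal(dl$anova$f_value, 0, tolerance = 1e-12)
  expect_equal(dl$anova$p_value, 1, tolerance = 1e-12)

  shifted <- c(base, base + 0.2, base + 0.4)
  m2 <- toy_metrics(rep("REF", 18), shifted, metric = "c_max_dn_uM",
                    dose = rep(c(0.1, 0.25, 0.5), each = 6))
  dl2 <- dose_linearity_test(m2, "c_max_dn_uM")
  groups <- split(shifted, rep(1:3, each = 6))
  gm <- vapply(groups, mean, 1); overall <- mean(shifted)
  ssb <- 6 * sum((gm - overall)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  f_oracle <- (ssb / 2) / (ssw / 15)
  expect_equal(dl2$anova$f_value, f_oracle, tolerance = 1e-12)
  expect_equal(nrow(dl2$pairwise), 3)
})

test_that("dose-arm ANOVA false-positive rate is near the nominal level", {
  set.seed(202)
  rejections <- replicate(400, {
    vals <- rln_mcv(30, 0.7, 0.5)
    m <- toy_metrics(rep("REF", 30), vals, metric = "c_max_dn_uM",
                     dose = rep(c(0.1, 0.25, 0.5), each = 10))
    dose_linearity_test(m, "c_max_dn_uM")$anova$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.09)
})

test_that("covariate correlations match the Fisher-z oracle and cover the null", {
  m <- toy_metrics(rep("REF", 6), c(1.2, 2.5, 2.1, 3.8, 3.2, 4.9))
  covs <- data.frame(age = c(30, 42, 38, 55, 51, 62))
  cc <- covariate_correlations(m, covs, "t_half_abs_h", "age")
  r <- stats::cor(m$t_half_abs_h, covs$age)
  z <- atanh(r); se <- 1 / sqrt(3)
  expect_equal(cc$r, r, tolerance = 1e-12)
  expect_equal(cc$ci_low, tanh(z - stats::qnorm(0.975) * se), tolerance = 1e-9)
  expect_equal(cc$ci_high, tanh(z + stats::qnorm(0.975) * se), tolerance = 1e-9)
  # metric correlated with itself
  self <- covariate_correlations(m, data.frame(age = m$t_half_abs_h),
                                 "t_half_abs_h", "age")
  expect_equal(self$r, 1)

  set.seed(33)
  covered <- replicate(200, {
    mm <- toy_metrics(rep("REF", 28), stats::rnorm(28))
    cv <- data.frame(age = stats::rnorm(28))
    ci <- covariate_correlations(mm, cv, "t_half_abs_h", "age")
    ci$ci_low <= 0 && ci$ci_high >= 0
  })
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.985)
})

test_that("group tests applied to truth-level cohorts recover configured contrasts", {
  # direction of the configured group effects, measured on generator truth
  set.seed(555)
  diffs <- replicate(50, {
    th_ref <- rln_mcv(28, 4.57, 0.72); th_iih <- rln_mcv(15, 2.32, 0.69)
    tl_ref <- rln_mcv(28, 0.74, 0.91); tl_inph <- rln_mcv(63, 1.16, 0.66)
    c(iih = mean(th_iih) - mean(th_ref), inph = mean(tl_inph) - mean(tl_ref))
  })
  expect_lt(mean(diffs["iih", ]), 0)   # faster absorption in IIH
  expect_gt(mean(diffs["inph", ]), 0)  # longer lag in iNPH

  # power of the IIH half-life contrast at the configured effect size
  set.seed(556)
  hits <- replicate(200, {
    p <- stats::t.test(rln_mcv(15, 2.32, 0.69), rln_mcv(28, 4.57, 0.72))$p.value
    p < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("the full pipeline runs deterministically on a scaled cohort", {
  cfg0 <- default_study_config(seed = 17)
  shrink <- function(g, n) {
    g$n_subjects <- as.integer(n)
    g$dose_allocation <- c("0.1" = 0L, "0.25" = 0L, "0.5" = as.integer(n))
    g
  }
  cfg <- cohort_config(groups = list(REF = shrink(cfg0$groups$REF, 6),
                                     IIH = shrink(cfg0$groups$IIH, 5)),
                       seed = 17)
  args <- list(ke_grid = c(0.08, 0.15, 0.3), refine_steps = 0,
               profile_n_initial = 60, profile_max_cycles = 12,
               final_n_initial = 100, final_max_cycles = 20)
  out_dir <- tempfile()
  on.exit(unlink(out_dir, recursive = TRUE))
  res <- suppressWarnings(run_pipeline(cfg, structures = "two_compartment",
                                       fit_args = args, out_dir = out_dir))
  expect_equal(nrow(res$metrics), 11)
  expect_true(all(c("concentrations.csv", "metrics.csv", "group_summary.csv",
                    "group_comparisons.csv", "population_model.json",
                    "truth.csv") %in% list.files(out_dir)))
  expect_true(all(res$metrics$t_max_h >= res$metrics$t_lag_h))
  expect_equal(res$ratio$n_pairs, 204)
  expect_lt(abs(res$ratio$slope - 1.795), 0.05)
  res2 <- suppressWarnings(run_pipeline(cfg, structures = "two_compartment",
                                        fit_args = args))
  expect_identical(res$metrics, res2$metrics)
  expect_identical(res$model$loglik, res2$model$loglik)
})

test_that("structure selection prefers the generating compartment structure", {
  cfg0 <- default_study_config(seed = 23)
  g <- cfg0$groups$REF
  g$n_subjects <- 15L
  g$dose_allocation <- c("0.1" = 0L, "0.25" = 0L, "0.5" = 15L)
  # pronounced tissue distribution: clearly biphasic profiles
  g$kinetics$kcp <- 0.5
  g$kinetics$kpc <- 0.03
  g$kinetics$ke <- 0.3
  cfg <- cohort_config(groups = list(REF = g), seed = 23)
  args <- list(ke_grid = c(0.1, 0.2, 0.4), refine_steps = 0,
               kcp = 0.5, kpc = 0.03,
               profile_n_initial = 80, profile_max_cycles = 15,
               final_n_initial = 120, final_max_cycles = 25)
  res <- suppressWarnings(run_pipeline(cfg, fit_args = args))
  expect_equal(res$selected_structure, "two_compartment")
})
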