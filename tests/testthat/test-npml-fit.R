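test_that("initial grid is deterministic, in-bounds and space-filling", {
  b <- default_bounds("two_compartment")
  expect_error(init_grid(b, 0), "positive")
  g1 <- init_grid(b, 1, seed = 3)
  expect_equal(nrow(g1), 1)
  for (nm in colnames(g1)) {
    expect_gte(g1[1, nm], b[[nm]][1]); expect_lte(g1[1, nm], b[[nm]][2])
  }
  expect_identical(init_grid(b, 200, seed = 9), init_grid(b, 200, seed = 9))

  g <- init_grid(b, 1000, seed = 1)
  for (nm in colnames(g)) {
    lo <- b[[nm]][1]; hi <- b[[nm]][2]
    expect_true(all(g[, nm] >= lo & g[, nm] <= hi))
    # every quartile of every dimension receives points
    q <- findInterval(g[, nm], lo + (hi - lo) * c(0.25, 0.5, 0.75))
    expect_true(all(tabulate(q + 1, 4) > 0))
  }
})

test_that("weight optimisation handles trivial and dominated supports", {
  expect_equal(optimize_weights(matrix(c(2, 1, 3), 3, 1))$weights, 1)
  # point 1 dominates point 2 by a factor 10 for every subject
  L <- cbind(c(1, 2, 0.5), 0.1 * c(1, 2, 0.5))
  w <- optimize_weights(L)$weights
  expect_lt(w[2], 1e-6)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  L0 <- rbind(c(1, 1), c(0, 0))
  expect_error(optimize_weights(L0), "zero likelihood")
})

test_that("weight optimisation matches a brute-force simplex grid search", {
  set.seed(31)
  L <- matrix(stats::runif(15, 0.05, 1), 5, 3)
  opt <- optimize_weights(L)
  res <- 1e-3
  w1 <- seq(0, 1, by = res)
  grid <- expand.grid(w1 = w1, w2 = w1)
  grid <- grid[grid$w1 + grid$w2 <= 1, ]
  W <- cbind(grid$w1, grid$w2, 1 - grid$w1 - grid$w2)
  best <- max(colSums(log(L %*% t(W))))
  expect_gte(opt$objective, best - 1e-8)
  expect_lte(opt$objective - best, 0.05)  # grid resolution error bound
})

test_that("condense removes negligible mass without losing likelihood", {
  set.seed(12)
  cohort <- single_group_cohort(6, seed = 21)
  cfg <- fit_config("two_compartment",
                    bounds = list(Ka = c(0.02, 1), Tlag = c(0, 3), V = c(50, 1000),
                                  Ke = 0.157, Kcp = 0.1, Kpc = 0.05),
                    n_initial = 120, max_cycles = 10, seed = 5)
  m <- suppressWarnings(npml_fit(cohort$subjects, cohort$config$noise, cfg))
  m0 <- condense(m, cohort$subjects)
  # no point below the floor: condensing keeps the support and likelihood
  m1 <- condense(m0, cohort$subjects, eps = 0)
  expect_equal(nrow(m1$support), nrow(m0$support))
  expect_gte(m1$loglik, m0$loglik - 1e-9)
  expect_lt(m1$loglik - m0$loglik, 0.01)
  # an explicit zero-weight point is removed and the likelihood unchanged
  m2 <- m0
  m2$support <- rbind(m2$support, m2$support[1, , drop = FALSE] * 0.9)
  m2$weights <- c(m2$weights, 0)
  m3 <- condense(m2, cohort$subjects)
  expect_equal(nrow(m3$support), nrow(m0$support))
  expect_gte(m3$loglik, m0$loglik - 1e-9)
  expect_lt(m3$loglik - m0$loglik, 0.01)
  expect_error(condense(structure(list(weights = numeric(0)), class = "population_model"),
                        cohort$subjects), "all support points|missing|max")
})

test_that("expansion never violates bounds and only improves the likelihood", {
  set.seed(2)
  cohort <- single_group_cohort(4, seed = 33)
  b <- list(Ka = c(0.02, 1), Tlag = c(0, 3), V = c(50, 1000),
            Ke = 0.157, Kcp = 0.1, Kpc = 0.05)
  cfg <- fit_config("two_compartment", bounds = b, n_initial = 60,
                    max_cycles = 5, seed = 5)
  m <- suppressWarnings(npml_fit(cohort$subjects, cohort$config$noise, cfg))
  m_id <- expand(m, cohort$subjects, delta = 0)
  expect_equal(m_id$loglik, m$loglik)
  m_ex <- expand(m, cohort$subjects, delta = 0.2)
  expect_gte(m_ex$loglik, m$loglik)
  for (nm in colnames(m_ex$support)) {
    expect_true(all(m_ex$support[, nm] >= b[[nm]][1] - 1e-12))
    expect_true(all(m_ex$support[, nm] <= b[[nm]][2] + 1e-12))
  }

  # a single subject whose lone support point is off the truth: any useful
  # displacement must strictly increase the log-likelihood
  truth <- ref_params(ka = 0.2, tlag = 0.5, v = 250, ke = 0.157)
  s <- make_subject(truth)
  off <- m
  off$support <- matrix(c(0.4, 1.2, 400), 1, 3,
                        dimnames = list(NULL, c("Ka", "Tlag", "V")))
  off$weights <- 1
  logL <- csfclear:::log_lik_matrix(list(s), csfclear:::full_theta(off$support, b),
                                    cohort$config$noise)
  off$loglik <- csfclear:::em_objective(logL, 1)
  off$n_subjects <- 1L
  ex <- expand(off, list(s), delta = 0.1)
  expect_gt(ex$loglik, off$loglik)
})

test_that("posterior individual estimates follow Bayes' rule", {
  cohort <- single_group_cohort(3, seed = 8)
  s <- cohort$subjects[[1]]
  b <- list(Ka = c(0.02, 1), Tlag = c(0, 3), V = c(50, 1000),
            Ke = 0.157, Kcp = 0.1, Kpc = 0.05)
  cfg <- fit_config("two_compartment", bounds = b, n_initial = 40,
                    max_cycles = 3, seed = 5)
  m <- suppressWarnings(npml_fit(cohort$subjects, cohort$config$noise, cfg))

  # single-point model: the posterior is that point
  m1 <- m
  m1$support <- m$support[1, , drop = FALSE]
  m1$weights <- 1
  p1 <- posterior_individual(s, m1)
  expect_equal(p1$posterior_weights, 1)
  expect_equal(unname(p1$posterior_mean[["Ka"]]), unname(m$support[1, "Ka"]))

  # two equally weighted points with likelihood ratio 3:1 -> 0.75 / 0.25
  m2 <- m1
  m2$support <- m$support[1:2, , drop = FALSE]
  m2$weights <- c(0.5, 0.5)
  ll <- csfclear:::log_lik_matrix(list(s), csfclear:::full_theta(m2$support, b),
                                  m$error_model)[1, ]
  # choose the prior so that prior x likelihood is exactly 3:1
  w <- c(0.75, 0.25) / exp(ll - max(ll))
  m2$weights <- w / sum(w)
  p2 <- posterior_individual(s, m2)
  expect_equal(unname(p2$posterior_weights), c(0.75, 0.25), tolerance = 1e-9)

  # random 5-point model equals a hand-rolled Bayes normalisation
  m5 <- m1
  m5$support <- m$support[1:5, , drop = FALSE]
  set.seed(4); w <- stats::runif(5); m5$weights <- w / sum(w)
  p5 <- posterior_individual(s, m5)
  ll5 <- csfclear:::log_lik_matrix(list(s), csfclear:::full_theta(m5$support, b),
                                   m$error_model)[1, ]
  post <- m5$weights * exp(ll5 - max(ll5))
  post <- post / sum(post)
  expect_equal(unname(p5$posterior_weights), unname(post), tolerance = 1e-12)
  expect_equal(p5$posterior_mean[["V"]], sum(post * m5$support[, "V"]),
               tolerance = 1e-12)
})

test_that("information criteria follow the stated formulas", {
  fake <- list(support = matrix(1, 1, 1), loglik = 0, n_obs = exp(1))
  ic <- information_criteria(fake)
  expect_equal(ic$p, 1)
  expect_equal(ic$AIC, 2)
  expect_equal(ic$BIC, 1)

  fake2 <- list(support = matrix(0, 7, 3), loglik = -123.45, n_obs = 200)
  ic2 <- information_criteria(fake2)
  p <- 7 * 4 - 1
  expect_equal(ic2$AIC, -2 * -123.45 + 2 * p)
  expect_equal(ic2$BIC, -2 * -123.45 + p * log(200))
})

test_that("a noiseless single-truth cohort collapses the support onto the truth", {
  set.seed(6)
  truth <- pk_parameters(ka = 0.2, tlag = 0.5, v = 250, ke = 0.157,
                         kcp = 0.1, kpc = 0.05)
  subjects <- lapply(1:6, function(i)
    make_subject(truth, times = seq(1, 48, by = 2.5), id = paste0("S", i)))
  cfg <- fit_config("two_compartment",
                    bounds = list(Ka = c(0.02, 1), Tlag = c(0, 3), V = c(50, 1000),
                                  Ke = 0.157, Kcp = 0.1, Kpc = 0.05),
                    n_initial = 150, max_cycles = 80, seed = 5)
  m <- suppressWarnings(npml_fit(subjects, assay_error_model(), cfg))
  near <- abs(m$support[, "Ka"] / 0.2 - 1) < 0.05 &
    abs(m$support[, "V"] / 250 - 1) < 0.05 &
    abs(m$support[, "Tlag"] - 0.5) < 0.15
  expect_gte(sum(m$weights[near]), 0.99)
  expect_gte(m$loglik, m$trace[1])  # final vs initial grid
})

test_that("a two-point mixture is recovered with weights near the truth", {
  set.seed(14)
  slow <- pk_parameters(ka = 0.1, tlag = 0.5, v = 250, ke = 0.157, kcp = 0.1, kpc = 0.05)
  fast <- pk_parameters(ka = 0.4, tlag = 0.5, v = 250, ke = 0.157, kcp = 0.1, kpc = 0.05)
  err <- assay_error_model(c0 = 0.001, c1 = 0.02)
  subjects <- c(
    lapply(1:18, function(i) make_subject(slow, error = err, id = paste0("A", i))),
    lapply(1:12, function(i) make_subject(fast, error = err, id = paste0("B", i))))
  cfg <- fit_config("two_compartment",
                    bounds = list(Ka = c(0.02, 1), Tlag = 0.5, V = 250,
                                  Ke = 0.157, Kcp = 0.1, Kpc = 0.05),
                    n_initial = 60, max_cycles = 60, seed = 5)
  m <- suppressWarnings(npml_fit(subjects, err, cfg))
  w_slow <- sum(m$weights[m$support[, "Ka"] < 0.2])
  expect_equal(w_slow, 0.6, tolerance = 0.1)
  expect_equal(1 - w_slow, 0.4, tolerance = 0.1)
})

test_that("fit results are invariant to subject ordering", {
  set.seed(77)
  cohort <- single_group_cohort(8, seed = 13)
  cfg <- fit_config("two_compartment",
                    bounds = list(Ka = c(0.02, 1), Tlag = c(0, 3), V = c(50, 1000),
                                  Ke = 0.157, Kcp = 0.1, Kpc = 0.05),
                    n_initial = 100, max_cycles = 25, seed = 5)
  m1 <- suppressWarnings(npml_fit(cohort$subjects, cohort$config$noise, cfg))
  m2 <- suppressWarnings(npml_fit(rev(cohort$subjects), cohort$config$noise, cfg))
  expect_equal(m1$loglik, m2$loglik, tolerance = 1e-8)
})

test_that("population model JSON serialisation round-trips bit-exactly", {
  cohort <- single_group_cohort(4, seed = 3)
  cfg <- fit_config("two_compartment",
                    bounds = list(Ka = c(0.02, 1), Tlag = c(0, 3), V = c(50, 1000),
                                  Ke = 0.157, Kcp = 0.1, Kpc = 0.05),
                    n_initial = 50, max_cycles = 5, seed = 5)
  m <- suppressWarnings(npml_fit(cohort$subjects, cohort$config$noise, cfg))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_population_model(m, path)
  back <- read_population_model(path)
  expect_identical(unname(back$support), unname(m$support))
  expect_identical(back$weights, m$weights)
  expect_identical(back$loglik, m$loglik)
  expect_identical(back$trace, m$trace)
  expect_identical(back$n_cycles, m$n_cycles)
})

test_that("profile likelihood over the shared elimination rate selects the truth", {
  set.seed(10)
  cohort <- single_group_cohort(8, seed = 19)
  ke_true <- cohort$config$groups$REF$kinetics$ke
  pf <- suppressWarnings(
    profile_ke_fit(cohort$subjects, cohort$config$noise, "two_compartment",
                   ke_grid = ke_true * c(0.5, 1, 2), refine_steps = 0,
                   profile_n_initial = 80, profile_max_cycles = 20,
                   final_n_initial = 120, final_max_cycles = 30, seed = 5))
  expect_equal(pf$ke, ke_true)
  expect_equal(nrow(pf$profile), 3)
  expect_equal(pf$profile$loglik[2], max(pf$profile$loglik))
})
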