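# Nonparametric maximum-likelihood population estimation on an adaptive grid.
#
# The population distribution of the structural parameters is represented as
# a discrete set of weighted support points. Fitting alternates between
# (i) the convex inner problem -- maximise sum_i log sum_j w_j L_ij over the
# probability simplex, solved by the monotone multiplicative EM update --
# and (ii) adaptive refinement of the support: low-weight points are dropped
# and each survivor spawns candidates displaced by a fraction of the
# parameter range, with the displacement halved whenever a cycle brings no
# improvement. All likelihood accumulation is done in the log domain with a
# per-subject max shift, so 8-11 observations per subject cannot underflow.

#' Fit configuration for the nonparametric population estimator
#'
#' @param structure `"one_compartment"` or `"two_compartment"`.
#' @param bounds Named list over `Ka, Tlag, V, Ke, Kcp, Kpc`. A length-2
#'   numeric `c(low, high)` marks a searched dimension; a scalar fixes the
#'   parameter at that value (it is then not part of the support grid).
#' @param n_initial Number of initial support points; default `2^d * 50`
#'   where `d` is the number of searched dimensions.
#' @param seed Integer seed for the (low-discrepancy) initial grid.
#' @param weight_floor Support points below this weight are dropped when the
#'   support is condensed; default `1e-8 * n_subjects`, resolved at fit time.
#' @param delta0 Initial expansion displacement as a fraction of each
#'   searched parameter's range.
#' @param delta_min Expansion displacement below which the search stops.
#' @param tol Convergence tolerance on the population log-likelihood:
#'   the expansion displacement is halved once a cycle improves by less
#'   than this (default 0.01 nats, a 1% likelihood ratio).
#' @param max_cycles Maximum number of adaptive cycles.
#' @param em_maxit,em_tol Iteration cap and objective tolerance of the inner
#'   multiplicative weight updates.
#' @param merge_tol Support points closer than this in range-scaled
#'   coordinates are merged, summing their weights.
#' @param max_support Cap on the number of support points kept after
#'   condensation; default `max(20, 2 * n_subjects)`, resolved at fit time.
#'   The nonparametric maximum-likelihood optimum needs at most one support
#'   point per subject, so the cap only trims redundant mass spread along
#'   flat likelihood directions.
#' @return A `fit_config` list.
#' @export
fit_config <- function(structure = c("two_compartment", "one_compartment"),
                       bounds = NULL, n_initial = NULL, seed = 1L,
                       weight_floor = NULL, delta0 = 0.2, delta_min = 1e-4,
                       tol = 1e-2, max_cycles = 100L,
                       em_maxit = 1000L, em_tol = 1e-10, merge_tol = 1e-8,
                       max_support = NULL) {
  structure <- match.arg(structure)
  if (is.null(bounds)) bounds <- default_bounds(structure)
  for (nm in PK_PARAM_NAMES) {
    if (is.null(bounds[[nm]])) stop("fit_config: bounds missing for ", nm)
    b <- bounds[[nm]]
    if (!length(b) %in% 1:2 || !all(is.finite(b))) {
      stop("fit_config: bounds for ", nm, " must be a finite scalar or c(low, high)")
    }
    if (length(b) == 2 && b[1] >= b[2]) {
      stop("fit_config: bounds for ", nm, " must satisfy low < high")
    }
  }
  if (structure == "one_compartment") {
    for (nm in c("Kcp", "Kpc")) {
      if (length(bounds[[nm]]) != 1 || bounds[[nm]] != 0) {
        stop("fit_config: one-compartment structure requires Kcp and Kpc fixed at 0")
      }
    }
  }
  stopifnot(delta_min < delta0, delta_min > 0, tol > 0)
  structure(list(structure = structure, bounds = bounds,
                 n_initial = n_initial, seed = as.integer(seed),
                 weight_floor = weight_floor, delta0 = delta0,
                 delta_min = delta_min, tol = tol,
                 max_cycles = as.integer(max_cycles),
                 em_maxit = as.integer(em_maxit), em_tol = em_tol,
                 merge_tol = merge_tol, max_support = max_support),
            class = "fit_config")
}

#' Default parameter bounds for each model structure
#'
#' Wide boxes covering the kinetics plausible for an intrathecal tracer with
#' absorption half-lives of minutes to days: `Ka` 0.01-3 /h, `Tlag` 0-4 h,
#' `V` 20-2000 L, `Ke` 0.02-1.5 /h and, for the two-compartment structure,
#' `Kcp` 0-1 and `Kpc` 0.005-1 /h.
#'
#' @param structure Model structure.
#' @return Named list of bounds usable in [fit_config()].
#' @export
default_bounds <- function(structure = c("two_compartment", "one_compartment")) {
  structure <- match.arg(structure)
  b <- list(Ka = c(0.01, 3), Tlag = c(0, 4), V = c(20, 2000), Ke = c(0.02, 1.5))
  if (structure == "two_compartment") {
    b$Kcp <- c(0, 1); b$Kpc <- c(0.005, 1)
  } else {
    b$Kcp <- 0; b$Kpc <- 0
  }
  b
}

searched_names <- function(bounds) {
  names(bounds)[vapply(bounds, length, 1L) == 2]
}

#' Seeded initial support grid
#'
#' Draws `n` points inside the searched bounds from a seeded Latin-hypercube
#' (low-discrepancy) design; deterministic given the seed.
#'
#' @param bounds Named bounds list as in [fit_config()].
#' @param n Number of points (> 0).
#' @param seed Integer seed.
#' @return Matrix `n x d` with one column per searched parameter.
#' @export
init_grid <- function(bounds, n, seed = 1L) {
  if (n <= 0) stop("init_grid: n must be positive")
  sn <- searched_names(bounds)
  if (!length(sn)) stop("init_grid: no searched dimensions in bounds")
  u <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    lhs::randomLHS(n, length(sn))
  })
  grid <- vapply(seq_along(sn), function(j) {
    b <- bounds[[sn[j]]]
    b[1] + u[, j] * (b[2] - b[1])
  }, numeric(n))
  grid <- matrix(grid, nrow = n, dimnames = list(NULL, sn))
  grid
}

# Full 6-parameter matrix (J x 6) from searched support + fixed values.
full_theta <- function(support, bounds) {
  J <- nrow(support)
  theta <- matrix(0, J, length(PK_PARAM_NAMES),
                  dimnames = list(NULL, PK_PARAM_NAMES))
  for (nm in PK_PARAM_NAMES) {
    theta[, nm] <- if (nm %in% colnames(support)) support[, nm] else bounds[[nm]][1]
  }
  theta
}

# Stack every subject's usable observations once; the likelihood matrix then
# needs a single vectorised profile evaluation per support point.
stack_observations <- function(subjects) {
  if (!length(subjects)) stop("stack_observations: no subjects")
  obs_list <- lapply(subjects, usable_observations)
  n_obs <- vapply(obs_list, nrow, 1L)
  bad <- which(n_obs == 0)
  if (length(bad)) {
    stop("stack_observations: no usable observations for subject(s) ",
         paste(vapply(subjects[bad], function(s) s$id, ""), collapse = ", "))
  }
  list(times = unlist(lapply(seq_along(subjects),
                             function(i) obs_list[[i]]$time_h - subjects[[i]]$dose$time)),
       conc = unlist(lapply(obs_list, function(o) o$conc_uM)),
       amount = unlist(lapply(seq_along(subjects),
                              function(i) rep(subjects[[i]]$dose$amount, n_obs[i]))),
       subject = rep(seq_along(subjects), n_obs),
       n_obs = n_obs)
}

# N x J matrix of per-subject log-likelihoods at each support point.
log_lik_matrix <- function(subjects, theta, error) {
  st <- stack_observations(subjects)
  N <- length(subjects)
  J <- nrow(theta)
  out <- matrix(NA_real_, N, J)
  log2pi <- log(2 * pi)
  for (j in seq_len(J)) {
    pred <- profile_stacked(theta[j, ], st$times, st$amount)
    sd <- error$c0 + error$c1 * pred
    ll <- -0.5 * ((st$conc - pred) / sd)^2 - log(sd) - 0.5 * log2pi
    out[, j] <- rowsum(ll, st$subject)[, 1]
  }
  out
}

em_objective <- function(logL, w) {
  shift <- apply(logL, 1, max)
  psi <- exp(logL - shift) %*% w
  sum(log(psi) + shift)
}

# Multiplicative EM on the simplex; monotone non-decreasing in the objective.
em_weights <- function(logL, w0 = NULL, maxit = 1000L, tol = 1e-10) {
  N <- nrow(logL); J <- ncol(logL)
  shift <- apply(logL, 1, max)
  if (any(!is.finite(shift))) {
    bad <- which(!is.finite(shift))[1]
    stop("em_weights: subject ", bad, " has zero likelihood at every support point")
  }
  Lrel <- exp(logL - shift)
  w <- if (is.null(w0)) rep(1 / J, J) else w0 / sum(w0)
  obj <- sum(log(Lrel %*% w) + shift)
  for (it in seq_len(maxit)) {
    psi <- as.vector(Lrel %*% w)
    w <- w * colSums(Lrel / psi) / N
    w <- w / sum(w)
    obj_new <- sum(log(as.vector(Lrel %*% w)) + shift)
    if (obj_new - obj < tol) { obj <- max(obj, obj_new); break }
    obj <- obj_new
  }
  list(weights = w, objective = obj)
}

#' Optimal mixture weights for a fixed support (inner convex problem)
#'
#' Maximises `sum_i log sum_j w_j L_ij` over the probability simplex via the
#' multiplicative EM update `w_j <- w_j * mean_i(L_ij / sum_k w_k L_ik)`,
#' which is monotone non-decreasing in the objective.
#'
#' @param likelihood_matrix Subjects x support points matrix of non-negative
#'   per-subject likelihoods; every row must contain a positive entry.
#' @param maxit,tol Iteration cap and objective-change tolerance.
#' @return List with `weights` (on the simplex) and `objective`
#'   (the maximised log-likelihood).
#' @export
optimize_weights <- function(likelihood_matrix, maxit = 10000L, tol = 1e-10) {
  L <- as.matrix(likelihood_matrix)
  if (any(L < 0)) stop("optimize_weights: likelihoods must be non-negative")
  zero_rows <- which(apply(L, 1, max) <= 0)
  if (length(zero_rows)) {
    stop("optimize_weights: subject(s) ", paste(zero_rows, collapse = ", "),
         " have zero likelihood at every support point")
  }
  em_weights(log(L), maxit = maxit, tol = tol)
}

new_population_model <- function(support, weights, loglik, trace, config,
                                 n_subjects, n_obs, error, cycles, converged,
                                 delta = NA_real_) {
  structure(list(structure = config$structure, bounds = config$bounds,
                 support = support, weights = weights, loglik = loglik,
                 trace = trace, n_cycles = cycles, converged = converged,
                 n_subjects = n_subjects, n_obs = n_obs,
                 error_model = error, seed = config$seed, delta = delta,
                 config = config),
            class = "population_model")
}

# Merge support points closer than merge_tol in range-scaled coordinates.
merge_support <- function(support, weights, bounds, merge_tol) {
  sn <- colnames(support)
  scaled <- vapply(sn, function(nm) {
    b <- bounds[[nm]]
    (support[, nm] - b[1]) / (b[2] - b[1])
  }, numeric(nrow(support)))
  scaled <- matrix(scaled, nrow = nrow(support))
  key <- apply(round(scaled / merge_tol), 1, paste, collapse = ":")
  if (!anyDuplicated(key)) return(list(support = support, weights = weights))
  first <- !duplicated(key)
  w <- as.vector(tapply(weights, factor(key, levels = key[first]), sum))
  list(support = support[first, , drop = FALSE], weights = w)
}

#' Drop negligible support points and re-optimise
#'
#' Removes support points with weight below `eps` (never all of them),
#' merges near-duplicates, renormalises and re-runs the weight optimisation.
#' The log-likelihood can decrease by at most
#' `n_subjects * log(1 / (1 - removed mass))`.
#'
#' @param model A fitted [`population_model`][npml_fit()].
#' @param subjects The subjects the model was fitted to.
#' @param eps Weight floor; defaults to the model's configured floor.
#' @return The condensed `population_model`.
#' @export
condense <- function(model, subjects, eps = NULL) {
  if (is.null(eps)) eps <- resolve_weight_floor(model$config, length(subjects))
  cap <- model$config$max_support
  if (is.null(cap)) cap <- max(20L, 2L * length(subjects))
  keep <- model$weights >= eps
  keep[which.max(model$weights)] <- TRUE
  if (!any(keep)) stop("condense: all support points removed")
  if (sum(keep) > cap) {
    keep <- keep & rank(-model$weights, ties.method = "first") <= cap
  }
  support <- model$support[keep, , drop = FALSE]
  weights <- model$weights[keep] / sum(model$weights[keep])
  m <- merge_support(support, weights, model$bounds, model$config$merge_tol)
  logL <- log_lik_matrix(subjects, full_theta(m$support, model$bounds), model$error_model)
  opt <- em_weights(logL, w0 = m$weights, maxit = model$config$em_maxit,
                    tol = model$config$em_tol)
  new_population_model(m$support, opt$weights, opt$objective,
                       c(model$trace, opt$objective), model$config,
                       model$n_subjects, model$n_obs, model$error_model,
                       model$n_cycles, model$converged, model$delta)
}

expand_candidates <- function(support, bounds, delta) {
  sn <- colnames(support)
  cand <- list()
  for (nm in sn) {
    b <- bounds[[nm]]
    # a fine displacement accompanies the coarse one so support points can
    # settle within a step instead of crawling across halving generations
    for (step in delta * (b[2] - b[1]) * c(1, 0.1)) {
      for (sgn in c(-1, 1)) {
        shifted <- support
        shifted[, nm] <- pmin(pmax(support[, nm] + sgn * step, b[1]), b[2])
        cand[[length(cand) + 1]] <- shifted
      }
    }
  }
  do.call(rbind, cand)
}

#' Expand the support with displaced candidate points and re-optimise
#'
#' Every support point spawns candidates at `+/- delta * (high - low)` along
#' each searched dimension (clipped to the bounds); weights are re-optimised
#' over the union. The refit is safeguarded so the log-likelihood never
#' decreases: if the re-optimisation ends below the incoming optimum, the
#' incoming weights (padded with zeros) are kept.
#'
#' @param model A fitted [`population_model`][npml_fit()].
#' @param subjects The subjects the model was fitted to.
#' @param delta Displacement as a fraction of each parameter's range.
#' @return The expanded `population_model`.
#' @export
expand <- function(model, subjects, delta) {
  if (delta <= 0) return(model)
  cand <- expand_candidates(model$support, model$bounds, delta)
  combined <- rbind(model$support, cand)
  m <- merge_support(combined, c(model$weights, rep(0, nrow(cand))),
                     model$bounds, model$config$merge_tol)
  logL <- log_lik_matrix(subjects, full_theta(m$support, model$bounds), model$error_model)
  J <- nrow(m$support)
  w_start <- 0.8 * m$weights + 0.2 / J
  opt <- em_weights(logL, w0 = w_start, maxit = model$config$em_maxit,
                    tol = model$config$em_tol)
  if (opt$objective < model$loglik) {
    w_old <- m$weights / sum(m$weights)
    opt <- list(weights = w_old, objective = em_objective(logL, w_old))
  }
  new_population_model(m$support, opt$weights, opt$objective,
                       c(model$trace, opt$objective), model$config,
                       model$n_subjects, model$n_obs, model$error_model,
                       model$n_cycles, model$converged, delta)
}

resolve_weight_floor <- function(config, n_subjects) {
  if (!is.null(config$weight_floor)) config$weight_floor else 1e-8 * n_subjects
}

#' Nonparametric adaptive-grid population fit
#'
#' Starting from a seeded space-filling grid, cycles of weight optimisation,
#' support condensation and adaptive expansion refine a discrete population
#' distribution over the structural parameters. The expansion displacement is
#' halved whenever a cycle fails to improve the log-likelihood by `tol`, and
#' the fit terminates once the displacement falls below `delta_min` with no
#' remaining improvement. The log-likelihood trace is monotone non-decreasing
#' up to the (negligible) mass removed by condensation.
#'
#' @param subjects List of [subject_record()] objects (>= 1, each with >= 1
#'   usable observation).
#' @param error An [assay_error_model()].
#' @param config A [fit_config()].
#' @return A `population_model`: support matrix (searched parameters),
#'   weights, log-likelihood and its cycle trace, cycle count and
#'   convergence flag.
#' @export
npml_fit <- function(subjects, error = assay_error_model(),
                     config = fit_config()) {
  if (!length(subjects)) stop("npml_fit: at least one subject required")
  N <- length(subjects)
  st <- stack_observations(subjects)
  d <- length(searched_names(config$bounds))
  n_init <- if (!is.null(config$n_initial)) config$n_initial else 2^d * 50
  eps <- resolve_weight_floor(config, N)

  support <- init_grid(config$bounds, n_init, config$seed)
  logL <- log_lik_matrix(subjects, full_theta(support, config$bounds), error)
  opt <- em_weights(logL, maxit = config$em_maxit, tol = config$em_tol)
  model <- new_population_model(support, opt$weights, opt$objective,
                                opt$objective, config, N, sum(st$n_obs),
                                error, 0L, FALSE, config$delta0)

  delta <- config$delta0
  obj_prev <- model$loglik
  converged <- FALSE
  cycle <- 0L
  while (cycle < config$max_cycles) {
    cycle <- cycle + 1L
    model <- condense(model, subjects, eps)
    model <- expand(model, subjects, delta)
    improvement <- model$loglik - obj_prev
    obj_prev <- model$loglik
    if (improvement < config$tol) delta <- delta / 2
    if (delta < config$delta_min && improvement < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("npml_fit: maximum cycles (", config$max_cycles,
            ") reached without convergence; result flagged")
  }
  model$n_cycles <- cycle
  model$converged <- converged
  model$delta <- delta
  model
}

#' Population fit with the elimination rate profiled as a population constant
#'
#' Sparse single-arm sampling cannot separate a subject's absorption rate
#' from their elimination rate: the one-compartment solution is exactly
#' symmetric under exchanging `Ka` and `Ke` (with `V` rescaled), so a
#' six-dimensional nonparametric fit is free to "flip" individual subjects
#' and corrupt the absorption half-life. The study-level fit therefore
#' treats disposition as shared across subjects: `Ke` is a population
#' constant estimated by profile likelihood -- a nonparametric fit of
#' `(Ka, Tlag, V)` at each candidate `Ke` on a log-spaced grid, refined by
#' parabolic interpolation of the profile in `log(Ke)` -- with the
#' central-peripheral exchange fixed at a mild default. The profile is
#' sharply peaked (hundreds of nats between neighbouring grid points at
#' realistic noise), so a coarse grid plus two refinements locates the
#' shared `Ke` to a few percent.
#'
#' @param subjects List of [subject_record()] objects.
#' @param error An [assay_error_model()].
#' @param structure Model structure; `"one_compartment"` fixes the exchange
#'   rates at zero.
#' @param ke_grid Candidate elimination rates (1/h) for the coarse profile.
#' @param kcp,kpc Fixed exchange rates for the two-compartment structure.
#' @param seed Seed passed to each inner [npml_fit()].
#' @param refine_steps Number of parabolic refinement fits after the coarse
#'   profile.
#' @param profile_n_initial,profile_max_cycles Inner-fit budget during
#'   profiling (non-convergence there is tolerated and recorded).
#' @param final_n_initial,final_max_cycles Budget of the final fit at the
#'   selected `Ke`.
#' @param max_support Optional support cap forwarded to [fit_config()];
#'   useful to bound the cost of large-cohort fits.
#' @return List with `model` (the final `population_model`), `ke` (selected
#'   elimination rate) and `profile` (data frame of `ke`, `loglik`,
#'   `converged` for every fit tried).
#' @export
profile_ke_fit <- function(subjects, error = assay_error_model(),
                           structure = c("two_compartment", "one_compartment"),
                           ke_grid = exp(seq(log(0.04), log(0.6), length.out = 7)),
                           kcp = 0.1, kpc = 0.05, seed = 1L,
                           refine_steps = 2L,
                           profile_n_initial = 200L, profile_max_cycles = 50L,
                           final_n_initial = 400L, final_max_cycles = 150L,
                           max_support = NULL) {
  structure <- match.arg(structure)
  if (structure == "one_compartment") { kcp <- 0; kpc <- 0 }
  base <- default_bounds("two_compartment")
  make_config <- function(ke, n_initial, max_cycles) {
    fit_config(structure,
               bounds = list(Ka = base$Ka, Tlag = base$Tlag, V = base$V,
                             Ke = ke, Kcp = kcp, Kpc = kpc),
               n_initial = n_initial, max_cycles = max_cycles, seed = seed,
               max_support = max_support)
  }
  profile_fit <- function(ke) {
    m <- suppressWarnings(
      npml_fit(subjects, error, make_config(ke, profile_n_initial, profile_max_cycles)))
    data.frame(ke = ke, loglik = m$loglik, converged = m$converged)
  }
  prof <- do.call(rbind, lapply(ke_grid, profile_fit))
  for (r in seq_len(refine_steps)) {
    prof <- prof[order(prof$ke), , drop = FALSE]
    i <- which.max(prof$loglik)
    if (i == 1 || i == nrow(prof)) break
    x <- log(prof$ke[(i - 1):(i + 1)]); y <- prof$loglik[(i - 1):(i + 1)]
    denom <- (x[2] - x[1]) * (y[2] - y[3]) - (x[2] - x[3]) * (y[2] - y[1])
    if (abs(denom) < 1e-12) break
    xv <- x[2] - 0.5 * ((x[2] - x[1])^2 * (y[2] - y[3]) -
                        (x[2] - x[3])^2 * (y[2] - y[1])) / denom
    xv <- min(max(xv, x[1] + 1e-6), x[3] - 1e-6)
    ke_new <- exp(xv)
    if (min(abs(log(ke_new) - log(prof$ke))) < 1e-3) break
    prof <- rbind(prof, profile_fit(ke_new))
  }
  ke_best <- prof$ke[which.max(prof$loglik)]
  model <- npml_fit(subjects, error,
                    make_config(ke_best, final_n_initial, final_max_cycles))
  list(model = model, ke = ke_best, profile = prof[order(prof$ke), ])
}

#' Bayesian posterior individual estimate
#'
#' Updates the population weights with one subject's likelihood: posterior
#' weight of support point `j` is proportional to `w_j * L(subject | theta_j)`.
#' The posterior mean is the posterior-weighted average of each parameter.
#'
#' @param subject A [subject_record()].
#' @param model A fitted [`population_model`][npml_fit()].
#' @param error Assay error model; defaults to the model's.
#' @return A `posterior_estimate`: `subject_id`, `posterior_weights`,
#'   `posterior_mean` ([pk_parameters()]) and the support used.
#' @export
posterior_individual <- function(subject, model, error = NULL) {
  if (is.null(error)) error <- model$error_model
  theta <- full_theta(model$support, model$bounds)
  ll <- log_lik_matrix(list(subject), theta, error)[1, ]
  lp <- ll + log(model$weights)
  if (all(!is.finite(lp))) {
    stop("posterior_individual: zero posterior mass for subject '", subject$id, "'")
  }
  lp <- lp - max(lp)
  w <- exp(lp)
  w <- w / sum(w)
  pm <- colSums(theta * w)
  structure(list(subject_id = subject$id,
                 posterior_weights = w,
                 posterior_mean = pk_parameters(pm[["Ka"]], pm[["Tlag"]], pm[["V"]],
                                                pm[["Ke"]], pm[["Kcp"]], pm[["Kpc"]]),
                 support = theta,
                 structure = model$structure),
            class = "posterior_estimate")
}

#' Information criteria of a fitted population model
#'
#' `AIC = -2 loglik + 2 p` and `BIC = -2 loglik + p log(n_obs)` with
#' `p = n_support * (d + 1) - 1`: each support point carries `d` searched
#' coordinates plus a weight, and the weights lose one degree of freedom to
#' the simplex constraint. The parameter count of a nonparametric mixture is
#' a convention; only comparisons between candidate structures are meaningful.
#'
#' @param model A fitted [`population_model`][npml_fit()].
#' @param n_obs Total observation count; defaults to the count stored in the
#'   model.
#' @return Named list with `AIC`, `BIC`, `p`, `n_obs`.
#' @export
information_criteria <- function(model, n_obs = NULL) {
  if (is.null(n_obs)) n_obs <- model$n_obs
  d <- ncol(model$support)
  p <- nrow(model$support) * (d + 1) - 1
  list(AIC = -2 * model$loglik + 2 * p,
       BIC = -2 * model$loglik + p * log(n_obs),
       p = p, n_obs = n_obs)
}

#' Serialise a fitted population model to JSON
#'
#' Numbers are written at full IEEE precision so that
#' [read_population_model()] round-trips bit-exactly.
#'
#' @param model A fitted [`population_model`][npml_fit()].
#' @param path Output JSON path.
#' @export
write_population_model <- function(model, path) {
  payload <- list(
    structure = model$structure,
    bounds = model$bounds,
    parameters = colnames(model$support),
    support = apply(model$support, 1, as.list),
    weights = model$weights,
    loglik = model$loglik,
    trace = model$trace,
    n_cycles = model$n_cycles,
    converged = model$converged,
    n_subjects = model$n_subjects,
    n_obs = model$n_obs,
    error_model = list(c0 = model$error_model$c0, c1 = model$error_model$c1),
    seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Reload a population model written by [write_population_model()]
#'
#' @param path JSON path.
#' @return A `population_model` (without the original fit configuration).
#' @export
read_population_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sn <- x$parameters
  support <- as.matrix(x$support[, sn, drop = FALSE])
  colnames(support) <- sn
  bounds <- lapply(x$bounds, as.numeric)
  config <- fit_config(structure = x$structure, bounds = bounds, seed = x$seed)
  model <- new_population_model(support, as.numeric(x$weights), x$loglik,
                                as.numeric(x$trace), config,
                                x$n_subjects, x$n_obs,
                                assay_error_model(x$error_model$c0, x$error_model$c1),
                                x$n_cycles, x$converged)
  model
}
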