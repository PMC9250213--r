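# Fixtures are built in code at test time; no stored data.

ref_params <- function(ka = 0.2, tlag = 0.5, v = 250, ke = 0.15,
                       kcp = 0.1, kpc = 0.05) {
  pk_parameters(ka, tlag, v, ke, kcp, kpc)
}

# One subject with observations read off (optionally noised) model curves.
make_subject <- function(params, dose_umol = 500,
                         times = c(1, 2, 4, 6, 8, 12, 24, 48),
                         error = NULL, id = "S1", group = "REF",
                         structure = "two_compartment") {
  dose <- dose_event(dose_umol)
  conc <- solve_profile(params, dose, times, structure)
  if (!is.null(error)) {
    conc <- pmax(conc + stats::rnorm(length(conc), 0, error$c0 + error$c1 * conc), 0)
  }
  subject_record(id, group, dose,
                 data.frame(time_h = times, conc_uM = conc,
                            matrix = "plasma", below_loq = FALSE))
}

# Single-group cohort drawn from the default study configuration's group
# profile, with every subject in one dose arm.
single_group_cohort <- function(n, seed, group = "REF", dose_mmol = 0.5,
                                noise = NULL) {
  cfg0 <- default_study_config(seed = seed)
  g <- cfg0$groups[[group]]
  alloc <- c("0.1" = 0L, "0.25" = 0L, "0.5" = 0L)
  alloc[as.character(dose_mmol)] <- as.integer(n)
  g$dose_allocation <- alloc
  g$n_subjects <- as.integer(n)
  groups <- list(g); names(groups) <- group
  cfg <- cohort_config(groups = groups, seed = seed)
  if (!is.null(noise)) cfg$noise <- noise
  simulate_cohort(cfg)
}

# Independent numerical oracle: adaptive-step ODE integration of the
# depot/central/peripheral system.
ode_profile <- function(params, dose, times) {
  ka <- params[["Ka"]]; ke <- params[["Ke"]]
  kcp <- params[["Kcp"]]; kpc <- params[["Kpc"]]
  rhs <- function(t, y, p) {
    list(c(-ka * y[1],
           ka * y[1] - (ke + kcp) * y[2] + kpc * y[3],
           kcp * y[2] - kpc * y[3]))
  }
  ts <- pmax(times - params[["Tlag"]], 0)
  grid <- sort(unique(c(0, ts)))
  out <- deSolve::ode(c(dose$amount, 0, 0), grid, rhs, NULL,
                      rtol = 1e-11, atol = 1e-13)
  ac <- out[match(ts, out[, 1]), 3]
  ifelse(times <= params[["Tlag"]], 0, ac / params[["V"]])
}

# Draw a random valid parameter vector inside the given box.
random_params <- function() {
  pk_parameters(stats::runif(1, 0.02, 1.5), stats::runif(1, 0, 2),
                stats::runif(1, 20, 500), stats::runif(1, 0.05, 1),
                stats::runif(1, 0, 1), stats::runif(1, 0.01, 1))
}

# Lognormal sampler on the (mean, cv) scale used by the generator.
rln_mcv <- function(n, mean, cv) {
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - s^2 / 2, s)
}
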