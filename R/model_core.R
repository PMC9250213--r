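# Structural kinetic models for an intrathecally administered tracer:
# a CSF depot drains by first-order transfer (rate Ka, after a lag Tlag)
# into a central blood compartment (volume V, first-order elimination Ke),
# optionally exchanging with a peripheral tissue compartment (Kcp, Kpc).
# All solutions are closed-form (partial fractions of the 3-state linear
# system), so there is no step-size-dependent error.
#
# Units are fixed so that no conversion constants appear anywhere:
# dose in umol, volume in L, concentration in uM (= umol/L), time in h.

PK_PARAM_NAMES <- c("Ka", "Tlag", "V", "Ke", "Kcp", "Kpc")

#' Structural pharmacokinetic parameter vector
#'
#' @param ka Absorption rate constant CSF -> blood (1/h), > 0.
#' @param tlag Absorption lag time (h), >= 0.
#' @param v Central (blood) volume of distribution (L), > 0.
#' @param ke First-order elimination rate from the central compartment (1/h), > 0.
#' @param kcp,kpc Central <-> peripheral transfer rates (1/h), >= 0. Both zero
#'   for a one-compartment structure.
#' @return A named `pk_parameters` vector `(Ka, Tlag, V, Ke, Kcp, Kpc)`.
#' @export
pk_parameters <- function(ka, tlag, v, ke, kcp = 0, kpc = 0) {
  p <- c(Ka = ka, Tlag = tlag, V = v, Ke = ke, Kcp = kcp, Kpc = kpc)
  validate_pk_parameters(p)
  structure(p, class = "pk_parameters")
}

validate_pk_parameters <- function(p) {
  if (!all(is.finite(p))) {
    stop("pk_parameters: all parameters must be finite, got (",
         paste(signif(unname(p), 4), collapse = ", "), ")")
  }
  if (p[["Ka"]] <= 0 || p[["Ke"]] <= 0 || p[["V"]] <= 0) {
    stop("pk_parameters: Ka, Ke and V must be strictly positive")
  }
  if (p[["Tlag"]] < 0 || p[["Kcp"]] < 0 || p[["Kpc"]] < 0) {
    stop("pk_parameters: Tlag, Kcp and Kpc must be non-negative")
  }
  invisible(p)
}

#' Dose event for an intrathecal depot administration
#'
#' @param amount Tracer amount in umol (dose in mmol times 1000). Zero is
#'   permitted for degenerate inputs.
#' @param time Administration time in hours (0 at injection).
#' @param route Administration route; only `"depot"` (intrathecal) is modelled.
#' @return A `dose_event` list.
#' @export
dose_event <- function(amount, time = 0, route = "depot") {
  stopifnot(is.finite(amount), amount >= 0, is.finite(time), time >= 0)
  route <- match.arg(route, "depot")
  structure(list(amount = amount, time = time, route = route),
            class = "dose_event")
}

#' Assay error model
#'
#' Residual-error polynomial in the style of nonparametric pharmacometrics tools:
#' the observation standard
#' deviation at predicted concentration C is `SD(C) = c0 + c1 * C`, with an
#' additive floor `c0` sitting just above the assay detection threshold and a
#' proportional component `c1`.
#'
#' @param c0 Additive SD floor in uM (> 0).
#' @param c1 Proportional SD coefficient (>= 0), dimensionless.
#' @return An `assay_error_model` list.
#' @export
assay_error_model <- function(c0 = 0.002, c1 = 0.05) {
  stopifnot(is.finite(c0), c0 > 0, is.finite(c1), c1 >= 0)
  structure(list(c0 = c0, c1 = c1), class = "assay_error_model")
}

#' One subject's dose event, observation series and metadata
#'
#' @param id Subject identifier (character).
#' @param group Diagnosis group label, one of REF, PC, AC, SIH, IIH, iNPH,
#'   CommHC, NonCommHC.
#' @param dose A [dose_event()].
#' @param observations Data frame with columns `time_h`, `conc_uM`, `matrix`
#'   (`"plasma"` or `"whole_blood"`) and logical `below_loq`; sorted by time.
#' @param covariates Optional named list (age, sex, height, weight, bmi, gfr).
#' @return A `subject_record` list.
#' @export
subject_record <- function(id, group, dose, observations, covariates = list()) {
  stopifnot(inherits(dose, "dose_event"), is.data.frame(observations))
  req <- c("time_h", "conc_uM", "matrix", "below_loq")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols)) {
    stop("subject_record: observations missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(observations) < 1) stop("subject_record: at least one observation required")
  if (any(observations$time_h < 0)) stop("subject_record: observation times must be >= 0")
  if (any(observations$conc_uM < 0)) stop("subject_record: concentrations must be >= 0")
  if (!all(observations$matrix %in% c("plasma", "whole_blood"))) {
    stop("subject_record: matrix must be 'plasma' or 'whole_blood'")
  }
  observations <- observations[order(observations$time_h), , drop = FALSE]
  rownames(observations) <- NULL
  structure(list(id = as.character(id), group = as.character(group),
                 dose = dose, observations = observations,
                 covariates = covariates),
            class = "subject_record")
}

# Disposition eigenvalues (alpha >= beta) of the central/peripheral pair.
disposition_rates <- function(ke, kcp, kpc) {
  s <- ke + kcp + kpc
  disc <- s^2 - 4 * ke * kpc
  disc <- max(disc, 0)
  alpha <- (s + sqrt(disc)) / 2
  beta <- (s - sqrt(disc)) / 2
  c(alpha = alpha, beta = beta)
}

# Nudge rate constants off (near-)confluent poles so the distinct-pole
# partial-fraction form stays valid. A minimum relative pole separation of
# 1e-8 is enforced (growing the nudge geometrically where the separation
# responds quadratically, e.g. Kcp = 0 with Kpc = Ke); the induced profile
# error is ~1e-6 relative at worst -- orders of magnitude below assay noise.
deconflict_rates <- function(ka, ke, kcp, kpc) {
  sep <- 1e-8
  ab <- disposition_rates(ke, kcp, kpc)
  pert <- 1e-9
  for (i in 1:40) {
    if (abs(ab[1] - ab[2]) >= sep * max(ab[1], 1e-300)) break
    kpc <- kpc * (1 + pert) + 1e-12
    pert <- pert * 4
    ab <- disposition_rates(ke, kcp, kpc)
  }
  for (r in ab) {
    if (abs(ka - r) < sep * max(ka, r)) ka <- ka * (1 + 2 * sep)
  }
  list(ka = ka, ke = ke, kcp = kcp, kpc = kpc,
       alpha = ab[["alpha"]], beta = ab[["beta"]])
}

#' Compartment amounts over time (closed form)
#'
#' Solves the depot/central/peripheral linear system
#' `dAd/dt = -Ka Ad`, `dAc/dt = Ka Ad - (Ke + Kcp) Ac + Kpc Ap`,
#' `dAp/dt = Kcp Ac - Kpc Ap` for a depot dose administered at `Tlag`
#' effective delay, by partial fractions over the three (deconflicted) poles.
#'
#' @param params A [pk_parameters()] vector.
#' @param dose A [dose_event()].
#' @param times Non-negative, sorted times (h).
#' @return Data frame with columns `time_h`, `depot`, `central`, `peripheral`
#'   (amounts in umol).
#' @export
solve_amounts <- function(params, dose, times) {
  validate_pk_parameters(params)
  stopifnot(inherits(dose, "dose_event"))
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("solve_amounts: times must be finite and non-negative")
  }
  if (is.unsorted(times)) stop("solve_amounts: times must be sorted")
  D <- dose$amount
  tl <- params[["Tlag"]] + dose$time
  ts <- pmax(times - tl, 0)
  k <- deconflict_rates(params[["Ka"]], params[["Ke"]], params[["Kcp"]], params[["Kpc"]])
  a <- k$alpha; b <- k$beta; ka <- k$ka; kpc <- k$kpc; kcp <- k$kcp
  ead <- exp(-ka * ts); ea <- exp(-a * ts); eb <- exp(-b * ts)
  depot <- D * ead
  central <- ka * D * ((kpc - a) * ea / ((ka - a) * (b - a)) +
                       (kpc - b) * eb / ((ka - b) * (a - b)) +
                       (kpc - ka) * ead / ((a - ka) * (b - ka)))
  peripheral <- ka * kcp * D * (ea / ((ka - a) * (b - a)) +
                                eb / ((ka - b) * (a - b)) +
                                ead / ((a - ka) * (b - ka)))
  pre <- times <= tl
  central[pre] <- 0
  peripheral[pre] <- 0
  depot[pre] <- D
  data.frame(time_h = times, depot = depot,
             central = pmax(central, 0), peripheral = pmax(peripheral, 0))
}

#' Predicted concentration profile (closed form)
#'
#' Central-compartment concentration `C(t) = Ac(t) / V` for a depot dose with
#' absorption lag. `C(t) = 0` for `t <= Tlag`; the solution is exact (no ODE
#' integration error) and linear in dose.
#'
#' @inheritParams solve_amounts
#' @param structure `"one_compartment"` (requires `Kcp = Kpc = 0`) or
#'   `"two_compartment"`.
#' @return Numeric vector of concentrations (uM), one per time.
#' @export
solve_profile <- function(params, dose, times,
                          structure = c("two_compartment", "one_compartment")) {
  structure <- match.arg(structure)
  if (structure == "one_compartment" &&
      (params[["Kcp"]] != 0 || params[["Kpc"]] != 0)) {
    stop("solve_profile: one-compartment structure requires Kcp = Kpc = 0")
  }
  amounts <- solve_amounts(params, dose, times)
  amounts$central / params[["V"]]
}

# Vectorised concentration evaluation for one parameter set over stacked
# (time, dose amount) pairs -- the inner loop of the population likelihood.
profile_stacked <- function(params, times, amounts) {
  tl <- params[["Tlag"]]
  ts <- times - tl
  act <- ts > 0
  out <- numeric(length(times))
  if (!any(act)) return(out)
  k <- deconflict_rates(params[["Ka"]], params[["Ke"]], params[["Kcp"]], params[["Kpc"]])
  a <- k$alpha; b <- k$beta; ka <- k$ka; kpc <- k$kpc
  tsa <- ts[act]
  ac <- ka * ((kpc - a) * exp(-a * tsa) / ((ka - a) * (b - a)) +
              (kpc - b) * exp(-b * tsa) / ((ka - b) * (a - b)) +
              (kpc - ka) * exp(-ka * tsa) / ((a - ka) * (b - ka)))
  out[act] <- pmax(ac, 0) * amounts[act] / params[["V"]]
  out
}

# Observations entering the likelihood: plasma-equivalent, above the
# quantification limit (below_loq excluded under the default BLQ policy).
usable_observations <- function(subject) {
  obs <- subject$observations
  obs[!obs$below_loq, , drop = FALSE]
}

#' Subject log-likelihood under the assay error model
#'
#' Gaussian observation model: each observed concentration is the model
#' prediction plus noise with `SD = c0 + c1 * C_pred`. Observations flagged
#' below the limit of quantification are excluded (default BLQ policy).
#' Observations must already be plasma-equivalent (see [convert_matrix()]).
#'
#' @param subject A [subject_record()].
#' @param params A [pk_parameters()] vector.
#' @param error An [assay_error_model()].
#' @param structure Model structure passed to [solve_profile()].
#' @return Log-likelihood in nats.
#' @export
subject_loglik <- function(subject, params, error,
                           structure = c("two_compartment", "one_compartment")) {
  structure <- match.arg(structure)
  obs <- usable_observations(subject)
  if (nrow(obs) == 0) {
    stop("subject_loglik: subject '", subject$id, "' has no usable observations")
  }
  pred <- solve_profile(params, subject$dose, obs$time_h, structure)
  sd <- error$c0 + error$c1 * pred
  sum(stats::dnorm(obs$conc_uM, mean = pred, sd = sd, log = TRUE))
}

#' Read a long-format concentration table
#'
#' Expects the standard header `subject_id, group, dose_mmol, time_h, conc_uM,
#' matrix, below_loq` with decimal hours from injection.
#'
#' @param path CSV file path.
#' @return List of [subject_record()] objects.
#' @export
read_conc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  conc_df_to_subjects(df)
}

#' Convert a long-format concentration data frame to subject records
#'
#' @param df Data frame with the standard long-format columns.
#' @return List of [subject_record()] objects.
#' @export
conc_df_to_subjects <- function(df) {
  req <- c("subject_id", "group", "dose_mmol", "time_h", "conc_uM", "matrix", "below_loq")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("conc_df_to_subjects: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  ids <- unique(df$subject_id)
  lapply(ids, function(sid) {
    sub <- df[df$subject_id == sid, , drop = FALSE]
    dm <- unique(sub$dose_mmol)
    if (length(dm) != 1) stop("conc_df_to_subjects: subject '", sid, "' has multiple doses")
    subject_record(
      id = sid, group = sub$group[1],
      dose = dose_event(amount = dm * 1000),
      observations = data.frame(time_h = sub$time_h, conc_uM = sub$conc_uM,
                                matrix = sub$matrix,
                                below_loq = as.logical(sub$below_loq)))
  })
}

#' Flatten subject records to the standard long-format data frame
#'
#' @param subjects List of [subject_record()] objects.
#' @return Data frame with the standard long-format columns.
#' @export
subjects_to_conc_df <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$id, group = s$group,
               dose_mmol = s$dose$amount / 1000,
               time_h = s$observations$time_h,
               conc_uM = s$observations$conc_uM,
               matrix = s$observations$matrix,
               below_loq = s$observations$below_loq)
  }))
}

#' Write subjects as a long-format concentration CSV
#'
#' @param subjects List of [subject_record()] objects.
#' @param path Output CSV path.
#' @export
write_conc_csv <- function(subjects, path) {
  utils::write.csv(subjects_to_conc_df(subjects), path, row.names = FALSE)
  invisible(path)
}
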