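.continuous_covariates <- c("age", "weight", "height", "eGFR", "pregnancy_week")

# resolve a covariate name against a patient (and the spec's formulation);
# comedication / formulation tags resolve to 0/1 flags
.resolve_covariate <- function(name, patient, spec) {
  if (name %in% .continuous_covariates) {
    v <- patient[[name]]
    if (is.null(v))
      stop(sprintf("covariate relation references '%s' but the patient does not provide it",
                   name), call. = FALSE)
    if (name != "pregnancy_week" && v <= 0)
      stop(sprintf("covariate '%s' outside its domain (must be > 0, got %g)", name, v),
           call. = FALSE)
    return(v)
  }
  if (name %in% .formulations) return(as.numeric(identical(spec$formulation, name)))
  # anything else is a comedication tag
  as.numeric(name %in% patient$comedications)
}

.relation_multiplier <- function(cr, patient, spec) {
  x <- .resolve_covariate(cr$covariate, patient, spec)
  m <- switch(cr$form,
    power        = (x / cr$ref_value)^cr$theta,
    proportional = 1 + cr$theta * x,
    linear       = 1 + cr$theta * (x - cr$ref_value),
    exponential  = exp(cr$theta * (x - cr$ref_value)))
  if (!is.finite(m) || m <= 0)
    stop(sprintf("covariate relation (%s on %s) yields non-positive multiplier %g",
                 cr$covariate, cr$target_param, m), call. = FALSE)
  m
}

#' Covariate-adjusted typical parameters for one patient
#'
#' Applies every covariate relation in spec order, each contributing a
#' multiplicative factor to its target parameter. `F_rel` defaults to 1 and
#' `tlag` to 0 when absent from the spec.
#'
#' @param spec A `poppk_spec`.
#' @param patient A `patient`.
#' @return Named list of adjusted typical parameter values (all > 0).
#' @export
apply_covariates <- function(spec, patient) {
  spec <- validate_model_spec(spec)
  tv <- spec$typical_params
  if (is.null(tv$F_rel)) tv$F_rel <- 1
  if (is.null(tv$tlag)) tv$tlag <- 0
  for (cr in spec$covariates)
    tv[[cr$target_param]] <- tv[[cr$target_param]] * .relation_multiplier(cr, patient, spec)
  tv
}

#' Sample virtual individuals from the population model
#'
#' Parameters are lognormally distributed around the covariate-adjusted
#' typical values: `P_i = TV * exp(eta_i)` with `eta ~ N(0, Omega)`, Omega
#' built from the spec's omega standard deviations and optional correlation
#' matrix. Parameters with omega 0 (or absent from omega) are identical to
#' the typical value in every individual. Fully reproducible for a fixed
#' seed.
#'
#' @param spec A `poppk_spec`.
#' @param patient A `patient`.
#' @param n Number of virtual individuals (>= 1).
#' @param seed Integer seed.
#' @return A data.frame with one row per individual and one column per
#'   parameter; attributes `eta` (matrix of random effects) and `seed`.
#' @export
sample_individuals <- function(spec, patient, n, seed = 1L) {
  stopifnot(n >= 1)
  tv <- apply_covariates(spec, patient)
  set.seed(as.integer(seed))
  eta <- .draw_etas(spec, n)
  out <- as.data.frame(lapply(names(tv), function(p) {
    if (p %in% colnames(eta)) tv[[p]] * exp(eta[, p]) else rep(tv[[p]], n)
  }))
  names(out) <- names(tv)
  attr(out, "eta") <- eta
  attr(out, "seed") <- as.integer(seed)
  out
}

# draw n x k matrix of etas using the current RNG state
.draw_etas <- function(spec, n) {
  om <- spec$omega
  pos <- names(om)[om > 0]
  eta <- matrix(0, n, length(om), dimnames = list(NULL, names(om)))
  if (length(pos)) {
    R <- if (is.null(spec$omega_corr)) diag(length(pos))
         else spec$omega_corr[pos, pos, drop = FALSE]
    Sigma <- diag(om[pos], length(pos)) %*% R %*% diag(om[pos], length(pos))
    L <- chol(Sigma + diag(1e-12, length(pos)))
    Z <- matrix(rnorm(n * length(pos)), n, length(pos))
    eta[, pos] <- Z %*% L
  }
  eta
}

# contribution of a single dose to concentration; p is a list of equal-length
# (or scalar) parameter vectors, dt time since dose (may contain <= 0)
.dose_contrib <- function(p, structure, dt, amount) {
  Frel <- p$F_rel %||% 1
  act <- dt > 0
  out <- numeric(length(dt))
  if (amount <= 0 || !any(act)) return(out)
  d <- pmax(dt, 0)
  if (structure == "one_cpt_bolus") {
    k <- p$CL_F / p$V_F
    gen <- Frel * amount / p$V_F * exp(-k * d)
  } else if (structure == "one_cpt_oral") {
    k <- p$CL_F / p$V_F
    Ka <- p$Ka
    gen <- Frel * amount * Ka / (p$V_F * (Ka - k)) * (exp(-k * d) - exp(-Ka * d))
    near <- which(abs(Ka - k) / k < 1e-8)
    if (length(near)) {
      kv <- rep_len(k, length(d)); Vv <- rep_len(p$V_F, length(d))
      gen[near] <- (Frel * amount * kv * d * exp(-kv * d) / Vv)[near]
    }
  } else if (structure == "two_cpt_oral") {
    k10 <- p$CL_F / p$V_F
    k12 <- p$Q_F / p$V_F
    k21 <- p$Q_F / p$Vp_F
    S <- k10 + k12 + k21
    disc <- sqrt(pmax(S^2 - 4 * k10 * k21, 0))
    alpha <- (S + disc) / 2
    beta <- (S - disc) / 2
    Ka <- p$Ka
    Ka <- Ka * (1 + 1e-6 * (abs(Ka - alpha) / alpha < 1e-8))
    Ka <- Ka * (1 + 1e-6 * (abs(Ka - beta) / beta < 1e-8))
    A <- (k21 - alpha) / ((Ka - alpha) * (beta - alpha))
    B <- (k21 - beta) / ((Ka - beta) * (alpha - beta))
    C <- (k21 - Ka) / ((alpha - Ka) * (beta - Ka))
    gen <- Frel * amount * Ka / p$V_F *
      (A * exp(-alpha * d) + B * exp(-beta * d) + C * exp(-Ka * d))
  } else {
    stop(sprintf("unknown structure '%s'", structure), call. = FALSE)
  }
  gen <- rep_len(gen, length(d))
  gen[!act] <- 0
  gen
}

#' Concentration under an arbitrary dose history (closed form)
#'
#' Linear-PK superposition: the concentration is the sum over dose events of
#' the single-dose closed-form solution (one-compartment first-order
#' absorption Bateman term, one-compartment bolus monoexponential, or
#' two-compartment tri-exponential with absorption). Doses with amount 0
#' (missed doses) contribute nothing; times before any dose give 0.
#'
#' @param ind Named list (or one-row data.frame) of individual parameters
#'   (`CL_F`, `V_F`, `Ka`, ... as required by `structure`).
#' @param doses data.frame with columns `time` (h) and `amount` (mg),
#'   sorted by time.
#' @param t Numeric vector of times (h).
#' @param structure Structural model name.
#' @return Numeric vector of concentrations (mg/L), same length as `t`.
#' @export
concentration <- function(ind, doses, t, structure) {
  p <- as.list(ind)
  tlag <- p$tlag %||% 0
  out <- numeric(length(t))
  for (i in seq_len(nrow(doses))) {
    if (doses$amount[i] <= 0) next
    out <- out + .dose_contrib(p, structure, t - doses$time[i] - tlag,
                               doses$amount[i])
  }
  pmax(out, 0)
}

# cohort path: parameters are N-vectors, single sampling time t; returns an
# N-vector. Used by the conditional simulator.
.cohort_conc <- function(pars, doses, t, structure) {
  p <- as.list(pars)
  tlag <- p$tlag %||% 0
  n <- length(p$CL_F)
  out <- numeric(n)
  for (i in seq_len(nrow(doses))) {
    if (doses$amount[i] <= 0) next
    dt <- t - doses$time[i] - tlag
    if (all(dt <= 0)) next
    out <- out + .dose_contrib(p, structure, rep(dt, length.out = n),
                               doses$amount[i])
  }
  pmax(out, 0)
}

# terminal disposition rate constant (slope of the log-linear tail)
.terminal_rate <- function(spec, tv) {
  k <- tv$CL_F / tv$V_F
  if (spec$structure == "two_cpt_oral") {
    k12 <- tv$Q_F / tv$V_F
    k21 <- tv$Q_F / tv$Vp_F
    S <- k + k12 + k21
    k <- (S - sqrt(S^2 - 4 * k * k21)) / 2
  }
  if (spec$structure %in% c("one_cpt_oral", "two_cpt_oral")) k <- min(k, tv$Ka)
  k
}

#' Steady-state dosing history with editable terminal slots
#'
#' Builds an explicit run-in dose train long enough that consecutive
#' pre-dose troughs differ by less than 1e-4 relative (length derived from
#' the terminal half-life, at least `ceil(10 * t_half / interval) + 1`
#' doses), followed by `n_considered` terminal dose slots that scenario
#' bitstrings may edit. The sampling time is one interval after the last
#' slot, i.e. immediately before the next scheduled dose (trough).
#'
#' @param spec A `poppk_spec`.
#' @param patient A `patient` (covariates set the typical half-life).
#' @param dose Dose amount, mg (> 0).
#' @param interval Dosing interval tau, h (> 0).
#' @param n_considered Number of terminal dose slots under scrutiny.
#' @return data.frame of dose events (`time`, `amount`) of class
#'   `dose_history`, with attributes `slots` (row indices of the editable
#'   terminal slots, oldest first), `interval`, `sampling_time` and
#'   `n_considered`.
#' @export
steady_state_history <- function(spec, patient, dose, interval,
                                 n_considered = 1L) {
  if (dose <= 0) stop("dose must be > 0", call. = FALSE)
  if (interval <= 0) stop("interval must be > 0", call. = FALSE)
  tv <- apply_covariates(spec, patient)
  lam <- .terminal_rate(spec, tv)
  t_half <- log(2) / lam
  n1 <- ceiling(10 * t_half / interval) + 1
  # smallest N with exp(-N*lam*tau) * (1 - exp(-lam*tau)) < 1e-4
  n2 <- ceiling(log((1 - exp(-lam * interval)) / 1e-4) / (lam * interval))
  n_runin <- max(n1, n2, 1)
  n_total <- n_runin + n_considered
  hist <- data.frame(time = (seq_len(n_total) - 1) * interval,
                     amount = rep(dose, n_total))
  structure(hist,
            class = c("dose_history", "data.frame"),
            slots = (n_runin + 1):n_total,
            interval = interval,
            sampling_time = n_total * interval,
            n_considered = as.integer(n_considered))
}
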