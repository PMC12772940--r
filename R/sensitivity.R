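#' Base configuration for sweeps and tables
#'
#' Bundles everything [adherence_analysis()] needs so sensitivity sweeps can
#' re-run the pipeline per factor level under one root seed (common random
#' numbers across levels: factor effects are isolated from Monte Carlo
#' noise).
#'
#' @inheritParams adherence_analysis
#' @return List of class `run_config`.
#' @export
run_config <- function(spec, patient, dose, interval, n = 2L,
                       prior_mode = "equal", p = NULL, priors = NULL,
                       settings = sim_settings(), n_grid = 512L,
                       cutoff = 0.8) {
  structure(list(spec = validate_model_spec(spec), patient = patient,
                 dose = dose, interval = interval, n = as.integer(n),
                 prior_mode = prior_mode, p = p, priors = priors,
                 settings = settings, n_grid = as.integer(n_grid),
                 cutoff = cutoff),
            class = "run_config")
}

.run_from_config <- function(cf) {
  adherence_analysis(cf$spec, cf$patient, cf$dose, cf$interval, n = cf$n,
                     prior_mode = cf$prior_mode, p = cf$p, priors = cf$priors,
                     settings = cf$settings, n_grid = cf$n_grid,
                     cutoff = cf$cutoff)
}

.sweep_factors <- c("eGFR", "comedication", "interval", "sampling_offset",
                    "prior_p", "ruv_prop")

.spec_has_covariate <- function(spec, name) {
  any(vapply(spec$covariates, function(cr) identical(cr$covariate, name),
             logical(1)))
}

# apply one factor level to a config
.config_at_level <- function(cf, factor, level) {
  switch(factor,
    eGFR = { cf$patient$eGFR <- as.numeric(level); cf },
    comedication = {
      cf$patient$comedications <- if (identical(level, "none")) character()
                                  else as.character(level)
      cf
    },
    interval = {
      # constant daily dose: dose scales with the interval (q12h 300 mg
      # <-> q24h 600 mg), emulating an extended-release formulation switch
      cf$dose <- cf$dose * as.numeric(level) / cf$interval
      cf$interval <- as.numeric(level)
      cf
    },
    sampling_offset = { cf$settings$sampling_offset <- as.numeric(level); cf },
    prior_p = { cf$prior_mode <- "per_dose"; cf$p <- as.numeric(level); cf },
    ruv_prop = { cf$settings$ruv_prop <- as.numeric(level); cf })
}

.default_ref_level <- function(cf, factor, levels) {
  cand <- switch(factor,
    eGFR = cf$patient$eGFR,
    comedication = "none",
    interval = cf$interval,
    sampling_offset = cf$settings$sampling_offset,
    prior_p = 0.5,
    ruv_prop = cf$settings$ruv_prop)
  if (cand %in% levels) cand else levels[[1]]
}

#' Sweep one critical factor and report threshold shifts
#'
#' Re-runs the full pipeline at every factor level with the same root seed
#' and reports, per level, the discrimination thresholds, the retrodiction
#' label, and the relative change of the lowest crossing (the boundary of
#' the fully-nonadherent region) versus the reference level, computed as
#' `(T_level - T_ref) / T_ref * 100`.
#'
#' Supported factors: `eGFR` (renal function; requires an eGFR covariate
#' relation in the spec), `comedication` (tags; `"none"` clears them;
#' requires a matching relation), `interval` (dosing interval at constant
#' daily dose), `sampling_offset` (h, negative = earlier), `prior_p`
#' (per-dose adherence prior), `ruv_prop` (proportional residual error).
#'
#' @param factor Factor name (see above).
#' @param levels Vector of factor levels.
#' @param config A [run_config()].
#' @param ref_level Reference level; defaults to the config's current value
#'   when present among `levels`, else the first level.
#' @return Object of class `sweep_result`: `summary` data.frame (`level`,
#'   `threshold`, `rel_change_pct`, `label`), plus per-level `thresholds`
#'   and `retrodiction` lists.
#' @export
sweep_factor <- function(factor, levels, config, ref_level = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!factor %in% .sweep_factors)
    stop(sprintf("unsupported factor '%s' (supported: %s)", factor,
                 paste(.sweep_factors, collapse = ", ")), call. = FALSE)
  if (factor == "eGFR" && !.spec_has_covariate(config$spec, "eGFR"))
    stop("spec has no covariate relation on 'eGFR'; cannot sweep renal function",
         call. = FALSE)
  if (factor == "comedication") {
    tags <- setdiff(unlist(levels), "none")
    miss <- tags[!vapply(tags, .spec_has_covariate, logical(1),
                         spec = config$spec)]
    if (length(miss))
      stop(sprintf("spec has no covariate relation for comedication tag(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (is.null(ref_level)) ref_level <- .default_ref_level(config, factor, levels)
  if (!ref_level %in% levels)
    stop("ref_level must be one of the swept levels", call. = FALSE)

  runs <- lapply(levels, function(lv) .run_from_config(
    .config_at_level(config, factor, lv)))
  low_threshold <- vapply(runs, function(an) {
    th <- an$thresholds$thresholds
    if (nrow(th)) min(th$crossing) else NA_real_
  }, numeric(1))
  labels <- vapply(runs, function(an) an$retrodiction$label, character(1))
  t_ref <- low_threshold[match(ref_level, levels)]
  structure(list(
    factor = factor, levels = levels, ref_level = ref_level,
    summary = data.frame(level = unlist(levels), threshold = low_threshold,
                         rel_change_pct = (low_threshold - t_ref) / t_ref * 100,
                         label = labels, stringsAsFactors = FALSE),
    thresholds = lapply(runs, function(an) an$thresholds),
    retrodiction = lapply(runs, function(an) an$retrodiction)),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> factor %s (reference level %s)\n", x$factor,
              format(x$ref_level)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Retrodiction ability table across drugs, populations and scenario depths
#'
#' The tabular analogue of the heat-map of retrodiction labels: for every
#' combination of model spec, patient population and number of considered
#' doses, runs the pipeline and records the complete/partial/none label.
#'
#' @param specs Named list of `poppk_spec` objects.
#' @param patients Named list of `patient` objects.
#' @param ns Integer vector of scenario depths (e.g. `1:3`).
#' @param dose Dose (mg); scalar or named by spec.
#' @param interval Dosing interval (h); scalar or named by spec.
#' @param settings A [sim_settings()].
#' @param cutoff Retrodiction cutoff.
#' @return data.frame with columns `drug`, `population`, `n`, `label`
#'   (one row per combination).
#' @export
retrodiction_table <- function(specs, patients, ns, dose = 300, interval = 12,
                               settings = sim_settings(), cutoff = 0.8) {
  if (is.null(names(specs))) names(specs) <- vapply(specs, `[[`, "", "drug_name")
  if (is.null(names(patients))) names(patients) <- paste0("pop", seq_along(patients))
  get1 <- function(v, nm) if (length(v) > 1) v[[nm]] else v[[1]]
  rows <- list()
  for (s in names(specs)) for (p in names(patients)) for (n in ns) {
    an <- adherence_analysis(specs[[s]], patients[[p]], get1(dose, s),
                             get1(interval, s), n = n, settings = settings,
                             cutoff = cutoff)
    rows[[length(rows) + 1]] <- data.frame(
      drug = s, population = p, n = as.integer(n),
      label = an$retrodiction$label, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
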