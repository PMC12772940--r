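#' Full adherence-retrodiction analysis for one drug, patient and regimen
#'
#' Orchestrates the whole pipeline: steady-state run-in, enumeration of the
#' 2^n dosing scenarios over the last `n` doses, prior assignment, Monte
#' Carlo simulation of each scenario's conditional concentration
#' distribution at the sampling time, density estimation on a shared grid,
#' posterior curves, discrimination thresholds and the retrodiction
#' classification.
#'
#' @param spec A `poppk_spec`.
#' @param patient A `patient`.
#' @param dose Dose amount per administration, mg.
#' @param interval Dosing interval, h.
#' @param n Number of terminal doses under scrutiny (scenario depth).
#' @param prior_mode `"equal"`, `"per_dose"` or `"custom"`.
#' @param p Per-dose adherence probability (per_dose mode).
#' @param priors Named prior table (custom mode).
#' @param settings A [sim_settings()].
#' @param n_grid Posterior grid resolution (default 512).
#' @param cutoff Retrodiction posterior cutoff (default 0.8).
#' @return Object of class `adherence_analysis` bundling all intermediate
#'   and final results (`scenarios`, `base`, `samples`, `densities`,
#'   `curves`, `thresholds`, `retrodiction`).
#' @examples
#' spec <- generate_fixture_spec("fast_clearance", seed = 1)
#' an <- adherence_analysis(spec, typical_patient("adult"),
#'                          dose = 500, interval = 12, n = 1,
#'                          settings = sim_settings(n_virtual = 2000))
#' an$retrodiction$label
#' @export
adherence_analysis <- function(spec, patient, dose, interval, n = 2L,
                               prior_mode = "equal", p = NULL, priors = NULL,
                               settings = sim_settings(), n_grid = 512L,
                               cutoff = 0.8) {
  spec <- validate_model_spec(spec)
  scen <- assign_priors(enumerate_scenarios(n), prior_mode, p = p,
                        table = priors)
  base <- steady_state_history(spec, patient, dose, interval, n_considered = n)
  samples <- simulate_scenarios(spec, patient, base, scen, settings)
  densities <- estimate_densities(samples, settings, n_grid = n_grid)
  curves <- posterior_curves(scen, densities)
  structure(list(spec = spec, patient = patient,
                 regimen = list(dose = dose, interval = interval),
                 scenarios = scen, base = base, samples = samples,
                 densities = densities, curves = curves,
                 thresholds = find_thresholds(curves),
                 retrodiction = classify_retrodiction(curves, cutoff),
                 settings = settings),
            class = "adherence_analysis")
}

#' @export
print.adherence_analysis <- function(x, ...) {
  cat(sprintf("<adherence_analysis> %s, %g mg q%gh, last %d dose(s)\n",
              x$spec$drug_name, x$regimen$dose, x$regimen$interval,
              x$scenarios$n))
  print(x$thresholds)
  cat(sprintf("  retrodiction: %s\n", x$retrodiction$label))
  invisible(x)
}

#' Assess adherence from one observed TDM concentration
#'
#' Evaluates the posterior probability of every dosing scenario at the
#' observed concentration (Bayes' rule on the Monte Carlo conditional
#' densities) and names the most likely scenario. If the observation lies
#' outside the supported concentration range (zero marginal), the result is
#' flagged undefined with the advice to increase the residual-error
#' settings rather than silently forced to zero.
#'
#' @param analysis An [adherence_analysis()] result.
#' @param observed_c Observed trough concentration, mg/L (>= 0).
#' @return Object of class `adherence_assessment`: `observed`, `posterior`
#'   (named, sums to 1), `most_likely`, `ties`, `undefined`, `advice`,
#'   `priors`, `settings`, `spec_hash`.
#' @export
assess <- function(analysis, observed_c) {
  stopifnot(inherits(analysis, "adherence_analysis"), observed_c >= 0)
  post <- posterior_at(observed_c, analysis$scenarios$prior,
                       analysis$densities[analysis$scenarios$bits])
  undefined <- isTRUE(attr(post, "undefined"))
  most <- NA_character_
  ties <- character()
  advice <- NULL
  if (!undefined) {
    mx <- max(post)
    at_max <- names(post)[post >= mx - 1e-12]
    most <- at_max[1]   # lexicographically lowest bitstring wins ties
    if (length(at_max) > 1) ties <- at_max
  } else {
    advice <- paste("observed concentration has zero marginal probability",
                    "under every scenario; consider increasing ruv_add /",
                    "ruv_prop to reflect assay and model uncertainty")
  }
  structure(list(observed = observed_c, posterior = post,
                 most_likely = most, ties = ties, undefined = undefined,
                 advice = advice, priors = setNames(analysis$scenarios$prior,
                                                    analysis$scenarios$bits),
                 settings = analysis$settings,
                 spec_hash = spec_hash(analysis$spec)),
            class = "adherence_assessment")
}

#' @export
print.adherence_assessment <- function(x, ...) {
  cat(sprintf("<adherence_assessment> C = %g mg/L\n", x$observed))
  if (x$undefined) {
    cat("  posterior undefined:", x$advice, "\n")
  } else {
    for (b in names(x$posterior))
      cat(sprintf("  P(w%s | C) = %.4f%s\n", b, x$posterior[b],
                  if (identical(b, x$most_likely)) "  <- most likely" else ""))
    if (length(x$ties)) cat("  ties:", paste0("w", x$ties, collapse = ", "), "\n")
  }
  invisible(x)
}
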