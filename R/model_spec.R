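# enumerations for the declarative model-spec format
.formulations <- c("IR_tablet", "ER_tablet", "solution", "suspension", "syrup")
.structures   <- c("one_cpt_oral", "one_cpt_bolus", "two_cpt_oral")
.cov_forms    <- c("power", "proportional", "linear", "exponential")

# parameters required / allowed per structural model
.required_params <- list(
  one_cpt_oral  = c("CL_F", "V_F", "Ka"),
  one_cpt_bolus = c("CL_F", "V_F"),
  two_cpt_oral  = c("CL_F", "V_F", "Ka", "Q_F", "Vp_F")
)
.optional_params <- c("F_rel", "tlag")

#' Population pharmacokinetic model specification
#'
#' A `poppk_spec` is a declarative description of one drug/formulation's
#' population pharmacokinetics: structural model, typical parameters,
#' between-subject variability (lognormal, on-diagonal standard deviations
#' plus an optional correlation matrix), covariate relations composed
#' multiplicatively, and residual unexplained variability (additive +
#' proportional). Units are fixed internally: time h, amount mg, volume L,
#' concentration mg/L.
#'
#' @param drug_name Character drug label.
#' @param formulation One of `"IR_tablet"`, `"ER_tablet"`, `"solution"`,
#'   `"suspension"`, `"syrup"`.
#' @param structure One of `"one_cpt_oral"`, `"one_cpt_bolus"`,
#'   `"two_cpt_oral"`.
#' @param typical_params Named list/vector of typical values. Required names
#'   depend on `structure` (e.g. `CL_F`, `V_F`, `Ka`); `F_rel` (relative
#'   bioavailability, default 1) and `tlag` (absorption lag, h, default 0)
#'   are optional.
#' @param covariates List of covariate relations, each created by
#'   [covariate_relation()].
#' @param omega Named numeric of between-subject standard deviations on the
#'   log scale (may be empty).
#' @param omega_corr Optional correlation matrix aligned with `names(omega)`.
#' @param sigma_add Additive residual error SD, mg/L.
#' @param sigma_prop Proportional residual error SD, fraction.
#' @param ref_covariates Named list of reference covariate values
#'   (e.g. `weight = 70`, `eGFR = 90`).
#' @return A validated object of class `poppk_spec`.
#' @seealso [parse_model_spec()], [write_model_spec()],
#'   [generate_fixture_spec()]
#' @export
poppk_spec <- function(drug_name, formulation, structure, typical_params,
                       covariates = list(), omega = numeric(),
                       omega_corr = NULL, sigma_add = 0, sigma_prop = 0,
                       ref_covariates = list()) {
  spec <- structure(
    list(drug_name = as.character(drug_name)[1],
         formulation = formulation,
         structure = structure,
         typical_params = as.list(typical_params),
         covariates = covariates,
         omega = unlist(omega) %||% numeric(),
         omega_corr = omega_corr,
         sigma_add = as.numeric(sigma_add),
         sigma_prop = as.numeric(sigma_prop),
         ref_covariates = as.list(ref_covariates)),
    class = "poppk_spec")
  validate_model_spec(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One covariate relation on a PK parameter
#'
#' Relations act multiplicatively on `target_param`, applied in spec order.
#' Forms: `power` = `(x/ref_value)^theta`; `proportional` = `1 + theta*x`
#' (for comedication/formulation flags `x` is 0/1, so the multiplier is
#' `1 + theta` when the tag is present); `linear` = `1 + theta*(x - ref_value)`;
#' `exponential` = `exp(theta*(x - ref_value))`.
#'
#' @param target_param Parameter name the multiplier applies to.
#' @param covariate Covariate name: `age`, `weight`, `height`, `eGFR`,
#'   `pregnancy_week`, a comedication tag, or a formulation tag.
#' @param form One of `"power"`, `"proportional"`, `"linear"`, `"exponential"`.
#' @param theta Coefficient.
#' @param ref_value Reference covariate value (unused for `proportional`).
#' @return List of class `covariate_relation`.
#' @export
covariate_relation <- function(target_param, covariate, form, theta,
                               ref_value = NULL) {
  structure(list(target_param = target_param, covariate = covariate,
                 form = form, theta = as.numeric(theta),
                 ref_value = if (is.null(ref_value)) NULL else as.numeric(ref_value)),
            class = "covariate_relation")
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stop_schema <- function(...) stop(sprintf(...), call. = FALSE)

#' Validate a population-PK model specification
#'
#' Enforces all structural invariants: positivity of typical parameters,
#' presence of structure-required parameters, nonnegative omega/sigma terms,
#' a symmetric positive semi-definite unit-diagonal correlation matrix (if
#' given), known covariate forms, and the absorption/elimination flip-flop
#' guard (`Ka` too close to `CL_F/V_F` is rejected or nudged for numerical
#' stability of the closed-form solution).
#'
#' @param spec A `poppk_spec` (or plain list with the same fields).
#' @return The validated (possibly Ka-nudged) `poppk_spec`, invisibly usable.
#' @export
validate_model_spec <- function(spec) {
  if (!is.list(spec)) .stop_schema("model spec must be a list")
  for (f in c("drug_name", "formulation", "structure", "typical_params"))
    if (is.null(spec[[f]])) .stop_schema("model spec missing field '%s'", f)
  if (!spec$formulation %in% .formulations)
    .stop_schema("unknown formulation '%s' (allowed: %s)", spec$formulation,
                 paste(.formulations, collapse = ", "))
  if (!spec$structure %in% .structures)
    .stop_schema("unknown structure '%s' (allowed: %s)", spec$structure,
                 paste(.structures, collapse = ", "))

  tp <- spec$typical_params
  req <- .required_params[[spec$structure]]
  missing <- setdiff(req, names(tp))
  if (length(missing))
    .stop_schema("structure '%s' requires parameter(s): %s", spec$structure,
                 paste(missing, collapse = ", "))
  unknown <- setdiff(names(tp), c(req, .optional_params))
  if (length(unknown))
    .stop_schema("unknown typical parameter(s): %s", paste(unknown, collapse = ", "))
  for (p in names(tp)) {
    v <- tp[[p]]
    if (!.is_count(v)) .stop_schema("typical parameter '%s' must be a finite number", p)
    if (p == "tlag") {
      if (v < 0) .stop_schema("tlag must be >= 0")
    } else if (v <= 0) .stop_schema("typical parameter '%s' must be > 0", p)
  }
  if (!is.null(tp$F_rel) && tp$F_rel > 1)
    .stop_schema("F_rel must be a fraction in (0, 1]")

  om <- spec$omega
  if (length(om)) {
    if (is.null(names(om)) || any(names(om) == ""))
      .stop_schema("omega entries must be named")
    bad <- setdiff(names(om), names(tp))
    if (length(bad)) .stop_schema("omega names not in typical_params: %s",
                                  paste(bad, collapse = ", "))
    if (any(!is.finite(om)) || any(om < 0)) .stop_schema("omega entries must be >= 0")
  }
  if (!is.null(spec$omega_corr)) {
    R <- as.matrix(spec$omega_corr)
    k <- length(om)
    if (!all(dim(R) == k))
      .stop_schema("omega_corr must be %d x %d to match omega", k, k)
    if (max(abs(R - t(R))) > 1e-8) .stop_schema("omega_corr must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-8) .stop_schema("omega_corr must have unit diagonal")
    ev <- eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      .stop_schema("omega_corr must be positive semi-definite (min eigenvalue %.3g)", min(ev))
    dimnames(R) <- list(names(om), names(om))
    spec$omega_corr <- R
  }

  if (!.is_count(spec$sigma_add) || spec$sigma_add < 0)
    .stop_schema("sigma_add must be >= 0")
  if (!.is_count(spec$sigma_prop) || spec$sigma_prop < 0)
    .stop_schema("sigma_prop must be >= 0")

  for (i in seq_along(spec$covariates)) {
    cr <- spec$covariates[[i]]
    for (f in c("target_param", "covariate", "form", "theta"))
      if (is.null(cr[[f]])) .stop_schema("covariate relation %d missing '%s'", i, f)
    if (!cr$form %in% .cov_forms)
      .stop_schema("unknown covariate form '%s' (allowed: %s)", cr$form,
                   paste(.cov_forms, collapse = ", "))
    if (!cr$target_param %in% names(tp))
      .stop_schema("covariate relation %d targets unknown parameter '%s'",
                   i, cr$target_param)
    if (cr$form == "power" && (is.null(cr$ref_value) || cr$ref_value <= 0))
      .stop_schema("power-form covariate relation on '%s' requires ref_value > 0",
                   cr$target_param)
    if (cr$form %in% c("linear", "exponential") && is.null(cr$ref_value))
      .stop_schema("%s-form covariate relation on '%s' requires ref_value",
                   cr$form, cr$target_param)
    spec$covariates[[i]] <- structure(cr[c("target_param", "covariate", "form",
                                           "theta", "ref_value")],
                                      class = "covariate_relation")
  }

  # flip-flop guard: Ka == CL/V makes the Bateman denominator vanish
  if (spec$structure %in% c("one_cpt_oral", "two_cpt_oral")) {
    k <- tp$CL_F / tp$V_F
    rel <- abs(tp$Ka - k) / k
    if (rel < 1e-6)
      .stop_schema("Ka (%.6g) indistinguishable from CL_F/V_F (%.6g): flip-flop degeneracy",
                   tp$Ka, k)
    if (rel < 1e-4) spec$typical_params$Ka <- tp$Ka * (1 + 1e-6)
  }

  class(spec) <- "poppk_spec"
  spec
}

#' @export
print.poppk_spec <- function(x, ...) {
  cat(sprintf("<poppk_spec> %s [%s, %s]\n", x$drug_name, x$formulation, x$structure))
  cat("  typical:", paste(sprintf("%s=%g", names(x$typical_params),
                                  unlist(x$typical_params)), collapse = ", "), "\n")
  if (length(x$omega))
    cat("  omega:  ", paste(sprintf("%s=%g", names(x$omega), x$omega), collapse = ", "), "\n")
  cat(sprintf("  RUV: additive %g mg/L, proportional %g\n", x$sigma_add, x$sigma_prop))
  if (length(x$covariates))
    cat(sprintf("  %d covariate relation(s)\n", length(x$covariates)))
  invisible(x)
}

#' Read a model specification from a YAML file
#'
#' Parses the declarative YAML format (one drug + formulation per file, see
#' the JSON-Schema shipped under `inst/schema/`) and validates every
#' invariant. Units are assumed to already be in the internal convention
#' (h, mg, L, mg/L).
#'
#' @param path Path to a YAML model-spec file.
#' @return A validated `poppk_spec`.
#' @export
parse_model_spec <- function(path) {
  if (!file.exists(path)) .stop_schema("model spec file not found: %s", path)
  raw <- yaml::read_yaml(path)
  covs <- lapply(raw$covariates %||% list(), function(cr)
    covariate_relation(cr$target_param, cr$covariate, cr$form, cr$theta,
                       cr$ref_value))
  oc <- raw$omega_corr
  if (!is.null(oc)) oc <- do.call(rbind, lapply(oc, unlist))
  validate_model_spec(structure(list(
    drug_name = raw$drug_name, formulation = raw$formulation,
    structure = raw$structure, typical_params = raw$typical_params,
    covariates = covs,
    omega = unlist(raw$omega) %||% numeric(),
    omega_corr = oc,
    sigma_add = raw$sigma_add %||% 0, sigma_prop = raw$sigma_prop %||% 0,
    ref_covariates = raw$ref_covariates %||% list()), class = "poppk_spec"))
}

#' Write a model specification to a YAML file
#'
#' Inverse of [parse_model_spec()]: `parse_model_spec(write_model_spec(x, f))`
#' is semantically identical to `x`.
#'
#' @param spec A `poppk_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  spec <- validate_model_spec(spec)
  out <- list(drug_name = spec$drug_name, formulation = spec$formulation,
              structure = spec$structure, typical_params = spec$typical_params)
  if (length(spec$covariates))
    out$covariates <- lapply(spec$covariates, function(cr)
      Filter(Negate(is.null), unclass(cr)))
  if (length(spec$omega)) out$omega <- as.list(spec$omega)
  if (!is.null(spec$omega_corr))
    out$omega_corr <- lapply(seq_len(nrow(spec$omega_corr)),
                             function(i) as.numeric(spec$omega_corr[i, ]))
  out$sigma_add <- spec$sigma_add
  out$sigma_prop <- spec$sigma_prop
  if (length(spec$ref_covariates)) out$ref_covariates <- spec$ref_covariates
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Content fingerprint of a model specification
#'
#' MD5 of the canonical YAML serialization; logged in every report so runs
#' can be traced to the exact model used.
#'
#' @param spec A `poppk_spec`.
#' @return Character MD5 hash.
#' @export
spec_hash <- function(spec) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_model_spec(spec, f)
  unname(tools::md5sum(f))
}

#' Patient descriptor
#'
#' @param age Years (> 0).
#' @param weight kg (> 0).
#' @param height cm (> 0).
#' @param sex `"male"` or `"female"`.
#' @param eGFR Estimated glomerular filtration rate, mL/min/1.73m^2 (> 0).
#' @param pregnancy_week Gestational week in \[0, 42\], or `NULL`.
#' @param comedications Character vector of comedication tags
#'   (e.g. `"enzyme_inducer"`).
#' @return Object of class `patient`.
#' @export
patient <- function(age, weight, height, sex = "male", eGFR = 90,
                    pregnancy_week = NULL, comedications = character()) {
  stopifnot(age > 0, weight > 0, height > 0, eGFR > 0)
  if (!sex %in% c("male", "female")) .stop_schema("sex must be 'male' or 'female'")
  if (!is.null(pregnancy_week) &&
      (pregnancy_week < 0 || pregnancy_week > 42))
    .stop_schema("pregnancy_week must be in [0, 42]")
  structure(list(age = age, weight = weight, height = height, sex = sex,
                 eGFR = eGFR, pregnancy_week = pregnancy_week,
                 comedications = as.character(comedications)),
            class = "patient")
}

#' Typical patients used throughout the simulations
#'
#' `"adult"`: 40 y, 70 kg, 180 cm. `"pediatric"`: 8 y, 25 kg, 127 cm.
#' `"pregnant"`: 25 y, 70 kg, 160 cm, 30 weeks pregnant. All with normal
#' renal function (eGFR 90) and no comedication.
#'
#' @param population One of `"adult"`, `"pediatric"`, `"pregnant"`.
#' @return A `patient`.
#' @export
typical_patient <- function(population = c("adult", "pediatric", "pregnant")) {
  switch(match.arg(population),
    adult     = patient(age = 40, weight = 70, height = 180, sex = "male"),
    pediatric = patient(age = 8, weight = 25, height = 127, sex = "male"),
    pregnant  = patient(age = 25, weight = 70, height = 160, sex = "female",
                        pregnancy_week = 30))
}
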