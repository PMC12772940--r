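# Shared fixtures and helpers. Everything is generated in code; no data
# files. Most unit tests run at reduced n_virtual; the acceptance suite
# uses the full 40,000 virtual patients.

fixture_fast <- function() generate_fixture_spec("fast_clearance", seed = 1)
fixture_slow <- function() generate_fixture_spec("slow_clearance", seed = 1)
fixture_cov  <- function() generate_fixture_spec("with_covariates", seed = 1)

adult <- function() typical_patient("adult")

small_settings <- function(n = 4000L, seed = 3L, ...)
  sim_settings(n_virtual = n, seed = seed, ...)

# standard test regimens for the two one-compartment profiles
fast_regimen <- list(dose = 500, interval = 12)
slow_regimen <- list(dose = 100, interval = 24)   # once-daily, phenobarbital-like

run_fast <- function(n = 2, settings = small_settings(), ...)
  adherence_analysis(fixture_fast(), adult(), fast_regimen$dose,
                     fast_regimen$interval, n = n, settings = settings, ...)

run_slow <- function(n = 2, settings = small_settings(), ...)
  adherence_analysis(fixture_slow(), adult(), slow_regimen$dose,
                     slow_regimen$interval, n = n, settings = settings, ...)

lowest_crossing <- function(an) min(an$thresholds$thresholds$crossing)

# spec with no between-subject variability and no residual error: the
# deterministic world where every scenario is a point mass
zero_bsv_spec <- function() poppk_spec(
  drug_name = "synthetic-deterministic", formulation = "IR_tablet",
  structure = "one_cpt_oral",
  typical_params = list(CL_F = 3, V_F = 50, Ka = 1.5),
  omega = c(CL_F = 0, V_F = 0, Ka = 0), sigma_add = 0, sigma_prop = 0)

# sup-norm between two posterior-curve sets over the jointly well-supported
# core (marginal >= `level` of its max in both runs), interpolating the
# second run onto the first run's grid
curves_supnorm <- function(c1, c2, level = 0.01) {
  core1 <- c1$marginal >= level * max(c1$marginal)
  g <- c1$grid[core1]
  m2 <- approx(c2$grid, c2$marginal, xout = g, rule = 2)$y
  keep <- m2 >= level * max(c2$marginal)
  p1 <- c1$posteriors[, core1, drop = FALSE][, keep, drop = FALSE]
  p2 <- vapply(seq_along(c2$bits), function(i)
    approx(c2$grid, c2$posteriors[i, ], xout = g[keep], rule = 2)$y,
    numeric(sum(keep)))
  max(abs(p1 - t(p2)), na.rm = TRUE)
}

# random admissible parameter set for the closed-form vs ODE comparison
random_pk_params <- function(structure) {
  p <- list(CL_F = runif(1, 0.5, 12), V_F = runif(1, 20, 120),
            Ka = runif(1, 0.3, 3), F_rel = runif(1, 0.5, 1),
            tlag = sample(c(0, runif(1, 0, 1.5)), 1))
  if (structure == "two_cpt_oral") {
    p$Q_F <- runif(1, 1, 10)
    p$Vp_F <- runif(1, 30, 200)
  }
  # keep away from the absorption/elimination flip-flop degeneracy
  k <- p$CL_F / p$V_F
  if (abs(p$Ka - k) / k < 0.05) p$Ka <- p$Ka * 1.2
  p
}

random_history <- function() {
  times <- cumsum(c(0, runif(3, 6, 18)))
  data.frame(time = times,
             amount = sample(c(0, 100, 200, 300), 4, replace = TRUE))
}
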