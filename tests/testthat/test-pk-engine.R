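# pk_engine: covariate algebra, between-subject sampling, closed-form
# superposition solver, steady-state run-in, ODE oracle agreement

test_that("covariate relations multiply as their closed forms dictate", {
  sp <- poppk_spec("d", "IR_tablet", "one_cpt_oral",
                   list(CL_F = 4, V_F = 50, Ka = 1),
                   covariates = list(
                     covariate_relation("CL_F", "weight", "power", 0.75, 70),
                     covariate_relation("CL_F", "eGFR", "power", 0.5, 90),
                     covariate_relation("CL_F", "inducer", "proportional", 0.5)))
  # at the reference point every multiplier is 1
  ref <- patient(40, 70, 180, eGFR = 90)
  expect_equal(apply_covariates(sp, ref)$CL_F, 4 * (45 / 90)^0 * 1)
  lowgfr <- patient(40, 70, 180, eGFR = 45)
  expect_equal(apply_covariates(sp, lowgfr)$CL_F, 4 * sqrt(0.5),
               tolerance = 1e-12)
  tagged <- patient(40, 70, 180, eGFR = 90, comedications = "inducer")
  expect_equal(apply_covariates(sp, tagged)$CL_F, 4 * 1.5)
  heavy <- patient(40, 140, 180, eGFR = 90)
  expect_equal(apply_covariates(sp, heavy)$CL_F, 4 * 2^0.75)
})

test_that("covariate resolution and domain errors are raised", {
  sp <- poppk_spec("d", "IR_tablet", "one_cpt_oral",
                   list(CL_F = 4, V_F = 50, Ka = 1),
                   covariates = list(covariate_relation(
                     "CL_F", "pregnancy_week", "linear", 0.02, 0)))
  expect_error(apply_covariates(sp, adult()), "pregnancy_week")
  expect_equal(apply_covariates(sp, typical_patient("pregnant"))$CL_F,
               4 * 1.6)
  sp2 <- poppk_spec("d", "IR_tablet", "one_cpt_oral",
                    list(CL_F = 4, V_F = 50, Ka = 1),
                    covariates = list(covariate_relation(
                      "CL_F", "eGFR", "power", 0.5, 90)))
  broken <- adult(); broken$eGFR <- -1
  expect_error(apply_covariates(sp2, broken), "domain")
  # a relation whose multiplier goes non-positive is refused
  sp3 <- poppk_spec("d", "IR_tablet", "one_cpt_oral",
                    list(CL_F = 4, V_F = 50, Ka = 1),
                    covariates = list(covariate_relation(
                      "CL_F", "age", "linear", -0.1, 40)))
  elderly <- patient(80, 70, 180)
  expect_error(apply_covariates(sp3, elderly), "non-positive")
})

test_that("individual sampling follows the stated lognormal law", {
  sp <- fixture_fast()
  # degenerate variance: individuals equal covariate-adjusted typicals
  sp0 <- sp; sp0$omega[] <- 0
  ind <- sample_individuals(sp0, adult(), 5, seed = 1)
  tv <- apply_covariates(sp0, adult())
  for (p in names(tv)) expect_true(all(ind[[p]] == tv[[p]]))
  # determinism
  expect_identical(sample_individuals(sp, adult(), 100, seed = 9),
                   sample_individuals(sp, adult(), 100, seed = 9))
  # n = 10,000, omega_CL = 0.25: mean log within 3 standard errors
  ind <- sample_individuals(sp, adult(), 10000, seed = 2)
  tv <- apply_covariates(sp, adult())
  se <- sp$omega[["CL_F"]] / sqrt(10000)
  expect_lt(abs(mean(log(ind$CL_F)) - log(tv$CL_F)), 3 * se)
  expect_lt(abs(sd(log(ind$CL_F)) - sp$omega[["CL_F"]]), 0.01)
})

test_that("correlated random effects honour the correlation matrix", {
  sp <- poppk_spec("d", "IR_tablet", "one_cpt_oral",
                   list(CL_F = 5, V_F = 50, Ka = 1),
                   omega = c(CL_F = 0.3, V_F = 0.2),
                   omega_corr = matrix(c(1, 0.6, 0.6, 1), 2))
  ind <- sample_individuals(sp, adult(), 20000, seed = 4)
  expect_lt(abs(cor(log(ind$CL_F), log(ind$V_F)) - 0.6), 0.03)
})

test_that("closed-form concentration obeys superposition, scaling and monotonicity", {
  p <- list(CL_F = 4, V_F = 50, Ka = 1.3, F_rel = 0.9, tlag = 0.5)
  dosesA <- data.frame(time = c(0, 12), amount = c(200, 200))
  dosesB <- data.frame(time = 24, amount = 300)
  both <- rbind(dosesA, dosesB)
  t <- seq(0, 60, by = 2.5)
  expect_equal(concentration(p, both, t, "one_cpt_oral"),
               concentration(p, dosesA, t, "one_cpt_oral") +
                 concentration(p, dosesB, t, "one_cpt_oral"),
               tolerance = 1e-12)
  # at a dose's own instant it contributes nothing
  expect_identical(concentration(p, data.frame(time = 5, amount = 100),
                                 c(0, 5), "one_cpt_oral"), c(0, 0))
  # missed doses (amount 0) contribute nothing
  miss <- both; miss$amount[2] <- 0
  drop2 <- concentration(p, both[-2, ], t, "one_cpt_oral")
  expect_equal(concentration(p, miss, t, "one_cpt_oral"), drop2,
               tolerance = 1e-12)
  # removing a dose strictly lowers concentration at every later time
  after <- t > both$time[2] + p$tlag
  expect_true(all(drop2[after] <
                    concentration(p, both, t, "one_cpt_oral")[after]))
  # dose scale-equivariance is exact
  scaled <- both; scaled$amount <- scaled$amount * 3
  expect_equal(concentration(p, scaled, t, "one_cpt_oral"),
               3 * concentration(p, both, t, "one_cpt_oral"),
               tolerance = 1e-12)
  expect_error(concentration(p, both, t, "pbpk"), "structure")
})

test_that("Ka ~ k collisions fall back to the exact limit form", {
  k <- 4 / 50
  p_lim <- list(CL_F = 4, V_F = 50, Ka = k * (1 + 1e-10), F_rel = 1, tlag = 0)
  p_ref <- list(CL_F = 4, V_F = 50, Ka = k * (1 + 1e-4), F_rel = 1, tlag = 0)
  doses <- data.frame(time = 0, amount = 100)
  c_lim <- concentration(p_lim, doses, c(5, 20), "one_cpt_oral")
  c_ref <- concentration(p_ref, doses, c(5, 20), "one_cpt_oral")
  expect_true(all(is.finite(c_lim)))
  expect_equal(c_lim, c_ref, tolerance = 1e-3)
})

test_that("closed forms match the independent ODE oracle across structures", {
  set.seed(42)
  for (structure in c("one_cpt_oral", "one_cpt_bolus", "two_cpt_oral")) {
    for (rep in 1:4) {
      p <- random_pk_params(structure)
      doses <- random_history()
      t <- sort(runif(4, 1, 70))
      cf <- concentration(p, doses, t, structure)
      od <- concentration_ode(p, doses, t, structure)
      expect_equal(cf, od, tolerance = 1e-6,
                   label = sprintf("%s rep %d closed form", structure, rep))
    }
  }
})

test_that("steady-state run-in satisfies its convergence contract", {
  # terminal half-life 10 h, interval 12 h
  sp <- poppk_spec("d", "IR_tablet", "one_cpt_oral",
                   list(CL_F = log(2) / 10 * 45, V_F = 45, Ka = 1.2))
  tv <- apply_covariates(sp, adult())
  base <- steady_state_history(sp, adult(), 300, 12, n_considered = 1)
  n_runin <- nrow(base) - 1
  # consecutive pre-dose troughs at the end of run-in differ < 1e-4 relative
  tr <- concentration(tv, base, c(n_runin - 1, n_runin, n_runin + 1) * 12,
                      sp$structure)
  expect_lt(abs(tr[3] - tr[2]) / tr[2], 1e-4)
  expect_lt(abs(tr[2] - tr[1]) / tr[1], 2e-4)
  # analytic one-compartment steady-state trough to 1e-3 relative
  k <- tv$CL_F / tv$V_F; Ka <- tv$Ka; tau <- 12
  css <- 300 * Ka / (tv$V_F * (Ka - k)) *
    (exp(-k * tau) / (1 - exp(-k * tau)) -
     exp(-Ka * tau) / (1 - exp(-Ka * tau)))
  got <- concentration(tv, base, attr(base, "sampling_time"), sp$structure)
  expect_equal(got, css, tolerance = 1e-3)
  # doubling the run-in changes the sampled trough < 1e-4 relative
  n2 <- 2 * n_runin + 1
  dbl <- data.frame(time = (seq_len(n2) - 1) * 12, amount = 300)
  got2 <- concentration(tv, dbl, n2 * 12, sp$structure)
  expect_lt(abs(got2 - got) / got, 1e-4)
  expect_error(steady_state_history(sp, adult(), -1, 12), "dose")
  expect_error(steady_state_history(sp, adult(), 300, 0), "interval")
})

test_that("run-in bookkeeping exposes slots, interval and sampling time", {
  base <- steady_state_history(fixture_fast(), adult(), 500, 12,
                               n_considered = 3)
  slots <- attr(base, "slots")
  expect_length(slots, 3)
  expect_identical(slots, (nrow(base) - 2):nrow(base))
  expect_equal(attr(base, "sampling_time"), base$time[nrow(base)] + 12)
  expect_true(all(base$amount == 500))
})
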