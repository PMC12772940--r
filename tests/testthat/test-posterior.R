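# bayes_posterior: Bayes' rule, posterior curves, thresholds,
# retrodiction taxonomy, single-observation assessment

grid15 <- seq(0, 15, length.out = 601)

normal_density <- function(mu, bits) density_estimate(
  grid15, dnorm(grid15, mu, 1), bits = bits)

test_that("posterior_at reproduces Bayes' rule exactly", {
  d <- list(density_estimate(c(0, 1, 2), c(0.5, 0.5, 0.5), "0"),
            density_estimate(c(0, 1, 2), c(0.5, 0.5, 0.5), "1"))
  expect_equal(as.numeric(posterior_at(1, c(0.3, 0.7), d)), c(0.3, 0.7))
  d2 <- list(density_estimate(c(0, 2), c(0.2, 0.2), "0"),
             density_estimate(c(0, 2), c(0.8, 0.8), "1"))
  expect_equal(as.numeric(posterior_at(1, c(0.5, 0.5), d2)), c(0.2, 0.8))
  # likelihood annihilation: zero density kills any prior < 1
  d3 <- list(density_estimate(c(0, 2), c(0, 0), "0"),
             density_estimate(c(0, 2), c(0.8, 0.8), "1"))
  expect_equal(as.numeric(posterior_at(1, c(0.95, 0.05), d3)), c(0, 1))
  # zero marginal: undefined, flagged, never silently zeroed
  d4 <- list(density_estimate(c(0, 2), c(0, 0), "0"),
             density_estimate(c(0, 2), c(0, 0), "1"))
  p <- posterior_at(1, c(0.5, 0.5), d4)
  expect_true(attr(p, "undefined"))
  expect_true(all(is.na(p)))
})

test_that("posterior_at equals direct evaluation on random discretized densities", {
  set.seed(8)
  g <- seq(0, 10, length.out = 41)
  for (rep in 1:10) {
    vals <- lapply(1:3, function(i) runif(41, 0, 1))
    dens <- lapply(1:3, function(i)
      density_estimate(g, vals[[i]], bits = as.character(i)))
    pr <- runif(3); pr <- pr / sum(pr)
    c0 <- runif(1, 0.2, 9.8)
    got <- as.numeric(posterior_at(c0, pr, dens))
    lik <- vapply(vals, function(v) approx(g, v, xout = c0)$y, numeric(1))
    expect_equal(got, pr * lik / sum(pr * lik), tolerance = 1e-12)
    expect_lt(abs(sum(got) - 1), 1e-9)
  }
})

test_that("posterior curves separate well-separated scenarios and stay normalized", {
  scen <- assign_priors(enumerate_scenarios(1), "equal")
  dens <- list("0" = normal_density(5, "0"), "1" = normal_density(10, "1"))
  cur <- posterior_curves(scen, dens)
  idx <- which(cur$defined)
  sums <- colSums(cur$posteriors[, idx, drop = FALSE])
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_gt(cur$posteriors[1, idx[1]], 0.999)   # low scenario wins at the bottom
  expect_lt(cur$posteriors[1, idx[length(idx)]], 0.001)
  th <- find_thresholds(cur)
  expect_equal(th$thresholds$crossing, 7.5, tolerance = 0.01)
  expect_identical(th$thresholds$below, "0")
  expect_identical(th$partition$bits, c("0", "1"))
  expect_error(posterior_curves(scen, list(
    "0" = normal_density(5, "0"),
    "1" = density_estimate(seq(0, 20, length.out = 601),
                           dnorm(seq(0, 20, length.out = 601), 10, 1), "1"))),
    "share one grid")
})

test_that("uninformative likelihoods return the prior everywhere", {
  scen <- assign_priors(enumerate_scenarios(1), "custom",
                        table = c("0" = 0.3, "1" = 0.7))
  dens <- list("0" = normal_density(7, "0"), "1" = normal_density(7, "1"))
  cur <- posterior_curves(scen, dens)
  expect_true(all(abs(cur$posteriors[1, cur$defined] - 0.3) < 1e-12))
  th <- find_thresholds(cur)
  expect_true(th$degenerate)
  expect_identical(nrow(th$thresholds), 0L)
})

test_that("the retrodiction taxonomy follows the 80% rule exactly", {
  synth_curves <- function(maxima) {
    # triangular posterior bumps peaking at the requested heights
    g <- seq(0, 1, length.out = 101)
    post <- do.call(rbind, lapply(seq_along(maxima), function(i) {
      center <- i / (length(maxima) + 1)
      pmax(0, maxima[i] * (1 - 10 * abs(g - center)))
    }))
    structure(list(grid = g, posteriors = post, marginal = rep(1, 101),
                   defined = rep(TRUE, 101),
                   bits = sprintf("s%d", seq_along(maxima)),
                   priors = rep(1 / length(maxima), length(maxima))),
              class = "posterior_curves")
  }
  expect_identical(
    classify_retrodiction(synth_curves(c(0.95, 0.9, 0.92, 0.99)))$label,
    "complete")
  expect_identical(
    classify_retrodiction(synth_curves(c(0.9, 0.6, 0.6, 0.85)))$label,
    "partial")
  expect_identical(
    classify_retrodiction(synth_curves(rep(0.25, 4)))$label, "none")
  expect_identical(
    classify_retrodiction(synth_curves(c(0.9, 0.5, 0.4, 0.6)))$label, "none")
  # cutoff is adjustable
  expect_identical(
    classify_retrodiction(synth_curves(c(0.7, 0.7, 0.7, 0.7)),
                          cutoff = 0.65)$label, "complete")
})

test_that("assessment identifies full adherence far above all thresholds", {
  # well-separated world: low between-subject variability
  sep <- poppk_spec("synthetic-sep", "IR_tablet", "one_cpt_oral",
                    list(CL_F = 2.6, V_F = 45, Ka = 1.5),
                    omega = c(CL_F = 0.03, V_F = 0.03, Ka = 0.03),
                    sigma_add = 0.01, sigma_prop = 0.001)
  an <- adherence_analysis(sep, adult(), 300, 12, n = 2,
                           settings = small_settings(n = 8000))
  tv <- apply_covariates(sep, adult())
  base <- steady_state_history(sep, adult(), 300, 12, n_considered = 2)
  c11 <- concentration(tv, base, attr(base, "sampling_time"), sep$structure)
  expect_gt(c11, max(an$thresholds$thresholds$crossing))   # above every threshold
  a <- assess(an, observed_c = c11)
  expect_identical(a$most_likely, "11")
  expect_gt(a$posterior[["11"]], 0.99)
  expect_lt(abs(sum(a$posterior) - 1), 1e-9)
  # far outside every scenario's support: undefined with advice, not zeros
  a2 <- assess(an, observed_c = max(an$curves$grid) * 50)
  expect_true(a2$undefined)
  expect_match(a2$advice, "ruv")
})

test_that("raising a scenario's prior never lowers its posterior", {
  sp <- fixture_fast()
  st <- small_settings(n = 8000)
  c0 <- 2.5
  base <- adherence_analysis(sp, adult(), 500, 12, n = 2, settings = st)
  p_eq <- assess(base, c0)$posterior[["01"]]
  up <- adherence_analysis(sp, adult(), 500, 12, n = 2,
                           prior_mode = "custom",
                           priors = c("00" = 1, "01" = 3, "10" = 1, "11" = 1),
                           settings = st)
  p_up <- assess(up, c0)$posterior[["01"]]
  expect_gte(p_up, p_eq)
})

test_that("a deterministic world puts all posterior mass on the matching scenario", {
  sp <- zero_bsv_spec()
  st <- small_settings(n = 500, ruv_add = 0, ruv_prop = 0)
  an <- adherence_analysis(sp, adult(), 300, 12, n = 2, settings = st)
  tv <- apply_covariates(sp, adult())
  base <- steady_state_history(sp, adult(), 300, 12, n_considered = 2)
  c01 <- concentration(tv, scenario_history(base, "01"),
                       attr(base, "sampling_time"), sp$structure)
  a <- assess(an, c01)
  expect_equal(a$posterior[["01"]], 1)
  expect_identical(a$most_likely, "01")
})

test_that("widening residual error blurs intermediate scenarios", {
  sharp <- run_fast(n = 2, settings = small_settings(n = 8000,
                                                     ruv_prop = 0.001))
  blurred <- run_fast(n = 2, settings = small_settings(n = 8000,
                                                       ruv_prop = 0.3))
  mids <- c("01", "10")
  expect_true(any(blurred$retrodiction$max_posterior[mids] <
                    sharp$retrodiction$max_posterior[mids]))
})
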