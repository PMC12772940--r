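# Independent numeric oracle for the closed-form PK solutions: the same
# absorption/disposition systems integrated with an adaptive Dormand-Prince
# RK5(4) scheme. Used by the test-suite only; deliberately shares no code
# with the superposition engine.

# Dormand-Prince coefficients
.dp_c <- c(0, 1/5, 3/10, 4/5, 8/9, 1, 1)
.dp_a <- list(
  c(1/5),
  c(3/40, 9/40),
  c(44/45, -56/15, 32/9),
  c(19372/6561, -25360/2187, 64448/6561, -212/729),
  c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
  c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
.dp_b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
.dp_b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)

# integrate dy/dt = f(t, y) from t0 to t1 with adaptive step control
.rk45 <- function(f, y0, t0, t1, rtol = 1e-9, atol = 1e-12) {
  t <- t0; y <- y0
  h <- max((t1 - t0) / 100, 1e-8)
  while (t < t1 - 1e-12) {
    h <- min(h, t1 - t)
    k <- vector("list", 7)
    k[[1]] <- f(t, y)
    for (s in 2:6) {
      acc <- y
      for (j in seq_len(s - 1)) acc <- acc + h * .dp_a[[s - 1]][j] * k[[j]]
      k[[s]] <- f(t + .dp_c[s] * h, acc)
    }
    y5 <- y
    for (j in 1:6) y5 <- y5 + h * .dp_b5[j] * k[[j]]
    k[[7]] <- f(t + h, y5)
    y4 <- y
    for (j in 1:7) y4 <- y4 + h * .dp_b4[j] * k[[j]]
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1 || h < 1e-10) {
      t <- t + h
      y <- y5
    }
    fac <- if (err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
  }
  y
}

#' Concentration by numeric ODE integration (independent oracle)
#'
#' Integrates the compartmental mass-balance ODE system (depot, central and
#' - for two-compartment models - peripheral amounts) with an adaptive
#' Dormand-Prince RK5(4) scheme, adding `F_rel * amount` to the depot (or
#' central, for bolus models) compartment at each dose time (+ `tlag`).
#' Serves as the independent check on the closed-form superposition solver
#' [concentration()]; the two implementations share no code.
#'
#' @param ind Named list of individual parameters.
#' @param doses data.frame with columns `time`, `amount`.
#' @param t Numeric vector of output times (h).
#' @param structure Structural model name.
#' @param rtol,atol Integrator tolerances.
#' @return Numeric vector of concentrations (mg/L).
#' @export
concentration_ode <- function(ind, doses, t, structure,
                              rtol = 1e-9, atol = 1e-12) {
  p <- as.list(ind)
  Frel <- p$F_rel %||% 1
  tlag <- p$tlag %||% 0
  nstate <- if (structure == "two_cpt_oral") 3L else 2L
  deriv <- switch(structure,
    one_cpt_oral = function(tt, y)
      c(-p$Ka * y[1], p$Ka * y[1] - (p$CL_F / p$V_F) * y[2]),
    one_cpt_bolus = function(tt, y)
      c(0, -(p$CL_F / p$V_F) * y[2]),
    two_cpt_oral = function(tt, y)
      c(-p$Ka * y[1],
        p$Ka * y[1] - (p$CL_F / p$V_F + p$Q_F / p$V_F) * y[2] + (p$Q_F / p$Vp_F) * y[3],
        (p$Q_F / p$V_F) * y[2] - (p$Q_F / p$Vp_F) * y[3]),
    stop(sprintf("unknown structure '%s'", structure), call. = FALSE))

  doses <- doses[doses$amount > 0, , drop = FALSE]
  events <- doses$time + tlag
  breaks <- sort(unique(c(events, t)))
  y <- numeric(nstate)
  out <- numeric(length(t))
  now <- breaks[1]
  depot <- if (structure == "one_cpt_bolus") 2L else 1L
  for (b in breaks) {
    if (b > now) {
      y <- .rk45(deriv, y, now, b, rtol, atol)
      now <- b
    }
    # record outputs before applying any simultaneous dose (a dose has no
    # effect at its own instant, matching the closed form)
    sel <- which(abs(t - b) < 1e-12)
    if (length(sel)) out[sel] <- y[2] / p$V_F
    hit <- which(abs(events - b) < 1e-12)
    if (length(hit)) y[depot] <- y[depot] + Frel * sum(doses$amount[hit])
  }
  out
}
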