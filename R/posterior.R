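# Bayes engine: P(scenario | C) = P(scenario) * P(C | scenario) / P(C),
# with P(C) = sum_j P(scenario_j) * P(C | scenario_j).

# likelihood of concentration c under one density estimate; atoms dominate
# the continuous part wherever they match (a point mass has infinite
# density relative to any continuous component)
.atom_match <- function(d, c) {
  if (!nrow(d$atoms)) return(0)
  hit <- (d$atoms$location == 0 & c <= d$floor) |
    abs(c - d$atoms$location) <= 1e-8 * pmax(1, d$atoms$location)
  if (any(hit)) sum(d$atoms$mass[hit]) else 0
}

.continuous_at <- function(d, c) {
  if (c < min(d$grid) || c > max(d$grid)) return(0)
  approx(d$grid, d$values, xout = c, rule = 2)$y
}

#' Posterior scenario probabilities at one concentration
#'
#' Direct application of Bayes' rule: the posterior vector is proportional
#' to prior times likelihood, normalized by the marginal
#' `P(C) = sum_j prior_j * P(C | scenario_j)`. The likelihood is the linear
#' interpolation of each scenario's density at `c`; probability atoms
#' (point masses) are handled exactly and dominate the continuous part
#' wherever they match (the atom at 0 matches any `c` at or below the
#' quantitation floor). When the marginal is zero the posterior is
#' undefined: a vector of `NA` with attribute `undefined = TRUE` is
#' returned (reported, never silently zeroed).
#'
#' @param c Observed concentration, mg/L (>= 0).
#' @param priors Numeric priors summing to 1, in scenario order.
#' @param densities List of `density_estimate` objects sharing one grid.
#' @return Named probability vector summing to 1 (or NA with attribute
#'   `undefined` when the marginal vanishes).
#' @export
posterior_at <- function(c, priors, densities) {
  stopifnot(c >= 0, abs(sum(priors) - 1) < 1e-6,
            length(priors) == length(densities))
  atom_lik <- vapply(densities, .atom_match, numeric(1), c = c)
  lik <- if (any(atom_lik > 0)) atom_lik
         else vapply(densities, .continuous_at, numeric(1), c = c)
  marg <- sum(priors * lik)
  bits <- vapply(densities, function(d) d$bits, character(1))
  if (marg <= 0) {
    out <- setNames(rep(NA_real_, length(priors)), bits)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- setNames(priors * lik / marg, bits)
  attr(out, "undefined") <- FALSE
  out
}

#' Posterior probability curves over the concentration grid
#'
#' Applies [posterior_at()] at every grid point, producing one posterior
#' curve per scenario plus the marginal P(C). Columns where the
#' log-concentration-scale marginal (`c * P(c)`, the scale on which the
#' kernel estimates are built and on which every scenario's density has
#' comparable height) falls below `support_floor` times its maximum are
#' masked as undefined: with 40,000 samples per scenario a relative density
#' of 1e-4 corresponds to less than one expected sample per kernel
#' bandwidth, so posteriors there would be read off pure tail
#' extrapolation, not data.
#'
#' @param scen A `scenario_set` with priors assigned.
#' @param densities Named list of `density_estimate`, one per scenario
#'   bitstring, sharing a single grid.
#' @param support_floor Relative marginal level below which the posterior
#'   is reported as undefined (default 1e-4).
#' @return Object of class `posterior_curves`: list with `grid`,
#'   `posteriors` (scenario x grid matrix), `marginal`, `defined` (logical
#'   mask), `bits`, `priors`.
#' @export
posterior_curves <- function(scen, densities, support_floor = 1e-4) {
  stopifnot(inherits(scen, "scenario_set"), !any(is.na(scen$prior)))
  densities <- densities[scen$bits]
  if (any(vapply(densities, is.null, logical(1))))
    stop("densities must cover every scenario in the set", call. = FALSE)
  grid <- densities[[1]]$grid
  for (d in densities)
    if (!isTRUE(all.equal(d$grid, grid)))
      stop("all densities must share one grid", call. = FALSE)
  G <- length(grid)
  L <- do.call(rbind, lapply(densities, function(d) d$values))
  # continuous-regime posteriors, vectorized over columns
  W <- L * scen$prior
  marg <- colSums(W)
  post <- sweep(W, 2, marg, "/")
  # atom regime: columns matched by any scenario's atoms are recomputed
  has_atoms <- which(vapply(densities, function(d) nrow(d$atoms) > 0, logical(1)))
  atom_cols <- integer()
  if (length(has_atoms)) {
    for (j in has_atoms) {
      d <- densities[[j]]
      for (r in seq_len(nrow(d$atoms))) {
        loc <- d$atoms$location[r]
        cols <- if (loc == 0) which(grid <= d$floor)
                else which(abs(grid - loc) <= 1e-8 * max(1, loc))
        atom_cols <- union(atom_cols, cols)
      }
    }
    for (col in atom_cols) {
      p <- posterior_at(grid[col], scen$prior, densities)
      post[, col] <- as.numeric(p)
      marg[col] <- if (isTRUE(attr(p, "undefined"))) 0 else
        sum(scen$prior * vapply(densities, .atom_match, numeric(1), c = grid[col]))
    }
  }
  lmarg <- grid * marg   # marginal per unit log-concentration
  defined <- is.finite(lmarg) & lmarg > support_floor * max(lmarg, na.rm = TRUE)
  # atom-regime columns are exact, never extrapolated: keep them defined
  if (length(atom_cols)) defined[atom_cols] <- marg[atom_cols] > 0
  post[, !defined] <- NA_real_
  structure(list(grid = grid, posteriors = post, marginal = marg,
                 defined = defined, bits = scen$bits, priors = scen$prior),
            class = "posterior_curves")
}

#' @export
print.posterior_curves <- function(x, ...) {
  cat(sprintf("<posterior_curves> %d scenarios x %d grid points (%.3g-%.3g mg/L), %d defined\n",
              nrow(x$posteriors), length(x$grid), min(x$grid), max(x$grid),
              sum(x$defined)))
  invisible(x)
}

#' Discrimination thresholds between dosing scenarios
#'
#' Partitions the concentration axis into most-probable-scenario intervals
#' (ties broken toward the lower bitstring, i.e. more missed doses) and
#' locates each boundary - the concentration at which the posterior
#' probabilities of the two adjacent scenarios are equal - by linear
#' interpolation of their posterior difference between the bracketing grid
#' points. Scenarios never most probable anywhere are reported as absent,
#' not an error; indistinguishable scenario sets yield a degenerate
#' single-interval partition, flagged.
#'
#' @param curves A `posterior_curves`.
#' @param pairwise Also compute every pairwise posterior crossing
#'   (diagnostics; default FALSE).
#' @return Object of class `threshold_set`: `thresholds` (data.frame with
#'   `below`, `above`, `crossing` in mg/L), `partition` (data.frame with
#'   `bits`, `lower`, `upper`), `absent`, `degenerate`, and optionally
#'   `pairwise`.
#' @export
find_thresholds <- function(curves, pairwise = FALSE) {
  idx <- which(curves$defined)
  if (!length(idx)) {
    # purely atomic world (e.g. zero variability): no continuous support
    return(structure(list(
      thresholds = data.frame(below = character(), above = character(),
                              crossing = numeric(), stringsAsFactors = FALSE),
      partition = data.frame(bits = character(), lower = numeric(),
                             upper = numeric(), stringsAsFactors = FALSE),
      absent = curves$bits, degenerate = TRUE), class = "threshold_set"))
  }
  post <- curves$posteriors[, idx, drop = FALSE]
  grid <- curves$grid[idx]
  mp <- apply(post, 2, which.max)  # first maximum = lowest bitstring on ties
  runs <- rle(mp)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  th <- data.frame(below = character(), above = character(),
                   crossing = numeric(), stringsAsFactors = FALSE)
  if (length(runs$values) > 1) {
    for (r in seq_len(length(runs$values) - 1)) {
      a <- runs$values[r]; b <- runs$values[r + 1]
      i1 <- ends[r]; i2 <- starts[r + 1]
      d1 <- post[a, i1] - post[b, i1]
      d2 <- post[a, i2] - post[b, i2]
      cross <- if (is.finite(d1) && is.finite(d2) && (d1 - d2) != 0)
        grid[i1] + (grid[i2] - grid[i1]) * d1 / (d1 - d2) else (grid[i1] + grid[i2]) / 2
      th <- rbind(th, data.frame(below = curves$bits[a], above = curves$bits[b],
                                 crossing = cross, stringsAsFactors = FALSE))
    }
  }
  bounds <- c(grid[1], th$crossing, grid[length(grid)])
  part <- data.frame(bits = curves$bits[runs$values],
                     lower = head(bounds, -1), upper = tail(bounds, -1),
                     stringsAsFactors = FALSE)
  out <- structure(list(thresholds = th, partition = part,
                        absent = setdiff(curves$bits, part$bits),
                        degenerate = length(runs$values) == 1),
                   class = "threshold_set")
  if (pairwise) {
    pw <- data.frame(a = character(), b = character(), crossing = numeric(),
                     stringsAsFactors = FALSE)
    nb <- length(curves$bits)
    for (a in seq_len(nb - 1)) for (b in (a + 1):nb) {
      diffs <- post[a, ] - post[b, ]
      sgn <- which(diff(sign(diffs)) != 0)
      for (i in sgn) {
        d1 <- diffs[i]; d2 <- diffs[i + 1]
        pw <- rbind(pw, data.frame(
          a = curves$bits[a], b = curves$bits[b],
          crossing = grid[i] + (grid[i + 1] - grid[i]) * d1 / (d1 - d2),
          stringsAsFactors = FALSE))
      }
    }
    out$pairwise <- pw
  }
  out
}

#' @export
print.threshold_set <- function(x, ...) {
  if (x$degenerate) cat("<threshold_set> degenerate (single most-probable scenario)\n")
  else {
    cat("<threshold_set> most-probable partition (mg/L):\n")
    p <- x$partition
    for (i in seq_len(nrow(p)))
      cat(sprintf("  %6.3g - %6.3g : w%s\n", p$lower[i], p$upper[i], p$bits[i]))
  }
  if (length(x$absent))
    cat("  never most probable:", paste0("w", x$absent, collapse = ", "), "\n")
  invisible(x)
}

#' Classify retrodiction ability of a posterior curve set
#'
#' The 80% rule: `complete` retrodiction when every scenario's maximum
#' posterior probability over the concentration axis reaches the cutoff;
#' `none` when at most one scenario reaches it; `partial` otherwise
#' (typically only the fully adherent and fully nonadherent scenarios
#' reach it).
#'
#' @param curves A `posterior_curves`.
#' @param cutoff Posterior probability cutoff (default 0.8).
#' @return Object of class `retrodiction`: list with `label` (one of
#'   `"complete"`, `"partial"`, `"none"`), `max_posterior` (named vector)
#'   and `cutoff`.
#' @export
classify_retrodiction <- function(curves, cutoff = 0.8) {
  if (!any(curves$defined)) {
    return(structure(list(label = "none",
                          max_posterior = setNames(rep(NA_real_,
                                                       length(curves$bits)),
                                                   curves$bits),
                          cutoff = cutoff), class = "retrodiction"))
  }
  mx <- apply(curves$posteriors[, curves$defined, drop = FALSE], 1,
              function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  mx <- setNames(mx, curves$bits)
  n_hit <- sum(mx >= cutoff, na.rm = TRUE)
  label <- if (n_hit == length(mx)) "complete"
           else if (n_hit <= 1) "none" else "partial"
  structure(list(label = label, max_posterior = mx, cutoff = cutoff),
            class = "retrodiction")
}

#' @export
print.retrodiction <- function(x, ...) {
  cat(sprintf("<retrodiction> %s (cutoff %.0f%%)\n", x$label, 100 * x$cutoff))
  print(round(x$max_posterior, 3))
  invisible(x)
}
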