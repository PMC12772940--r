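# Dosing-behavior hypotheses: bitstrings omega over the last n scheduled
# doses, most-recent-first (first digit = last dose before sampling;
# 1 = taken, 0 = missed).

#' Enumerate all dosing scenarios over the last n doses
#'
#' Generates the full set of 2^n scenario bitstrings in canonical
#' lexicographic order ("00" < "01" < "10" < "11"). Digits are ordered
#' most-recent-first: the i-th digit describes the i-th most recent
#' scheduled dose before sampling (1 = taken, 0 = missed).
#'
#' @param n Number of considered dose slots, 1..10.
#' @return Object of class `scenario_set`: list with `n`, `bits`
#'   (character vector of length 2^n) and `prior` (NA until
#'   [assign_priors()] is called).
#' @export
enumerate_scenarios <- function(n) {
  if (!.is_count(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (n > 10) stop("n capped at 10 (2^n scenarios become impractical)", call. = FALSE)
  n <- as.integer(n)
  bits <- vapply(0:(2^n - 1), function(i)
    paste(rev(as.integer(intToBits(i))[1:n]), collapse = ""), character(1))
  structure(list(n = n, bits = sort(bits), prior = rep(NA_real_, 2^n)),
            class = "scenario_set")
}

#' Assign prior probabilities to a scenario set
#'
#' Modes: `"equal"` gives every scenario prior 2^-n (the maximum-uncertainty
#' default); `"per_dose"` treats each dose as independently taken with
#' probability `p`, so prior(omega) = p^(#1s) * (1-p)^(#0s); `"custom"`
#' takes a named table over bitstrings, normalized to sum to 1.
#'
#' @param set A `scenario_set`.
#' @param mode `"equal"`, `"per_dose"` or `"custom"`.
#' @param p Per-dose adherence probability in (0, 1) (per_dose mode).
#' @param table Named numeric over all bitstrings (custom mode).
#' @return The `scenario_set` with priors summing to 1.
#' @export
assign_priors <- function(set, mode = c("equal", "per_dose", "custom"),
                          p = NULL, table = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "scenario_set"))
  if (mode == "equal") {
    set$prior <- rep(1 / length(set$bits), length(set$bits))
  } else if (mode == "per_dose") {
    if (is.null(p) || p <= 0 || p >= 1)
      stop("per_dose mode requires p in (0, 1)", call. = FALSE)
    ones <- nchar(gsub("0", "", set$bits))
    set$prior <- p^ones * (1 - p)^(set$n - ones)
    set$prior <- set$prior / sum(set$prior)
  } else {
    if (is.null(table) || is.null(names(table)))
      stop("custom mode requires a named prior table", call. = FALSE)
    missing <- setdiff(set$bits, names(table))
    if (length(missing))
      stop(sprintf("custom priors missing scenario(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    w <- as.numeric(table[set$bits])
    if (any(w < 0)) stop("custom priors must be nonnegative", call. = FALSE)
    if (sum(w) <= 0) stop("custom priors must not all be zero", call. = FALSE)
    set$prior <- w / sum(w)
  }
  stopifnot(abs(sum(set$prior) - 1) < 1e-12)
  set
}

#' @export
print.scenario_set <- function(x, ...) {
  cat(sprintf("<scenario_set> n = %d (%d scenarios)\n", x$n, length(x$bits)))
  print(data.frame(scenario = paste0("w", x$bits), prior = x$prior),
        row.names = FALSE)
  invisible(x)
}

#' Translate a scenario bitstring into an edited dose history
#'
#' Digit i (1-indexed from the left, i.e. the i-th most recent dose) equal
#' to 0 sets that terminal slot's amount to 0 (a missed dose keeps its slot,
#' preserving the schedule alignment); run-in doses are untouched. The
#' full-adherence bitstring returns the base history unchanged.
#'
#' @param base A `dose_history` from [steady_state_history()].
#' @param bits Scenario bitstring (length must not exceed the editable
#'   slots of `base`).
#' @return The edited `dose_history`.
#' @export
scenario_history <- function(base, bits) {
  slots <- attr(base, "slots")
  digits <- strsplit(bits, "")[[1]]
  if (!all(digits %in% c("0", "1")))
    stop("scenario bits must be a string over {0,1}", call. = FALSE)
  if (length(digits) > length(slots))
    stop(sprintf("scenario has %d digits but the history has only %d editable slots",
                 length(digits), length(slots)), call. = FALSE)
  for (i in seq_along(digits)) {
    # digit i = i-th most recent dose = i-th slot from the end
    if (digits[i] == "0") base$amount[slots[length(slots) - i + 1]] <- 0
  }
  base
}
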