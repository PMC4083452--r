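# Seed plumbing: every stage draws from a seed derived deterministically from
# the master seed so stages can be re-run in isolation.

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic, collision-unlikely mapping of (master seed, stage label) to
#' a 31-bit positive integer suitable for `set.seed()`.
#'
#' @param master Integer master seed.
#' @param stage Character stage label (e.g. `"cohort"`, `"asl/p003"`).
#' @return A single positive integer below 2^31.
#' @export
#' @examples
#' derive_seed(1, "cohort")
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1, is.finite(master), is.character(stage))
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h + 1)
}

# Truncated-normal draw via inverse CDF (lower truncation only).
rnorm_trunc_lower <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

# Truncated-normal draw with upper truncation only.
rnorm_trunc_upper <- function(n, mean, sd, upper) {
  p_hi <- stats::pnorm(upper, mean, sd)
  u <- runif(n, 0, p_hi)
  stats::qnorm(u, mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
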