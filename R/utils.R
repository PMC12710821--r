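# internal helpers shared across modules

# Deterministic per-stage seed derivation from one master seed.
# Keeps results of partial reruns identical to the full pipeline.
.deriveSeed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 7919 + h * 104729) %% .Machine$integer.max)
}

.setSeedIfGiven <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Truncated-normal sampler by inverse-CDF (exact, no rejection loop).
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  .clamp(stats::qnorm(u, mean, sd), lower, upper)
}

.isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
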