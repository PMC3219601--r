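# Internal helpers shared across modules.

# Derive a per-stage seed from a root seed; stays inside 32-bit integer range.
.stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 7919 + stage * 104729) %% 2147483647L)
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

# Haldane-Anscombe corrected odds ratio for a 2x2 table (display only; the
# exact Fisher p never uses the correction).
.odds_ratio <- function(a, b, c, d) {
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(or = (a * d) / (b * c), corrected = corrected)
}
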