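# Calendar conventions used throughout: months and years are fixed-length
# (1 month = 30.44 days, 1 year = 365.25 days) so window rules are exact
# arithmetic on dates rather than calendar-dependent.
DAYS_PER_MONTH <- 30.44
DAYS_PER_YEAR <- 365.25

# DAS28-BSR instrument range; every generated or forecast score is clamped here.
DAS28_MIN <- 0
DAS28_MAX <- 9.4

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a stage seed from a master seed
#'
#' All stochastic stages (registry simulation, fold assignment, weight
#' initialisation, minibatch shuffling) draw their seed from one master seed
#' through this map, so any stage can be reproduced in isolation.
#'
#' @param master_seed integer master seed.
#' @param stage character stage label.
#' @param k optional integer sub-index (e.g. fold or replicate number).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, stage, k = 0L) {
  h <- fnv1a32(paste(master_seed, stage, k, sep = "/"))
  # keep strictly below 2^31 and non-negative
  as.integer(h %% 2147483647)
}

# 32-bit FNV-1a hash, implemented over doubles (exact for 32-bit arithmetic
# via modular reduction after each multiply).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # bitwXor works on 32-bit signed ints; route through a safe representation
  ai <- as.integer(a %% 2147483648) # low 31 bits
  hi <- (a %/% 2147483648) %% 2
  r <- bitwXor(ai, as.integer(b))
  r + hi * 2147483648
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_anet <- function(..., class = "anet_error") {
  stop(errorCondition(paste0(...), class = c(class, "anet_error")))
}
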