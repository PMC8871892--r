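# Named random-number substreams.
#
# Every stochastic element (arrivals per class, each station's service draws,
# attribute assignment, downtime episodes, server selection) consumes its own
# substream whose seed is derived deterministically from the master seed, the
# replication index and a stream name. Scenarios that share a master seed
# therefore share attribute and service draws patient-for-patient (common
# random numbers), which reduces the variance of scenario-vs-base comparisons.

# 31-bit deterministic hash of a string (exact in double arithmetic).
.str_hash <- function(name) {
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% 2147483647
  h
}

#' Derive a substream seed from a master seed
#'
#' Deterministically maps `(master, rep, name)` to an integer seed in
#' `[1, 2^31 - 2]`. Distinct stream names or replication indices give
#' (for practical purposes) unrelated seeds.
#'
#' @param master integer master seed.
#' @param rep replication index (>= 1).
#' @param name character stream name, e.g. `"arrivals/public"`.
#' @return a single integer seed.
#' @export
substream_seed <- function(master, rep, name) {
  h <- .str_hash(name)
  s <- (as.numeric(master) %% 2147483647) * 48271 %% 2147483647
  s <- (s + as.numeric(rep) * 16807) %% 2147483647
  s <- (s * 69621 + h) %% 2147483647
  as.integer(s %% 2147483645 + 1)
}

# Evaluate expr with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
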