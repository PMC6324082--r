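# Minimal seeded RNG (Park-Miller minstd LCG) kept separate from R's global
# RNG stream so that generated fixtures are byte-identical across platforms
# and unaffected by the caller's set.seed() state.

.lcg_new <- function(seed) {
  state <- (as.numeric(seed) %% 2147483646) + 1  # in [1, 2147483646]
  env <- new.env(parent = emptyenv())
  env$state <- state
  env
}

# uniform draws in (0, 1)
.lcg_unif <- function(rng, n = 1L) {
  out <- numeric(n)
  s <- rng$state
  for (i in seq_len(n)) {
    s <- (16807 * s) %% 2147483647
    out[i] <- s / 2147483647
  }
  rng$state <- s
  out
}

# integer in 1..k
.lcg_int <- function(rng, k, n = 1L) {
  pmin(floor(.lcg_unif(rng, n) * k) + 1L, k)
}

# Fisher-Yates permutation of 1..n
.lcg_shuffle <- function(rng, n) {
  out <- seq_len(n)
  if (n < 2L) return(out)
  for (i in n:2) {
    j <- .lcg_int(rng, i)
    tmp <- out[i]; out[i] <- out[j]; out[j] <- tmp
  }
  out
}

.lcg_bernoulli <- function(rng, p, n = 1L) {
  .lcg_unif(rng, n) < p
}
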