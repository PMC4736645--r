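# Shared helpers: small parameter sets and randomly populated worlds.

params_3x3 <- function(...) {
  sim_params(width = 3, height = 3, ...)
}

# a reproducible random world with mixed production rates
random_world <- function(H = 8, W = 8, density = 0.6, seed = 1,
                         p_max = 10) {
  rng <- rng_stream(seed)
  w <- world_state(W, H)
  u <- matrix(rng_uniform(rng, H * W), H, W)
  occ <- u < density
  sites <- which(occ, arr.ind = TRUE)
  if (nrow(sites) > 0) {
    p <- rng_uniform(rng, nrow(sites)) * p_max
    w <- place_individuals(w, sites, p, strain = seq_len(nrow(sites)))
  }
  w
}

# binomial 3-sigma check helper
expect_binomial_3sigma <- function(successes, n, prob) {
  sd3 <- 3 * sqrt(n * prob * (1 - prob))
  expect_lt(abs(successes - n * prob), max(sd3, 1e-9))
}
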