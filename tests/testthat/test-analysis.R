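test_that("production_histogram bins correctly at the edges", {
  w <- place_individuals(world_state(5, 5), cbind(3, 3), p = 10)
  h <- production_histogram(w, 10)
  expect_equal(h$counts[10], 1)     # p = p_max lands in the last bin
  expect_equal(sum(h$counts), 1)

  expect_equal(sum(production_histogram(world_state(5, 5), 10)$counts), 0)

  w2 <- place_individuals(world_state(5, 5), rbind(c(2, 2), c(4, 4)),
                          p = c(0, 10))
  h2 <- production_histogram(w2, 10)
  expect_equal(h2$counts[c(1, 10)], c(1, 1))
  expect_equal(sum(h2$counts), 2)

  expect_error(production_histogram(w, 1), "n_bins")
})

test_that("histogram mass always equals population size", {
  for (seed in 1:5) {
    w <- random_world(12, 12, density = runif(1, 0.2, 0.9), seed = seed)
    h <- production_histogram(w, 37)
    expect_equal(sum(h$counts), population_size(w))
  }
})

test_that("classify_lineages splits at the threshold and is threshold-monotone", {
  w <- place_individuals(world_state(5, 5),
                         rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 4)),
                         p = c(0, 0.1, 6, 7))
  cl <- classify_lineages(w, 1.0)
  expect_equal(cl$selfish_fraction, 0.5)
  expect_equal(cl$cooperator_fraction, 0.5)
  expect_equal(cl$mean_p_selfish, 0.05)
  expect_equal(cl$mean_p_cooperator, 6.5)
  expect_equal(cl$selfish_fraction + cl$cooperator_fraction, 1)

  all_coop <- place_individuals(world_state(4, 4),
                                as.matrix(expand.grid(1:4, 1:4)), p = 6)
  expect_equal(classify_lineages(all_coop, 1)$cooperator_fraction, 1)
  all_self <- place_individuals(world_state(4, 4),
                                as.matrix(expand.grid(1:4, 1:4)), p = 0)
  expect_equal(classify_lineages(all_self, 1)$selfish_fraction, 1)

  empty <- classify_lineages(world_state(4, 4), 1)
  expect_true(empty$empty)
  expect_equal(empty$selfish_fraction + empty$cooperator_fraction, 0)

  # monotone in the threshold
  w <- random_world(10, 10, density = 0.7, seed = 8)
  fr <- vapply(seq(0.5, 9.5, by = 1),
               function(th) classify_lineages(w, th)$selfish_fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("detect_bimodality separates well-split modes and rejects near-misses", {
  # all mass in one bin
  one <- c(rep(0, 4), 100, rep(0, 5))
  expect_equal(detect_bimodality(one)$modality, "unimodal")

  # 45% at bin 1, 45% at bin 9, plus a bit elsewhere
  two <- c(45, 0, 0, 0, 0, 0, 0, 0, 45, 10)
  r <- detect_bimodality(two)
  expect_equal(r$modality, "bimodal")
  expect_equal(r$modes, c(0.5, 8.5))

  # two adjacent populated bins: gap requirement unmet
  adj <- c(0, 0, 50, 50, 0, 0, 0, 0, 0, 0)
  expect_equal(detect_bimodality(adj)$modality, "unimodal")

  # empty histogram
  r0 <- detect_bimodality(rep(0, 10))
  expect_equal(r0$modality, "unimodal")
  expect_true(r0$empty)

  # second mode below the mass floor is ignored
  tiny <- c(96, 0, 0, 0, 0, 0, 0, 0, 0, 2)
  expect_equal(detect_bimodality(tiny, min_mode_mass = 0.05)$modality,
               "unimodal")

  # mixture of two separated narrow distributions (constructed fixture)
  set.seed(1)
  pv <- c(pmax(0, rnorm(400, 0.2, 0.15)), pmin(10, rnorm(600, 6, 0.4)))
  w <- place_individuals(world_state(40, 40),
                         which(matrix(TRUE, 40, 40), arr.ind = TRUE)[1:1000, ],
                         p = pv)
  h <- production_histogram(w, 50)
  expect_equal(detect_bimodality(h)$modality, "bimodal")

  # a single narrow distribution is unimodal
  w1 <- place_individuals(world_state(40, 40),
                          which(matrix(TRUE, 40, 40), arr.ind = TRUE)[1:1000, ],
                          p = pmin(10, pmax(0, rnorm(1000, 5, 0.4))))
  expect_equal(detect_bimodality(production_histogram(w1, 50))$modality,
               "unimodal")
})

test_that("extinction_time finds the first zero-population sample", {
  tr <- data.frame(t = 0:3, population_size = c(10, 4, 0, 0),
                   mean_p = c(5, 5, NA, NA))
  expect_equal(extinction_time(tr), 2L)
  tr2 <- data.frame(t = 0:3, population_size = c(10, 4, 2, 1))
  expect_true(is.na(extinction_time(tr2)))
  tr3 <- data.frame(t = 0:2, population_size = c(0, 0, 0))
  expect_equal(extinction_time(tr3), 0L)
})

test_that("distribution_heatmap stacks histograms consistently", {
  pars <- sim_params(width = 10, height = 10, cost = 2)
  w <- random_world(10, 10, density = 0.6, seed = 12)
  res <- run_simulation(w, pars, 20, rng_stream(4), sample_every = 5,
                        n_bins = 10)
  hm <- distribution_heatmap(res)
  expect_equal(nrow(hm), nrow(res$trajectory))
  # row sums equal population sizes when un-normalised
  expect_equal(unname(rowSums(hm)), res$trajectory$population_size)
  hmn <- distribution_heatmap(res, normalise = TRUE)
  expect_equal(unname(rowSums(hmn)[res$trajectory$population_size > 0]),
               rep(1, sum(res$trajectory$population_size > 0)))

  # single-record trajectory -> single row equal to its histogram
  res0 <- run_simulation(w, pars, 0, rng_stream(4), n_bins = 10)
  hm0 <- distribution_heatmap(res0)
  expect_equal(nrow(hm0), 1)
  expect_equal(as.numeric(hm0[1, ]),
               production_histogram(w, 10)$counts)
})
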