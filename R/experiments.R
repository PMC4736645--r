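#' Evolutionary run from a homogeneous highly-producing population
#'
#' Seeds the lattice uniformly at random at density `init_density`, with
#' every individual starting at production rate `init_p`, and runs the full
#' evolutionary dynamics (mutation on). The default initial condition is a
#' fully occupied lattice of maximal producers, the configuration from
#' which the high-cost regime shows its characteristic collapse,
#' re-expansion and speciation into a cooperative and a selfish lineage.
#'
#' @param params A [sim_params()]; lattice geometry is taken from it.
#' @param n_steps Number of Monte-Carlo steps.
#' @param rng An [rng_stream()]; if missing, one is created from
#'   `params$seed`.
#' @param init_density Initial occupation fraction, in `(0, 1]`.
#' @param init_p Initial production rate of all founders (default
#'   `p_max`).
#' @param sample_every,n_bins Trajectory sampling controls, see
#'   [run_simulation()].
#' @param variant Optional [variant_config()].
#' @return A `sim_result` (see [run_simulation()]).
#' @export
evolutionary_run <- function(params, n_steps, rng = rng_stream(params$seed),
                             init_density = 1.0, init_p = params$p_max,
                             sample_every = 200L, n_bins = 50L,
                             variant = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (init_density < 0 || init_density > 1)
    stop("`init_density` must be in [0, 1]")
  if (init_p < 0 || init_p > params$p_max)
    stop("`init_p` must be in [0, p_max]")
  w <- world_state(params$width, params$height)
  w <- seed_world(w, init_density, init_p, rng, boundary = params$boundary)
  run_simulation(w, params, n_steps, rng, sample_every = sample_every,
                 n_bins = n_bins, variant = variant)
}

#' Steady-state production across a grid of costs
#'
#' Runs one [evolutionary_run()] per cost and per seed, discards a burn-in
#' fraction of each trajectory, and pools the remaining production
#' histograms into a per-cost steady-state distribution and mean. Runs that
#' went extinct are flagged and excluded from the pooled distribution.
#'
#' @param base_params A [sim_params()]; `cost` is overridden per grid point.
#' @param costs Numeric vector of costs to sweep.
#' @param n_steps Steps per run.
#' @param seeds Integer vector; one replicate run per seed.
#' @param burn_in Fraction of each trajectory discarded before pooling
#'   (default first 50%).
#' @param sample_every,n_bins See [run_simulation()].
#' @param progress If `TRUE`, report each completed run via [message()].
#' @return An object of class `cost_sweep`: list with `summary` (data frame
#'   with one row per cost x seed: `cost`, `seed`, `mean_p`, `final_pop`,
#'   `extinct`), `distributions` (matrix of pooled post-burn-in histogram
#'   counts, one row per cost), `mean_p` (named per-cost means pooled over
#'   seeds), `bin_edges`, and the arguments used.
#' @export
cost_sweep <- function(base_params, costs, n_steps, seeds = 1:3,
                       burn_in = 0.5, sample_every = 500L, n_bins = 50L,
                       progress = FALSE) {
  stopifnot(inherits(base_params, "sim_params"), length(costs) >= 1)
  if (burn_in < 0 || burn_in >= 1) stop("`burn_in` must be in [0, 1)")
  rows <- list()
  dists <- matrix(0, length(costs), n_bins,
                  dimnames = list(format(costs), NULL))
  pooled_sum <- numeric(length(costs))
  pooled_n <- numeric(length(costs))
  for (ci in seq_along(costs)) {
    for (s in seeds) {
      pars <- update_params(base_params, cost = costs[ci], seed = s)
      t_run <- proc.time()[3]
      res <- evolutionary_run(pars, n_steps, rng = rng_stream(s),
                              sample_every = sample_every, n_bins = n_bins)
      if (progress)
        message(sprintf("cost %g seed %s: %.0f s%s", costs[ci], format(s),
                        proc.time()[3] - t_run,
                        if (res$extinct) " (extinct)" else ""))
      tr <- res$trajectory
      keep <- tr$t > burn_in * n_steps
      bins <- as.matrix(tr[keep, grep("^bin_", names(tr)), drop = FALSE])
      counts <- colSums(bins)
      mids <- attr(tr, "bin_edges")
      mids <- (mids[-1] + mids[-length(mids)]) / 2
      mp <- if (sum(counts) > 0) sum(counts * mids) / sum(counts) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        cost = costs[ci], seed = s, mean_p = mp,
        final_pop = population_size(res$world), extinct = res$extinct)
      if (!res$extinct) {
        dists[ci, ] <- dists[ci, ] + counts
        pooled_sum[ci] <- pooled_sum[ci] + sum(counts * mids)
        pooled_n[ci] <- pooled_n[ci] + sum(counts)
      }
    }
  }
  mean_p <- ifelse(pooled_n > 0, pooled_sum / pooled_n, NA_real_)
  names(mean_p) <- format(costs)
  out <- list(
    summary = do.call(rbind, rows),
    distributions = dists,
    mean_p = mean_p,
    bin_edges = seq(0, base_params$p_max, length.out = n_bins + 1),
    costs = costs, seeds = seeds, n_steps = n_steps, burn_in = burn_in
  )
  class(out) <- "cost_sweep"
  out
}

#' @export
print.cost_sweep <- function(x, ...) {
  cat("<cost_sweep>", length(x$costs), "costs x", length(x$seeds),
      "seeds,", x$n_steps, "steps each\n")
  ext <- vapply(x$costs,
                function(cc) any(x$summary$extinct[x$summary$cost == cc]),
                logical(1))
  df <- data.frame(cost = x$costs, mean_p = round(unname(x$mean_p), 3),
                   any_extinct = ext)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Invasion scenario for the strip assays
#'
#' Describes a mutation-free invasion experiment on a long narrow strip
#' with no-flux absorbing boundaries: either cooperators expanding into
#' empty space, or selfish individuals invading a homogeneous resident
#' population of cooperators. The invading population is seeded in the
#' first `seed_cols` interior columns; arrival is detected on the last
#' interior column at the far end, and the invasion rate is the invaded
#' length divided by the arrival time.
#'
#' @param kind `"cooperators_into_empty"` or `"selfish_into_cooperators"`.
#' @param invader_p Production rate of the invading strain.
#' @param resident_p Production rate of the resident cooperators (required
#'   for `"selfish_into_cooperators"`, unused otherwise).
#' @param cost,b Cost and benefit per unit public good for the assay.
#' @param strip_length,strip_width Strip dimensions in nodes (length along
#'   the invasion axis; `strip_length` should be much larger than
#'   `strip_width`).
#' @param seed_cols Number of interior columns initially given to the
#'   invader.
#' @return An object of class `invasion_scenario`.
#' @export
invasion_scenario <- function(kind = c("cooperators_into_empty",
                                       "selfish_into_cooperators"),
                              invader_p, resident_p = NULL,
                              cost = 4, b = 10,
                              strip_length = 512L, strip_width = 32L,
                              seed_cols = 8L) {
  kind <- match.arg(kind)
  if (kind == "selfish_into_cooperators" && is.null(resident_p))
    stop("`resident_p` is required when selfish individuals invade cooperators")
  if (strip_length < seed_cols + 4 || strip_width < 3)
    stop("degenerate strip geometry")
  structure(list(kind = kind, invader_p = as.numeric(invader_p),
                 resident_p = if (is.null(resident_p)) NULL
                              else as.numeric(resident_p),
                 cost = cost, b = b,
                 strip_length = as.integer(strip_length),
                 strip_width = as.integer(strip_width),
                 seed_cols = as.integer(seed_cols)),
            class = "invasion_scenario")
}

# internal: build the initial strip world for an invasion/competition assay.
# Interior = rows 2..H-1, cols 2..W-1; the 1-node edge ring absorbs.
strip_world <- function(strip_length, strip_width) {
  world_state(strip_length, strip_width)
}

strip_params <- function(params, scenario) {
  update_params(params,
                cost = scenario$cost, b = scenario$b, mu = 0,
                width = scenario$strip_length, height = scenario$strip_width,
                boundary = "no_flux")
}

#' Measure an invasion rate on a strip
#'
#' Runs the scenario until the invading strain first occupies the
#' detection column (the last interior column), the invader goes extinct,
#' or `max_steps` elapses. The invasion rate is the invaded length (from
#' the far edge of the seeded region to the detection column) divided by
#' the arrival time, in nodes per Monte-Carlo step. Mutation is off and
#' boundaries are no-flux absorbing.
#'
#' @param scenario An [invasion_scenario()].
#' @param params A [sim_params()] supplying the remaining constants
#'   (`k_death`, `k_move`, `p_max`, altruism mode); cost, benefit, geometry,
#'   boundary and `mu = 0` are taken from / forced by the scenario.
#' @param rng An [rng_stream()].
#' @param max_steps Timeout in Monte-Carlo steps.
#' @param sample_every Trajectory sampling interval.
#' @return An object of class `invasion_measurement`: list with the
#'   scenario, `arrival_time`, `invaded_length`, `invasion_rate` (0 if the
#'   invader died out, NA on timeout), `invader_extinct`, `timed_out` and
#'   the full `sim_result`.
#' @export
invasion_assay <- function(scenario, params = sim_params(), rng,
                           max_steps = 50000L, sample_every = 500L) {
  stopifnot(inherits(scenario, "invasion_scenario"),
            inherits(rng, "rng_stream"))
  pars <- strip_params(params, scenario)
  H <- scenario$strip_width
  W <- scenario$strip_length
  w <- strip_world(W, H)
  interior_rows <- 2:(H - 1)
  seed_cols <- 2:(1 + scenario$seed_cols)
  if (scenario$kind == "selfish_into_cooperators") {
    resident <- as.matrix(expand.grid(interior_rows, 2:(W - 1)))
    w <- place_individuals(w, resident, p = scenario$resident_p, strain = 0L)
  }
  invader <- as.matrix(expand.grid(interior_rows, seed_cols))
  w <- place_individuals(w, invader, p = scenario$invader_p, strain = 1L)

  detect_col <- W - 1L                       # last interior column (1-based)
  invaded_length <- detect_col - max(seed_cols)
  res <- kernel_steps(w, pars, max_steps, rng, sample_every = sample_every,
                      detect_col = detect_col - 1L, detect_label = 1L)
  res <- build_sim_result(res, pars, NULL, 50L)

  arrival <- res$arrival_step
  out <- list(
    scenario = scenario,
    arrival_time = arrival,
    invaded_length = invaded_length,
    invasion_rate = if (!is.na(arrival)) invaded_length / arrival
                    else if (res$invader_lost || res$extinct) 0
                    else NA_real_,
    invader_extinct = res$invader_lost || res$extinct,
    timed_out = is.na(arrival) && !(res$invader_lost || res$extinct),
    result = res
  )
  class(out) <- "invasion_measurement"
  out
}

#' @export
print.invasion_measurement <- function(x, ...) {
  cat("<invasion_measurement>", x$scenario$kind, "\n")
  cat(sprintf("  invader p = %g, cost = %g, strip %d x %d\n",
              x$scenario$invader_p, x$scenario$cost,
              x$scenario$strip_length, x$scenario$strip_width))
  if (!is.na(x$arrival_time))
    cat(sprintf("  arrived at t = %d over %d nodes: rate = %.4f nodes/step\n",
                x$arrival_time, x$invaded_length, x$invasion_rate))
  else if (x$invader_extinct)
    cat("  invader went extinct before arrival (rate 0)\n")
  else cat("  timed out before arrival\n")
  invisible(x)
}

#' Invasion rates over a grid of costs and production rates
#'
#' Convenience wrapper running [invasion_assay()] for every combination of
#' cost and invader production rate, with several replicate seeds per cell.
#'
#' @param kind Scenario kind, see [invasion_scenario()].
#' @param production_rates,costs Grids to cross.
#' @param params Base [sim_params()].
#' @param seeds One replicate per seed.
#' @param resident_p Resident cooperator production (selfish scenario).
#' @param ... Passed to [invasion_scenario()] / [invasion_assay()].
#' @return Data frame with one row per cost x production x seed and columns
#'   `kind`, `cost`, `invader_p`, `seed`, `arrival_time`, `invasion_rate`,
#'   `invader_extinct`.
#' @export
invasion_grid <- function(kind, production_rates, costs,
                          params = sim_params(), seeds = 1:5,
                          resident_p = 6, ...) {
  rows <- list()
  for (cost in costs) for (p in production_rates) for (s in seeds) {
    sc <- invasion_scenario(kind, invader_p = p,
                            resident_p = if (kind == "selfish_into_cooperators")
                              resident_p else NULL,
                            cost = cost, ...)
    m <- invasion_assay(sc, params, rng_stream(s))
    rows[[length(rows) + 1]] <- data.frame(
      kind = kind, cost = cost, invader_p = p, seed = s,
      arrival_time = m$arrival_time, invasion_rate = m$invasion_rate,
      invader_extinct = m$invader_extinct)
  }
  do.call(rbind, rows)
}

#' Pairwise competition at the front or the back of a wave
#'
#' Two labelled strains with fixed production rates (mutation off) compete
#' on a strip. At the `"front"`, two cooperator blocks abreast expand into
#' empty space; at the `"back"`, two selfish blocks abreast invade a
#' homogeneous resident population of cooperators. The assay runs until one
#' strain fixes: either a strain disappears from the lattice entirely, or
#' the advancing wave reaches the far end of the strip, at which point the
#' strain holding the majority of the leading `front_depth` columns has won
#' the advancing region. A timeout (or an exact tie at arrival) is reported
#' as coexistence.
#'
#' @param position `"front"` or `"back"`.
#' @param strain_ps Length-2 numeric: production rates of strains A and B.
#' @param params Base [sim_params()].
#' @param rng An [rng_stream()].
#' @param resident_p Resident cooperator production rate (back assay).
#' @param cost,b Assay cost and benefit.
#' @param strip_length,strip_width,seed_cols Strip geometry, as in
#'   [invasion_scenario()].
#' @param front_depth Depth (columns) of the advancing region inspected for
#'   fixation.
#' @param check_every Steps between fixation checks.
#' @param max_steps Timeout.
#' @return An object of class `competition_outcome`: list with `position`,
#'   `strain_ps`, `winner` (`"A"`, `"B"` or `NA` on coexistence),
#'   `winner_p`, `outcome` (`"fixation"`, `"coexistence"`, `"extinct"`),
#'   and `t` (step at which the assay ended).
#' @export
competition_assay <- function(position = c("front", "back"), strain_ps,
                              params = sim_params(), rng,
                              resident_p = 6, cost = 4, b = 10,
                              strip_length = 512L, strip_width = 32L,
                              seed_cols = 8L, front_depth = 16L,
                              check_every = 25L, max_steps = 60000L) {
  position <- match.arg(position)
  stopifnot(length(strain_ps) == 2, inherits(rng, "rng_stream"))
  pars <- update_params(params, cost = cost, b = b, mu = 0,
                        width = strip_length, height = strip_width,
                        boundary = "no_flux")
  H <- as.integer(strip_width); W <- as.integer(strip_length)
  w <- strip_world(W, H)
  interior_rows <- 2:(H - 1)
  seed_cols_idx <- 2:(1 + seed_cols)
  if (position == "back") {
    resident <- as.matrix(expand.grid(interior_rows, 2:(W - 1)))
    w <- place_individuals(w, resident, p = resident_p, strain = 0L)
  }
  half <- interior_rows[seq_len(floor(length(interior_rows) / 2))]
  other <- setdiff(interior_rows, half)
  w <- place_individuals(w, as.matrix(expand.grid(half, seed_cols_idx)),
                         p = strain_ps[1], strain = 1L)
  w <- place_individuals(w, as.matrix(expand.grid(other, seed_cols_idx)),
                         p = strain_ps[2], strain = 2L)

  t_end <- NA_integer_
  winner <- NA_integer_
  outcome <- "coexistence"
  steps_done <- 0L
  while (steps_done < max_steps) {
    chunk <- min(check_every, max_steps - steps_done)
    res <- kernel_steps(w, pars, chunk, rng)
    w <- world_from_kernel(res)
    steps_done <- steps_done + chunk
    lab <- w$strain[w$occupancy != 0L]
    nA <- sum(lab == 1L); nB <- sum(lab == 2L)
    if (nA + nB == 0L) { outcome <- "extinct"; t_end <- w$t; break }
    if (nA == 0L || nB == 0L) {
      # one strain excluded everywhere: unambiguous fixation
      winner <- if (nA > 0L) 1L else 2L
      outcome <- "fixation"; t_end <- w$t; break
    }
    # when the advancing wave has crossed the strip, the strain holding
    # the leading front_depth columns has won the advancing region
    has_strain <- (w$strain == 1L | w$strain == 2L) & w$occupancy != 0L
    rc <- max(which(colSums(has_strain) > 0))
    if (rc >= W - 1L) {
      cols <- max(2L, rc - front_depth + 1L):rc
      reg <- has_strain[, cols, drop = FALSE]
      reg_lab <- w$strain[, cols, drop = FALSE][reg]
      nAr <- sum(reg_lab == 1L); nBr <- sum(reg_lab == 2L)
      t_end <- w$t
      if (nAr != nBr) {
        winner <- if (nAr > nBr) 1L else 2L
        outcome <- "fixation"
      }
      break
    }
  }
  if (is.na(t_end)) t_end <- w$t
  out <- list(position = position, strain_ps = strain_ps,
              winner = if (is.na(winner)) NA_character_
                       else c("A", "B")[winner],
              winner_p = if (is.na(winner)) NA_real_ else strain_ps[winner],
              outcome = outcome, t = t_end, world = w)
  class(out) <- "competition_outcome"
  out
}

#' @export
print.competition_outcome <- function(x, ...) {
  cat(sprintf("<competition_outcome> %s assay, p = (%g, %g): %s",
              x$position, x$strain_ps[1], x$strain_ps[2], x$outcome))
  if (x$outcome == "fixation")
    cat(sprintf(" of %s (p = %g) at t = %d", x$winner, x$winner_p, x$t))
  cat("\n")
  invisible(x)
}
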