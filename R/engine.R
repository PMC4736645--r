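#' Moore neighbours of a lattice site
#'
#' Under toroidal boundaries every site has exactly 8 neighbours
#' (wrap-around); under no-flux boundaries only the subset of the 8 that
#' lies inside the lattice is returned.
#'
#' @param world A [world_state()].
#' @param params A [sim_params()] (supplies the boundary rule).
#' @param site `c(row, col)`, 1-based.
#' @return Two-column integer matrix of neighbour (row, col) positions.
#' @export
neighbor_sites <- function(world, params, site) {
  check_world(world)
  site <- site_index(world, site)
  H <- nrow(world$occupancy)
  W <- ncol(world$occupancy)
  lin <- cpp_neighbor_sites(H, W, params$boundary == "toroidal",
                            site[1] - 1L, site[2] - 1L)
  cbind(row = lin %% H + 1L, col = lin %/% H + 1L)
}

#' Benefit collected by an individual
#'
#' The public good produced in a node's 3x3 neighbourhood is shared in
#' ninth parts; under weak altruism the focal individual receives its own
#' share \eqn{p_i/9} plus \eqn{p_j/9} from every occupied neighbour, so
#' \eqn{B_i = b\,(p_i + \sum_j p_j)/9}. Under strong altruism the own-good
#' term is excluded (see [sim_params()] for the share denominator). The
#' good is not accumulated over steps: the benefit is computed fresh from
#' the current state.
#'
#' @inheritParams neighbor_sites
#' @return Non-negative benefit; error if the site is empty.
#' @examples
#' w <- world_state(5, 5)
#' w <- place_individuals(w, cbind(3, 3), p = 9)
#' benefit(w, sim_params(), c(3, 3))  # isolated: b * 9/9 = 10
#' @export
benefit <- function(world, params, site) {
  check_world(world)
  site <- site_index(world, site)
  cpp_benefit(world$occupancy, world$production, params,
              site[1] - 1L, site[2] - 1L)
}

#' Fitness of an individual
#'
#' `f = max(0, B - cost * p)`: the difference between the benefit collected
#' from the neighbourhood and the cost of the individual's own production,
#' clamped at zero when costs exceed benefits.
#'
#' @inheritParams neighbor_sites
#' @return Non-negative fitness; error if the site is empty.
#' @export
fitness <- function(world, params, site) {
  check_world(world)
  site <- site_index(world, site)
  cpp_fitness(world$occupancy, world$production, params,
              site[1] - 1L, site[2] - 1L)
}

#' Replication lottery at an empty node
#'
#' The occupied Moore neighbours of an empty node compete to replicate into
#' it. Competitor `i` wins with probability
#' \eqn{f_i/f_{tot}\,(1 - e^{-f_{tot}})}, where \eqn{f_{tot}} is the summed
#' fitness of all competitors; with the residual probability
#' \eqn{e^{-f_{tot}}} nobody replicates, so replication is rare where little
#' public good is produced. With no competitors, or all fitnesses zero, the
#' result is always `NULL`.
#'
#' @inheritParams neighbor_sites
#' @param empty_site `c(row, col)` of an unoccupied node.
#' @param rng An [rng_stream()].
#' @return The winning competitor's `c(row, col)`, or `NULL` if nobody
#'   replicates; error if `empty_site` is occupied.
#' @export
select_replicator <- function(world, params, empty_site, rng) {
  check_world(world)
  site <- site_index(world, empty_site)
  lin <- cpp_select_replicator(world$occupancy, world$production, params,
                               site[1] - 1L, site[2] - 1L, rng$ptr)
  if (lin < 0) return(NULL)
  H <- nrow(world$occupancy)
  c(row = lin %% H + 1L, col = lin %/% H + 1L)
}

#' Mutate a production rate at replication
#'
#' With probability `mu` the offspring's production rate is shifted by a
#' uniform draw from `[-delta/2, delta/2]` and clipped to `[0, p_max]`;
#' otherwise it is inherited unchanged. Mutation happens only at
#' replication, never to survivors.
#'
#' @param p Parent production rate(s).
#' @param params A [sim_params()].
#' @param rng An [rng_stream()].
#' @return Offspring production rate(s), same length as `p`.
#' @export
mutate_production <- function(p, params, rng) {
  cpp_mutate_production(as.numeric(p), params, rng$ptr)
}

#' Movement event at an occupied node
#'
#' With probability `k_move` the node's content is swapped with that of one
#' of its 8 adjacent nodes, chosen uniformly (the target may be empty or
#' occupied). Under no-flux boundaries, moving onto the absorbing boundary
#' ring removes the individual from the population.
#'
#' @inheritParams neighbor_sites
#' @param rng An [rng_stream()].
#' @return The updated `world_state`, with attributes `moved` and `removed`.
#' @export
apply_move <- function(world, params, site, rng) {
  check_world(world)
  site <- site_index(world, site)
  res <- cpp_apply_move(world$occupancy, world$production, world$strain,
                        params, site[1] - 1L, site[2] - 1L, rng$ptr)
  out <- world_from_kernel(c(res[c("occupancy", "production", "strain")],
                             list(t = world$t)))
  attr(out, "moved") <- res$moved
  attr(out, "removed") <- res$removed
  out
}

#' Death event at an occupied node
#'
#' With probability `k_death` the node becomes empty. Death is independent
#' of fitness.
#'
#' @inheritParams apply_move
#' @return The updated `world_state`, with attribute `died`.
#' @export
apply_death <- function(world, params, site, rng) {
  check_world(world)
  site <- site_index(world, site)
  res <- cpp_apply_death(world$occupancy, world$production, world$strain,
                         params, site[1] - 1L, site[2] - 1L, rng$ptr)
  out <- world_from_kernel(c(res[c("occupancy", "production", "strain")],
                             list(t = world$t)))
  attr(out, "died") <- res$died
  out
}

variant_mode_int <- function(variant) {
  if (is.null(variant)) return(c(0L, 0L))
  stopifnot(inherits(variant, "variant_config"))
  mode <- switch(variant$mode, spatial = 0L, well_mixed = 1L, mix_from_t = 2L)
  c(mode, as.integer(variant$mix_start))
}

# internal: one or more Monte-Carlo steps through the C++ kernel
kernel_steps <- function(world, params, n_steps, rng, sample_every = 1L,
                         n_bins = 50L, variant = NULL, detect_col = -1L,
                         detect_label = -1L) {
  vm <- variant_mode_int(variant)
  cpp_run(world$occupancy, world$production, world$strain, world$t,
          params, as.integer(n_steps), as.integer(sample_every),
          as.integer(n_bins), vm[1], vm[2],
          as.integer(detect_col), as.integer(detect_label), rng$ptr)
}

#' One Monte-Carlo step
#'
#' Visits every lattice node exactly once in a fresh uniform random
#' permutation, applying events immediately (asynchronous updating). An
#' empty node runs the replication lottery among its occupied neighbours
#' and, on success, receives a (possibly mutated) copy of the winner; an
#' occupied node is tested for movement first and then for death at the
#' visited node. The time counter advances by one.
#'
#' @inheritParams apply_move
#' @return The updated `world_state` with `t` incremented by 1.
#' @export
monte_carlo_step <- function(world, params, rng) {
  check_world(world)
  res <- kernel_steps(world, params, 1L, rng)
  world_from_kernel(res)
}

#' Run a simulation
#'
#' Drives [monte_carlo_step()] (through the compiled kernel) for `n_steps`
#' steps, recording a summary of the state — population size, mean
#' production and a fixed-width production histogram — every `sample_every`
#' steps. The run terminates early if the population goes extinct.
#'
#' @param world Initial [world_state()].
#' @param params A [sim_params()].
#' @param n_steps Number of Monte-Carlo steps (>= 0).
#' @param rng An [rng_stream()]; identical seeds give identical output.
#' @param sample_every Sampling interval in steps.
#' @param n_bins Number of histogram bins on `[0, p_max]`.
#' @param variant Optional [variant_config()] switching on the well-mixed or
#'   mixing dynamics; `NULL` runs the plain spatial model.
#' @return An object of class `sim_result`: a list with elements
#'   `trajectory` (data frame with columns `t`, `population_size`, `mean_p`
#'   and `bin_*` histogram counts), `world` (final state), `extinct`,
#'   `extinction_step`, `params` and `variant`.
#' @examples
#' pars <- sim_params(cost = 1, width = 16, height = 16)
#' rng <- rng_stream(1)
#' w <- seed_world(world_state(16, 16), 1, pars$p_max, rng)
#' res <- run_simulation(w, pars, n_steps = 10, rng = rng)
#' tail(res$trajectory[, 1:3])
#' @export
run_simulation <- function(world, params, n_steps, rng, sample_every = 100L,
                           n_bins = 50L, variant = NULL) {
  check_world(world)
  stopifnot(inherits(params, "sim_params"), inherits(rng, "rng_stream"))
  if (n_steps < 0) stop("`n_steps` must be >= 0")
  res <- kernel_steps(world, params, n_steps, rng, sample_every, n_bins,
                      variant)
  build_sim_result(res, params, variant, n_bins)
}

# internal: dress kernel output as a sim_result
build_sim_result <- function(res, params, variant, n_bins) {
  traj <- as.data.frame(res$trajectory)
  names(traj) <- c("t", "population_size", "mean_p",
                   sprintf("bin_%02d", seq_len(n_bins)))
  attr(traj, "bin_edges") <- seq(0, params$p_max, length.out = n_bins + 1)
  out <- list(
    trajectory = traj,
    world = world_from_kernel(res),
    extinct = res$extinct,
    extinction_step = if (is.na(res$extinction_step)) NA_integer_
                      else as.integer(res$extinction_step),
    arrival_step = if (is.na(res$arrival_step)) NA_integer_
                   else as.integer(res$arrival_step),
    invader_lost = isTRUE(res$invader_lost),
    params = params,
    variant = variant
  )
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<sim_result> %d samples, t = %d .. %d\n", nrow(tr),
              min(tr$t), max(tr$t)))
  last <- tr[nrow(tr), ]
  cat(sprintf("  final: population %d, mean p %s%s\n",
              as.integer(last$population_size),
              ifelse(is.na(last$mean_p), "-", sprintf("%.3f", last$mean_p)),
              if (x$extinct) sprintf("  [extinct at t = %d]", x$extinction_step)
              else ""))
  invisible(x)
}
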