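#' Variant configuration: spatial, well-mixed, or mixing from a given time
#'
#' The spatial model can be contrasted with controls in which spatial
#' structure is destroyed. `"well_mixed"` randomly permutes the contents of
#' all lattice nodes before every Monte-Carlo step, so that interactions are
#' random while demographic stochasticity and the replication lottery are
#' unchanged. `"mix_from_t"` runs the plain spatial dynamics until
#' `mix_start` and applies the per-step shuffling afterwards, emulating the
#' destruction of an evolved spatial pattern.
#'
#' @param mode One of `"spatial"`, `"well_mixed"`, `"mix_from_t"`.
#' @param mix_start Monte-Carlo step at which mixing begins (mode
#'   `"mix_from_t"`; >= 0).
#' @return An object of class `variant_config`.
#' @export
variant_config <- function(mode = c("spatial", "well_mixed", "mix_from_t"),
                           mix_start = 0L) {
  mode <- match.arg(mode)
  mix_start <- as.integer(mix_start)
  if (is.na(mix_start) || mix_start < 0)
    stop("`mix_start` must be a non-negative integer", call. = FALSE)
  structure(list(mode = mode, mix_start = mix_start),
            class = "variant_config")
}

#' @export
print.variant_config <- function(x, ...) {
  cat("<variant_config>", x$mode)
  if (x$mode == "mix_from_t") cat(" (mix_start =", x$mix_start, ")")
  cat("\n")
  invisible(x)
}

#' Randomly permute the contents of all lattice nodes
#'
#' The multiset of node contents (occupancy, production, strain) is
#' preserved exactly; only positions change, via a uniform random
#' permutation. The time counter is unchanged.
#'
#' @param world A [world_state()].
#' @param rng An [rng_stream()].
#' @param params A [sim_params()] (only geometry-independent fields are
#'   used; defaults suffice).
#' @return The shuffled `world_state`.
#' @export
shuffle_world <- function(world, rng, params = sim_params()) {
  check_world(world)
  res <- cpp_shuffle_world(world$occupancy, world$production, world$strain,
                           params, rng$ptr)
  world_from_kernel(c(res, list(t = world$t)))
}

#' One Monte-Carlo step under a variant
#'
#' Dispatches on the variant mode: `"spatial"` is a plain
#' [monte_carlo_step()]; `"well_mixed"` shuffles the world before the step;
#' `"mix_from_t"` shuffles only once `t >= mix_start`.
#'
#' @param world A [world_state()].
#' @param params A [sim_params()].
#' @param variant A [variant_config()].
#' @param rng An [rng_stream()].
#' @return The updated `world_state`.
#' @export
step_with_variant <- function(world, params, variant, rng) {
  check_world(world)
  stopifnot(inherits(variant, "variant_config"))
  res <- kernel_steps(world, params, 1L, rng, variant = variant)
  world_from_kernel(res)
}

#' Lag-1 spatial autocorrelation of occupancy
#'
#' Pearson correlation between the occupancy indicator of each node and
#' that of its lag-1 neighbours (the four axial directions, wrapped),
#' averaged. Near zero for a well-mixed world; positive where individuals
#' cluster.
#'
#' @param world A [world_state()].
#' @return A single correlation value (NA if occupancy is constant).
#' @export
occupancy_autocorr_lag1 <- function(world) {
  check_world(world)
  occ <- world$occupancy != 0L
  if (all(occ) || !any(occ)) return(NA_real_)
  H <- nrow(occ); W <- ncol(occ)
  shifts <- list(occ[c(2:H, 1), ], occ[c(H, 1:(H - 1)), ],
                 occ[, c(2:W, 1)], occ[, c(W, 1:(W - 1))])
  mean(vapply(shifts, function(s) stats::cor(as.numeric(occ), as.numeric(s)),
              numeric(1)))
}
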