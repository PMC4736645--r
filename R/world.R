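#' Lattice world state
#'
#' A `world_state` holds the full configuration of the lattice: per-node
#' occupancy, per-individual public-good production rate, an optional
#' integer strain label (inherited unchanged on replication; used by the
#' competition assays) and the elapsed Monte-Carlo time. Matrices are
#' `height x width`; a site is addressed as `c(row, col)`, 1-based.
#'
#' @param width,height Lattice dimensions in nodes.
#' @param t Elapsed Monte-Carlo steps.
#' @return An empty `world_state`.
#' @examples
#' w <- world_state(8, 8)
#' w <- place_individuals(w, cbind(4, 4), p = 6)
#' population_size(w)
#' @export
world_state <- function(width, height, t = 0L) {
  width <- as.integer(width)
  height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 3 || height < 3)
    stop("lattice dimensions must be >= 3", call. = FALSE)
  w <- list(
    occupancy = matrix(0L, height, width),
    production = matrix(0, height, width),
    strain = matrix(0L, height, width),
    t = as.integer(t)
  )
  class(w) <- "world_state"
  w
}

# internal: validate a world object and a (row, col) site
check_world <- function(world) {
  stopifnot(inherits(world, "world_state"))
  invisible(world)
}

site_index <- function(world, site) {
  site <- as.integer(site)
  if (length(site) != 2 || any(is.na(site)))
    stop("a site is addressed as c(row, col)", call. = FALSE)
  H <- nrow(world$occupancy); W <- ncol(world$occupancy)
  if (site[1] < 1 || site[1] > H || site[2] < 1 || site[2] > W)
    stop(sprintf("site (%d, %d) out of range for %d x %d lattice",
                 site[1], site[2], H, W), call. = FALSE)
  site
}

#' Place individuals on a lattice
#'
#' @param world A [world_state()].
#' @param sites Two-column matrix of (row, col) positions, 1-based.
#' @param p Production rate(s), recycled over sites.
#' @param strain Integer strain label(s), recycled over sites.
#' @return The updated `world_state`.
#' @export
place_individuals <- function(world, sites, p, strain = 0L) {
  check_world(world)
  sites <- matrix(as.integer(sites), ncol = 2)
  p <- rep_len(as.numeric(p), nrow(sites))
  strain <- rep_len(as.integer(strain), nrow(sites))
  idx <- cbind(sites[, 1], sites[, 2])
  world$occupancy[idx] <- 1L
  world$production[idx] <- p
  world$strain[idx] <- strain
  world
}

#' Seed a lattice uniformly at random
#'
#' Occupies each node independently with probability `density`, all
#' individuals starting at production rate `p`. Under no-flux boundaries the
#' absorbing boundary ring is left empty.
#'
#' @param world A [world_state()].
#' @param density Occupation probability per node, in `(0, 1]`.
#' @param p Initial production rate of every individual.
#' @param rng An [rng_stream()] supplying the draws.
#' @param strain Strain label given to all seeded individuals.
#' @param boundary `"toroidal"` or `"no_flux"`; under `"no_flux"` the edge
#'   ring is kept empty.
#' @return The seeded `world_state`.
#' @export
seed_world <- function(world, density, p, rng, strain = 0L,
                       boundary = "toroidal") {
  check_world(world)
  if (density < 0 || density > 1) stop("`density` must be in [0, 1]")
  H <- nrow(world$occupancy); W <- ncol(world$occupancy)
  u <- matrix(rng_uniform(rng, H * W), H, W)
  occupy <- u < density
  if (boundary == "no_flux") {
    occupy[c(1, H), ] <- FALSE
    occupy[, c(1, W)] <- FALSE
  }
  world$occupancy[] <- 0L
  world$production[] <- 0
  world$strain[] <- 0L
  world$occupancy[occupy] <- 1L
  world$production[occupy] <- p
  world$strain[occupy] <- as.integer(strain)
  world
}

#' Seed a two-lineage (cooperator + cheater) population
#'
#' Occupies each node independently with probability `density` and assigns
#' each founder to the selfish lineage with probability `selfish_fraction`
#' (production `selfish_p`, strain label 2) or to the cooperative lineage
#' otherwise (production `coop_p`, strain label 1). This emulates the
#' speciated state of the high-cost regime and is the starting point for
#' studying the travelling-wave dynamics on lattices too small to reach
#' that state from a monomorphic founder population.
#'
#' @param world A [world_state()].
#' @param rng An [rng_stream()].
#' @param coop_p,selfish_p Production rates of the two lineages.
#' @param density Occupation probability per node.
#' @param selfish_fraction Probability that a founder is selfish.
#' @return The seeded `world_state`.
#' @export
seed_lineages <- function(world, rng, coop_p = 6, selfish_p = 0.2,
                          density = 0.9, selfish_fraction = 0.1) {
  check_world(world)
  H <- nrow(world$occupancy); W <- ncol(world$occupancy)
  u <- matrix(rng_uniform(rng, H * W), H, W)
  sites <- which(u < density, arr.ind = TRUE)
  if (nrow(sites) == 0) return(world)
  selfish <- rng_uniform(rng, nrow(sites)) < selfish_fraction
  place_individuals(world, sites,
                    p = ifelse(selfish, selfish_p, coop_p),
                    strain = ifelse(selfish, 2L, 1L))
}

#' Population size of a world
#'
#' @param world A [world_state()].
#' @return Number of occupied nodes.
#' @export
population_size <- function(world) {
  check_world(world)
  sum(world$occupancy != 0L)
}

#' Production rates of all living individuals
#'
#' @param world A [world_state()].
#' @return Numeric vector (possibly empty) of production rates.
#' @export
production_values <- function(world) {
  check_world(world)
  world$production[world$occupancy != 0L]
}

#' @export
print.world_state <- function(x, ...) {
  n <- population_size(x)
  cat(sprintf("<world_state> %d x %d lattice, t = %d, %d individual%s\n",
              nrow(x$occupancy), ncol(x$occupancy), x$t, n,
              if (n == 1) "" else "s"))
  if (n > 0) {
    pv <- production_values(x)
    cat(sprintf("  production: mean %.3f, range [%.3f, %.3f]\n",
                mean(pv), min(pv), max(pv)))
  }
  invisible(x)
}

# internal: rebuild a world_state from kernel output
world_from_kernel <- function(res) {
  w <- list(
    occupancy = res$occupancy,
    production = res$production,
    strain = res$strain,
    t = as.integer(res$t)
  )
  class(w) <- "world_state"
  w
}
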