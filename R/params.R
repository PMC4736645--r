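#' Simulation parameters
#'
#' One validated record of all model constants and variant switches. The
#' defaults are the reference parameter set used throughout the package:
#' benefit per unit of public good `b = 10`, death probability
#' `k_death = 0.2`, movement probability `k_move = 0.02`, mutation
#' probability `mu = 0.05`, mutation range width `delta = 0.1` and
#' production cap `p_max = 10`. The cost per unit of public good produced,
#' `cost` (the `c` of the standard notation), is the main experimental
#' knob and defaults to the focal high-cost regime `cost = 4.5`.
#'
#' @param b Benefit per unit of public good (dimensionless, >= 0).
#' @param cost Cost per unit of public good produced (>= 0).
#' @param k_death Per-step death probability of an occupied node, in `[0, 1]`.
#' @param k_move Per-step probability that an individual swaps its node with
#'   a random adjacent node, in `[0, 1]`.
#' @param mu Mutation probability per replication, in `[0, 1]`.
#' @param delta Mutation range width: a mutated offspring's production rate
#'   is shifted by a uniform draw from `[-delta/2, delta/2]`.
#' @param p_max Production cap; offspring production is clipped to
#'   `[0, p_max]`.
#' @param width,height Lattice dimensions in nodes (both >= 3).
#' @param boundary `"toroidal"` (wrap-around) or `"no_flux"` (no wrapping;
#'   the one-node boundary ring absorbs: individuals moving or replicating
#'   into it are removed, the geometry of the invasion assays).
#' @param altruism `"weak"` (a producer receives its own share `p/9`) or
#'   `"strong"` (a producer receives nothing from its own good).
#' @param strong_share Sharing rule under strong altruism:
#'   `"neighbours"` splits the produced good `p/8` among the 8 neighbours
#'   (total emitted good equals `p`, as under weak altruism);
#'   `"discard_self"` keeps `p/9` shares and discards the self share.
#' @param seed Default RNG seed recorded with the run.
#' @return An object of class `sim_params` (a named list).
#' @examples
#' p <- sim_params(cost = 1.0, width = 64, height = 64)
#' p$cost
#' @export
sim_params <- function(b = 10, cost = 4.5, k_death = 0.2, k_move = 0.02,
                       mu = 0.05, delta = 0.1, p_max = 10,
                       width = 128, height = 128,
                       boundary = c("toroidal", "no_flux"),
                       altruism = c("weak", "strong"),
                       strong_share = c("neighbours", "discard_self"),
                       seed = 1) {
  boundary <- match.arg(boundary)
  altruism <- match.arg(altruism)
  strong_share <- match.arg(strong_share)

  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    as.numeric(x)
  }
  prob1 <- function(x, nm) {
    x <- num1(x, nm)
    if (x < 0 || x > 1)
      stop(sprintf("`%s` must be a probability in [0, 1], got %g", nm, x),
           call. = FALSE)
    x
  }
  nonneg1 <- function(x, nm) {
    x <- num1(x, nm)
    if (x < 0)
      stop(sprintf("`%s` must be >= 0, got %g", nm, x), call. = FALSE)
    x
  }

  width <- num1(width, "width")
  height <- num1(height, "height")
  if (width < 3 || height < 3 || width != round(width) || height != round(height))
    stop(sprintf(
      "lattice dimensions must be integers >= 3 (the Moore neighbourhood is degenerate below 3), got %g x %g",
      width, height), call. = FALSE)

  p <- list(
    b = nonneg1(b, "b"),
    cost = nonneg1(cost, "cost"),
    k_death = prob1(k_death, "k_death"),
    k_move = prob1(k_move, "k_move"),
    mu = prob1(mu, "mu"),
    delta = nonneg1(delta, "delta"),
    p_max = nonneg1(p_max, "p_max"),
    width = as.integer(width),
    height = as.integer(height),
    boundary = boundary,
    altruism = altruism,
    strong_share = strong_share,
    strong_share_n = if (strong_share == "neighbours") 8L else 9L,
    connectivity = 8L,
    seed = num1(seed, "seed")
  )
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  b = %g, cost = %g, k_death = %g, k_move = %g\n",
              x$b, x$cost, x$k_death, x$k_move))
  cat(sprintf("  mu = %g, delta = %g, p_max = %g\n", x$mu, x$delta, x$p_max))
  cat(sprintf("  lattice %d x %d, boundary = %s, altruism = %s\n",
              x$width, x$height, x$boundary, x$altruism))
  if (x$altruism == "strong")
    cat(sprintf("  strong-altruism sharing: %s (1/%d shares)\n",
                x$strong_share, x$strong_share_n))
  cat(sprintf("  seed = %g\n", x$seed))
  invisible(x)
}

# Update a sim_params record, re-validating.
#' Modify simulation parameters
#'
#' Returns a copy of `params` with the named fields replaced, passing
#' everything through the [sim_params()] validator again.
#'
#' @param params A [sim_params()] object.
#' @param ... Named fields to replace.
#' @return A validated `sim_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "sim_params"))
  new <- modifyList(unclass(params), list(...))
  keep <- c("b", "cost", "k_death", "k_move", "mu", "delta", "p_max",
            "width", "height", "boundary", "altruism", "strong_share", "seed")
  do.call(sim_params, new[keep])
}
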