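# Brute-force oracles and enumerable fixtures. Everything here is computed
# in plain R, independently of the compiled engine, so that the engine's
# stochastic behaviour can be tested against closed forms on small lattices.

#' Small enumerable fixture worlds
#'
#' A catalogue of hand-specified lattices (at most 5 x 5) with fully
#' enumerable neighbourhoods:
#' \describe{
#'   \item{`isolated`}{5 x 5, a single individual at the centre.}
#'   \item{`full_3x3`}{3 x 3, all nine nodes occupied (homogeneous `p`).}
#'   \item{`ring_3x3`}{3 x 3, centre empty, the 8 surrounding nodes
#'     occupied (homogeneous `p`).}
#'   \item{`pair`}{5 x 5, two adjacent individuals at the centre.}
#' }
#'
#' @param name Fixture name.
#' @param p Production rate given to every individual.
#' @return A [world_state()].
#' @export
fixture_world <- function(name = c("isolated", "full_3x3", "ring_3x3",
                                   "pair"), p = 6) {
  name <- match.arg(name)
  switch(name,
    isolated = place_individuals(world_state(5, 5), cbind(3, 3), p),
    full_3x3 = place_individuals(world_state(3, 3),
                                 as.matrix(expand.grid(1:3, 1:3)), p),
    ring_3x3 = {
      sites <- as.matrix(expand.grid(1:3, 1:3))
      sites <- sites[!(sites[, 1] == 2 & sites[, 2] == 2), ]
      place_individuals(world_state(3, 3), sites, p)
    },
    pair = place_individuals(world_state(5, 5), rbind(c(3, 3), c(3, 4)), p)
  )
}

# pure-R Moore neighbourhood (independent of the C++ table)
r_neighbors <- function(H, W, toroidal, row, col) {
  d <- expand.grid(dr = -1:1, dc = -1:1)
  d <- d[!(d$dr == 0 & d$dc == 0), ]
  rr <- row + d$dr
  cc <- col + d$dc
  if (toroidal) {
    rr <- (rr - 1) %% H + 1
    cc <- (cc - 1) %% W + 1
    cbind(row = rr, col = cc)
  } else {
    keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    cbind(row = rr[keep], col = cc[keep])
  }
}

# pure-R fitness of the individual at (row, col)
r_fitness <- function(world, params, row, col) {
  stopifnot(world$occupancy[row, col] != 0L)
  H <- nrow(world$occupancy); W <- ncol(world$occupancy)
  nb <- r_neighbors(H, W, params$boundary == "toroidal", row, col)
  occn <- world$occupancy[nb] != 0L
  psum_nb <- sum(world$production[nb][occn])
  pi <- world$production[row, col]
  B <- if (params$altruism == "weak") params$b * (pi + psum_nb) / 9
       else params$b * psum_nb / params$strong_share_n
  max(0, B - params$cost * pi)
}

#' Exact replication-lottery distribution at an empty node
#'
#' Enumerates the occupied Moore neighbours of an empty node, computes each
#' competitor's fitness from first principles in plain R, and evaluates the
#' closed-form lottery: competitor `i` replicates with probability
#' \eqn{f_i/f_{tot}\,(1 - e^{-f_{tot}})} and nobody does with probability
#' \eqn{e^{-f_{tot}}} (probability 1 when there are no competitors or all
#' fitnesses are zero). The returned probabilities sum to 1 exactly.
#'
#' @param world A [world_state()] (typically a [fixture_world()]).
#' @param params A [sim_params()].
#' @param empty_site `c(row, col)` of an unoccupied node.
#' @return List with `competitors` (data frame: `row`, `col`, `fitness`,
#'   `prob`) and `none` (probability that nobody replicates).
#' @export
exact_lottery_distribution <- function(world, params, empty_site) {
  check_world(world)
  site <- site_index(world, empty_site)
  stopifnot(world$occupancy[site[1], site[2]] == 0L)
  H <- nrow(world$occupancy); W <- ncol(world$occupancy)
  nb <- r_neighbors(H, W, params$boundary == "toroidal", site[1], site[2])
  nb <- nb[world$occupancy[nb] != 0L, , drop = FALSE]
  if (nrow(nb) == 0)
    return(list(competitors = data.frame(row = integer(0), col = integer(0),
                                         fitness = numeric(0),
                                         prob = numeric(0)),
                none = 1))
  f <- vapply(seq_len(nrow(nb)),
              function(i) r_fitness(world, params, nb[i, 1], nb[i, 2]),
              numeric(1))
  ftot <- sum(f)
  if (ftot <= 0) {
    prob <- rep(0, length(f))
    none <- 1
  } else {
    prob <- f / ftot * (1 - exp(-ftot))
    none <- exp(-ftot)
  }
  list(competitors = data.frame(row = nb[, 1], col = nb[, 2], fitness = f,
                                prob = prob),
       none = none)
}

#' Closed-form one-step event probabilities for canonical configurations
#'
#' For a small catalogue of fully enumerable configurations, returns exact
#' per-step event probabilities against which empirical frequencies from
#' repeated engine steps can be tested. The closed forms require movement
#' to be off (`k_move = 0`), and for `ring_3x3` also death to be off, so
#' that the event of interest is not entangled with the visiting order
#' within the step; the oracle refuses parameter sets outside its
#' catalogue.
#'
#' \describe{
#'   \item{`isolated`}{`p_death = k_death` for the single individual; it
#'     never replicates when its own fitness is zero.}
#'   \item{`full_3x3`}{every node dies independently, so the number of
#'     deaths in one step is Binomial(9, `k_death`); `expected_deaths` is
#'     its mean.}
#'   \item{`ring_3x3`}{`p_fill` = probability that the empty centre is
#'     occupied after one step, `1 - exp(-f_tot)` with `f_tot` evaluated
#'     on the enumerated fixture, together with the per-parent
#'     probabilities.}
#' }
#'
#' @param params A [sim_params()].
#' @param configuration Catalogue entry name.
#' @param p Production rate of the fixture's individuals.
#' @return List of exact probabilities (contents depend on the
#'   configuration) plus the `world` fixture used.
#' @export
single_site_markov_oracle <- function(params,
                                      configuration = c("isolated",
                                                        "full_3x3",
                                                        "ring_3x3"),
                                      p = 6) {
  configuration <- match.arg(configuration)
  if (params$k_move != 0)
    stop("oracle catalogued for k_move = 0 only", call. = FALSE)
  w <- fixture_world(configuration, p = p)
  if (configuration == "isolated") {
    f <- r_fitness(w, params, 3, 3)
    return(list(world = w, p_death = params$k_death, fitness = f,
                p_replicate_any = if (f == 0) 0 else NA_real_))
  }
  if (configuration == "full_3x3") {
    return(list(world = w, p_death_per_node = params$k_death,
                expected_deaths = 9 * params$k_death))
  }
  # ring_3x3: centre-fill probability, valid for k_death = 0
  if (params$k_death != 0)
    stop("ring_3x3 centre-fill oracle requires k_death = 0", call. = FALSE)
  lot <- exact_lottery_distribution(w, params, c(2, 2))
  list(world = w, p_fill = 1 - lot$none, per_parent = lot$competitors,
       f_tot = sum(lot$competitors$fitness))
}
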