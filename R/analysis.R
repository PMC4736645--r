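#' Histogram of production rates
#'
#' Fixed-width bins on `[0, p_max]`, left-closed and right-open except for
#' the last bin, which is closed at `p_max`; `p = 0` falls in the first
#' bin. Counts sum to the population size.
#'
#' @param world A [world_state()].
#' @param n_bins Number of bins (>= 2).
#' @param p_max Production cap defining the bin range.
#' @return An object of class `production_histogram`: list with `counts`,
#'   `bin_edges`, `mids`, `t` and `n`.
#' @export
production_histogram <- function(world, n_bins = 50L, p_max = 10) {
  check_world(world)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("`n_bins` must be >= 2")
  pv <- production_values(world)
  idx <- pmin(pmax(floor(pv / p_max * n_bins), 0), n_bins - 1) + 1
  counts <- tabulate(idx, nbins = n_bins)
  edges <- seq(0, p_max, length.out = n_bins + 1)
  structure(list(counts = counts, bin_edges = edges,
                 mids = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 t = world$t, n = length(pv)),
            class = "production_histogram")
}

#' @export
print.production_histogram <- function(x, ...) {
  cat(sprintf("<production_histogram> %d bins on [0, %g], %d individuals, t = %d\n",
              length(x$counts), max(x$bin_edges), x$n, x$t))
  invisible(x)
}

#' Split the population into selfish and cooperator lineages
#'
#' Individuals with production rate below `threshold` are labelled selfish,
#' the rest cooperators. In the high-cost regime the selfish lineage
#' evolves to (almost) zero production, so any threshold inside the valley
#' of the bimodal distribution identifies the two lineages; the default of
#' 1.0 sits below the weak-altruism self-benefit break-even scale `b/9`
#' for the reference `b = 10`.
#'
#' @param world A [world_state()].
#' @param threshold Classification threshold, in `(0, p_max)`.
#' @return List with `threshold`, `selfish_fraction`,
#'   `cooperator_fraction` (summing to 1 over occupied nodes),
#'   `mean_p_selfish`, `mean_p_cooperator` and `empty` (TRUE when there is
#'   no population, in which case both fractions are 0).
#' @export
classify_lineages <- function(world, threshold = 1.0) {
  check_world(world)
  pv <- production_values(world)
  if (length(pv) == 0)
    return(list(threshold = threshold, selfish_fraction = 0,
                cooperator_fraction = 0, mean_p_selfish = NA_real_,
                mean_p_cooperator = NA_real_, empty = TRUE))
  selfish <- pv < threshold
  list(threshold = threshold,
       selfish_fraction = mean(selfish),
       cooperator_fraction = mean(!selfish),
       mean_p_selfish = if (any(selfish)) mean(pv[selfish]) else NA_real_,
       mean_p_cooperator = if (any(!selfish)) mean(pv[!selfish]) else NA_real_,
       empty = FALSE)
}

#' Detect bimodality of a production distribution
#'
#' A histogram is called bimodal when two local maxima exist whose basins
#' (the two sides of the deepest valley between them) each carry at least
#' `min_mode_mass` of the population, and at least `min_gap_bins` bins
#' between the maxima have counts below `valley_fraction` times the
#' smaller maximum. The defaults (50 bins, 5% minimum mode mass, 3 gap
#' bins, valley fraction 0.5) are robust to the mutation noise of width
#' `delta = 0.1` of the reference parameter set.
#'
#' @param hist A [production_histogram()] or a bare vector of counts.
#' @param min_gap_bins Minimum number of low bins between the two modes.
#' @param min_mode_mass Minimum fraction of the population per mode.
#' @param valley_fraction Bins count as "valley" when below this fraction
#'   of the smaller mode's peak count.
#' @return List with `modality` (`"unimodal"` or `"bimodal"`), `modes`
#'   (bin centres of the detected modes; one centre when unimodal, empty
#'   when the histogram is empty) and `empty`.
#' @export
detect_bimodality <- function(hist, min_gap_bins = 3L, min_mode_mass = 0.05,
                              valley_fraction = 0.5) {
  if (inherits(hist, "production_histogram")) {
    counts <- hist$counts
    mids <- hist$mids
  } else {
    counts <- as.numeric(hist)
    mids <- seq_along(counts) - 0.5
  }
  n <- length(counts)
  total <- sum(counts)
  if (total == 0)
    return(list(modality = "unimodal", modes = numeric(0), empty = TRUE))

  # local maxima, collapsing plateaus to their first bin
  ext <- c(-Inf, counts, -Inf)
  peaks <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && counts[j + 1] == counts[i]) j <- j + 1
    if (counts[i] > 0 && ext[i] < counts[i] && counts[i] > ext[j + 2])
      peaks <- c(peaks, i)
    i <- j + 1
  }
  if (length(peaks) < 2)
    return(list(modality = "unimodal",
                modes = mids[which.max(counts)], empty = FALSE))

  best <- NULL
  for (a in seq_len(length(peaks) - 1)) {
    for (b in (a + 1):length(peaks)) {
      i <- peaks[a]; j <- peaks[b]
      between <- counts[(i + 1):(j - 1)]
      if (length(between) == 0) next
      smaller <- min(counts[i], counts[j])
      gap <- sum(between < valley_fraction * smaller)
      if (gap < min_gap_bins) next
      split <- i + which.min(between)          # deepest valley bin
      mass_left <- sum(counts[1:split]) / total
      mass_right <- sum(counts[(split + 1):n]) / total
      if (mass_left < min_mode_mass || mass_right < min_mode_mass) next
      score <- min(mass_left, mass_right)
      if (is.null(best) || score > best$score)
        best <- list(i = i, j = j, score = score)
    }
  }
  if (is.null(best))
    return(list(modality = "unimodal",
                modes = mids[which.max(counts)], empty = FALSE))
  list(modality = "bimodal", modes = mids[c(best$i, best$j)], empty = FALSE)
}

#' Time of extinction in a trajectory
#'
#' @param trajectory A `sim_result` or its `trajectory` data frame.
#' @return The first sampled Monte-Carlo step with population size 0, or
#'   `NA` if the population never vanished.
#' @export
extinction_time <- function(trajectory) {
  if (inherits(trajectory, "sim_result")) trajectory <- trajectory$trajectory
  stopifnot(is.data.frame(trajectory), nrow(trajectory) >= 1)
  hit <- which(trajectory$population_size == 0)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(trajectory$t[hit[1]])
}

#' Time-resolved production distribution
#'
#' Stacks the per-sample production histograms of a trajectory into a
#' time x bin matrix (the data behind a distribution-over-time heat map).
#'
#' @param trajectory A `sim_result` or its `trajectory` data frame.
#' @param normalise If `TRUE`, each row is divided by its population size
#'   (all-zero rows are left as zeros).
#' @return Numeric matrix with one row per sampling time (rownames are the
#'   times) and one column per production bin.
#' @export
distribution_heatmap <- function(trajectory, normalise = FALSE) {
  if (inherits(trajectory, "sim_result")) trajectory <- trajectory$trajectory
  stopifnot(is.data.frame(trajectory))
  bins <- as.matrix(trajectory[, grep("^bin_", names(trajectory)),
                               drop = FALSE])
  if (ncol(bins) == 0) stop("trajectory has no histogram columns")
  rownames(bins) <- trajectory$t
  if (normalise) {
    pop <- trajectory$population_size
    bins <- sweep(bins, 1, ifelse(pop > 0, pop, 1), "/")
  }
  bins
}
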