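# Configuration, persistence and rendering.

PARAM_KEYS <- c("b", "cost", "k_death", "k_move", "mu", "delta", "p_max",
                "width", "height", "boundary", "altruism", "strong_share",
                "seed")
VARIANT_KEYS <- c("mode", "mix_start")
EXPERIMENT_KEYS <- c("experiment", "n_steps", "sample_every", "n_bins",
                     "init_density", "init_p", "costs", "burn_in",
                     "replicates", "seeds", "strip_length", "strip_width",
                     "seed_cols", "kind", "invader_p", "resident_p",
                     "position", "strain_ps", "max_steps", "front_depth",
                     "check_every", "out_prefix", "outputs",
                     "goodwave_version")

#' Load a simulation configuration file
#'
#' Configurations are flat key-value YAML. Keys are partitioned into model
#' parameters (see [sim_params()]), variant switches (see
#' [variant_config()]) and experiment options; unknown keys and
#' out-of-range values raise descriptive errors. An empty file yields the
#' reference defaults.
#'
#' @param path Path to a YAML file.
#' @return List with elements `params` (a `sim_params`), `variant` (a
#'   `variant_config`) and `experiment` (named list of remaining options).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(cfg), c(PARAM_KEYS, VARIANT_KEYS, EXPERIMENT_KEYS))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- do.call(sim_params, cfg[intersect(names(cfg), PARAM_KEYS)])
  vc <- cfg[intersect(names(cfg), VARIANT_KEYS)]
  variant <- variant_config(mode = if (is.null(vc$mode)) "spatial" else vc$mode,
                            mix_start = if (is.null(vc$mix_start)) 0L
                                        else vc$mix_start)
  list(params = params, variant = variant,
       experiment = cfg[intersect(names(cfg), EXPERIMENT_KEYS)])
}

#' Save and load world-state snapshots
#'
#' Snapshots are plain text: a YAML header (dimensions, time, parameters,
#' seed, and optionally the exact RNG state) separated by a `---` line from
#' a TSV table of occupied nodes (`row`, `col`, `p`, `strain`). Production
#' rates are written with full precision, so `load_snapshot(save_snapshot(w))`
#' reproduces the state field-for-field, and a run resumed from a snapshot
#' carrying the RNG state continues exactly as an uninterrupted one.
#'
#' @param world A [world_state()].
#' @param path File path.
#' @param params Optional [sim_params()] stored alongside the state.
#' @param rng Optional [rng_stream()]; its seed and current state are
#'   recorded.
#' @return `save_snapshot()` returns `path` invisibly; `load_snapshot()`
#'   returns a list with `world`, `params` (or NULL), `seed` and
#'   `rng_state` (or NULL).
#' @export
save_snapshot <- function(world, path, params = NULL, rng = NULL) {
  check_world(world)
  header <- list(
    goodwave_snapshot = 1L,
    height = nrow(world$occupancy),
    width = ncol(world$occupancy),
    t = world$t
  )
  if (!is.null(params)) {
    stopifnot(inherits(params, "sim_params"))
    header$params <- unclass(params)[PARAM_KEYS]
  }
  if (!is.null(rng)) {
    header$seed <- rng$seed
    header$rng_state <- rng_state(rng)
  }
  occ <- which(world$occupancy != 0L, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(yaml::as.yaml(header), con)
  writeLines("---", con)
  writeLines("row\tcol\tp\tstrain", con)
  if (nrow(occ) > 0) {
    writeLines(sprintf("%d\t%d\t%.17g\t%d", occ[, 1], occ[, 2],
                       world$production[occ], world$strain[occ]), con)
  }
  invisible(path)
}

#' @rdname save_snapshot
#' @export
load_snapshot <- function(path) {
  if (!file.exists(path)) stop("snapshot not found: ", path, call. = FALSE)
  lines <- readLines(path)
  sep <- which(lines == "---")[1]
  if (is.na(sep)) stop("corrupt snapshot: missing '---' separator",
                       call. = FALSE)
  header <- yaml::yaml.load(paste(lines[seq_len(sep - 1)], collapse = "\n"))
  if (is.null(header$goodwave_snapshot))
    stop("corrupt snapshot: missing header", call. = FALSE)
  w <- world_state(header$width, header$height, t = header$t)
  body <- lines[(sep + 1):length(lines)]
  body <- body[nzchar(body)]
  if (length(body) > 1) {
    tab <- read.table(text = body, header = TRUE, sep = "\t")
    w <- place_individuals(w, cbind(tab$row, tab$col), tab$p, tab$strain)
  }
  params <- if (!is.null(header$params)) do.call(sim_params, header$params)
            else NULL
  list(world = w, params = params, seed = header$seed,
       rng_state = header$rng_state)
}

#' Render a world as a PNG image
#'
#' One pixel block per node: empty nodes are white, occupied nodes are
#' coloured on a monotone colour ramp in the production rate (dark blue at
#' `p = 0` through green to yellow at `p = p_max`).
#'
#' @param world A [world_state()].
#' @param path Output PNG path.
#' @param p_max Production cap anchoring the colour scale.
#' @param scale Integer pixel-block size per node.
#' @return `path`, invisibly.
#' @export
render_world <- function(world, path, p_max = 10, scale = 1L) {
  check_world(world)
  H <- nrow(world$occupancy); W <- ncol(world$occupancy)
  ramp <- grDevices::colorRamp(c("#0d1a50", "#2166ac", "#1a9850", "#d9ef8b",
                                 "#ffff33"))
  img <- array(1, dim = c(H, W, 3))
  occ <- world$occupancy != 0L
  if (any(occ)) {
    frac <- pmin(pmax(world$production[occ] / p_max, 0), 1)
    cols <- ramp(frac) / 255
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[occ] <- cols[, ch]
      img[, , ch] <- plane
    }
  }
  if (scale > 1) {
    idxr <- rep(seq_len(H), each = scale)
    idxc <- rep(seq_len(W), each = scale)
    img <- img[idxr, idxc, , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Write a trajectory to CSV
#'
#' Columns: `t`, `population_size`, `mean_p` and the fixed-width histogram
#' bin counts.
#'
#' @param result A `sim_result` (or a trajectory data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(result, path) {
  tr <- if (inherits(result, "sim_result")) result$trajectory else result
  stopifnot(is.data.frame(tr))
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' The manifest is itself a valid configuration file (flat YAML) recording
#' the full parameter set, variant, seed, package version and output paths
#' of a run: feeding it back through the command-line driver (or
#' [load_config()]) re-executes the run bit-identically.
#'
#' @param path Output YAML path.
#' @param params A [sim_params()].
#' @param variant A [variant_config()] or NULL.
#' @param experiment Named list of experiment options.
#' @param outputs Character vector of files the run wrote.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, variant = NULL,
                           experiment = list(), outputs = character(0)) {
  stopifnot(inherits(params, "sim_params"))
  m <- unclass(params)[PARAM_KEYS]
  if (!is.null(variant)) {
    m$mode <- variant$mode
    m$mix_start <- variant$mix_start
  }
  m <- c(m, experiment)
  m$outputs <- as.list(outputs)
  m$goodwave_version <- as.character(utils::packageVersion("goodwave"))
  writeLines(yaml::as.yaml(m), path)
  invisible(path)
}
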