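#' Parameter-sweep configuration
#'
#' Describes a sweep over (B(0), beta(0)) benefit pairs: for each pair,
#' `trials` independent single-invader simulations are run for up to
#' `max_iterations` death-birth iterations. By default the swept pairs follow
#' the full study protocol: B(0) in 1..40 and beta(0) in 1..B(0), 20 trials
#' of 50,000 iterations each with d = 10, delta = 1 and base cost 10.
#'
#' Per-trial seeds are derived deterministically from the master seed, the
#' pair and the trial index, so any subset of pairs can be run (or re-run)
#' independently and reproduces exactly the same records.
#'
#' @param topology_kind One of `"all_to_all"`, `"nn4"`, `"nn8"`,
#'   `"prob_spatial"`.
#' @param width,height Grid dimensions (default 40 x 40; for all-to-all only
#'   the product is used as the node count).
#' @param gamma Density parameter for `"prob_spatial"` (default 10).
#' @param b0_values Integer vector of B(0) values (default `1:40`).
#' @param beta0_values Optional integer vector of beta(0) values; by default
#'   every beta(0) in `1..B(0)` is swept, and explicit values are filtered to
#'   `beta0 <= B0` per pair.
#' @param cost,cost_mode,d,delta,payoff_aggregation Game parameters (see
#'   [game_params()]).
#' @param max_iterations Iteration budget per trial (default 50000).
#' @param trials Trials per pair (default 20).
#' @param seed Master seed (integer).
#' @return An object of class `oscomm_sweep_config`.
#' @export
sweep_config <- function(topology_kind = c("nn8", "nn4", "all_to_all", "prob_spatial"),
                         width = 40L, height = 40L, gamma = 10,
                         b0_values = 1:40, beta0_values = NULL,
                         cost = 10, cost_mode = c("uniform", "degree_adjusted"),
                         d = 10L, delta = 1,
                         payoff_aggregation = c("mean", "sum"),
                         max_iterations = 50000L, trials = 20L, seed = 1L) {
  topology_kind <- match.arg(topology_kind)
  cost_mode <- match.arg(cost_mode)
  payoff_aggregation <- match.arg(payoff_aggregation)
  b0_values <- sort(unique(as.integer(b0_values)))
  if (any(b0_values < 0L)) stop("B(0) values must be non-negative")
  pairs <- do.call(rbind, lapply(b0_values, function(b0) {
    betas <- if (is.null(beta0_values)) seq_len(b0) else
      beta0_values[beta0_values <= b0]
    if (length(betas) == 0L) return(NULL)
    data.frame(B0 = b0, beta0 = as.integer(betas))
  }))
  if (is.null(pairs) || nrow(pairs) == 0L) stop("sweep contains no (B0, beta0) pairs")
  structure(list(topology_kind = topology_kind, width = as.integer(width),
                 height = as.integer(height), gamma = gamma,
                 b0_values = b0_values,
                 beta0_values = if (is.null(beta0_values)) NULL else
                   sort(unique(as.integer(beta0_values))),
                 pairs = pairs, cost = cost, cost_mode = cost_mode,
                 d = as.integer(d), delta = delta,
                 payoff_aggregation = payoff_aggregation,
                 max_iterations = as.integer(max_iterations),
                 trials = as.integer(trials), seed = as.integer(seed)),
            class = "oscomm_sweep_config")
}

#' Read / write a sweep configuration as JSON
#'
#' The config file mirrors every field of [sweep_config()]; `b0_values` and
#' `beta0_values` are stored instead of the expanded pair list.
#'
#' @param config An `oscomm_sweep_config`.
#' @param file Path to a JSON file.
#' @return `write_sweep_config()` returns the path invisibly;
#'   `read_sweep_config()` returns the config object.
#' @export
write_sweep_config <- function(config, file) {
  stopifnot(inherits(config, "oscomm_sweep_config"))
  out <- unclass(config)
  out$pairs <- NULL
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], file,
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_sweep_config
#' @export
read_sweep_config <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(sweep_config, raw[intersect(names(raw), names(formals(sweep_config)))])
}

# Deterministic per-trial seed: Lehmer-style fold of the master seed with the
# pair and trial index, kept below 2^31.
trial_seed <- function(master, B0, beta0, trial) {
  m <- 2147483647
  h <- master %% m
  for (v in c(B0, beta0, trial)) {
    h <- (h * 48271 + v + 1) %% m
  }
  as.integer(h)
}

build_sweep_topology <- function(config) {
  switch(config$topology_kind,
    all_to_all = topology_all_to_all(config$width * config$height),
    nn4 = topology_nn4(grid_layout(config$width, config$height)),
    nn8 = topology_nn8(grid_layout(config$width, config$height)),
    prob_spatial = topology_prob_spatial(grid_layout(config$width, config$height),
                                         config$gamma))
}

#' Run a parameter sweep
#'
#' For every swept (B(0), beta(0)) pair, runs `trials` independent
#' single-invader simulations and aggregates the final communicative fraction
#' and convergence time. Probabilistic spatial topologies are regenerated
#' fresh for every trial (under the trial's seed); the deterministic
#' topologies are built once. Non-converged trials contribute the sentinel
#' `max_iterations` to the mean convergence time.
#'
#' @param config An `oscomm_sweep_config`.
#' @param pairs Optional subset of pairs to run, as a data.frame with columns
#'   `B0` and `beta0` (default: all pairs in the config). Because trial seeds
#'   depend only on the master seed and the pair, partial runs compose into
#'   the full sweep.
#' @param progress If `TRUE`, message one line per pair.
#' @return An object of class `oscomm_sweep` with elements `config`,
#'   `trials` (one row per trial: B0, beta0, trial, seed, final_p,
#'   convergence_iteration, absorbed) and `pairs` (per-pair aggregates:
#'   mean_final_p, mean_convergence_time, n_not_converged, region).
#' @examples
#' cfg <- sweep_config("nn4", width = 4, height = 4, b0_values = c(5, 30),
#'                     beta0_values = 5, max_iterations = 200, trials = 2)
#' run_sweep(cfg)
#' @export
run_sweep <- function(config, pairs = NULL, progress = FALSE) {
  stopifnot(inherits(config, "oscomm_sweep_config"))
  if (is.null(pairs)) pairs <- config$pairs
  if (!all(c("B0", "beta0") %in% names(pairs)) || nrow(pairs) == 0L ||
      any(pairs$beta0 > pairs$B0) || any(pairs$beta0 < 0)) {
    stop("`pairs` must have columns B0, beta0 with 0 <= beta0 <= B0")
  }
  fixed_topo <- if (config$topology_kind != "prob_spatial") {
    assign_costs(build_sweep_topology(config), config$cost, config$cost_mode)
  }
  trial_rows <- vector("list", nrow(pairs))
  pair_rows <- vector("list", nrow(pairs))
  for (pi in seq_len(nrow(pairs))) {
    b0 <- pairs$B0[pi]; be <- pairs$beta0[pi]
    params <- game_params(b0, be, cost = config$cost,
                          cost_mode = config$cost_mode, d = config$d,
                          delta = config$delta,
                          payoff_aggregation = config$payoff_aggregation)
    recs <- lapply(seq_len(config$trials), function(tr) {
      sd <- trial_seed(config$seed, b0, be, tr)
      set.seed(sd)
      topo <- if (is.null(fixed_topo)) {
        assign_costs(build_sweep_topology(config), config$cost,
                     config$cost_mode)
      } else fixed_topo
      st <- run_simulation(params, topo, config$max_iterations)
      data.frame(B0 = b0, beta0 = be, trial = tr, seed = sd,
                 final_p = st$final_p,
                 convergence_iteration = if (st$absorbed) st$absorption_time
                                         else config$max_iterations,
                 absorbed = st$absorbed)
    })
    recs <- do.call(rbind, recs)
    trial_rows[[pi]] <- recs
    pair_rows[[pi]] <- data.frame(
      B0 = b0, beta0 = be,
      mean_final_p = mean(recs$final_p),
      mean_convergence_time = mean(recs$convergence_iteration),
      n_not_converged = sum(!recs$absorbed),
      region = classify_game(params))
    if (progress) {
      message(sprintf("pair B0=%d beta0=%d: mean p = %.3f", b0, be,
                      pair_rows[[pi]]$mean_final_p))
    }
  }
  structure(list(config = config,
                 trials = do.call(rbind, trial_rows),
                 pairs = do.call(rbind, pair_rows)),
            class = "oscomm_sweep")
}

#' @export
print.oscomm_sweep <- function(x, ...) {
  cat(sprintf("sweep on %s: %d pairs x %d trials (seed %d)\n",
              x$config$topology_kind, nrow(x$pairs), x$config$trials,
              x$config$seed))
  print(utils::head(x$pairs))
  invisible(x)
}

#' Mean convergence time arranged on the (B0, beta0) grid
#'
#' Rows are beta(0) values, columns B(0) values; non-converged trials carry
#' the sentinel `max_iterations` inside the means. Pairs absent from the
#' result are `NA` and listed in the `missing_pairs` attribute rather than
#' silently zeroed.
#'
#' @param result An `oscomm_sweep`.
#' @return A numeric matrix with dimnames; attribute `missing_pairs` holds a
#'   data.frame of requested-but-absent pairs (`beta0 <= B0` cells only).
#' @export
convergence_time_summary <- function(result) {
  stopifnot(inherits(result, "oscomm_sweep"))
  pr <- result$pairs
  b0s <- sort(unique(result$config$pairs$B0))
  bes <- sort(unique(result$config$pairs$beta0))
  grid <- matrix(NA_real_, length(bes), length(b0s),
                 dimnames = list(beta0 = bes, B0 = b0s))
  for (i in seq_len(nrow(pr))) {
    grid[as.character(pr$beta0[i]), as.character(pr$B0[i])] <-
      pr$mean_convergence_time[i]
  }
  want <- result$config$pairs
  have <- paste(pr$B0, pr$beta0)
  missing <- want[!paste(want$B0, want$beta0) %in% have, , drop = FALSE]
  structure(grid, missing_pairs = missing)
}

#' Annotate sweep pairs with their game region
#'
#' Labels every pair with [classify_game()] and the theoretically expected
#' invasion outcome under all-to-all connectivity (`"C"` when
#' `B0 >= beta0 > c`, `"N"` when both differences are unfavorable, mixed
#' otherwise), and tabulates the mean final communicative fraction by region.
#' Boundary pairs are flagged, not folded into a region.
#'
#' @param result An `oscomm_sweep`.
#' @param cost Base cost used for the classification (default the sweep's).
#' @return A list with `pairs` (the per-pair table plus `region` and
#'   `expected` columns) and `by_region` (mean of mean_final_p per region).
#' @export
region_annotation <- function(result, cost = result$config$cost) {
  stopifnot(inherits(result, "oscomm_sweep"))
  pr <- result$pairs
  pr$region <- vapply(seq_len(nrow(pr)), function(i) {
    classify_game(game_params(pr$B0[i], pr$beta0[i], cost = cost))
  }, character(1))
  pr$expected <- ifelse(pr$region == "boundary", "boundary",
                 ifelse(pr$beta0 > cost, "C",
                 ifelse(pr$region %in% c("prisoners_dilemma", "coordination"),
                        "N", "mixed")))
  by_region <- stats::aggregate(mean_final_p ~ region, data = pr, FUN = mean)
  list(pairs = pr, by_region = by_region)
}

#' Export sweep results
#'
#' Writes the per-trial records (`trials.csv`), the per-pair summary
#' (`pairs.csv`) and a JSON run manifest (`manifest.json`: full configuration
#' including the master seed, package version, timestamp) into a directory.
#'
#' @param result An `oscomm_sweep`.
#' @param dir Destination directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
export_results <- function(result, dir) {
  stopifnot(inherits(result, "oscomm_sweep"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(result$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  cfg <- unclass(result$config)
  cfg$pairs <- NULL
  cfg$b0_values <- sort(unique(result$config$pairs$B0))
  manifest <- list(config = cfg,
                   package_version = as.character(utils::packageVersion("oscomm")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Heatmap of a sweep summary
#'
#' Simple base-graphics image of either the mean final communicative fraction
#' or the mean convergence time over the (B0, beta0) grid.
#'
#' @param x An `oscomm_sweep`.
#' @param what `"final_p"` or `"convergence_time"`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plot.oscomm_sweep <- function(x, what = c("final_p", "convergence_time"), ...) {
  what <- match.arg(what)
  pr <- x$pairs
  b0s <- sort(unique(pr$B0)); bes <- sort(unique(pr$beta0))
  z <- matrix(NA_real_, length(b0s), length(bes))
  val <- if (what == "final_p") pr$mean_final_p else pr$mean_convergence_time
  for (i in seq_len(nrow(pr))) {
    z[match(pr$B0[i], b0s), match(pr$beta0[i], bes)] <- val[i]
  }
  graphics::image(b0s, bes, z, xlab = "B(0)", ylab = "beta(0)",
                  main = if (what == "final_p")
                    "mean final communicative fraction"
                  else "mean convergence time", ...)
  invisible(z)
}
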