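#' Single-communicator invasion initial condition
#'
#' Sets every oscillator to the non-communicative resident strategy at phase 1
#' except one invader, chosen uniformly at random, which communicates at the
#' maximally distant phase `1 + floor(d/2)` (exactly opposite for even `d`).
#' This makes adoption of communication as hard as possible. Consumes the
#' current R random stream unless `invader_node` is given.
#'
#' @param topology An `oscomm_topology`.
#' @param d Number of phases.
#' @param invader_node Optional fixed node index for the invader.
#' @return An object of class `oscomm_state` with integer vectors `flags`
#'   (1 = C, 0 = N) and `phases`, the phase count `d`, the communicative
#'   fraction trajectory (initialized to `1/n`), and absorption bookkeeping.
#' @export
initialize_invasion <- function(topology, d, invader_node = NULL) {
  stopifnot(inherits(topology, "oscomm_topology"))
  d <- as.integer(d)
  n <- topology$n
  if (n < 2L || d < 2L) stop("need n >= 2 and d >= 2")
  invader <- if (is.null(invader_node)) sample.int(n, 1L) else as.integer(invader_node)
  stopifnot(invader >= 1L, invader <= n)
  flags <- integer(n)
  phases <- rep(1L, n)
  flags[invader] <- 1L
  phases[invader] <- 1L + d %/% 2L
  new_state(flags, phases, d)
}

new_state <- function(flags, phases, d, trajectory = NULL, iteration = 0L,
                      absorbed = NULL, absorption_time = NA_integer_) {
  n <- length(flags)
  p <- sum(flags) / n
  if (is.null(trajectory)) trajectory <- p
  if (is.null(absorbed)) absorbed <- p %in% c(0, 1)
  if (absorbed && is.na(absorption_time)) {
    absorption_time <- iteration
  }
  structure(list(flags = as.integer(flags), phases = as.integer(phases),
                 d = as.integer(d), n = n, iteration = as.integer(iteration),
                 trajectory = trajectory, final_p = p,
                 absorbed = absorbed,
                 absorption_time = as.integer(absorption_time)),
            class = "oscomm_state")
}

#' @export
print.oscomm_state <- function(x, ...) {
  cat(sprintf("population of %d oscillators after %d iterations: p = %.4f%s\n",
              x$n, x$iteration, x$final_p,
              if (x$absorbed) sprintf(" (absorbed at iteration %d)",
                                      x$absorption_time) else ""))
  invisible(x)
}

node_costs_for <- function(topology, params) {
  if (!is.null(topology$node_costs)) return(topology$node_costs)
  if (params$cost_mode == "degree_adjusted") {
    assign_costs(topology, params$cost, "degree_adjusted")$node_costs
  } else {
    rep(params$cost, topology$n)
  }
}

#' Expected payoff of a node
#'
#' The payoff a node accrues playing its strategy against each of its
#' neighbors, `pi(i) = sum_j M_ij P(S(i), S(j))` (summed by default; divided
#' by the degree when `params$payoff_aggregation == "mean"`). In
#' degree-adjusted cost mode the focal node's own cost `c(i)` is used in every
#' cost-bearing payoff entry. A node with no neighbors has payoff 0.
#'
#' @param state An `oscomm_state`.
#' @param params An `oscomm_game`.
#' @param topology An `oscomm_topology`.
#' @param node Node index.
#' @return The expected payoff in payoff units.
#' @export
expected_payoff <- function(state, params, topology, node) {
  nb <- topology$adj[[node]]
  if (length(nb) == 0L) return(0)
  costs <- node_costs_for(topology, params)
  pays <- pair_payoff(state$flags[node], state$phases[node],
                      state$flags[nb], state$phases[nb], params,
                      node_cost = costs[node])
  if (params$payoff_aggregation == "mean") mean(pays) else sum(pays)
}

#' Exponential fitness
#'
#' `f = exp(delta * pi)`: strictly increasing in the payoff, equal to 1 at
#' zero payoff or under neutral selection (`delta = 0`).
#'
#' @param pi Expected payoff (vectorized).
#' @param delta Selection strength.
#' @return Positive fitness value(s).
#' @export
fitness <- function(pi, delta) exp(delta * pi)

#' Fitness profile of a node's neighborhood
#'
#' The probability distribution over the neighbors of `node` from which the
#' death-birth replacement strategy is drawn: each neighbor j has weight
#' `exp(delta * pi_j)` with `pi_j` its expected payoff in the current full
#' configuration, normalized to sum to 1. Computed in the log domain
#' (max-subtracted) so the result is finite for arbitrarily large payoffs.
#'
#' @inheritParams expected_payoff
#' @return A named numeric vector of probabilities over the neighbor indices.
#' @export
fitness_profile <- function(state, params, topology, node) {
  nb <- topology$adj[[node]]
  if (length(nb) == 0L) {
    stop(structure(class = c("oscomm_no_neighbors", "error", "condition"),
                   list(message = sprintf("node %d has no neighbors", node),
                        call = sys.call())))
  }
  pis <- vapply(nb, function(j) expected_payoff(state, params, topology, j),
                numeric(1))
  w <- params$delta * pis
  w <- exp(w - max(w))
  stats::setNames(w / sum(w), nb)
}

#' One death-birth update (reference implementation)
#'
#' Picks an oscillator uniformly at random to die and replaces it with a new
#' oscillator carrying the full (flag, phase) strategy of a neighbor drawn
#' from the fitness profile. Payoffs are evaluated on the pre-replacement
#' configuration (the dying node still contributes to its neighbors'
#' payoffs). A node with no neighbors keeps its strategy. The trajectory is
#' extended by one entry. Consumes the current R random stream.
#'
#' This pure-R step is the reference path shared with the exact-chain oracle;
#' [run_simulation()] uses a compiled equivalent by default.
#'
#' @inheritParams expected_payoff
#' @return The updated `oscomm_state`.
#' @export
death_birth_step <- function(state, params, topology) {
  n <- state$n
  i <- sample.int(n, 1L)
  flags <- state$flags; phases <- state$phases
  if (length(topology$adj[[i]]) > 0L) {
    prof <- fitness_profile(state, params, topology, i)
    j <- as.integer(names(prof))[.sample_index(prof)]
    flags[i] <- flags[j]
    phases[i] <- phases[j]
  }
  traj <- c(state$trajectory, sum(flags) / n)
  new_state(flags, phases, state$d, trajectory = traj,
            iteration = state$iteration + 1L,
            absorbed = NULL,
            absorption_time = if (state$absorbed) state$absorption_time
                              else NA_integer_)
}

.sample_index <- function(prob) {
  u <- stats::runif(1) * sum(prob)
  min(which(cumsum(prob) >= u), length(prob))
}

#' Run the death-birth process
#'
#' Iterates the death-birth update from a single-invader initial condition
#' (or a supplied state) for up to `max_iterations`, recording the
#' communicative fraction p after every iteration. Stops early once p reaches
#' 0 or 1: with no mutation these are absorbing, so the trajectory's constant
#' tail is represented implicitly by `absorption_time` and `final_p` rather
#' than stored. Fully reproducible given `set.seed()`.
#'
#' @param params An `oscomm_game`.
#' @param topology An `oscomm_topology`.
#' @param max_iterations Iteration budget (default 50000).
#' @param init Optional starting `oscomm_state`; by default a single-invader
#'   configuration from [initialize_invasion()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference loop over
#'   [death_birth_step()]; only sensible for small systems).
#' @return The final `oscomm_state`, with `trajectory` holding p at iteration
#'   0 up to the stopping iteration, `absorbed`, `absorption_time` (first
#'   iteration with p in {0,1}, `NA` if never reached) and `final_p`.
#' @examples
#' topo <- assign_costs(topology_nn8(grid_layout(8, 8)), 10)
#' set.seed(1)
#' run_simulation(game_params(30, 15), topo, max_iterations = 2000)
#' @export
run_simulation <- function(params, topology, max_iterations = 50000L,
                           init = NULL, engine = c("cpp", "r")) {
  stopifnot(inherits(params, "oscomm_game"),
            inherits(topology, "oscomm_topology"))
  engine <- match.arg(engine)
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("`max_iterations` must be >= 1")
  if (is.null(init)) init <- initialize_invasion(topology, params$d)
  stopifnot(inherits(init, "oscomm_state"), init$n == topology$n)
  if (init$absorbed) return(init)

  if (engine == "r") {
    state <- init
    for (it in seq_len(max_iterations)) {
      state <- death_birth_step(state, params, topology)
      if (state$absorbed) break
    }
    return(state)
  }

  costs <- node_costs_for(topology, params)
  res <- run_death_birth_cpp(topology$adj, init$flags, init$phases,
                             params$B0, params$beta0, params$d, params$delta,
                             costs, params$payoff_aggregation == "mean",
                             max_iterations)
  new_state(res$flags, res$phases, params$d,
            trajectory = c(init$trajectory, res$trajectory),
            iteration = init$iteration + res$iterations,
            absorbed = res$absorbed,
            absorption_time = if (res$absorbed)
              init$iteration + res$absorption_time else NA_integer_)
}

#' Export a trajectory as CSV
#'
#' Writes (iteration, p) rows, optionally decimated to every `decimate`-th
#' iteration (iteration 0 and the final recorded iteration always included).
#'
#' @param state An `oscomm_state` from [run_simulation()].
#' @param file Output path.
#' @param decimate Positive integer decimation factor (default 1 = all rows).
#' @return Invisibly, the file path.
#' @export
write_trajectory_csv <- function(state, file, decimate = 1L) {
  stopifnot(inherits(state, "oscomm_state"), decimate >= 1L)
  iters <- seq_along(state$trajectory) - 1L
  keep <- iters %% as.integer(decimate) == 0L
  keep[length(keep)] <- TRUE
  utils::write.csv(data.frame(iteration = iters[keep],
                              p = state$trajectory[keep]),
                   file, row.names = FALSE)
  invisible(file)
}

#' Export a final-state snapshot as CSV
#'
#' Writes one row per node: index, grid coordinates (if the topology has a
#' layout), flag and phase index.
#'
#' @param state An `oscomm_state`.
#' @param topology The `oscomm_topology` the state lives on.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_state_csv <- function(state, topology, file) {
  stopifnot(inherits(state, "oscomm_state"),
            inherits(topology, "oscomm_topology"),
            state$n == topology$n)
  df <- data.frame(node = seq_len(state$n),
                   flag = ifelse(state$flags == 1L, "C", "N"),
                   phase_index = state$phases)
  if (!is.null(topology$layout)) {
    df$x <- topology$layout$coords[, "x"]
    df$y <- topology$layout$coords[, "y"]
    df <- df[, c("node", "x", "y", "flag", "phase_index")]
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
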