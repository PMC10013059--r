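#' Oscillator strategy
#'
#' A strategy is the full description of an oscillator: a communication flag
#' (`"C"` for communicative, `"N"` for non-communicative) and a phase index in
#' `1..d`, one of `d` phases evenly spaced around the oscillation cycle.
#'
#' @param flag `"C"` or `"N"`.
#' @param phase Integer phase index in `1..d`.
#' @param d Number of phases (>= 2).
#' @return An object of class `oscomm_strategy`.
#' @examples
#' strategy("C", 6, d = 10)
#' @export
strategy <- function(flag, phase, d) {
  flag <- match.arg(flag, c("C", "N"))
  d <- as.integer(d)
  phase <- as.integer(phase)
  if (d < 2L) stop("`d` must be at least 2")
  if (is.na(phase) || phase < 1L || phase > d) {
    stop("`phase` must be an integer in 1..", d)
  }
  structure(list(flag = flag, phase = phase, d = d),
            class = "oscomm_strategy")
}

#' @export
print.oscomm_strategy <- function(x, ...) {
  cat(sprintf("(%s, phi_%d) of %d phases\n", x$flag, x$phase, x$d))
  invisible(x)
}

#' @export
`==.oscomm_strategy` <- function(e1, e2) {
  e1$flag == e2$flag && e1$phase == e2$phase
}

#' Game parameters
#'
#' Bundles the cost/benefit parameters that define the communication game:
#' benefit intercepts `B0` (communicators) and `beta0` (non-communicators),
#' base communication cost, cost mode, phase count `d`, selection strength
#' `delta`, and the payoff aggregation rule used for a node's expected payoff.
#'
#' Benefits are linear and non-increasing in the cyclic phase distance `k`:
#' `B(k) = B0 * (1 - k/d)` and `beta(k) = beta0 * (1 - k/d)`, with
#' `B0 >= beta0 >= 0` so that communicators never benefit less.
#'
#' @param B0 Benefit intercept for communicators (payoff units, >= beta0).
#' @param beta0 Benefit intercept for non-communicators (>= 0).
#' @param cost Base communication cost (default 10).
#' @param cost_mode `"uniform"` (every node pays `cost`) or
#'   `"degree_adjusted"` (node i pays `cost * N(i) / mu`, where `N(i)` is its
#'   degree and `mu` the mean degree, keeping the mean cost equal to `cost`).
#' @param d Number of phases (>= 2, default 10).
#' @param delta Selection strength (>= 0, default 1); fitness is
#'   `exp(delta * payoff)`.
#' @param payoff_aggregation `"mean"` (default) averages payoffs over
#'   neighbors; `"sum"` leaves them summed. The average keeps selection
#'   pressure comparable across degrees and reproduces the reported
#'   mixed-state snowdrift band; the summed variant is exposed for
#'   sensitivity analysis.
#' @return An object of class `oscomm_game`.
#' @examples
#' game_params(B0 = 30, beta0 = 15)
#' @export
game_params <- function(B0, beta0, cost = 10, cost_mode = c("uniform", "degree_adjusted"),
                        d = 10L, delta = 1,
                        payoff_aggregation = c("mean", "sum")) {
  cost_mode <- match.arg(cost_mode)
  payoff_aggregation <- match.arg(payoff_aggregation)
  d <- as.integer(d)
  if (!is.finite(B0) || !is.finite(beta0) || B0 < beta0 || beta0 < 0) {
    stop("require B0 >= beta0 >= 0")
  }
  if (!is.finite(cost) || cost < 0) stop("`cost` must be non-negative")
  if (is.na(d) || d < 2L) stop("`d` must be an integer >= 2")
  if (!is.finite(delta) || delta < 0) stop("`delta` must be non-negative")
  structure(list(B0 = as.numeric(B0), beta0 = as.numeric(beta0),
                 cost = as.numeric(cost), cost_mode = cost_mode,
                 d = d, delta = as.numeric(delta),
                 payoff_aggregation = payoff_aggregation),
            class = "oscomm_game")
}

#' @export
print.oscomm_game <- function(x, ...) {
  cat(sprintf("communication game: B(0)=%g, beta(0)=%g, c=%g (%s), d=%d, delta=%g [%s]\n",
              x$B0, x$beta0, x$cost, x$cost_mode, x$d, x$delta,
              x$payoff_aggregation))
  cat("  region:", classify_game(x), "\n")
  invisible(x)
}

#' Convert game parameters to/from a plain configuration list
#'
#' @param params An `oscomm_game` object.
#' @param config A named list (e.g. parsed from JSON) with the fields of
#'   [game_params()].
#' @return `as_game_config()` returns a plain named list serializable to JSON;
#'   `game_params_from_config()` returns an `oscomm_game`.
#' @export
as_game_config <- function(params) {
  stopifnot(inherits(params, "oscomm_game"))
  unclass(params)
}

#' @rdname as_game_config
#' @export
game_params_from_config <- function(config) {
  do.call(game_params, config[intersect(names(config),
    c("B0", "beta0", "cost", "cost_mode", "d", "delta", "payoff_aggregation"))])
}

#' Cyclic distance between phase indices
#'
#' The minimal number of steps between two phase indices around the `d`-cycle:
#' `k = |q - r|` when that is at most `floor(d/2)`, and `d - |q - r|`
#' otherwise. This integer multiple of `2*pi/d` is the argument of the benefit
#' functions.
#'
#' @param q,r Phase indices in `1..d` (vectorized).
#' @param d Number of phases.
#' @return Integer distance(s) in `0..floor(d/2)`.
#' @examples
#' cyclic_phase_distance(2, 9, d = 10) # 3
#' @export
cyclic_phase_distance <- function(q, r, d) {
  d <- as.integer(d)
  if (d < 2L) stop("`d` must be at least 2")
  q <- as.integer(q); r <- as.integer(r)
  if (anyNA(q) || anyNA(r) || any(q < 1L | q > d) || any(r < 1L | r > d)) {
    stop("phase indices must lie in 1..", d)
  }
  k <- abs(q - r)
  pmin(k, d - k)
}

#' Benefit functions
#'
#' Linear benefits of interacting at cyclic phase distance `k`:
#' `benefit_B()` for a communicator, `B0 * (1 - k/d)`, and `benefit_beta()`
#' for a non-communicator, `beta0 * (1 - k/d)`.
#'
#' @param k Cyclic phase distance in `0..floor(d/2)` (vectorized).
#' @param params An `oscomm_game` object.
#' @return Benefit in payoff units.
#' @export
benefit_B <- function(k, params) {
  .check_k(k, params)
  params$B0 * (1 - k / params$d)
}

#' @rdname benefit_B
#' @export
benefit_beta <- function(k, params) {
  .check_k(k, params)
  params$beta0 * (1 - k / params$d)
}

.check_k <- function(k, params) {
  stopifnot(inherits(params, "oscomm_game"))
  if (anyNA(k) || any(k < 0) || any(k > params$d %/% 2L)) {
    stop("`k` must lie in 0..", params$d %/% 2L)
  }
}

# Vectorized payoff to the row player for (flag_row, phase_row) meeting
# (flag_col, phase_col); flags are integers (1 = C, 0 = N). `node_cost` is the
# cost borne by the ROW (focal) player, which differs per node in
# degree-adjusted mode. Single code path shared by the payoff table, the
# expected-payoff operation and the exact-chain oracle.
pair_payoff <- function(flag_row, phase_row, flag_col, phase_col, params,
                        node_cost = params$cost) {
  k <- cyclic_phase_distance(phase_row, phase_col, params$d)
  mult <- 1 - k / params$d
  benefit <- ifelse(flag_col == 1L, params$B0, params$beta0) * mult
  free_ride <- ifelse(flag_col == 1L, params$beta0 * mult, 0)
  # recycle all arguments to the common length before branching on the focal
  # flag, so a scalar focal strategy meets a vector of neighbors correctly
  len <- length(mult)
  ifelse(rep_len(flag_row == 1L, len),
         -rep_len(node_cost, len) + benefit, free_ride)
}

strategy_labels <- function(d) {
  c(paste0("C", seq_len(d)), paste0("N", seq_len(d)))
}

#' Build the 2d x 2d payoff matrix
#'
#' Rows and columns are indexed by the strategy list
#' `((C,phi_1)..(C,phi_d), (N,phi_1)..(N,phi_d))`; the entry at (row i, col j)
#' is the payoff to the row player. The matrix has four `d x d` blocks:
#' communicators pay the cost and reap `B(k)` against communicators and
#' `beta(k)` against non-communicators; non-communicators free-ride `beta(k)`
#' off communicators; the all-N block is identically zero.
#'
#' @param params An `oscomm_game` object.
#' @param node_cost Cost borne by the focal (row) player; defaults to
#'   `params$cost` and is overridden per node in degree-adjusted mode.
#' @return A numeric matrix of class `oscomm_payoff_table` with strategy
#'   labels as dimnames and the parameters attached as attributes.
#' @examples
#' A <- payoff_table(game_params(B0 = 20, beta0 = 15))
#' A["C1", "C1"] # -c + B(0) = 10
#' @export
payoff_table <- function(params, node_cost = params$cost) {
  stopifnot(inherits(params, "oscomm_game"))
  if (!is.finite(node_cost) || node_cost < 0) stop("`node_cost` must be >= 0")
  d <- params$d
  flags <- rep(c(1L, 0L), each = d)
  phases <- rep(seq_len(d), 2L)
  idx <- seq_len(2L * d)
  A <- outer(idx, idx, function(i, j) {
    pair_payoff(flags[i], phases[i], flags[j], phases[j], params, node_cost)
  })
  dimnames(A) <- list(strategy_labels(d), strategy_labels(d))
  structure(A, params = params, node_cost = node_cost,
            class = c("oscomm_payoff_table", "matrix", "array"))
}

#' Look up a payoff-table entry for two strategies
#'
#' @param table A payoff table from [payoff_table()].
#' @param s_row,s_col Strategies from [strategy()] (the row player receives
#'   the returned payoff).
#' @return The payoff to `s_row` when meeting `s_col`.
#' @export
payoff <- function(table, s_row, s_col) {
  stopifnot(inherits(table, "oscomm_payoff_table"),
            inherits(s_row, "oscomm_strategy"),
            inherits(s_col, "oscomm_strategy"))
  d <- attr(table, "params")$d
  if (s_row$d != d || s_col$d != d) {
    stop("strategy phase count does not match the table's d = ", d)
  }
  table[paste0(s_row$flag, s_row$phase), paste0(s_col$flag, s_col$phase)]
}

#' Classify the induced 2x2 game region
#'
#' Reduces the flag game at equal phase to a symmetric 2x2 game with
#' `R = B0 - c` (mutual communication), `S = beta0 - c` (communicating with a
#' non-communicator), `T = beta0` (free-riding) and `P = 0`, and classifies it
#' by the signs of `R - T = B0 - beta0 - c` and `S - P = beta0 - c`:
#' both positive gives mutualism (harmony), `R - T < 0 < S - P` snowdrift,
#' `R - T > 0 > S - P` coordination, both negative the Prisoner's Dilemma.
#' A zero in either difference sits exactly on a region boundary and is
#' labelled `"boundary"` rather than folded into a neighboring region.
#'
#' @param params An `oscomm_game` object.
#' @return One of `"mutualism"`, `"snowdrift"`, `"coordination"`,
#'   `"prisoners_dilemma"`, `"boundary"`.
#' @examples
#' classify_game(game_params(30, 15)) # mutualism
#' classify_game(game_params(30, 25)) # snowdrift
#' @export
classify_game <- function(params) {
  stopifnot(inherits(params, "oscomm_game"))
  rt <- params$B0 - params$beta0 - params$cost # R - T
  sp <- params$beta0 - params$cost             # S - P
  if (rt == 0 || sp == 0) return("boundary")
  if (rt > 0 && sp > 0) return("mutualism")
  if (rt < 0 && sp > 0) return("snowdrift")
  if (rt > 0 && sp < 0) return("coordination")
  "prisoners_dilemma"
}

#' Export a payoff table as CSV
#'
#' Writes the 2d x 2d matrix with strategy labels on rows and columns for
#' inspection.
#'
#' @param table A payoff table from [payoff_table()].
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_payoff_table <- function(table, file) {
  stopifnot(inherits(table, "oscomm_payoff_table"))
  utils::write.csv(as.data.frame(unclass(table)), file)
  invisible(file)
}
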