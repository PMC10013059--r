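#' Exact two-strategy death-birth chain on a small system
#'
#' In the invasion setting only two strategies are present: the
#' non-communicative resident and the communicative invader at maximal phase
#' distance. On a system with at most `max_n` nodes the death-birth process
#' restricted to these two strategies is a Markov chain over the 2^n
#' assignments, with two absorbing states (all-invader, all-resident). This
#' object holds the topology, parameters and strategy pair; the transition
#' matrix and fixation probabilities are computed by
#' [build_transition_matrix()] and [exact_fixation_probability()], using the
#' same R payoff/fitness code path as [death_birth_step()], so they serve as
#' independent ground truth for the stochastic engine.
#'
#' @param topology An `oscomm_topology` with a small node count.
#' @param params An `oscomm_game`.
#' @param invader_phase Phase index of the invader (default the maximally
#'   distant `1 + floor(d/2)`).
#' @param resident_phase Phase index of the resident (default 1).
#' @param max_n Refusal threshold on the node count (default 12, i.e. at most
#'   4096 states).
#' @return An object of class `oscomm_chain`.
#' @export
two_strategy_chain <- function(topology, params,
                               invader_phase = 1L + params$d %/% 2L,
                               resident_phase = 1L, max_n = 12L) {
  stopifnot(inherits(topology, "oscomm_topology"),
            inherits(params, "oscomm_game"))
  if (topology$n > max_n) {
    stop("state space 2^", topology$n, " too large to enumerate (n > ",
         max_n, ")")
  }
  structure(list(topology = topology, params = params,
                 invader_phase = as.integer(invader_phase),
                 resident_phase = as.integer(resident_phase)),
            class = "oscomm_chain")
}

chain_state_flags <- function(index, n) {
  # state index 0..2^n-1; bit b (node b+1) set means node carries the invader
  as.integer(bitwAnd(index %/% 2^(0:(n - 1L)), 1L) == 1L)
}

chain_phases <- function(chain, flags) {
  ifelse(flags == 1L, chain$invader_phase, chain$resident_phase)
}

#' Exact transition matrix of the two-strategy chain
#'
#' Enumerates all 2^n strategy assignments and, for each, averages over the
#' uniform death choice and the exact fitness-profile birth distribution
#' computed with [fitness_profile()]. Homogeneous states map to themselves
#' with probability 1; a node without neighbors contributes a self-loop.
#'
#' @param chain An `oscomm_chain`.
#' @return A `2^n x 2^n` row-stochastic matrix; state 1 is all-resident and
#'   state `2^n` all-invader.
#' @export
build_transition_matrix <- function(chain) {
  stopifnot(inherits(chain, "oscomm_chain"))
  topo <- chain$topology
  params <- chain$params
  n <- topo$n
  m <- 2L^n
  P <- matrix(0, m, m)
  for (s in seq_len(m) - 1L) {
    flags <- chain_state_flags(s, n)
    state <- new_state(flags, chain_phases(chain, flags), params$d)
    for (i in seq_len(n)) {
      nb <- topo$adj[[i]]
      if (length(nb) == 0L) {
        P[s + 1L, s + 1L] <- P[s + 1L, s + 1L] + 1 / n
        next
      }
      prof <- fitness_profile(state, params, topo, i)
      for (a in seq_along(nb)) {
        new_flag <- flags[nb[a]]
        s_new <- s + (new_flag - flags[i]) * 2L^(i - 1L)
        P[s + 1L, s_new + 1L] <- P[s + 1L, s_new + 1L] + prof[a] / n
      }
    }
  }
  P
}

#' Exact fixation probability of the invader strategy
#'
#' Solves the absorbing-chain linear system `(I - Q) h = r` for the
#' probability that the chain started from `start` is absorbed in the
#' all-invader state.
#'
#' @param chain An `oscomm_chain`.
#' @param start Either an integer 0/1 flag vector (1 = invader) of length n,
#'   or `"single"` (default) for the average over the n single-invader
#'   states, matching a uniformly placed invader.
#' @param P Optional precomputed transition matrix from
#'   [build_transition_matrix()].
#' @return A fixation probability in [0, 1].
#' @examples
#' topo <- topology_all_to_all(3)
#' ch <- two_strategy_chain(topo, game_params(0, 0, cost = 0))
#' exact_fixation_probability(ch) # neutral drift: 1/3
#' @export
exact_fixation_probability <- function(chain, start = "single", P = NULL) {
  stopifnot(inherits(chain, "oscomm_chain"))
  n <- chain$topology$n
  m <- 2L^n
  if (is.null(P)) P <- build_transition_matrix(chain)
  i_res <- 1L       # all-resident (state 0)
  i_inv <- m        # all-invader (state 2^n - 1)
  trans <- setdiff(seq_len(m), c(i_res, i_inv))
  h <- numeric(m)
  h[i_inv] <- 1
  Q <- P[trans, trans, drop = FALSE]
  r <- P[trans, i_inv]
  h[trans] <- solve(diag(length(trans)) - Q, r)
  if (identical(start, "single")) {
    singles <- 2L^(seq_len(n) - 1L) + 1L
    return(mean(h[singles]))
  }
  start <- as.integer(start)
  stopifnot(length(start) == n, all(start %in% c(0L, 1L)))
  h[sum(start * 2L^(seq_len(n) - 1L)) + 1L]
}

#' Monte-Carlo fixation frequency
#'
#' Repeatedly runs the death-birth process to absorption from a
#' single-invader start on a small system and returns the fixation frequency
#' of the invader (communicative) strategy with its binomial standard error.
#' Consumes the current R random stream.
#'
#' @param params An `oscomm_game`.
#' @param topology An `oscomm_topology`.
#' @param trials Number of independent runs (>= 1).
#' @param max_iterations Safety budget per run (absorption on small systems
#'   is fast; the run errors if any trial fails to absorb).
#' @param engine Simulation engine passed to [run_simulation()].
#' @return A list with `estimate`, `se`, `fixed` (count) and `trials`.
#' @export
monte_carlo_fixation <- function(params, topology, trials,
                                 max_iterations = 1000000L,
                                 engine = c("cpp", "r")) {
  stopifnot(inherits(params, "oscomm_game"),
            inherits(topology, "oscomm_topology"))
  engine <- match.arg(engine)
  trials <- as.integer(trials)
  if (is.na(trials) || trials < 1L) stop("`trials` must be >= 1")
  fixed <- 0L
  for (t in seq_len(trials)) {
    init <- initialize_invasion(topology, params$d)
    st <- run_simulation(params, topology, max_iterations, init = init,
                         engine = engine)
    if (!st$absorbed) stop("trial ", t, " did not absorb within the budget")
    fixed <- fixed + (st$final_p == 1)
  }
  est <- fixed / trials
  list(estimate = est, se = sqrt(est * (1 - est) / trials),
       fixed = fixed, trials = trials)
}

#' Export exact fixation probabilities as CSV
#'
#' Writes one row per state (0-based index, flag bitstring, fixation
#' probability of the invader) for regression baselines.
#'
#' @param chain An `oscomm_chain`.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_fixation_table <- function(chain, file) {
  n <- chain$topology$n
  P <- build_transition_matrix(chain)
  m <- 2L^n
  h <- vapply(seq_len(m) - 1L, function(s) {
    exact_fixation_probability(chain, chain_state_flags(s, n), P = P)
  }, numeric(1))
  bits <- vapply(seq_len(m) - 1L, function(s) {
    paste(chain_state_flags(s, n), collapse = "")
  }, character(1))
  utils::write.csv(data.frame(state = seq_len(m) - 1L, flags = bits,
                              fixation_probability = h),
                   file, row.names = FALSE)
  invisible(file)
}
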