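# small graph fixtures built in code

cycle_topology <- function(n) {
  topology_from_edges(n, cbind(seq_len(n), c(seq_len(n)[-1], 1L)),
                      kind = "cycle")
}

path_topology <- function(n) {
  topology_from_edges(n, cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
                      kind = "path")
}

# star with `leaves` leaves; center is node 1
star_topology <- function(leaves) {
  topology_from_edges(leaves + 1L, cbind(1L, 1L + seq_len(leaves)),
                      kind = "star")
}

# a population state with given flags/phases, bypassing the invasion setup
make_state <- function(flags, phases, d = 10L) {
  oscomm:::new_state(as.integer(flags), as.integer(phases), d)
}

neutral_params <- function(...) {
  game_params(B0 = 0, beta0 = 0, cost = 0, ...)
}
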