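test_that("invasion initial condition places one maximally distant communicator", {
  topo <- topology_nn8(grid_layout(5, 5))
  set.seed(1)
  st <- initialize_invasion(topo, d = 10)
  expect_equal(sum(st$flags), 1L)
  inv <- which(st$flags == 1L)
  expect_equal(st$phases[inv], 6L)
  expect_true(all(st$phases[-inv] == 1L))
  expect_equal(cyclic_phase_distance(st$phases[inv], 1L, 10L), 5L)
  expect_equal(st$final_p, 1 / 25)
  expect_equal(st$trajectory, 1 / 25)
  # odd d: floor(d/2) steps away
  st7 <- initialize_invasion(topo, d = 7, invader_node = 3)
  expect_equal(st7$phases[3], 4L)
  expect_equal(cyclic_phase_distance(4L, 1L, 7L), 3L)
})

test_that("expected payoff sums the table entries over the neighborhood", {
  # focal node 1 on a 4-leaf star; hand sums below use the summed variant
  topo <- star_topology(4)
  params <- game_params(20, 15, payoff_aggregation = "sum")
  st <- make_state(flags = c(1, 1, 1, 1, 0), phases = c(1, 1, 1, 6, 1))
  expect_equal(expected_payoff(st, params, topo, 1), 10 + 10 + 0 + 5) # 25
  st2 <- make_state(flags = c(0, 1, 1, 0, 0), phases = c(1, 1, 6, 1, 1))
  # only the two communicative neighbors pay out: beta(0) + beta(5)
  expect_equal(expected_payoff(st2, params, topo, 1), 15 + 7.5)
  # all-N neighborhood yields zero for a non-communicative focal node
  stN <- make_state(flags = rep(0, 5), phases = rep(1, 5))
  expect_equal(expected_payoff(stN, params, topo, 1), 0)
  # mean aggregation divides by the degree
  pm <- game_params(20, 15, payoff_aggregation = "mean")
  expect_equal(expected_payoff(st, pm, topo, 1), 25 / 4)
  # isolated node has payoff 0
  iso <- topology_from_edges(3, cbind(1L, 2L))
  expect_equal(expected_payoff(make_state(c(1, 1, 1), c(1, 1, 1)),
                               params, iso, 3), 0)
})

test_that("degree-adjusted costs enter the focal node's payoff", {
  topo <- assign_costs(path_topology(3), 10, "degree_adjusted")
  params <- game_params(20, 15, cost_mode = "degree_adjusted",
                        payoff_aggregation = "sum")
  st <- make_state(flags = c(1, 1, 1), phases = c(1, 1, 1))
  # center has degree 2, mu = 4/3, so its cost is 15 per interaction
  expect_equal(expected_payoff(st, params, topo, 2), 2 * (-15 + 20))
  expect_equal(expected_payoff(st, params, topo, 1), -7.5 + 20)
})

test_that("fitness is exponential in payoff", {
  expect_equal(fitness(0, 1), 1)
  expect_equal(fitness(25, 0), 1)
  expect_equal(fitness(25, 1), exp(25))
  expect_true(all(diff(fitness(c(-5, 0, 5), 2)) > 0))
})

test_that("fitness profiles are normalized softmax distributions", {
  topo <- topology_all_to_all(5)
  params <- game_params(30, 25)
  st <- make_state(flags = c(1, 1, 0, 0, 0), phases = c(6, 6, 1, 1, 1))
  prof <- fitness_profile(st, params, topo, 3)
  expect_equal(sum(prof), 1)
  expect_equal(as.integer(names(prof)), c(1, 2, 4, 5))
  # consistency with the expected payoffs it is built from
  pis <- vapply(c(1, 2, 4, 5), function(j) expected_payoff(st, params, topo, j),
                numeric(1))
  w <- exp(params$delta * (pis - max(pis)))
  expect_equal(unname(prof), w / sum(w))
  # equal payoffs give the uniform distribution
  prof0 <- fitness_profile(make_state(rep(0, 5), rep(1, 5)),
                           neutral_params(), topo, 1)
  expect_equal(unname(prof0), rep(1 / 4, 4))
  # nodes with identical neighbor sets share a profile
  k23 <- topology_from_edges(5, rbind(c(1, 3), c(1, 4), c(1, 5),
                                      c(2, 3), c(2, 4), c(2, 5)))
  stk <- make_state(c(0, 1, 1, 0, 0), c(1, 6, 6, 1, 1))
  expect_equal(fitness_profile(stk, params, k23, 1),
               fitness_profile(stk, params, k23, 2))
  expect_error(fitness_profile(st, params, topology_from_edges(5, cbind(1L, 2L)), 3),
               class = "oscomm_no_neighbors")
})

test_that("fitness profiles stay finite under extreme payoffs", {
  # payoffs far beyond the floating-point exponent range of exp()
  topo <- topology_all_to_all(20)
  params <- game_params(1e6, 1e6, cost = 0, payoff_aggregation = "sum")
  st <- make_state(flags = c(rep(1, 10), rep(0, 10)),
                   phases = rep(c(1, 6), 10))
  prof <- fitness_profile(st, params, topo, 1)
  expect_true(all(is.finite(prof)))
  expect_equal(sum(prof), 1)
  # and in the compiled engine
  set.seed(8)
  out <- run_simulation(params, topo, 50, init = st)
  expect_true(all(is.finite(out$trajectory)))
})

test_that("compiled and reference payoff computations agree", {
  set.seed(21)
  for (rep in 1:5) {
    topo <- topology_prob_spatial(grid_layout(5, 5), 3)
    topo <- assign_costs(topo, 10, sample(c("uniform", "degree_adjusted"), 1))
    agg <- sample(c("sum", "mean"), 1)
    params <- game_params(sample(5:40, 1), sample(0:5, 1), d = 10,
                          cost_mode = topo$cost_mode,
                          payoff_aggregation = agg)
    st <- make_state(flags = sample(0:1, 25, replace = TRUE),
                     phases = sample(1:10, 25, replace = TRUE))
    pis_r <- vapply(1:25, function(i) expected_payoff(st, params, topo, i),
                    numeric(1))
    pis_c <- oscomm:::node_payoffs_cpp(topo$adj, st$flags, st$phases,
                                       params$B0, params$beta0, params$d,
                                       topo$node_costs, agg == "mean")
    expect_equal(pis_r, pis_c)
  }
})

test_that("a death-birth step changes at most one node and respects consensus", {
  params <- game_params(30, 25)
  topo <- topology_all_to_all(6)
  # homogeneous population: composition is invariant
  hom <- make_state(rep(1, 6), rep(4, 6))
  set.seed(2)
  after <- death_birth_step(hom, params, topo)
  expect_equal(after$flags, hom$flags)
  expect_equal(after$phases, hom$phases)
  expect_equal(after$iteration, 1L)
  expect_length(after$trajectory, 2L)
  # a node whose neighbors all share a strategy adopts it when it dies: on a
  # star with center (N,1) and leaves (C,6), every death is deterministic
  st <- make_state(c(0, 1, 1, 1, 1), c(1, 6, 6, 6, 6))
  star <- star_topology(4)
  center_changed <- FALSE
  set.seed(3)
  for (i in 1:50) {
    nxt <- death_birth_step(st, params, star)
    dif <- which(nxt$flags != st$flags | nxt$phases != st$phases)
    expect_lte(length(dif), 1L)
    if (length(dif) == 1L) {
      if (dif == 1L) {
        expect_equal(nxt$flags[1], 1L)  # center copies its leaves
        expect_equal(nxt$phases[1], 6L)
        center_changed <- TRUE
      } else {
        expect_equal(nxt$flags[dif], 0L) # a leaf copies the center
        expect_equal(nxt$phases[dif], 1L)
      }
    }
  }
  expect_true(center_changed)
})

test_that("the communicative count moves by at most one per iteration", {
  topo <- topology_nn4(grid_layout(4, 4))
  params <- game_params(30, 25)
  set.seed(6)
  st <- initialize_invasion(topo, 10)
  out <- run_simulation(params, topo, 400, init = st)
  counts <- round(out$trajectory * topo$n)
  expect_true(all(abs(diff(counts)) <= 1))
  expect_true(all(out$trajectory >= 0 & out$trajectory <= 1))
})

test_that("absorbing states terminate the simulation immediately", {
  topo <- topology_all_to_all(5)
  params <- game_params(30, 25)
  hom <- make_state(rep(1, 5), rep(2, 5))
  out <- run_simulation(params, topo, 100, init = hom)
  expect_true(out$absorbed)
  expect_equal(out$absorption_time, 0L)
  expect_equal(out$final_p, 1)
  # after stochastic absorption, absorption_time marks the first hit
  set.seed(10)
  run <- run_simulation(game_params(8, 5), topo, 5000)
  expect_true(run$absorbed)
  expect_equal(run$trajectory[run$absorption_time + 1L], run$final_p)
  expect_true(all(run$trajectory[seq_len(run$absorption_time)] > 0 &
                  run$trajectory[seq_len(run$absorption_time)] < 1))
})

test_that("simulations are reproducible from the seed in both engines", {
  topo <- topology_nn8(grid_layout(5, 5))
  params <- game_params(30, 25)
  for (eng in c("cpp", "r")) {
    set.seed(42); a <- run_simulation(params, topo, 300, engine = eng)
    set.seed(42); b <- run_simulation(params, topo, 300, engine = eng)
    expect_identical(a$trajectory, b$trajectory)
    expect_identical(a$flags, b$flags)
  }
})

test_that("neutral replacement copies a uniformly drawn neighbor", {
  # with all fitnesses equal the engine's choice frequencies are uniform;
  # compare the compiled one-step distribution with the exact chain row
  topo <- path_topology(3)
  params <- neutral_params()
  flags <- c(1L, 0L, 0L); phases <- c(6L, 1L, 1L)
  set.seed(17)
  outcomes <- replicate(3000, {
    r <- oscomm:::run_death_birth_cpp(topo$adj, flags, phases, 0, 0, 10L, 1,
                                      rep(0, 3), TRUE, 1L)
    sum(r$flags * 2L^(0:2))
  })
  emp <- as.numeric(table(factor(outcomes, levels = 0:7))) / 3000
  ch <- two_strategy_chain(topo, params)
  exact_row <- build_transition_matrix(ch)[2, ] # state with node 1 invading
  expect_true(all(abs(emp - exact_row) < 3 * sqrt(exact_row / 3000 + 1e-4)))
})

test_that("trajectory and snapshot exports round-trip", {
  topo <- topology_nn4(grid_layout(3, 3))
  set.seed(5)
  st <- run_simulation(game_params(30, 25), topo, 50)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(st, f)
  tr <- utils::read.csv(f)
  expect_equal(tr$p, st$trajectory)
  expect_equal(tr$iteration, seq_along(st$trajectory) - 1L)
  write_trajectory_csv(st, f, decimate = 10)
  tr10 <- utils::read.csv(f)
  expect_lte(nrow(tr10), nrow(tr))
  expect_equal(tr10$p[1], st$trajectory[1])
  fs <- withr::local_tempfile(fileext = ".csv")
  write_state_csv(st, topo, fs)
  snap <- utils::read.csv(fs)
  expect_equal(nrow(snap), 9L)
  expect_equal(names(snap), c("node", "x", "y", "flag", "phase_index"))
  expect_equal(snap$flag, ifelse(st$flags == 1, "C", "N"))
})
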