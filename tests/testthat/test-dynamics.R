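test_that("schedules evaluate and locate their zero crossings", {
  cs <- env_schedule("constant", delta_o0 = 4)
  expect_equal(schedule_delta(cs, c(0, 10, 1e3)), rep(4, 3))
  expect_equal(nrow(schedule_crossings(cs, 1e3)), 0)

  ls <- env_schedule("linear", delta_o0 = 10, rate = 0.1)
  expect_equal(schedule_delta(ls, c(0, 50, 100)), c(10, 5, 0))
  expect_equal(schedule_crossings(ls, 400),
               data.frame(time = 100, to_sign = -1))

  ss <- env_schedule("sinusoidal", amplitude = 10, period = 200)
  expect_equal(schedule_delta(ss, 50), 10)
  expect_equal(schedule_delta(ss, c(0, 100, 200)), rep(0, 3),
               tolerance = 1e-9)
  cr <- schedule_crossings(ss, 600)
  expect_equal(cr$time, c(100, 200, 300, 400, 500, 600))
  expect_equal(cr$to_sign, c(-1, 1, -1, 1, -1, 1))
})

test_that("population initialization enforces exact counts and types", {
  set.seed(20)
  g <- generate_er(200, 10)
  comp <- half_half()
  pop <- init_population(g, comp, initial_fraction_A = 1)
  expect_true(all(pop$spin == 1L))
  pop <- init_population(g, comp, initial_fraction_A = 0.37)
  expect_equal(sum(pop$spin > 0), round(0.37 * 200))
  # half/half preferences differ by at most one agent
  expect_lte(abs(sum(pop$delta_o > 0) - sum(pop$delta_o < 0)), 1)
  # by-subpopulation initialization is exact within each subpopulation
  pop2 <- init_population(g, comp, initial_fraction_A = 0.5,
                          init_mode = "by_subpop")
  for (r in 1:2)
    expect_equal(sum(pop2$spin[pop2$subpop == r] > 0),
                 round(0.5 * sum(pop2$subpop == r)))
  # anticonformist rows must match the placement
  mix <- mix_anticonformists(comp, 0.2)
  pl <- place_types(g, 0.2, 0, tolerance = 0.05)
  pop3 <- init_population(g, mix, pl)
  expect_true(all(pop3$w[pl$anti] < 0))
  expect_true(all(pop3$w[!pl$anti] > 0))
  expect_error(init_population(g, mix, NULL), "placement")
  expect_error(init_population(g, comp, pl$anti), "no w < 0 rows")
  # determinism of the whole assignment
  set.seed(77); a <- init_population(g, mix, pl, 0.5)
  set.seed(77); b <- init_population(g, mix, pl, 0.5)
  expect_identical(a$spin, b$spin)
  expect_identical(a$subpop, b$subpop)
})

test_that("async_step updates exactly one agent by the Fermi rule", {
  g <- full_graph(21)
  comp <- half_half()
  # all nonconformists with delta_o = 10: any update lands on A
  nc <- agent_composition(10, 0, 1)
  pop <- pop_with_spins(g, nc, rep(-1L, 21))
  res <- async_step(pop)
  expect_true(res$flipped)
  expect_equal(res$pop$spin[res$agent], 1L)
  expect_equal(sum(res$pop$spin != pop$spin), 1)
  # conformist in an all-B sea flips to B despite preferring A
  cf <- agent_composition(10, 1, 1)
  pop <- pop_with_spins(g, cf, c(1L, rep(-1L, 20)))  # focal degree 20
  set.seed(1)
  repeat {
    res <- async_step(pop)
    if (res$agent == 1) break
  }
  expect_equal(res$pop$spin[1], -1L)  # dU = 10 - 20 < 0
})

test_that("consensus of conformists is absorbing and recorded as such", {
  set.seed(30)
  g <- generate_ba(100, 8)  # min degree 8 > |delta_o|: consensus frozen
  pop <- init_population(g, half_half(delta = 2), initial_fraction_A = 1)
  tr <- run_dynamics(pop, horizon = 500, quiet_sweeps = 50)
  expect_true(tr$equilibrium)
  expect_true(all(tr$records$frac_A == 1))
  expect_true(all(tr$records$flips == 0))
  expect_equal(tr$sweeps_run, 50)
})

test_that("trajectory bookkeeping: subpopulation fractions aggregate to the global", {
  set.seed(31)
  g <- generate_ba(150, 5)
  comp <- half_half(delta = 2)
  pop <- init_population(g, comp, initial_fraction_A = 0.5,
                         params = decision_params(0.5))
  tr <- run_dynamics(pop, horizon = 30, quiet_sweeps = 0)
  wts <- tr$subpop_sizes / tr$n
  agg <- as.matrix(tr$records[, paste0("frac_A_", comp$name)]) %*% wts
  expect_equal(as.numeric(agg), tr$records$frac_A, tolerance = 1e-12)
  expect_true(all(tr$records$frac_A >= 0 & tr$records$frac_A <= 1))
  # flip accounting matches the per-node totals
  expect_equal(sum(tr$records$flips), sum(tr$flips_per_node))
})

test_that("seeded runs are bitwise reproducible", {
  g <- generate_ba(80, 4)
  pop <- init_population(g, half_half(), initial_fraction_A = 0.6)
  set.seed(55); t1 <- run_dynamics(pop, horizon = 40, quiet_sweeps = 0)
  set.seed(55); t2 <- run_dynamics(pop, horizon = 40, quiet_sweeps = 0)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$final_spin, t2$final_spin)
})

test_that("nonconformist populations always express their preferences", {
  set.seed(33)
  for (net in list(generate_er(120, 6), generate_ba(120, 3))) {
    comp <- agent_composition(c(5, -1), c(0, 0), c(0.4, 0.6))
    pop <- init_population(net, comp, initial_fraction_A = 0)
    tr <- run_dynamics(pop, horizon = 200)
    expect_equal(alignment(tr)$global, 1)
  }
})

test_that("mirrored scenarios give complementary dynamics", {
  sc <- scenario(network = list(family = "er", n = 120, mean_degree = 10),
                 base_composition = agent_composition(c(5, -5), c(1, 1),
                                                      c(0.6, 0.4)),
                 initial_fraction_A = 0.8, horizon = 150,
                 realizations = 8, seed = 41)
  mir <- sc
  mir$base_composition <- agent_composition(c(-5, 5), c(1, 1), c(0.6, 0.4))
  mir$initial_fraction_A <- 0.2
  mir$seed <- 42
  e1 <- run_ensemble(sc)
  e2 <- run_ensemble(mir)
  f1 <- vapply(e1$trajectories, function(t) utils::tail(t$records$frac_A, 1),
               numeric(1))
  f2 <- vapply(e2$trajectories, function(t) utils::tail(t$records$frac_A, 1),
               numeric(1))
  expect_lt(abs(median(f1) - (1 - median(f2))), 0.1)
})

test_that("frozen configurations at the deterministic limit are exactly the no-switch states", {
  # exhaustive over all configurations of a small conformist graph
  g <- ring_graph(6)
  adj <- igraph::as_adj_list(g)
  delta_o <- c(2, -2, 2, -2, 2, -2)
  w <- rep(1, 6)
  pars <- decision_params(1e4)
  set.seed(60)
  for (code in 0:63) {
    spin <- ifelse(bitwAnd(code, 2^(0:5)) > 0, 1L, -1L)
    # route 1: closed-form switch probabilities
    p_switch <- vapply(1:6, function(i) {
      nb <- as.integer(adj[[i]])
      pA <- prob_choose_A(marginal_utility(delta_o[i], w[i],
                                           sum(spin[nb] > 0),
                                           sum(spin[nb] < 0)), pars)
      if (spin[i] > 0) 1 - pA else pA
    }, numeric(1))
    frozen_rule <- all(p_switch < 1e-9)
    # route 2: repeated draws of the actual sampling rule
    frozen_sim <- all(vapply(1:6, function(i) {
      nb <- as.integer(adj[[i]])
      draws <- sample_choice(rep(delta_o[i], 40), w[i],
                             sum(spin[nb] > 0), sum(spin[nb] < 0), pars)
      all(choice_to_spin(draws) == spin[i])
    }, logical(1)))
    expect_equal(frozen_rule, frozen_sim)
  }
})

test_that("ensembles summarise reproducibly and respect the seed contract", {
  sc <- scenario(network = list(family = "er", n = 60, mean_degree = 8),
                 base_composition = half_half(), initial_fraction_A = 0.5,
                 horizon = 30, quiet_sweeps = 0, realizations = 3,
                 seed = 14)
  e1 <- run_ensemble(sc)
  e2 <- run_ensemble(sc)
  expect_identical(e1$summary, e2$summary)
  # single-realization ensembles: the median is the trajectory
  e3 <- run_ensemble(sc, n_realizations = 1)
  expect_equal(e3$summary$frac_A_med,
               e3$trajectories[[1]]$records$frac_A)
  # disjoint seeds give different draws
  e4 <- run_ensemble(sc, seed = 15)
  expect_false(identical(e1$summary, e4$summary))
  # initial A-fraction honoured at t = 0
  expect_equal(e1$summary$frac_A_med[1], 0.5)
})
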