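test_that("alignment matches choices against preference signs", {
  g <- full_graph(20)
  comp <- half_half()
  # everyone on their preferred side
  pop <- init_population(g, comp, initial_fraction_A = 0.5)
  pop$spin <- ifelse(pop$delta_o > 0, 1L, -1L)
  al <- alignment(pop)
  expect_equal(al$global, 1)
  expect_equal(unname(al$by_subpop), c(1, 1))
  expect_equal(al$n_excluded, 0)
  # consensus on A with half/half preferences: exactly half match
  pop$spin <- rep(1L, 20)
  expect_equal(alignment(pop)$global, 0.5)
  # mirrored population has identical alignment
  mir <- pop
  mir$delta_o <- -pop$delta_o
  mir$spin <- -pop$spin
  expect_equal(alignment(mir)$global, alignment(pop)$global)
  # indifferent agents are excluded, and all-indifferent errors
  comp0 <- agent_composition(c(10, 0), c(1, 1), c(0.5, 0.5))
  pop0 <- init_population(g, comp0, initial_fraction_A = 1)
  expect_equal(alignment(pop0)$n_excluded, sum(pop0$delta_o == 0))
  pall <- init_population(g, agent_composition(0, 1, 1),
                          initial_fraction_A = 1)
  expect_error(alignment(pall), "undefined")
})

test_that("trajectory alignment equals the final-state alignment once frozen", {
  set.seed(44)
  g <- generate_ba(150, 8)
  pop <- init_population(g, half_half(delta = 2), initial_fraction_A = 1)
  tr <- run_dynamics(pop, horizon = 300)
  expect_true(tr$equilibrium)
  expect_equal(alignment(tr)$global,
               alignment(final_population(pop, tr))$global)
})

test_that("volatility counts flips per agent per sweep after burn-in", {
  comp <- half_half()
  rec <- data.frame(sweep = 0:10, delta_o = NA, frac_A = 0.5,
                    frac_aligned = 0.5, flips = 0,
                    frac_A_conf_o10 = 0.5, `frac_A_conf_o-10` = 0.5,
                    check.names = FALSE)
  tr <- fake_trajectory(rec, n = 50, comp)
  expect_equal(volatility(tr, burn_in = 2), 0)      # frozen
  rec$flips <- c(0, rep(1, 10))                     # one flip every sweep
  tr <- fake_trajectory(rec, n = 50, comp)
  expect_equal(volatility(tr, burn_in = 0), 1 / 50)
  expect_equal(volatility(tr, burn_in = 4), 1 / 50)
  expect_error(volatility(tr, burn_in = 10), "burn_in")
})

test_that("tipping detection reports lag and the not-tipped sentinel", {
  comp <- agent_composition(10, 1, 1)
  ls <- env_schedule("linear", delta_o0 = 10, rate = 0.1)  # crosses at 100
  rec <- data.frame(sweep = 0:400, delta_o = 10 - 0.1 * (0:400),
                    frac_A = 1, frac_aligned = NA, flips = 0,
                    frac_A_conf_o10 = 1)
  # never tips
  tr <- fake_trajectory(rec, 100, comp, schedule = ls)
  tp <- tipping_time(tr)
  expect_false(tp$tipped)
  expect_true(is.na(tp$lag))
  # tips at sweep 130
  rec$frac_A <- ifelse(rec$sweep >= 130, 0.2, 1)
  tr <- fake_trajectory(rec, 100, comp, schedule = ls)
  tp <- tipping_time(tr)
  expect_true(tp$tipped)
  expect_equal(tp$crossing_time, 100)
  expect_equal(tp$tipping_time, 130)
  expect_equal(tp$lag, 30)
  # constant schedule has no crossing
  expect_error(tipping_time(tr, env_schedule("constant")), "cross")
  expect_equal(tipping_time(tr, env_schedule("constant"),
                            crossing_time = 100)$lag, 30)
})

test_that("nonconformists under a linear environment tip essentially at the crossing", {
  set.seed(46)
  sc <- scenario(network = list(family = "er", n = 200, mean_degree = 10),
                 base_composition = agent_composition(10, 0, 1),
                 schedule = env_schedule("linear", delta_o0 = 10,
                                         rate = 0.1),
                 initial_fraction_A = 1, horizon = 200, realizations = 5,
                 seed = 3)
  ens <- run_ensemble(sc)
  lags <- vapply(ens$trajectories,
                 function(t) tipping_time(t, sc$schedule)$lag, numeric(1))
  expect_true(all(lags >= 0))
  expect_lte(median(lags), 3)  # only the resampling delay
})

test_that("lead time is signed and validated", {
  comp <- agent_composition(10, 1, 1)
  ss <- env_schedule("sinusoidal", amplitude = 10, period = 200)
  sweep <- 0:600
  rec <- data.frame(sweep = sweep, delta_o = schedule_delta(ss, sweep),
                    frac_A = 0.5, frac_aligned = NA, flips = 0,
                    frac_A_conf_o10 = 0.5)
  # majority tracks the environment with a 20-sweep delay
  delayed <- schedule_delta(ss, pmax(sweep - 20, 0))
  rec$frac_A_conf_o10 <- ifelse(delayed > 0, 1, ifelse(delayed < 0, 0, 0.5))
  tr <- fake_trajectory(rec, 100, comp, schedule = ss)
  ld <- lead_time(tr, subpop = "conf_o10")
  # recorded majority flips one sweep after the delayed zero crossing
  expect_equal(ld$mean_lead, 21)
  # anticipating by 30 sweeps gives a negative lead
  ahead <- schedule_delta(ss, sweep + 30)
  rec$frac_A_conf_o10 <- ifelse(ahead > 0, 1, ifelse(ahead < 0, 0, 0.5))
  tr <- fake_trajectory(rec, 100, comp, schedule = ss)
  expect_lt(lead_time(tr, subpop = "conf_o10")$mean_lead, -25)
  expect_error(lead_time(tr, env_schedule("constant"), "conf_o10"),
               "sinusoidal")
  expect_error(lead_time(tr, subpop = "nope"), "unknown")
})

test_that("welfare decomposes exactly into preference and social terms", {
  g <- full_graph(10)
  comp <- half_half()
  pop <- init_population(g, comp, initial_fraction_A = 0.5)
  pop$spin <- ifelse(pop$delta_o > 0, 1L, -1L)
  wf <- welfare(pop)
  expect_equal(wf$preference_utility, 5)  # full alignment at |delta_o|=10
  expect_equal(wf$total, wf$preference_utility + wf$social_utility)
  # consensus maximizes social utility for conformists
  cons <- pop; cons$spin <- rep(1L, 10)
  expect_gt(welfare(cons)$social_utility, welfare(pop)$social_utility)
  set.seed(48)
  for (i in 1:5) {
    cand <- pop
    cand$spin <- sample(c(-1L, 1L), 10, replace = TRUE)
    expect_lte(welfare(cand)$social_utility, welfare(cons)$social_utility)
    w2 <- welfare(cand)
    expect_equal(w2$total, w2$preference_utility + w2$social_utility)
  }
  # preference utility is affine in alignment at constant |delta_o|
  a <- vapply(0:10, function(k) {
    cand <- pop
    cand$spin <- ifelse(seq_len(10) <= k, 1L, -1L) *
      ifelse(cand$delta_o > 0, 1L, -1L)
    welfare(cand)$preference_utility
  }, numeric(1))
  expect_equal(diff(a), rep(1, 10))  # slope |delta_o|/2 * 2/n * n = const
})
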