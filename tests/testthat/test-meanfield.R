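test_that("response map composes subpopulation logistic responses", {
  m <- mean_field_model(agent_composition(0, 1, 1), k = 10)
  expect_equal(response_map(m, 0.5), 0.5)
  # nonconformists respond independently of X
  mn <- mean_field_model(agent_composition(10, 0, 1), k = 10)
  expect_equal(response_map(mn, seq(0, 1, 0.1)), rep(1, 11),
               tolerance = 1e-12)
  # pure anticonformists at delta_o = 0: strictly decreasing
  ma <- mean_field_model(agent_composition(0, -1, 1), k = 10, beta = 1)
  g <- response_map(ma, seq(0, 1, 0.05))
  expect_true(all(diff(g) < 0))
  expect_true(all(g >= 0 & g <= 1))
  expect_error(response_map(m, 1.5), "0, 1")
  expect_error(mean_field_model(agent_composition(0, 1, 1), k = -1))
})

test_that("fixed points of the symmetric bistable map are {0, 1/2, 1}", {
  m <- mean_field_model(agent_composition(0, 1, 1), k = 20)
  fp <- find_fixed_points(m)
  expect_equal(fp$X_star, c(0, 0.5, 1), tolerance = 1e-6)
  expect_equal(fp$stable, c(TRUE, FALSE, TRUE))
  expect_true(all(fp$residual < 1e-8))
  # nonconformists with a positive preference: unique stable root at 1
  mn <- mean_field_model(agent_composition(10, 0, 1), k = 20)
  fpn <- find_fixed_points(mn)
  expect_equal(nrow(fpn), 1)
  expect_equal(fpn$X_star, 1, tolerance = 1e-9)
  expect_true(fpn$stable)
})

test_that("the half/half conformist composition shows the conformity trap", {
  m <- mean_field_model(half_half(), k = 20)
  fp <- find_fixed_points(m)
  stable <- fp$X_star[fp$stable]
  # two misaligned consensus roots flanking the expressive root at 1/2
  expect_equal(sort(stable), c(0, 0.5, 1), tolerance = 1e-6)
  expect_equal(sum(!fp$stable), 2)
  # at the trap root X = 1 both preference groups choose A
  top <- fp[which.max(fp$X_star), ]
  expect_equal(top[["x_conf_o10"]], 1, tolerance = 1e-9)
  expect_equal(top[["x_conf_o-10"]], 1, tolerance = 1e-9)
})

test_that("mirror symmetry maps fixed points to their complements", {
  set.seed(70)
  for (i in 1:5) {
    comp <- agent_composition(delta_o = runif(3, -8, 8),
                              w = c(runif(2, 0.2, 1.5), -runif(1, 0.2, 1.5)),
                              frac = rep(1 / 3, 3))
    mir <- agent_composition(-comp$delta_o, comp$w, comp$frac)
    m1 <- mean_field_model(comp, k = 15, beta = 5)
    m2 <- mean_field_model(mir, k = 15, beta = 5)
    X <- seq(0, 1, 0.01)
    expect_equal(response_map(m1, X), 1 - response_map(m2, 1 - X),
                 tolerance = 1e-12)
    f1 <- find_fixed_points(m1)
    f2 <- find_fixed_points(m2)
    expect_equal(sort(f1$X_star), sort(1 - f2$X_star), tolerance = 1e-6)
    expect_equal(f1$stable[order(f1$X_star)],
                 rev(f2$stable[order(f2$X_star)]))
    # odd number of roots off the grid boundary (degree argument)
    if (all(f1$residual < 1e-10) && all(f1$X_star %% 1 > 1e-9))
      expect_equal(nrow(f1) %% 2, 1)
  }
})

test_that("critical fraction: boundary case, bisection vs brute force", {
  # preferences dominate conformity: no bistability, f* = 0
  weak <- mean_field_model(half_half(delta = 10, w = 0.2), k = 20)
  expect_equal(critical_fraction(weak)$f_star, 0)
  # the half/half trap model loses its misaligned branch at f*
  m <- mean_field_model(half_half(), k = 40)
  cf <- critical_fraction(m, tol_f = 1e-4)
  expect_true(cf$found)
  # step-rule prediction: trap root 1 - f crosses the conformist
  # flip threshold 1/2 + delta_o / (2 k)
  expect_equal(cf$f_star, 0.5 - 10 / (2 * 40), tolerance = 5e-3)
  expect_gt(cf$jump, 0.1)  # discontinuous branch jump
  # brute-force scan agrees with the bisection
  fs <- seq(0, 0.6, by = 0.002)
  n_stab <- vapply(fs, function(f) {
    comp <- mix_anticonformists(m$subpops, f)
    sum(find_fixed_points(mean_field_model(comp, 40))$stable)
  }, numeric(1))
  brute <- fs[which(n_stab <= 1)[1]]
  expect_lt(abs(cf$f_star - brute), 0.002 + 1e-4)
  # stronger conformity pressure (larger w k relative to delta_o)
  # needs a larger anticonformist share to break the trap
  cf2 <- critical_fraction(mean_field_model(half_half(), k = 25),
                           tol_f = 1e-4)
  expect_lt(cf2$f_star, cf$f_star)
  # no transition in a too-small range is reported, not invented
  expect_false(critical_fraction(m, f_range = c(0, 0.1))$found)
})

test_that("nonconformists need twice the critical fraction of anticonformists", {
  m <- mean_field_model(half_half(), k = 40)
  f_anti <- critical_fraction(m, anti_w = -1, tol_f = 1e-4)$f_star
  f_non <- critical_fraction(m, anti_w = 0, f_range = c(0, 0.95),
                             tol_f = 1e-4)$f_star
  expect_equal(f_anti / f_non, 0.5, tolerance = 0.02)
})

test_that("finite Markov chain: symmetry, absorption flag, ergodic oracle", {
  # two indifferent conformists at large beta: symmetric absorption
  m2 <- mean_field_model(agent_composition(0, 1, 1), k = 1, beta = 100)
  mk2 <- finite_markov_stationary(m2, 2)
  expect_true(mk2$absorbing)
  expect_equal(mk2$absorption$prob[mk2$absorption[[1]] == 0],
               mk2$absorption$prob[mk2$absorption[[1]] == 2])
  # moderate beta: stationary distribution matches a long simulation
  comp <- agent_composition(c(0.5, -0.5), c(0.25, 0.25), c(0.5, 0.5))
  mf <- mean_field_model(comp, k = 7, beta = 2)
  mk <- finite_markov_stationary(mf, 8)
  expect_false(mk$absorbing)
  expect_equal(sum(mk$stationary), 1, tolerance = 1e-9)
  set.seed(80)
  g <- full_graph(8)
  pop <- init_population(g, comp, initial_fraction_A = 0.5,
                         init_mode = "by_subpop",
                         params = decision_params(2))
  tr <- run_dynamics(pop, horizon = 60000, quiet_sweeps = 0)
  n1 <- tr$subpop_sizes[1]
  key <- paste(round(tr$records[[paste0("frac_A_", comp$name[1])]] * n1),
               round(tr$records[[paste0("frac_A_", comp$name[2])]] *
                       (8 - n1)))
  emp <- table(key) / length(key)
  theo <- tapply(mk$stationary,
                 paste(mk$states[[1]], mk$states[[2]]), sum)
  all_states <- union(names(emp), names(theo))
  tv <- 0.5 * sum(abs(ifelse(all_states %in% names(emp),
                             emp[all_states], 0) -
                      ifelse(all_states %in% names(theo),
                             theo[all_states], 0)))
  expect_lt(tv, 0.02)
  # state-space guard
  big <- mean_field_model(agent_composition(0, 1, 1), k = 10)
  expect_error(finite_markov_stationary(big, 2e5), "state space")
})

test_that("stationary mass concentrates near the mean-field stable roots", {
  comp <- agent_composition(1, 0.4, 1)
  gap <- vapply(c(8, 12), function(N) {
    mfN <- mean_field_model(comp, k = N - 1, beta = 1.2)
    fpN <- find_fixed_points(mfN)
    x_stable <- fpN$X_star[fpN$stable]
    mk <- finite_markov_stationary(mfN, N)
    mode_x <- mk$states[[1]][which.max(mk$stationary)] / N
    min(abs(mode_x - x_stable))
  }, numeric(1))
  expect_lte(gap[2], gap[1] + 1e-9)
  expect_lt(gap[2], 0.15)
})
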