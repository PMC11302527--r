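# small graphs and populations used across tests

full_graph <- function(n) igraph::make_full_graph(n)

ring_graph <- function(n) igraph::make_ring(n)

half_half <- function(delta = 10, w = 1)
  agent_composition(delta_o = c(delta, -delta), w = c(w, w),
                    frac = c(0.5, 0.5))

# population with explicitly set spins
pop_with_spins <- function(g, comp, spins, anti = NULL, beta = 100) {
  pop <- init_population(g, comp, anti, initial_fraction_A = 0.5,
                         params = decision_params(beta))
  pop$spin <- as.integer(spins)
  pop
}

# minimal hand-built trajectory for metric unit tests
fake_trajectory <- function(records, n, comp, sweeps_run = max(records$sweep),
                            schedule = NULL) {
  structure(list(records = records, final_spin = NULL,
                 flips_per_node = NULL, equilibrium = TRUE,
                 sweeps_run = sweeps_run, n = n,
                 subpop_sizes = rep(n / nrow(comp), nrow(comp)),
                 composition = comp, schedule = schedule,
                 record_every = 1),
            class = "abm_trajectory")
}
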