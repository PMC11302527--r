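#' One asynchronous update step
#'
#' Picks one agent uniformly at random and resamples its choice with the
#' Fermi rule given its current neighbourhood; all other agents are
#' untouched. Mainly useful for inspection and testing; long runs should
#' use [run_dynamics()], which performs the same update in compiled code.
#'
#' @param pop an `abm_population`.
#' @param schedule optional [env_schedule()]; when given, the agent uses
#'   the shared net preference `schedule_delta(schedule, t)` instead of
#'   its own `delta_o`.
#' @param t current time in sweeps (used only with a schedule).
#' @return list with `pop` (updated population), `agent` (index updated)
#'   and `flipped` (logical).
#' @export
async_step <- function(pop, schedule = NULL, t = 0) {
  stopifnot(inherits(pop, "abm_population"), t >= 0)
  n <- igraph::vcount(pop$graph)
  i <- sample.int(n, 1)
  nb <- as.integer(igraph::neighbors(pop$graph, i))
  n_A <- sum(pop$spin[nb] > 0)
  n_B <- length(nb) - n_A
  d_i <- if (is.null(schedule)) pop$delta_o[i] else schedule_delta(schedule, t)
  new <- choice_to_spin(sample_choice(d_i, pop$w[i], n_A, n_B, pop$params))
  flipped <- new != pop$spin[i]
  pop$spin[i] <- new
  list(pop = pop, agent = i, flipped = flipped)
}

# flattened 0-based CSR adjacency for the compiled engine
adj_csr <- function(g) {
  adjl <- igraph::as_adj_list(g)
  lens <- lengths(adjl)
  list(adj = as.integer(unlist(adjl, use.names = FALSE)) - 1L,
       ptr = as.integer(c(0L, cumsum(lens))))
}

#' Run the asynchronous choice dynamics
#'
#' Executes `horizon` sweeps (one sweep = N single-agent updates) of the
#' Fermi-rule dynamics in compiled code, recording the global and
#' per-subpopulation fractions choosing A, the fraction of agents aligned
#' with their current preference, and flip counts. For constant
#' environments the run stops early once no choice has changed for
#' `quiet_sweeps` consecutive sweeps (quasi-equilibrium) and the
#' trajectory is flagged accordingly.
#'
#' @param pop an `abm_population`.
#' @param schedule optional [env_schedule()]. `NULL` keeps each agent's
#'   own static `delta_o`; a `constant` schedule imposes one shared static
#'   preference; `linear`/`sinusoidal` schedules impose a shared
#'   time-varying preference evaluated once per sweep.
#' @param horizon maximum number of sweeps (>= 1).
#' @param record_every recording cadence in sweeps.
#' @param quiet_sweeps flip-free sweeps required to declare
#'   quasi-equilibrium (static runs only); 0 disables early stopping.
#' @return an object of class `abm_trajectory`: list with `records` (data
#'   frame: sweep, delta_o, frac_A, frac_aligned, flips, plus one
#'   `frac_A_<name>` column per subpopulation), `final_spin`,
#'   `flips_per_node`, `equilibrium`, `sweeps_run`, `n`, `subpop_sizes`,
#'   `composition`, `schedule`.
#' @export
run_dynamics <- function(pop, schedule = NULL, horizon = 2000,
                         record_every = 1, quiet_sweeps = 50) {
  stopifnot(inherits(pop, "abm_population"), horizon >= 1)
  n <- igraph::vcount(pop$graph)
  csr <- adj_csr(pop$graph)
  static <- is.null(schedule) || schedule$kind == "constant"
  delta_o <- pop$delta_o
  if (!is.null(schedule) && schedule$kind == "constant")
    delta_o <- rep(schedule$delta_o0, n)
  sched_vec <- if (static) numeric(0)
               else schedule_delta(schedule, seq_len(horizon) - 1)
  n_sub <- nrow(pop$composition)
  res <- run_abm_cpp(csr$adj, csr$ptr, pop$spin, as.numeric(delta_o),
                     as.numeric(pop$w), pop$params$beta, sched_vec,
                     as.integer(horizon), as.integer(record_every),
                     as.integer(if (static) quiet_sweeps else 0L),
                     pop$subpop - 1L, n_sub)
  rec <- data.frame(sweep = res$sweep, delta_o = res$delta_o,
                    frac_A = res$frac_A, frac_aligned = res$frac_aligned,
                    flips = res$flips)
  sub <- as.data.frame(res$frac_A_sub)
  names(sub) <- paste0("frac_A_", pop$composition$name)
  rec <- cbind(rec, sub)
  if (static && all(is.na(rec$delta_o)) &&
      length(unique(delta_o)) == 1)
    rec$delta_o <- delta_o[1]
  structure(list(records = rec, final_spin = res$final_spin,
                 flips_per_node = res$flips_per_node,
                 equilibrium = res$equilibrium,
                 sweeps_run = res$sweeps_run, n = n,
                 subpop_sizes = tabulate(pop$subpop, n_sub),
                 composition = pop$composition,
                 schedule = schedule, record_every = record_every),
            class = "abm_trajectory")
}

#' @export
print.abm_trajectory <- function(x, ...) {
  cat(sprintf(
    "abm_trajectory: %d agents, %d sweeps (%s), final fraction A %.3f\n",
    x$n, x$sweeps_run,
    if (x$equilibrium) "quasi-equilibrium" else "horizon reached",
    utils::tail(x$records$frac_A, 1)))
  invisible(x)
}

#' Final state of a trajectory as a population
#'
#' Re-attaches the final choices of a run to its population, so state
#' metrics ([alignment()], [welfare()]) can be computed on the end point.
#'
#' @param pop the `abm_population` the trajectory was run from.
#' @param traj an `abm_trajectory`.
#' @return the population with `spin` replaced by the final choices.
#' @export
final_population <- function(pop, traj) {
  stopifnot(inherits(pop, "abm_population"), inherits(traj, "abm_trajectory"))
  pop$spin <- as.integer(traj$final_spin)
  pop
}

#' Write a trajectory (or ensemble) as tidy CSV
#'
#' One row per (realization, recorded sweep), columns as in the trajectory
#' records plus a `realization` index.
#'
#' @param x an `abm_trajectory` or `abm_ensemble`.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(x, file) {
  if (inherits(x, "abm_trajectory")) x <- list(x)
  if (inherits(x, "abm_ensemble")) x <- x$trajectories
  rows <- lapply(seq_along(x), function(i)
    cbind(realization = i, x[[i]]$records))
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}
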