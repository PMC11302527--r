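#' Define a simulation scenario
#'
#' A scenario bundles everything needed to reproduce an ensemble of runs:
#' network family and parameters, anticonformist fraction and placement
#' target, base subpopulation composition (the anticonformist share is
#' mixed in with [mix_anticonformists()]), environment schedule, decision
#' parameters, horizon, ensemble size and master seed. Scenarios
#' serialize losslessly to YAML/JSON configs (see [write_config()]).
#'
#' @param name scenario label.
#' @param network list: `family` (`"ba"`, `"er"` or `"file"`), `n`, and
#'   `m` (BA), `mean_degree` (ER) or `path` (edge-list file).
#' @param fraction_anti fraction of agents replaced by weight-`anti_w`
#'   agents.
#' @param target_corr degree-type correlation target (number, `"max"` or
#'   `"min"`); ignored when `fraction_anti = 0` or `anti_w >= 0`.
#' @param base_composition [agent_composition()] of the `f = 0`
#'   population.
#' @param anti_w,anti_delta_o weight (and optional preference override)
#'   of the introduced agents; see [mix_anticonformists()].
#' @param schedule an [env_schedule()] or `NULL` (agents keep their own
#'   static preferences).
#' @param beta inverse temperature.
#' @param initial_fraction_A,init_mode initial choice assignment, see
#'   [init_population()].
#' @param horizon,record_every,quiet_sweeps run controls, see
#'   [run_dynamics()].
#' @param assortative_mode optional `"assortative"` / `"disassortative"` /
#'   `"neutral"` rewiring applied to the generated network.
#' @param assortative_steps proposed rewirings (default `10 * edges`).
#' @param assortative_target_r optional assortativity magnitude to stop
#'   at, see [rewire_assortative()].
#' @param realizations ensemble size.
#' @param seed master seed; every realization derives independent
#'   substream seeds for network, placement, initialization and dynamics.
#' @param placement_tolerance,placement_max_iters swap-loop controls, see
#'   [place_types()].
#' @param thresholds list of metric thresholds: `alignment` (expression
#'   threshold, default 0.9), `tipping` (B-fraction, default 0.5),
#'   `burn_in` (volatility burn-in, default 100 sweeps).
#' @return an object of class `abm_scenario`.
#' @export
scenario <- function(name = "scenario",
                     network = list(family = "ba", n = 500, m = 20),
                     fraction_anti = 0, target_corr = 0,
                     base_composition = agent_composition(
                       delta_o = c(10, -10), w = c(1, 1),
                       frac = c(0.5, 0.5)),
                     anti_w = -1, anti_delta_o = NULL,
                     schedule = NULL, beta = 100,
                     initial_fraction_A = 1,
                     init_mode = "random",
                     horizon = 2000, record_every = 1, quiet_sweeps = 50,
                     assortative_mode = NULL, assortative_steps = NULL,
                     assortative_target_r = NULL,
                     realizations = 20, seed = 1,
                     placement_tolerance = 0.01,
                     placement_max_iters = 1e6,
                     thresholds = list()) {
  stopifnot(is.list(network), !is.null(network$family))
  stopifnot(fraction_anti >= 0, fraction_anti < 1)
  thresholds <- modifyList(list(alignment = 0.9, tipping = 0.5,
                                burn_in = 100), thresholds)
  structure(list(name = name, network = network,
                 fraction_anti = fraction_anti, target_corr = target_corr,
                 base_composition = base_composition, anti_w = anti_w,
                 anti_delta_o = anti_delta_o, schedule = schedule,
                 beta = beta, initial_fraction_A = initial_fraction_A,
                 init_mode = init_mode, horizon = horizon,
                 record_every = record_every, quiet_sweeps = quiet_sweeps,
                 assortative_mode = assortative_mode,
                 assortative_steps = assortative_steps,
                 assortative_target_r = assortative_target_r,
                 realizations = realizations, seed = seed,
                 placement_tolerance = placement_tolerance,
                 placement_max_iters = placement_max_iters,
                 thresholds = thresholds),
            class = "abm_scenario")
}

#' @export
print.abm_scenario <- function(x, ...) {
  cat(sprintf(
    "abm_scenario '%s': %s network n=%d, f_anti=%.3g (w=%g), %s schedule, %d realizations, seed %d\n",
    x$name, x$network$family, x$network$n, x$fraction_anti, x$anti_w,
    if (is.null(x$schedule)) "static" else x$schedule$kind,
    x$realizations, x$seed))
  invisible(x)
}

scenario_network <- function(sc) {
  net <- switch(sc$network$family,
    ba = generate_ba(sc$network$n, sc$network$m),
    er = generate_er(sc$network$n, sc$network$mean_degree),
    file = read_network(sc$network$path, n_nodes = sc$network$n),
    stop("unknown network family: ", sc$network$family, call. = FALSE))
  if (!is.null(sc$assortative_mode))
    net <- rewire_assortative(net, sc$assortative_mode,
                              sc$assortative_steps,
                              sc$assortative_target_r)
  net
}

#' Simulate one realization of a scenario
#'
#' Independent substream seeds derived from `seed` drive network
#' generation, type placement, initialization and dynamics, so any one
#' component can be varied with the others held fixed.
#'
#' @param sc an [scenario()].
#' @param seed integer seed for this realization.
#' @return an `abm_trajectory` with attributes `achieved_corr` (realized
#'   degree-type correlation) and `assortativity_r` (Newman coefficient of
#'   the network used).
#' @export
simulate_realization <- function(sc, seed) {
  seeds <- derive_seeds(seed, 4,
                        c("network", "placement", "init", "dynamics"))
  set.seed(seeds["network"])
  net <- scenario_network(sc)
  comp <- mix_anticonformists(sc$base_composition, sc$fraction_anti,
                              sc$anti_w, sc$anti_delta_o)
  anti <- NULL
  achieved <- NA_real_
  if (any(comp$w < 0)) {
    set.seed(seeds["placement"])
    pl <- place_types(net, sum(comp$frac[comp$w < 0]), sc$target_corr,
                      sc$placement_tolerance, sc$placement_max_iters)
    anti <- pl$anti
    achieved <- pl$achieved
  }
  set.seed(seeds["init"])
  pop <- init_population(net, comp, anti, sc$initial_fraction_A,
                         sc$init_mode, decision_params(sc$beta))
  set.seed(seeds["dynamics"])
  traj <- run_dynamics(pop, sc$schedule, sc$horizon, sc$record_every,
                       sc$quiet_sweeps)
  attr(traj, "achieved_corr") <- achieved
  attr(traj, "assortativity_r") <- igraph::assortativity_degree(net)
  attr(traj, "population") <- pop
  traj
}

#' Run an ensemble of independent realizations
#'
#' @param sc an [scenario()].
#' @param n_realizations ensemble size (default from the scenario).
#' @param seed master seed (default from the scenario); per-realization
#'   seeds are derived from it, or a vector of length `n_realizations`
#'   may be given directly.
#' @return an object of class `abm_ensemble`: `trajectories` (list),
#'   `summary` (per recorded sweep: median and 25/75% quantiles of the
#'   global A-fraction and per-subpopulation medians; runs that stopped
#'   early are carried forward at their final value), `scenario`, `seeds`.
#' @export
run_ensemble <- function(sc, n_realizations = NULL, seed = NULL) {
  stopifnot(inherits(sc, "abm_scenario"))
  n_realizations <- n_realizations %||% sc$realizations
  seed <- seed %||% sc$seed
  seeds <- if (length(seed) == n_realizations && n_realizations > 1) seed
           else derive_seeds(seed, n_realizations)
  trajs <- lapply(seeds, function(s) simulate_realization(sc, s))
  structure(list(trajectories = trajs,
                 summary = ensemble_summary(trajs),
                 scenario = sc, seeds = seeds),
            class = "abm_ensemble")
}

# median/quantile bands over realizations on a common sweep grid,
# carrying early-stopped runs forward at their final value
ensemble_summary <- function(trajs) {
  grid <- sort(unique(unlist(lapply(trajs, function(t) t$records$sweep))))
  cols <- setdiff(names(trajs[[1]]$records), c("sweep", "flips"))
  per_col <- lapply(cols, function(cl) {
    m <- vapply(trajs, function(tr) {
      idx <- findInterval(grid, tr$records$sweep)
      idx[idx < 1] <- 1
      tr$records[[cl]][idx]
    }, numeric(length(grid)))
    m <- matrix(m, nrow = length(grid))
    data.frame(median = apply(m, 1, median, na.rm = TRUE),
               q25 = apply(m, 1, quantile, 0.25, na.rm = TRUE, names = FALSE),
               q75 = apply(m, 1, quantile, 0.75, na.rm = TRUE, names = FALSE))
  })
  out <- data.frame(sweep = grid)
  for (i in seq_along(cols)) {
    d <- per_col[[i]]
    names(d) <- paste0(cols[i], c("_med", "_q25", "_q75"))
    out <- cbind(out, d)
  }
  out
}

#' @export
print.abm_ensemble <- function(x, ...) {
  cat(sprintf("abm_ensemble: %d realizations of '%s'\n",
              length(x$trajectories), x$scenario$name))
  invisible(x)
}

#' Run a scenario and compute its outcome metrics
#'
#' Runs the ensemble and evaluates, per realization, the metrics relevant
#' to the schedule kind: equilibrium alignment and volatility (static),
#' tipping time and lag (linear), time-averaged alignment (dynamic).
#' Optionally writes the tidy trajectory CSV and a JSON summary embedding
#' the resolved configuration.
#'
#' @param sc an [scenario()].
#' @param out_dir optional output directory; created if missing.
#' @param ... passed to [run_ensemble()].
#' @return list of class `scenario_result`: `ensemble`, `metrics` (one
#'   row per realization), `summary` (medians across realizations),
#'   `scenario`.
#' @export
run_scenario <- function(sc, out_dir = NULL, ...) {
  ens <- run_ensemble(sc, ...)
  kind <- if (is.null(sc$schedule)) "static" else sc$schedule$kind
  rows <- lapply(seq_along(ens$trajectories), function(i) {
    tr <- ens$trajectories[[i]]
    row <- data.frame(realization = i,
                      achieved_corr = attr(tr, "achieved_corr"),
                      assortativity_r = attr(tr, "assortativity_r"),
                      equilibrium = tr$equilibrium,
                      sweeps_run = tr$sweeps_run,
                      final_frac_A = utils::tail(tr$records$frac_A, 1))
    al <- tryCatch(alignment(tr), error = function(e) NULL)
    row$alignment <- if (is.null(al)) NA_real_ else al$global
    if (kind %in% c("static", "constant")) {
      bi <- min(sc$thresholds$burn_in, tr$sweeps_run - 1)
      row$volatility <- volatility(tr, bi)
    }
    if (kind == "linear") {
      tp <- tipping_time(tr, sc$schedule, sc$thresholds$tipping)
      row$tipping_time <- tp$tipping_time
      row$tipping_lag <- tp$lag
      row$tipped <- tp$tipped
    }
    if (kind %in% c("linear", "sinusoidal")) {
      rec <- tr$records
      va <- rec$frac_aligned[!is.na(rec$frac_aligned)]
      row$mean_alignment_over_time <- mean(va)
    }
    row
  })
  metrics <- do.call(rbind, rows)
  num <- vapply(metrics, is.numeric, logical(1))
  summ <- lapply(metrics[num], median, na.rm = TRUE)
  summ$realization <- NULL
  res <- structure(list(ensemble = ens, metrics = metrics,
                        summary = summ, scenario = sc),
                   class = "scenario_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory(ens, file.path(out_dir,
                                    paste0(sc$name, "_trajectory.csv")))
    payload <- list(scenario = scenario_to_config(sc),
                    package_version =
                      as.character(utils::packageVersion("anticonf")),
                    metrics = metrics, summary = summ)
    jsonlite::write_json(payload,
                         file.path(out_dir, paste0(sc$name, "_summary.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario_result '%s' (%d realizations)\n",
              x$scenario$name, nrow(x$metrics)))
  str(x$summary, give.attr = FALSE)
  invisible(x)
}

set_scenario_field <- function(sc, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  cur <- sc
  for (p in parts) {
    if (!is.list(cur) || !(p %in% names(cur)))
      stop("unknown scenario field: ", path, call. = FALSE)
    cur <- cur[[p]]
  }
  if (!is.null(cur) && (!is.atomic(cur) || length(cur) != 1))
    stop("`axis` must resolve to a scalar field: ", path, call. = FALSE)
  sc[[parts]] <- value
  sc
}

#' Sweep a scenario over one scalar parameter
#'
#' Runs one ensemble per value of a scalar configuration field (dotted
#' path, e.g. `"fraction_anti"` or `"network.m"`), collecting the
#' per-realization metrics in long format.
#'
#' @param sc an [scenario()].
#' @param axis dotted path to a scalar field of the scenario.
#' @param values vector of values to sweep.
#' @param ... passed to [run_scenario()] (e.g. `n_realizations`).
#' @return data frame of class `scenario_sweep`: metrics rows with an
#'   `axis_value` column; the summary across realizations per value is
#'   in `attr(, "summary")`.
#' @export
sweep_scenario <- function(sc, axis, values, ...) {
  stopifnot(inherits(sc, "abm_scenario"), length(values) >= 1)
  if (length(values) > 0 && !is.atomic(values))
    stop("`values` must be a vector of scalars", call. = FALSE)
  res <- lapply(values, function(v) {
    sci <- set_scenario_field(sc, axis, v)
    r <- run_scenario(sci, ...)
    cbind(axis_value = v, r$metrics)
  })
  out <- do.call(rbind, res)
  num <- names(out)[vapply(out, is.numeric, logical(1))]
  num <- setdiff(num, c("axis_value", "realization"))
  summ <- do.call(rbind, lapply(split(out, out$axis_value), function(d)
    cbind(data.frame(axis_value = d$axis_value[1]),
          as.data.frame(lapply(d[num], median, na.rm = TRUE)))))
  attr(out, "summary") <- summ
  attr(out, "axis") <- axis
  class(out) <- c("scenario_sweep", "data.frame")
  out
}

#' Empirical critical anticonformist fraction of a scenario
#'
#' Bisects on the fraction of introduced agents for the smallest value at
#' which the median equilibrium alignment of the ensemble reaches the
#' expression threshold. The same master seed is reused at every
#' evaluated fraction (common random numbers), which makes the bisection
#' deterministic and reduces sampling noise.
#'
#' @param sc an [scenario()] (static schedule).
#' @param theta expression threshold on the median alignment (default the
#'   scenario's `thresholds$alignment`).
#' @param f_range search interval for the fraction.
#' @param tol_f bisection tolerance.
#' @param ... passed to [run_ensemble()] (e.g. `n_realizations`).
#' @return list of class `critical_fraction_abm`: `f_star`, `found`,
#'   `evaluations` (data frame of fraction, median alignment).
#' @export
find_critical_fraction_abm <- function(sc, theta = NULL,
                                       f_range = c(0, 0.6), tol_f = 0.01,
                                       ...) {
  stopifnot(inherits(sc, "abm_scenario"))
  theta <- theta %||% sc$thresholds$alignment
  evals <- data.frame(f = numeric(0), median_alignment = numeric(0))
  med_align <- function(f) {
    sci <- sc
    sci$fraction_anti <- f
    ens <- run_ensemble(sci, ...)
    al <- vapply(ens$trajectories, function(tr) alignment(tr)$global,
                 numeric(1))
    m <- median(al)
    evals <<- rbind(evals, data.frame(f = f, median_alignment = m))
    m
  }
  lo <- f_range[1]; hi <- f_range[2]
  if (med_align(lo) >= theta)
    return(structure(list(f_star = lo, found = TRUE, evaluations = evals),
                     class = "critical_fraction_abm"))
  if (med_align(hi) < theta)
    return(structure(list(f_star = NA_real_, found = FALSE,
                          evaluations = evals),
                     class = "critical_fraction_abm"))
  while (hi - lo > tol_f) {
    mid <- (lo + hi) / 2
    if (med_align(mid) >= theta) hi <- mid else lo <- mid
  }
  structure(list(f_star = (lo + hi) / 2, found = TRUE,
                 evaluations = evals),
            class = "critical_fraction_abm")
}

#' @export
print.critical_fraction_abm <- function(x, ...) {
  if (x$found)
    cat(sprintf("empirical critical fraction f* = %.3f (%d ensemble evaluations)\n",
                x$f_star, nrow(x$evaluations)))
  else cat("no critical fraction found in the searched range\n")
  invisible(x)
}

#' Mean-field bifurcation scan over the anticonformist fraction
#'
#' Fixed points and stability across a grid of fractions, with the
#' discontinuity of the followed stable branch (the largest stable root)
#' marked.
#'
#' @param base_model a [mean_field_model()] at `f = 0`.
#' @param f_grid fractions to scan.
#' @inheritParams critical_fraction
#' @return data frame (`f`, `X_star`, `stable`) with attribute `f_jump`:
#'   the grid location of the largest drop in the followed stable branch
#'   (NA if the branch moves continuously).
#' @export
meanfield_scan <- function(base_model, f_grid, anti_w = -1,
                           anti_delta_o = NULL, grid_size = 4001) {
  rows <- lapply(f_grid, function(f) {
    comp <- mix_anticonformists(base_model$subpops, f, anti_w,
                                anti_delta_o)
    fp <- find_fixed_points(mean_field_model(comp, base_model$k,
                                             base_model$beta), grid_size)
    data.frame(f = f, X_star = fp$X_star, stable = fp$stable)
  })
  out <- do.call(rbind, rows)
  branch <- vapply(split(out, out$f),
                   function(d) max(d$X_star[d$stable]), numeric(1))
  f_sorted <- sort(unique(out$f))
  jumps <- -diff(branch[order(unique(out$f))])
  attr(out, "f_jump") <- if (length(jumps) && max(jumps) > 0.1)
    f_sorted[which.max(jumps) + 1] else NA_real_
  attr(out, "branch_jump") <- if (length(jumps)) max(jumps) else 0
  out
}
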