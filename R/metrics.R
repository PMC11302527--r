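#' Choice-preference alignment
#'
#' Fraction of agents whose current choice matches the sign of their net
#' preference (A for \eqn{\Delta o > 0}, B for \eqn{\Delta o < 0}). Agents
#' with \eqn{\Delta o = 0} have no defined preference and are excluded;
#' their count is reported. For a trajectory, the per-sweep aligned
#' fraction is averaged over the last `window` sweeps of the run (the
#' quasi-equilibrium window).
#'
#' @param x an `abm_population` or `abm_trajectory`.
#' @param window averaging window in sweeps (trajectories only).
#' @return an object of class `alignment_result`: list with `global`,
#'   `by_subpop` (named vector) and `n_excluded`.
#' @export
alignment <- function(x, window = 10) {
  if (inherits(x, "abm_population")) {
    keep <- x$delta_o != 0
    if (!any(keep))
      stop("alignment undefined: every agent has delta_o = 0", call. = FALSE)
    match_i <- (x$delta_o > 0) == (x$spin > 0)
    by_sub <- vapply(seq_len(nrow(x$composition)), function(r) {
      ids <- which(x$subpop == r & keep)
      if (length(ids) == 0) return(NA_real_)
      mean(match_i[ids])
    }, numeric(1))
    names(by_sub) <- x$composition$name
    return(structure(list(global = mean(match_i[keep]),
                          by_subpop = by_sub,
                          n_excluded = sum(!keep)),
                     class = "alignment_result"))
  }
  stopifnot(inherits(x, "abm_trajectory"))
  rec <- x$records
  rows <- rec$sweep > max(rec$sweep) - window
  if (all(is.na(rec$frac_aligned[rows])))
    stop("alignment undefined: every agent has delta_o = 0", call. = FALSE)
  comp <- x$composition
  sub_cols <- paste0("frac_A_", comp$name)
  dynamic <- !is.null(x$schedule) &&
    x$schedule$kind %in% c("linear", "sinusoidal")
  by_sub <- vapply(seq_len(nrow(comp)), function(r) {
    if (dynamic) {
      # shared time-varying preference: alignment follows its sign
      d <- rec$delta_o[rows]
      f <- rec[[sub_cols[r]]][rows]
      vals <- ifelse(d > 0, f, ifelse(d < 0, 1 - f, NA))
      return(mean(vals, na.rm = TRUE))
    }
    if (comp$delta_o[r] == 0) return(NA_real_)
    f <- mean(rec[[sub_cols[r]]][rows])
    if (comp$delta_o[r] > 0) f else 1 - f
  }, numeric(1))
  names(by_sub) <- comp$name
  structure(list(global = mean(rec$frac_aligned[rows], na.rm = TRUE),
                 by_subpop = by_sub,
                 n_excluded = sum(x$subpop_sizes[comp$delta_o == 0])),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment: %.3f global (%d agents excluded)\n",
              x$global, x$n_excluded))
  for (nm in names(x$by_subpop))
    cat(sprintf("  %-12s %.3f\n", nm, x$by_subpop[nm]))
  invisible(x)
}

#' Choice volatility
#'
#' Number of choice changes per agent per sweep after a burn-in period: a
#' proximity signal for the critical point, where flip activity peaks.
#'
#' @param traj an `abm_trajectory`.
#' @param burn_in sweeps discarded before counting (must be shorter than
#'   the run).
#' @return flips per agent per sweep (non-negative).
#' @export
volatility <- function(traj, burn_in = 100) {
  stopifnot(inherits(traj, "abm_trajectory"))
  if (burn_in >= traj$sweeps_run)
    stop("`burn_in` must be shorter than the trajectory", call. = FALSE)
  rec <- traj$records
  flips <- sum(rec$flips[rec$sweep > burn_in])
  flips / traj$n / (traj$sweeps_run - burn_in)
}

#' Social tipping time and cultural lag
#'
#' For a monotone (linear) environment schedule that crosses zero, finds
#' the first time the global fraction choosing B exceeds `threshold` and
#' reports the lag behind the environmental crossing. A trajectory that
#' never reaches the threshold gets `tipped = FALSE` and `NA` times.
#'
#' @param traj an `abm_trajectory`.
#' @param schedule the [env_schedule()] the run used (defaults to the one
#'   stored in the trajectory); must cross zero unless `crossing_time` is
#'   supplied.
#' @param threshold B-fraction that counts as "tipped"; default 0.5
#'   (majority), 0.9 also conventional.
#' @param crossing_time override for the environmental crossing time.
#' @return an object of class `tipping_result`: list with
#'   `crossing_time`, `tipping_time`, `lag`, `tipped`.
#' @export
tipping_time <- function(traj, schedule = traj$schedule, threshold = 0.5,
                         crossing_time = NULL) {
  stopifnot(inherits(traj, "abm_trajectory"))
  if (is.null(crossing_time)) {
    if (is.null(schedule))
      stop("no schedule available to locate the crossing", call. = FALSE)
    cr <- schedule_crossings(schedule, traj$sweeps_run)
    if (nrow(cr) == 0)
      stop("schedule does not cross zero within the run; supply `crossing_time`",
           call. = FALSE)
    crossing_time <- cr$time[1]
  }
  rec <- traj$records
  hit <- which(1 - rec$frac_A > threshold)
  if (length(hit) == 0)
    return(structure(list(crossing_time = crossing_time,
                          tipping_time = NA_real_, lag = NA_real_,
                          tipped = FALSE), class = "tipping_result"))
  tt <- rec$sweep[hit[1]]
  structure(list(crossing_time = crossing_time, tipping_time = tt,
                 lag = tt - crossing_time, tipped = TRUE),
            class = "tipping_result")
}

#' @export
print.tipping_result <- function(x, ...) {
  if (x$tipped)
    cat(sprintf("tipped at sweep %g (environment crossed at %g, lag %g)\n",
                x$tipping_time, x$crossing_time, x$lag))
  else cat(sprintf("not tipped (environment crossed at %g)\n",
                   x$crossing_time))
  invisible(x)
}

#' Lead time of a subpopulation under a fluctuating environment
#'
#' For each zero-crossing of a sinusoidal schedule, the time at which the
#' subpopulation's majority first sits on the newly preferred side, minus
#' the crossing time. Negative values mean the subpopulation switched
#' before the environment made the new option preferable (it leads);
#' positive values mean it lags. Crossings whose surrounding half-cycles
#' show no switch are skipped; the mean over measurable crossings is
#' returned.
#'
#' @param traj an `abm_trajectory` run under a sinusoidal schedule.
#' @param schedule the schedule (defaults to the trajectory's).
#' @param subpop subpopulation name or row index in the composition.
#' @return list of class `lead_result`: `mean_lead`, `per_crossing` (data
#'   frame with crossing time, switch time, lead).
#' @export
lead_time <- function(traj, schedule = traj$schedule, subpop) {
  stopifnot(inherits(traj, "abm_trajectory"))
  if (is.null(schedule) || schedule$kind != "sinusoidal")
    stop("`lead_time` requires a sinusoidal schedule", call. = FALSE)
  comp <- traj$composition
  r <- if (is.character(subpop)) match(subpop, comp$name) else as.integer(subpop)
  if (is.na(r) || r < 1 || r > nrow(comp))
    stop("unknown subpopulation", call. = FALSE)
  col <- paste0("frac_A_", comp$name[r])
  rec <- traj$records
  cr <- schedule_crossings(schedule, traj$sweeps_run)
  if (nrow(cr) < 1)
    stop("fewer than one complete half-cycle in the run", call. = FALSE)
  half <- schedule$period / 2
  out <- data.frame(crossing = numeric(0), switch_time = numeric(0),
                    lead = numeric(0))
  for (j in seq_len(nrow(cr))) {
    tc <- cr$time[j]; s <- cr$to_sign[j]
    lo <- max(0, tc - half); hi <- min(traj$sweeps_run, tc + half)
    rows <- which(rec$sweep >= lo & rec$sweep <= hi)
    if (length(rows) < 2) next
    f <- rec[[col]][rows]
    on_new <- if (s > 0) f > 0.5 else f < 0.5
    on_old <- if (s > 0) f < 0.5 else f > 0.5
    first_old <- which(on_old)[1]
    if (is.na(first_old)) next    # never held the outgoing majority
    first_new <- which(on_new & seq_along(f) > first_old)[1]
    if (is.na(first_new)) next    # never switched within the window
    sw <- rec$sweep[rows[first_new]]
    out <- rbind(out, data.frame(crossing = tc, switch_time = sw,
                                 lead = sw - tc))
  }
  if (nrow(out) == 0)
    stop("no measurable majority switches for this subpopulation",
         call. = FALSE)
  structure(list(mean_lead = mean(out$lead), per_crossing = out,
                 subpop = comp$name[r]), class = "lead_result")
}

#' @export
print.lead_result <- function(x, ...) {
  cat(sprintf("lead time of %s: %.1f sweeps over %d crossings (negative = ahead)\n",
              x$subpop, x$mean_lead, nrow(x$per_crossing)))
  invisible(x)
}

#' Welfare decomposition of a population state
#'
#' Package-local welfare accounting with spins \eqn{\sigma_i \in \{+1,-1\}}:
#' preference utility \eqn{\mathrm{mean}_i\, \sigma_i \Delta o_i / 2},
#' social utility
#' \eqn{\mathrm{mean}_i\, (w_i/2) \sum_{j \in N(i)} \sigma_i \sigma_j},
#' and their sum. These are a transparent per-capita bookkeeping of the
#' two utility channels of the decision rule, not a welfare measure taken
#' from elsewhere.
#'
#' @param pop an `abm_population`.
#' @return list of class `welfare_result`: `preference_utility`,
#'   `social_utility`, `total`.
#' @export
welfare <- function(pop) {
  stopifnot(inherits(pop, "abm_population"))
  s <- pop$spin
  adj <- igraph::as_adjacency_matrix(pop$graph, sparse = TRUE)
  neigh <- as.numeric(adj %*% s)
  pref <- mean(s * pop$delta_o / 2)
  soc <- mean((pop$w / 2) * s * neigh)
  structure(list(preference_utility = pref, social_utility = soc,
                 total = pref + soc), class = "welfare_result")
}

#' @export
print.welfare_result <- function(x, ...) {
  cat(sprintf("welfare: preference %.3f + social %.3f = %.3f per capita\n",
              x$preference_utility, x$social_utility, x$total))
  invisible(x)
}
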