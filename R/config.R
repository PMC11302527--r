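#' Serialize scenarios to and from configuration files
#'
#' Scenarios round-trip losslessly through plain nested lists, written as
#' YAML (or JSON). `scenario_from_config()` accepts a file path or an
#' already-parsed list and reports missing or malformed fields by name.
#'
#' @param sc an [scenario()].
#' @param x config file path (`.yaml`/`.yml`/`.json`) or a named list.
#' @param file output path; format chosen by extension (YAML default).
#' @return `scenario_to_config()` a plain list; `write_config()` the path
#'   invisibly; `scenario_from_config()` an `abm_scenario`.
#' @export
scenario_to_config <- function(sc) {
  stopifnot(inherits(sc, "abm_scenario"))
  comp <- sc$base_composition
  list(name = sc$name, network = sc$network,
       fraction_anti = sc$fraction_anti, target_corr = sc$target_corr,
       base_composition = list(name = comp$name, delta_o = comp$delta_o,
                               w = comp$w, frac = comp$frac),
       anti_w = sc$anti_w, anti_delta_o = sc$anti_delta_o,
       schedule = if (is.null(sc$schedule)) NULL else unclass(sc$schedule),
       beta = sc$beta, initial_fraction_A = sc$initial_fraction_A,
       init_mode = sc$init_mode, horizon = sc$horizon,
       record_every = sc$record_every, quiet_sweeps = sc$quiet_sweeps,
       assortative_mode = sc$assortative_mode,
       assortative_steps = sc$assortative_steps,
       assortative_target_r = sc$assortative_target_r,
       realizations = sc$realizations, seed = sc$seed,
       placement_tolerance = sc$placement_tolerance,
       placement_max_iters = sc$placement_max_iters,
       thresholds = sc$thresholds)
}

#' @rdname scenario_to_config
#' @export
write_config <- function(sc, file) {
  cfg <- scenario_to_config(sc)
  if (grepl("\\.json$", file))
    jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  else yaml::write_yaml(cfg, file)
  invisible(file)
}

#' @rdname scenario_to_config
#' @export
scenario_from_config <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- if (grepl("\\.json$", x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  # hand-written YAML: an unquoted `n:` key parses as boolean FALSE
  if (is.list(x$network) && "FALSE" %in% names(x$network))
    names(x$network)[names(x$network) == "FALSE"] <- "n"
  required <- c("network", "base_composition")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(x$network$family))
    stop("config is missing required field: network.family", call. = FALSE)
  bc <- x$base_composition
  for (f in c("delta_o", "w", "frac"))
    if (is.null(bc[[f]]))
      stop("config is missing required field: base_composition.", f,
           call. = FALSE)
  comp <- agent_composition(as.numeric(bc$delta_o), as.numeric(bc$w),
                            as.numeric(bc$frac),
                            name = if (is.null(bc$name)) NULL
                                   else as.character(bc$name))
  sched <- NULL
  if (!is.null(x$schedule)) {
    s <- x$schedule
    if (is.null(s$kind))
      stop("config is missing required field: schedule.kind", call. = FALSE)
    sched <- switch(s$kind,
      constant = env_schedule("constant", delta_o0 = s$delta_o0),
      linear = env_schedule("linear", delta_o0 = s$delta_o0,
                            rate = s$rate),
      sinusoidal = env_schedule("sinusoidal", amplitude = s$amplitude,
                                period = s$period,
                                phase = s$phase %||% 0),
      stop("unknown schedule kind: ", s$kind, call. = FALSE))
  }
  args <- x[setdiff(names(x), c("base_composition", "schedule"))]
  # empty containers from JSON/YAML null round-trips mean "unset"
  args <- lapply(args, function(v)
    if (is.list(v) && length(v) == 0) NULL else v)
  args$base_composition <- comp
  args$schedule <- sched
  do.call(scenario, args)
}

#' Canned study scenarios
#'
#' Ready-made scaled-down scenarios for the package's headline
#' experiments. All run at desk scale by default (population 500, 20
#' realizations); `full_size = TRUE` restores the larger study sizes
#' (population 2000/1000, 100 realizations).
#'
#' \describe{
#'   \item{`conformity_trap`}{BA network, half prefer A / half B
#'     (\eqn{\Delta o = \pm 10}, `w = 1`), no anticonformists, consensus-A
#'     start: the population stays on A and alignment sits near 0.5.}
#'   \item{`centrality_phase`}{the same population with a tunable
#'     anticonformist fraction and degree-type correlation, for mapping
#'     the alignment phase boundary.}
#'   \item{`linear_tipping`}{shared preference decreasing linearly through
#'     zero; tipping time vs anticonformist fraction or centrality.}
#'   \item{`sinusoidal_lead`}{shared preference oscillating; lead/lag of
#'     anticonformists and conformists.}
#' }
#' The aliases `fig2a`, `fig2b`, `fig3a`, `fig3b`, `fig4` map to
#' `conformity_trap`, `centrality_phase`, `linear_tipping` (fraction and
#' centrality variants) and `sinusoidal_lead` respectively.
#'
#' @param name one of the scenario names or aliases above.
#' @param full_size use the full study sizes instead of desk scale.
#' @param seed master seed.
#' @return an [scenario()].
#' @export
canned_scenario <- function(name, full_size = FALSE, seed = 1) {
  alias <- c(fig2a = "conformity_trap", fig2b = "centrality_phase",
             fig3a = "linear_tipping", fig3b = "linear_tipping_centrality",
             fig4 = "sinusoidal_lead")
  if (name %in% names(alias)) name <- alias[[name]]
  n_static <- if (full_size) 2000 else 500
  n_dyn <- if (full_size) 1000 else 500
  reals <- if (full_size) 100 else 20
  half_half <- agent_composition(delta_o = c(10, -10), w = c(1, 1),
                                 frac = c(0.5, 0.5))
  shared <- agent_composition(delta_o = 10, w = 1, frac = 1)
  switch(name,
    conformity_trap = scenario(
      name = "conformity_trap",
      network = list(family = "ba", n = n_static, m = 20),
      fraction_anti = 0, base_composition = half_half,
      initial_fraction_A = 1, horizon = 2000, quiet_sweeps = 50,
      realizations = reals, seed = seed),
    centrality_phase = scenario(
      name = "centrality_phase",
      network = list(family = "ba", n = n_static, m = 20),
      fraction_anti = 0.1, target_corr = 0,
      base_composition = half_half, initial_fraction_A = 1,
      horizon = 2000, quiet_sweeps = 50, realizations = reals,
      seed = seed),
    linear_tipping = scenario(
      name = "linear_tipping",
      network = list(family = "ba", n = n_dyn, m = 20),
      fraction_anti = 0.15, target_corr = 0,
      base_composition = shared,
      schedule = env_schedule("linear", delta_o0 = 10, rate = 0.1),
      initial_fraction_A = 1, horizon = 400, realizations = reals,
      seed = seed),
    linear_tipping_centrality = {
      sc <- canned_scenario("linear_tipping", full_size, seed)
      sc$name <- "linear_tipping_centrality"
      sc$target_corr <- "max"
      sc
    },
    sinusoidal_lead = scenario(
      name = "sinusoidal_lead",
      network = list(family = "ba", n = n_dyn, m = 20),
      fraction_anti = 0.2, target_corr = 0,
      base_composition = shared,
      schedule = env_schedule("sinusoidal", amplitude = 10,
                              period = 200),
      initial_fraction_A = 0.5, horizon = 600, realizations = reals,
      seed = seed),
    stop("unknown canned scenario: ", name, call. = FALSE))
}
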