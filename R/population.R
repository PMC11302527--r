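#' Subpopulation composition table
#'
#' One row per subpopulation: its net preference, conformity weight and
#' size fraction. Rows with `w < 0` are anticonformist subpopulations and
#' are matched to the nodes marked anticonformist by a placement (see
#' [init_population()]).
#'
#' @param delta_o numeric net preferences per subpopulation.
#' @param w numeric conformity weights per subpopulation.
#' @param frac size fractions, summing to 1.
#' @param name optional subpopulation labels; default auto-generated from
#'   weight sign and preference.
#' @return a data frame of class `agent_composition`.
#' @examples
#' # half prefer A, half prefer B, everyone a conformist
#' agent_composition(delta_o = c(10, -10), w = c(1, 1), frac = c(0.5, 0.5))
#' @export
agent_composition <- function(delta_o, w, frac, name = NULL) {
  stopifnot(length(delta_o) == length(w), length(w) == length(frac))
  if (abs(sum(frac) - 1) > 1e-8) stop("`frac` must sum to 1", call. = FALSE)
  if (any(frac < 0)) stop("`frac` must be non-negative", call. = FALSE)
  if (is.null(name)) {
    type <- ifelse(w > 0, "conf", ifelse(w < 0, "anti", "non"))
    name <- make.unique(paste0(type, "_o", delta_o))
  }
  structure(data.frame(name = name, delta_o = delta_o, w = w, frac = frac,
                       stringsAsFactors = FALSE),
            class = c("agent_composition", "data.frame"))
}

# largest-remainder rounding of n * frac to integers summing to n
apportion <- function(frac, n) {
  raw <- frac * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Assemble a simulated population
#'
#' Attaches agent states to a network: per-node net preference, conformity
#' weight, subpopulation id and an initial choice. Anticonformist
#' subpopulations (composition rows with `w < 0`) are assigned to the
#' nodes marked by `anti`; all other rows to the remaining nodes. Within
#' each pool, nodes are assigned to rows uniformly at random with
#' largest-remainder rounding of the target counts. Initial choices are
#' drawn without replacement so the realized A-count is exactly
#' `round(initial_fraction_A * n)` (globally, or per subpopulation for
#' `init_mode = "by_subpop"`).
#'
#' @param net an `igraph` graph.
#' @param composition an [agent_composition()] table.
#' @param anti logical vector or [place_types()] result marking
#'   anticonformist nodes; required iff the composition has rows with
#'   `w < 0` and `NULL` otherwise.
#' @param initial_fraction_A initial fraction choosing A, in `[0, 1]`.
#' @param init_mode `"random"` (exact global count) or `"by_subpop"`
#'   (exact count within each subpopulation).
#' @param params a [decision_params()] object.
#' @return an object of class `abm_population`: list with `graph`,
#'   `delta_o`, `w`, `spin` (+1/-1 choices), `subpop` (row index into
#'   `composition`), `composition`, `params`.
#' @export
init_population <- function(net, composition, anti = NULL,
                            initial_fraction_A = 0.5,
                            init_mode = c("random", "by_subpop"),
                            params = decision_params()) {
  stopifnot(inherits(composition, "agent_composition"))
  init_mode <- match.arg(init_mode)
  stopifnot(initial_fraction_A >= 0, initial_fraction_A <= 1)
  n <- igraph::vcount(net)
  if (inherits(anti, "type_placement")) anti <- anti$anti
  is_anti_row <- composition$w < 0
  subpop <- integer(n)

  if (any(is_anti_row)) {
    if (is.null(anti))
      stop("composition has anticonformist rows but no `anti` placement",
           call. = FALSE)
    stopifnot(length(anti) == n)
    f_anti <- sum(composition$frac[is_anti_row])
    if (abs(sum(anti) - round(f_anti * n)) > 1)
      stop(sprintf(
        "placement marks %d anticonformists but composition implies %d",
        sum(anti), round(f_anti * n)), call. = FALSE)
    pool_a <- which(anti)
    rows_a <- which(is_anti_row)
    cnt <- apportion(composition$frac[rows_a] / f_anti, length(pool_a))
    subpop[sample(pool_a)] <- rep(rows_a, cnt)
    pool_c <- which(!anti)
  } else {
    if (!is.null(anti) && any(anti))
      stop("`anti` marks nodes but composition has no w < 0 rows",
           call. = FALSE)
    pool_c <- seq_len(n)
  }
  rows_c <- which(!is_anti_row)
  if (length(pool_c) > 0) {
    f_c <- sum(composition$frac[rows_c])
    cnt <- apportion(composition$frac[rows_c] / f_c, length(pool_c))
    subpop[sample(pool_c)] <- rep(rows_c, cnt)
  }

  spin <- integer(n)
  if (init_mode == "random") {
    n_A <- round(initial_fraction_A * n)
    spin[] <- -1L
    spin[sample.int(n, n_A)] <- 1L
  } else {
    spin[] <- -1L
    for (r in unique(subpop)) {
      ids <- which(subpop == r)
      n_A <- round(initial_fraction_A * length(ids))
      spin[sample(ids, n_A)] <- 1L
    }
  }

  structure(list(graph = net,
                 delta_o = composition$delta_o[subpop],
                 w = composition$w[subpop],
                 spin = spin, subpop = subpop,
                 composition = composition, params = params),
            class = "abm_population")
}

#' @export
print.abm_population <- function(x, ...) {
  cat(sprintf("abm_population: %d agents, %d edges, %d subpopulations, beta = %g\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              nrow(x$composition), x$params$beta))
  cat(sprintf("  fraction A: %.3f\n", mean(x$spin > 0)))
  invisible(x)
}

#' Current choices of a population
#'
#' @param pop an `abm_population`.
#' @return character vector of `"A"`/`"B"`.
#' @export
choices <- function(pop) spin_to_choice(pop$spin)
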