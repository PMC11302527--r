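#' Generate an Erdos-Renyi random network
#'
#' Draws a \eqn{G(n, p)} graph with \eqn{p = \bar{k}/(n-1)}. Because the
#' choice dynamics are ill-posed on disconnected shells, connectivity is
#' enforced: for `mean_degree >= log(n)` the draw is repeated (up to 100
#' times) until connected; for sparser graphs the giant component is
#' retained and its size recorded in the graph attribute
#' `component_frac`.
#'
#' @param n number of nodes (>= 2).
#' @param mean_degree target mean degree, in `(0, n-1]`.
#' @return an undirected simple `igraph` graph.
#' @export
generate_er <- function(n, mean_degree) {
  stopifnot(n >= 2)
  if (!is.numeric(mean_degree) || mean_degree <= 0 || mean_degree > n - 1)
    stop("`mean_degree` must lie in (0, n-1]", call. = FALSE)
  p <- mean_degree / (n - 1)
  if (mean_degree >= log(n)) {
    for (i in seq_len(100)) {
      g <- igraph::sample_gnp(n, p)
      if (igraph::is_connected(g)) {
        g <- igraph::set_graph_attr(g, "component_frac", 1)
        return(g)
      }
    }
    stop("failed to draw a connected G(n, p) in 100 attempts", call. = FALSE)
  }
  g <- igraph::sample_gnp(n, p)
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  g2 <- igraph::induced_subgraph(g, which(comp$membership == giant))
  igraph::set_graph_attr(g2, "component_frac", max(comp$csize) / n)
}

#' Generate a Barabasi-Albert scale-free network
#'
#' Preferential attachment starting from a complete graph on `m` nodes,
#' each arriving node attaching `m` edges. Every non-seed node therefore
#' has degree at least `m` (the minimum degree of the network), and the
#' graph is connected.
#'
#' @param n number of nodes.
#' @param m edges per arriving node (`1 <= m < n`); equals the minimum
#'   degree of non-seed nodes.
#' @return an undirected simple `igraph` graph.
#' @export
generate_ba <- function(n, m) {
  stopifnot(n >= 2)
  if (!is.numeric(m) || m < 1 || m >= n)
    stop("`m` must satisfy 1 <= m < n", call. = FALSE)
  igraph::sample_pa(n, power = 1, m = m, directed = FALSE,
                    start.graph = igraph::make_full_graph(m))
}

#' Pearson correlation between node degree and a binary type indicator
#'
#' The point-biserial correlation used as the measure of anticonformist
#' degree centrality. Returns 0 by convention when either the degree
#' vector or the indicator is constant.
#'
#' @param net an `igraph` graph.
#' @param anti logical (or 0/1) vector over nodes: `TRUE` = anticonformist.
#' @return a number in `[-1, 1]`.
#' @export
corr_degree_type <- function(net, anti) {
  d <- igraph::degree(net)
  a <- as.numeric(anti)
  if (length(a) != length(d)) stop("`anti` must cover all nodes")
  if (stats::sd(d) == 0 || stats::sd(a) == 0) return(0)
  cor(d, a)
}

#' Attainable range of the degree-type correlation
#'
#' The extreme Pearson correlations reachable for a given degree sequence
#' and anticonformist count: placing the anticonformists on the
#' highest-degree nodes (maximum) or lowest-degree nodes (minimum), ties
#' broken by node id.
#'
#' @inheritParams place_types
#' @return named numeric vector `c(min = ..., max = ...)`.
#' @export
corr_range <- function(net, fraction_anti) {
  d <- igraph::degree(net)
  n <- length(d)
  n_anti <- round(fraction_anti * n)
  if (n_anti == 0 || n_anti == n) return(c(min = 0, max = 0))
  top <- order(-d, seq_len(n))[seq_len(n_anti)]
  bot <- order(d, seq_len(n))[seq_len(n_anti)]
  ind <- function(ids) { a <- rep(0, n); a[ids] <- 1; a }
  c(min = corr_degree_type(net, ind(bot)),
    max = corr_degree_type(net, ind(top)))
}

#' Place anticonformists with a target degree-type correlation
#'
#' Starts from the extreme placement (anticonformists on the
#' highest-degree nodes for non-negative targets, lowest-degree for
#' negative ones; ties broken by node id) and greedily swaps the
#' attributes of a random anticonformist/other pair, accepting a swap only
#' if it does not move the achieved Pearson correlation further from the
#' target. Edges are never touched, so the degree sequence is invariant.
#'
#' @param net an `igraph` graph.
#' @param fraction_anti fraction of nodes to mark anticonformist, in
#'   `[0, 1]`; the realized count is `round(fraction_anti * n)`.
#' @param target_corr numeric target in the attainable range (see
#'   [corr_range()]), or `"max"` / `"min"` for the extreme placements.
#' @param tolerance convergence tolerance on `|achieved - target|`.
#' @param max_iters cap on proposed swaps.
#' @return an object of class `type_placement`: list with elements `anti`
#'   (logical vector), `achieved`, `target`, `iters`, `converged`, and
#'   `trace` (the non-increasing sequence of distances after each accepted
#'   swap). Failure to converge is an error reporting the achieved value.
#' @export
place_types <- function(net, fraction_anti, target_corr = 0,
                        tolerance = 0.01, max_iters = 1e6) {
  stopifnot(fraction_anti >= 0, fraction_anti <= 1, tolerance > 0)
  d <- igraph::degree(net)
  n <- length(d)
  n_anti <- round(fraction_anti * n)
  if (fraction_anti > 0 && n_anti < 1)
    stop("`fraction_anti` too small: rounds to zero anticonformists",
         call. = FALSE)
  rng <- corr_range(net, fraction_anti)
  if (is.character(target_corr)) {
    target_corr <- match.arg(target_corr, c("max", "min"))
    target_corr <- unname(rng[target_corr])
  }
  assert_scalar_num(target_corr, "target_corr")
  if (n_anti > 0 && n_anti < n &&
      (target_corr < rng["min"] - 1e-12 || target_corr > rng["max"] + 1e-12))
    stop(sprintf("target correlation %.3f outside attainable [%.3f, %.3f]",
                 target_corr, rng["min"], rng["max"]), call. = FALSE)
  init <- rep(FALSE, n)
  if (n_anti > 0) {
    ord <- if (target_corr >= 0) order(-d, seq_len(n)) else order(d, seq_len(n))
    init[ord[seq_len(n_anti)]] <- TRUE
  }
  res <- swap_to_corr_cpp(as.numeric(d), init, target_corr, tolerance,
                          as.integer(max_iters))
  if (!res$converged)
    stop(sprintf(
      "degree-type correlation target %.3f not reached in %d swaps (achieved %.3f)",
      target_corr, as.integer(max_iters), res$achieved), call. = FALSE)
  structure(list(anti = as.logical(res$anti), achieved = res$achieved,
                 target = target_corr, iters = res$iters,
                 converged = res$converged, trace = res$trace),
            class = "type_placement")
}

#' @export
print.type_placement <- function(x, ...) {
  cat(sprintf(
    "type_placement: %d anticonformists, degree-type corr %.3f (target %.3f, %d swaps)\n",
    sum(x$anti), x$achieved, x$target, x$iters))
  invisible(x)
}

#' Degree-preserving (dis)assortative rewiring
#'
#' Two-edge rewiring in the Xulvi-Brunet--Sokolov style: repeatedly pick
#' two random edges with four distinct endpoints and re-pair the
#' endpoints — two highest-degree together and two lowest together
#' (assortative), highest with lowest (disassortative), or at random
#' (neutral). Proposals creating self-loops or duplicate edges are
#' rejected, so the degree sequence is preserved exactly.
#'
#' @param net an `igraph` graph with at least 2 edges.
#' @param mode `"assortative"`, `"disassortative"` or `"neutral"`.
#' @param steps number of proposed rewirings; default `10 * ecount(net)`.
#' @param target_r optional magnitude of Newman's assortativity
#'   coefficient to stop at: rewiring proceeds in batches of
#'   `ecount(net)` proposals until `r >= target_r` (assortative) or
#'   `r <= -target_r` (disassortative), or `steps` proposals have been
#'   made. Matching the magnitude across modes makes
#'   assortative/disassortative comparisons symmetric instead of running
#'   both to their (asymmetric) saturation values.
#' @return the rewired `igraph` graph (same vertex set and degree
#'   sequence); Newman's assortativity coefficient can be read off with
#'   `igraph::assortativity_degree()`.
#' @export
rewire_assortative <- function(net,
                               mode = c("assortative", "disassortative",
                                        "neutral"),
                               steps = NULL, target_r = NULL) {
  mode <- match.arg(mode)
  m <- igraph::ecount(net)
  if (m < 2) stop("network must have at least 2 edges", call. = FALSE)
  steps <- steps %||% (10 * m)
  code <- switch(mode, assortative = 1L, disassortative = -1L, neutral = 0L)
  el <- igraph::as_edgelist(net, names = FALSE) - 1L
  storage.mode(el) <- "integer"
  n <- igraph::vcount(net)
  if (is.null(target_r) || code == 0L) {
    out <- rewire_edges_cpp(el, n, code, as.integer(steps))
    return(igraph::graph_from_edgelist(out + 1L, directed = FALSE))
  }
  stopifnot(target_r > 0)
  done <- 0
  g <- net
  batch_size <- max(10, m %/% 10)
  while (done < steps) {
    batch <- min(batch_size, steps - done)
    el <- rewire_edges_cpp(el, n, code, as.integer(batch))
    done <- done + batch
    g <- igraph::graph_from_edgelist(el + 1L, directed = FALSE)
    r <- igraph::assortativity_degree(g)
    if ((code > 0 && r >= target_r) || (code < 0 && r <= -target_r)) break
  }
  g
}

#' Read and write networks as plain-text files
#'
#' Edge lists are whitespace-delimited pairs of 0-based node ids; GraphML
#' goes through igraph's reader/writer. Node attributes (type, net
#' preference, conformity weight, ...) travel in a companion CSV keyed by
#' 0-based node id, see [write_node_attributes()].
#'
#' @param net an `igraph` graph.
#' @param file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @param n_nodes for `read_network`, the total node count (edge lists do
#'   not record isolated nodes); default: largest id + 1.
#' @return `read_network` returns an `igraph` graph; `write_network`
#'   returns `file` invisibly.
#' @export
write_network <- function(net, file, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, file, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net, names = FALSE) - 1L
    utils::write.table(el, file, row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file, format = c("edgelist", "graphml"),
                         n_nodes = NULL) {
  format <- match.arg(format)
  if (format == "graphml") return(igraph::read_graph(file, format = "graphml"))
  el <- as.matrix(utils::read.table(file, col.names = c("from", "to")))
  n_nodes <- n_nodes %||% (max(el) + 1)
  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  igraph::add_edges(g, t(el + 1L))
}

#' Node attribute tables keyed by 0-based node id
#'
#' @param df data frame with a `node` column of 0-based ids plus arbitrary
#'   attribute columns (`anti`, `delta_o`, `w`, ...).
#' @param file CSV path.
#' @return `read_node_attributes` returns the data frame ordered by node
#'   id.
#' @export
write_node_attributes <- function(df, file) {
  stopifnot("node" %in% names(df))
  write.csv(df[order(df$node), , drop = FALSE], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_node_attributes
#' @export
read_node_attributes <- function(file) {
  df <- read.csv(file)
  df[order(df$node), , drop = FALSE]
}
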