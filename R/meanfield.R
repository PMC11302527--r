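#' Well-mixed mean-field model
#'
#' Annealed approximation of the networked dynamics: every agent sees
#' `k` neighbours of which a fraction `X` (the global A-fraction) chooses
#' A, so a subpopulation with preference \eqn{\Delta o_s} and weight
#' \eqn{w_s} has marginal utility
#' \eqn{\Delta U_s(X) = \Delta o_s + w_s k (2X - 1)} and responds with
#' probability \eqn{p_s(X) = 1/(1 + e^{-\beta \Delta U_s(X)})}.
#'
#' @param subpops an [agent_composition()] (or data frame with columns
#'   `frac`, `delta_o`, `w`).
#' @param k effective degree (> 0); typically the mean degree of the
#'   network being approximated.
#' @param beta inverse temperature (> 0).
#' @return an object of class `mean_field_model`.
#' @export
mean_field_model <- function(subpops, k, beta = 100) {
  stopifnot(is.data.frame(subpops),
            all(c("frac", "delta_o", "w") %in% names(subpops)))
  if (abs(sum(subpops$frac) - 1) > 1e-8)
    stop("subpopulation fractions must sum to 1", call. = FALSE)
  assert_scalar_num(k, "k"); assert_scalar_num(beta, "beta")
  if (k <= 0 || beta <= 0) stop("`k` and `beta` must be > 0", call. = FALSE)
  structure(list(subpops = as.data.frame(subpops), k = k, beta = beta),
            class = "mean_field_model")
}

#' Per-subpopulation response probabilities
#'
#' @param model a [mean_field_model()].
#' @param X global A-fraction(s) in `[0, 1]`.
#' @return matrix (length(X) x subpopulations) of \eqn{p_s(X)}.
#' @export
subpop_response <- function(model, X) {
  stopifnot(inherits(model, "mean_field_model"))
  sp <- model$subpops
  du <- outer(2 * X - 1, sp$w * model$k) +
    matrix(sp$delta_o, length(X), nrow(sp), byrow = TRUE)
  p <- plogis(model$beta * du)
  colnames(p) <- if (!is.null(sp$name)) sp$name else NULL
  p
}

#' Mean-field self-consistency map
#'
#' \eqn{G(X) = \sum_s n_s p_s(X)}: the expected A-fraction after one
#' relaxation given a current A-fraction `X`. Fixed points of the
#' aggregated dynamics solve \eqn{G(X) = X}; the drift is
#' \eqn{G(X) - X}.
#'
#' @inheritParams subpop_response
#' @return numeric vector `G(X)` in `[0, 1]`.
#' @export
response_map <- function(model, X) {
  if (any(X < 0 | X > 1)) stop("`X` must lie in [0, 1]", call. = FALSE)
  as.numeric(subpop_response(model, X) %*% model$subpops$frac)
}

#' Fixed points of the mean-field map
#'
#' Locates all roots of \eqn{G(X) - X} on `[0, 1]` by a sign-change scan
#' on a grid followed by bisection, classifies stability by the sign of
#' \eqn{G'(X^*) - 1} (central finite difference; one-sided drift at the
#' boundaries), and reports per-subpopulation occupancies
#' \eqn{x_s^* = p_s(X^*)}. Since `G` maps `[0, 1]` into itself a root
#' always exists.
#'
#' @param model a [mean_field_model()].
#' @param grid_size number of scan points (>= 100; steep near-threshold
#'   maps need a fine grid, default 4001).
#' @param tol root-finding tolerance.
#' @return data frame of class `mf_fixed_points` with columns `X_star`,
#'   `stable`, `residual`, plus one `x_<name>` column per subpopulation.
#' @export
find_fixed_points <- function(model, grid_size = 4001, tol = 1e-10) {
  stopifnot(inherits(model, "mean_field_model"), grid_size >= 100)
  g <- function(x) response_map(model, x) - x
  xs <- seq(0, 1, length.out = grid_size)
  gx <- g(xs)
  roots <- numeric(0)
  if (abs(gx[1]) < 1e-9) roots <- c(roots, 0)
  if (abs(gx[grid_size]) < 1e-9) roots <- c(roots, 1)
  for (i in seq_len(grid_size - 1)) {
    if (is.na(gx[i]) || is.na(gx[i + 1])) next
    if (gx[i] == 0 && xs[i] > 0) roots <- c(roots, xs[i])
    if (gx[i] * gx[i + 1] < 0)
      roots <- c(roots, uniroot(g, c(xs[i], xs[i + 1]), tol = tol)$root)
  }
  roots <- sort(unique(roots))
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-7)]
  stopifnot(length(roots) >= 1)
  h <- 1e-6
  stab <- vapply(roots, function(r) {
    lo <- max(0, r - h); hi <- min(1, r + h)
    if (hi - lo < h / 2) return(TRUE)
    gp <- (g(hi) - g(lo)) / (hi - lo) + 1  # derivative of G
    if (r < h) return(g(hi) < 0)           # boundary: one-sided drift
    if (r > 1 - h) return(g(lo) > 0)
    gp < 1
  }, logical(1))
  out <- data.frame(X_star = roots, stable = stab,
                    residual = abs(g(roots)))
  xsub <- subpop_response(model, roots)
  colnames(xsub) <- paste0("x_", model$subpops$name %||%
                             seq_len(ncol(xsub)))
  out <- cbind(out, as.data.frame(xsub))
  class(out) <- c("mf_fixed_points", "data.frame")
  out
}

#' Mix anticonformists into a base composition
#'
#' Replaces a uniform share `f` of every base subpopulation by agents with
#' conformity weight `anti_w` (negative: anticonformists; zero:
#' nonconformists), keeping each subpopulation's preference unless
#' `anti_delta_o` overrides it. This is the default way the anticonformist
#' fraction is varied, both in the mean field and in simulated scenarios.
#'
#' @param base an [agent_composition()] of the `f = 0` population.
#' @param f fraction replaced, in `[0, 1)`.
#' @param anti_w conformity weight of the introduced agents (default -1).
#' @param anti_delta_o optional preference override for introduced agents.
#' @return an [agent_composition()].
#' @export
mix_anticonformists <- function(base, f, anti_w = -1, anti_delta_o = NULL) {
  stopifnot(is.data.frame(base), f >= 0, f < 1)
  if (f == 0) return(agent_composition(base$delta_o, base$w, base$frac))
  d_anti <- if (is.null(anti_delta_o)) base$delta_o
            else rep(anti_delta_o, nrow(base))
  agent_composition(delta_o = c(base$delta_o, d_anti),
                    w = c(base$w, rep(anti_w, nrow(base))),
                    frac = c(base$frac * (1 - f), base$frac * f))
}

#' Critical anticonformist fraction (mean field)
#'
#' The smallest fraction `f` of agents with weight `anti_w` at which the
#' mean-field map loses its bistability: the misaligned stable branch
#' disappears and the stable-root count drops. Located by bisection in `f`
#' between a bistable lower end and a monostable upper end. A base model
#' that is not bistable at `f = f_range[1]` returns `f_star = f_range[1]`
#' (preferences already dominate); a range whose upper end is still
#' bistable returns `f_star = NA` (not found).
#'
#' @param base_model a [mean_field_model()] of the `f = 0` population.
#' @param anti_w conformity weight of the introduced agents.
#' @param anti_delta_o optional preference override (see
#'   [mix_anticonformists()]).
#' @param f_range search interval.
#' @param tol_f bisection tolerance on `f`.
#' @param grid_size passed to [find_fixed_points()].
#' @return list of class `critical_fraction`: `f_star`, `found`,
#'   `jump` (change in the largest stable root across the transition),
#'   `roots_below`, `roots_above` (fixed points just below/above).
#' @export
critical_fraction <- function(base_model, anti_w = -1, anti_delta_o = NULL,
                              f_range = c(0, 0.8), tol_f = 1e-4,
                              grid_size = 4001) {
  stopifnot(inherits(base_model, "mean_field_model"),
            length(f_range) == 2, f_range[1] >= 0, f_range[2] < 1)
  base <- base_model$subpops
  fp_at <- function(f) {
    comp <- mix_anticonformists(base, f, anti_w, anti_delta_o)
    find_fixed_points(mean_field_model(comp, base_model$k,
                                       base_model$beta), grid_size)
  }
  n_stable <- function(fp) sum(fp$stable)
  lo <- f_range[1]; hi <- f_range[2]
  fp_lo <- fp_at(lo)
  if (n_stable(fp_lo) <= 1)
    return(structure(list(f_star = lo, found = TRUE, jump = 0,
                          roots_below = fp_lo, roots_above = fp_lo),
                     class = "critical_fraction"))
  fp_hi <- fp_at(hi)
  if (n_stable(fp_hi) > 1)
    return(structure(list(f_star = NA_real_, found = FALSE, jump = NA_real_,
                          roots_below = fp_hi, roots_above = NULL),
                     class = "critical_fraction"))
  while (hi - lo > tol_f) {
    mid <- (lo + hi) / 2
    if (n_stable(fp_at(mid)) > 1) lo <- mid else hi <- mid
  }
  below <- fp_at(lo); above <- fp_at(hi)
  jump <- max(below$X_star[below$stable]) - max(above$X_star[above$stable])
  structure(list(f_star = (lo + hi) / 2, found = TRUE, jump = jump,
                 roots_below = below, roots_above = above),
            class = "critical_fraction")
}

#' @export
print.critical_fraction <- function(x, ...) {
  if (x$found)
    cat(sprintf(
      "critical fraction f* = %.4f (stable-branch jump %.3f at the transition)\n",
      x$f_star, x$jump))
  else cat("no critical fraction found in the searched range\n")
  invisible(x)
}

#' Exact finite-population Markov chain on the complete graph
#'
#' Builds the exact single-update transition matrix of the dynamics on a
#' complete graph of `N_small` agents (neighbour counts exclude the focal
#' agent), with macro-states the per-subpopulation A-counts. If the chain
#' has absorbing states (typical at large `beta`), absorption
#' probabilities from every state are returned and flagged; otherwise the
#' stationary distribution is computed by power iteration.
#'
#' @param model a [mean_field_model()] giving the subpopulation
#'   composition and `beta` (its `k` is ignored: the complete graph fixes
#'   the neighbourhood).
#' @param N_small total number of agents; the product state space
#'   \eqn{\prod_s (N_s + 1)} must not exceed `1e5`.
#' @param init optional initial distribution over states (default
#'   uniform); used to aggregate absorption probabilities.
#' @return list of class `finite_markov`: `states` (data frame of
#'   per-subpop A-counts with subpop sizes as attribute), `P` (sparse
#'   transition matrix), `absorbing` (logical: chain has absorbing
#'   states), and either `stationary` (probability vector over states) or
#'   `absorption` (data frame of absorbing states with their absorption
#'   probability under `init`) plus `absorption_matrix`.
#' @export
finite_markov_stationary <- function(model, N_small, init = NULL) {
  stopifnot(inherits(model, "mean_field_model"), N_small >= 2)
  sp <- model$subpops
  Ns <- apportion(sp$frac, N_small)
  keep <- Ns > 0
  Ns <- Ns[keep]
  delta_o <- sp$delta_o[keep]; w <- sp$w[keep]
  S <- length(Ns); N <- sum(Ns)
  n_states <- prod(Ns + 1)
  if (n_states > 1e5) stop("state space larger than 1e5", call. = FALSE)

  radix <- cumprod(c(1, (Ns + 1)[-S]))
  states <- as.matrix(expand.grid(lapply(Ns, function(m) 0:m)))
  colnames(states) <- sp$name[keep] %||% paste0("s", seq_len(S))
  A <- rowSums(states)

  ii <- jj <- integer(0); pp <- numeric(0)
  stay <- rep(1, n_states)
  for (s in seq_len(S)) {
    a_s <- states[, s]
    # focal A-agent of subpop s: neighbours split (A-1, N-A)
    p_keep_A <- plogis(model$beta * (delta_o[s] + w[s] * (2 * A - N - 1)))
    p_down <- (a_s / N) * (1 - p_keep_A)
    # focal B-agent of subpop s: neighbours split (A, N-A-1)
    p_to_A <- plogis(model$beta * (delta_o[s] + w[s] * (2 * A - N + 1)))
    p_up <- ((Ns[s] - a_s) / N) * p_to_A
    ok <- p_down > 0
    ii <- c(ii, which(ok)); jj <- c(jj, which(ok) - radix[s])
    pp <- c(pp, p_down[ok])
    ok <- p_up > 0
    ii <- c(ii, which(ok)); jj <- c(jj, which(ok) + radix[s])
    pp <- c(pp, p_up[ok])
    stay <- stay - p_down - p_up
  }
  ii <- c(ii, seq_len(n_states)); jj <- c(jj, seq_len(n_states))
  pp <- c(pp, pmax(stay, 0))
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = pp,
                            dims = c(n_states, n_states))

  init <- init %||% rep(1 / n_states, n_states)
  stopifnot(length(init) == n_states, abs(sum(init) - 1) < 1e-8)
  absorbing_states <- abs(Matrix::diag(P) - 1) < 1e-12
  out <- list(states = as.data.frame(states), P = P,
              absorbing = any(absorbing_states), subpop_sizes = Ns)
  if (out$absorbing) {
    tr <- which(!absorbing_states); ab <- which(absorbing_states)
    if (length(tr) > 0) {
      Q <- P[tr, tr, drop = FALSE]
      R <- P[tr, ab, drop = FALSE]
      B <- as.matrix(Matrix::solve(Matrix::Diagonal(length(tr)) - Q, R))
    } else B <- matrix(0, 0, length(ab))
    mass <- init[ab] + as.numeric(init[tr] %*% B)
    out$absorption <- cbind(as.data.frame(states[ab, , drop = FALSE]),
                            prob = mass)
    out$absorption_matrix <- B
  } else {
    v <- init
    for (it in seq_len(200000)) {
      v_new <- as.numeric(v %*% P)
      if (sum(abs(v_new - v)) < 1e-13) { v <- v_new; break }
      v <- v_new
    }
    out$stationary <- v / sum(v)
  }
  class(out) <- "finite_markov"
  out
}

#' @export
print.finite_markov <- function(x, ...) {
  cat(sprintf("finite_markov: %d states over subpop sizes (%s), %s\n",
              nrow(x$states), paste(x$subpop_sizes, collapse = ", "),
              if (x$absorbing) "absorbing (absorption probabilities)"
              else "ergodic (stationary distribution)"))
  invisible(x)
}
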