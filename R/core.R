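#' Decision parameters for the Fermi choice rule
#'
#' @param beta positive inverse temperature of the logistic choice rule.
#'   The default 100 makes decisions effectively deterministic away from
#'   the indifference point \eqn{\Delta U = 0}, where the choice is a fair
#'   coin.
#' @return an object of class `decision_params`.
#' @export
decision_params <- function(beta = 100) {
  assert_scalar_num(beta, "beta")
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  structure(list(beta = beta), class = "decision_params")
}

#' Marginal utility of choosing A over B
#'
#' \eqn{\Delta U = \Delta o + w (n_A - n_B)}: the private net preference
#' for A plus the conformity weight times the surplus of neighbours
#' currently choosing A.
#'
#' @param delta_o net preference for A (\eqn{o_A - o_B}), any finite real.
#' @param w conformity weight: positive for conformists, negative for
#'   anticonformists, zero for nonconformists.
#' @param n_A,n_B non-negative counts of neighbours choosing A and B.
#' @return numeric vector of marginal utilities (arguments recycle).
#' @examples
#' marginal_utility(10, 1, n_A = 5, n_B = 15)   # 0: preference vs pressure
#' marginal_utility(-10, -1, n_A = 20, n_B = 0) # -30
#' @export
marginal_utility <- function(delta_o, w, n_A, n_B) {
  if (any(!is.finite(delta_o)) || any(!is.finite(w)))
    stop("`delta_o` and `w` must be finite", call. = FALSE)
  if (any(n_A < 0) || any(n_B < 0))
    stop("neighbour counts must be non-negative", call. = FALSE)
  delta_o + w * (n_A - n_B)
}

#' Probability of choosing A under the Fermi rule
#'
#' \eqn{p_A = 1 / (1 + e^{-\beta \Delta U})}, evaluated without overflow
#' for arbitrarily large \eqn{|\beta \Delta U|}.
#'
#' @param delta_U marginal utility of A (finite).
#' @param params a [decision_params()] object.
#' @return probabilities in `[0, 1]`.
#' @examples
#' prob_choose_A(0)            # 0.5
#' prob_choose_A(10)           # 1 up to rounding at beta = 100
#' @export
prob_choose_A <- function(delta_U, params = decision_params()) {
  if (any(!is.finite(delta_U)))
    stop("`delta_U` must be finite", call. = FALSE)
  plogis(params$beta * delta_U)
}

#' Sample a choice for one agent
#'
#' Resamples the agent's choice from scratch: A with probability
#' `prob_choose_A(marginal_utility(...))`, B otherwise. The draw does not
#' depend on the agent's current choice.
#'
#' @inheritParams marginal_utility
#' @inheritParams prob_choose_A
#' @return a character vector of `"A"`/`"B"` labels.
#' @export
sample_choice <- function(delta_o, w, n_A, n_B, params = decision_params()) {
  p <- prob_choose_A(marginal_utility(delta_o, w, n_A, n_B), params)
  ifelse(runif(length(p)) < p, "A", "B")
}

#' Convert between choice labels and the spin encoding
#'
#' The package-wide canonical encoding is \eqn{\sigma(A) = +1},
#' \eqn{\sigma(B) = -1}.
#'
#' @param choice character vector of `"A"`/`"B"`.
#' @param spin integer vector of `+1`/`-1`.
#' @return the converted vector.
#' @export
choice_to_spin <- function(choice) {
  if (!all(choice %in% c("A", "B"))) stop("choices must be 'A' or 'B'")
  ifelse(choice == "A", 1L, -1L)
}

#' @rdname choice_to_spin
#' @export
spin_to_choice <- function(spin) {
  if (!all(spin %in% c(-1L, 1L))) stop("spins must be +1 or -1")
  ifelse(spin > 0, "A", "B")
}
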