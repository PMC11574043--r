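#' Dosing policies over the discrete action space
#'
#' A `dex_policy` maps a state matrix (rows = patient-steps, columns = state
#' features in schema order) to a matrix of action probabilities over the 16
#' discrete dexmedetomidine actions (action 0 = no drug, action k = dose bin
#' `(0.1*(k-1), 0.1*k]` mcg/kg/h).
#'
#' @param states Numeric matrix of states.
#' @param policy A `dex_policy`.
#' @return `policy_probs()` returns an `n x n_actions` probability matrix
#'   whose rows sum to 1; `policy_act()` samples (or, for deterministic
#'   policies, selects) one 0-based action index per row.
#' @name dex_policy
NULL

new_policy <- function(probs_fn, n_actions, kind, deterministic = FALSE) {
  structure(list(probs_fn = probs_fn, n_actions = as.integer(n_actions),
                 kind = kind, deterministic = deterministic),
            class = "dex_policy")
}

#' @rdname dex_policy
#' @export
policy_probs <- function(policy, states) {
  stopifnot(inherits(policy, "dex_policy"))
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  P <- policy$probs_fn(states)
  stopifnot(ncol(P) == policy$n_actions)
  P
}

#' @rdname dex_policy
#' @export
policy_act <- function(policy, states) {
  P <- policy_probs(policy, states)
  if (policy$deterministic) return(max.col(P, ties.method = "first") - 1L)
  cs <- t(apply(P, 1, cumsum))
  u <- runif(nrow(P)) * cs[, ncol(cs)]
  (max.col(cs >= u, ties.method = "first") - 1L)
}

#' Greedy policy induced by a trained Q-function
#'
#' @param trained A `trained_policy` (see [train_cql()], [select_checkpoint()],
#'   [as_trained_policy()]).
#' @return A deterministic `dex_policy` putting probability 1 on the
#'   lowest-index maximizer of the Q-values.
#' @export
policy_greedy <- function(trained) {
  stopifnot(inherits(trained, "trained_policy"))
  n_a <- trained$net$spec$n_actions
  new_policy(function(S) {
    Q <- qnet_forward(trained$net, apply_scaler(trained$scaler, S))$Q
    a <- max.col(Q, ties.method = "first")
    P <- matrix(0, nrow(Q), n_a)
    P[cbind(seq_len(nrow(Q)), a)] <- 1
    P
  }, n_actions = n_a, kind = "greedy-q", deterministic = TRUE)
}

#' Soften a deterministic policy for importance sampling
#'
#' Reassigns probability `p_top` to the recommended action and spreads the
#' remaining `1 - p_top` uniformly over the other actions, so that importance
#' ratios against a stochastic behavior policy stay finite.
#'
#' @param policy A `dex_policy`.
#' @param p_top Probability on the recommended (modal) action; default 0.99.
#' @return A stochastic `dex_policy`.
#' @export
soften <- function(policy, p_top = 0.99) {
  stopifnot(inherits(policy, "dex_policy"))
  n_a <- policy$n_actions
  if (!is.numeric(p_top) || length(p_top) != 1 || p_top <= 1 / n_a || p_top > 1)
    stopf("p_top must lie in (1/%d, 1]", n_a)
  rest <- (1 - p_top) / (n_a - 1)
  new_policy(function(S) {
    base <- policy$probs_fn(S)
    a <- max.col(base, ties.method = "first")
    P <- matrix(rest, nrow(base), n_a)
    P[cbind(seq_len(nrow(base)), a)] <- p_top
    P
  }, n_actions = n_a, kind = sprintf("softened(%s, %.3g)", policy$kind, p_top),
  deterministic = p_top == 1)
}

#' Uniform random dosing policy
#'
#' @param n_actions Size of the action space (default 16).
#' @return A `dex_policy` assigning probability `1/n_actions` to every action.
#' @export
random_policy <- function(n_actions = 16L) {
  n_a <- as.integer(n_actions)
  new_policy(function(S) matrix(1 / n_a, nrow(S), n_a),
             n_actions = n_a, kind = "random")
}

#' Fixed-dose policy
#'
#' Always recommends the action whose bin contains `dose`; useful as a simple
#' reference policy in simulations.
#'
#' @param dose Dose in mcg/kg/h (snapped to the 0.1 grid).
#' @param n_actions Size of the action space.
#' @return A deterministic `dex_policy`.
#' @export
constant_policy <- function(dose, n_actions = 16L) {
  a <- discretize_dose(dose)
  n_a <- as.integer(n_actions)
  new_policy(function(S) {
    P <- matrix(0, nrow(S), n_a)
    P[, a + 1L] <- 1
    P
  }, n_actions = n_a, kind = sprintf("constant(%.1f)", dose),
  deterministic = TRUE)
}

#' @export
print.dex_policy <- function(x, ...) {
  cat(sprintf("<dex_policy> %s over %d actions\n", x$kind, x$n_actions))
  invisible(x)
}
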