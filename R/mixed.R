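# Arbitration between the planner (DPEFE) and the learner (CL): a per-state
# bias beta(s) in [0, 1] tracks which scheme is more confident (lower
# action-distribution entropy) at that state, and the two action
# distributions are combined as a geometric mixture weighted by beta.

#' Construct a per-state bias map
#'
#' Every state starts at the prior bias `beta_prior = 0.5` (no preference
#' between planner and learner).  `alpha_norm` is the normalisation
#' parameter scaling the entropy-difference increments of [update_bias()]
#' (distinct from the action precision), and `efe_precision` is the scalar
#' multiplying `G` when the planner's distribution is formed inside the
#' mixed agent.
#'
#' @param n_states Positive integer.
#' @param beta_prior Initial bias value, default 0.5.
#' @param alpha_norm Increment scale of the bias update, default 0.1.
#' @param efe_precision EFE precision of the mixed agent's planner arm,
#'   default 1.
#' @return Object of class `bias_map`.
#' @export
bias_map <- function(n_states, beta_prior = 0.5, alpha_norm = 0.1,
                     efe_precision = 1) {
  stopifnot(beta_prior >= 0, beta_prior <= 1, alpha_norm > 0,
            efe_precision >= 0)
  structure(list(beta = rep(beta_prior, n_states), beta_prior = beta_prior,
                 alpha_norm = alpha_norm, efe_precision = efe_precision,
                 n_states = n_states),
            class = "bias_map")
}

#' @export
print.bias_map <- function(x, ...) {
  cat(sprintf("<bias_map> %d states, mean beta = %.3f (prior %.2f, alpha_norm %.3g)\n",
              x$n_states, mean(x$beta), x$beta_prior, x$alpha_norm))
  invisible(x)
}

#' Entropy-driven update of the bias at a state
#'
#' Moves the bias at the visited state by the (scaled) difference of the two
#' schemes' action-distribution entropies:
#' \deqn{\beta(s) \leftarrow \beta(s) + \alpha\,(H[P_{CL}(u|s)] -
#'   H[P_{DPEFE}(u|s)]),}
#' then clips to `[0, 1]`.  When the learner is still undecided (high
#' entropy) and the planner confident (low entropy), the bias moves toward
#' the planner, and vice versa; equal entropies leave it unchanged.
#'
#' @param map A `bias_map`.
#' @param s Visited state index.
#' @param p_cl,p_dpefe Normalized action distributions of the two schemes at
#'   `s`.
#' @return The updated `bias_map`.
#' @export
update_bias <- function(map, s, p_cl, p_dpefe) {
  if (s < 1L || s > map$n_states) stop("update_bias: state out of range")
  if (abs(sum(p_cl) - 1) > 1e-6 || abs(sum(p_dpefe) - 1) > 1e-6)
    stop("update_bias: action distributions must be normalized")
  b <- map$beta[s] +
    map$alpha_norm * (shannon_entropy(p_cl) - shannon_entropy(p_dpefe))
  map$beta[s] <- min(max(b, 0), 1)
  map
}

#' Closed-form (variational) bias from the two entropies
#'
#' Logistic sigmoid of the entropy difference,
#' \eqn{\beta = \mathrm{sig}(H_{CL} - H_{DPEFE})}: the stationary value that
#' the incremental rule of [update_bias()] approximates to first order
#' around 0.5 when the entropy difference is small.
#'
#' @param h_dpefe,h_cl Non-negative entropies (nats).
#' @return Bias value in (0, 1).
#' @export
bias_closed_form <- function(h_dpefe, h_cl) {
  stopifnot(h_dpefe >= 0, h_cl >= 0)
  stats::plogis(h_cl - h_dpefe)
}

#' Geometric mixture of the two action distributions
#'
#' Combines the learner's and planner's distributions entrywise as
#' \eqn{P_{MM}(u) \propto P_{CL}(u)^{1-\beta} P_{DPEFE}(u)^{\beta}} and
#' renormalizes (the product alone is not a distribution).  `beta = 0`
#' returns the learner's distribution exactly and `beta = 1` the planner's.
#'
#' @param p_cl,p_dpefe Normalized action distributions.
#' @param beta Bias value in `[0, 1]`.
#' @return Probability vector over actions.
#' @export
mix_action_distributions <- function(p_cl, p_dpefe, beta) {
  stopifnot(beta >= 0, beta <= 1, length(p_cl) == length(p_dpefe))
  if (beta == 0) return(p_cl)
  if (beta == 1) return(p_dpefe)
  w <- exp((1 - beta) * safe_log(p_cl) + beta * safe_log(p_dpefe))
  w / sum(w)
}

#' Sample an action index from a probability vector
#'
#' Inverse-CDF sampling using one draw from the session's random number
#' generator, so a fixed seed yields a reproducible draw sequence.
#'
#' @param p Normalized probability vector over actions.
#' @return Integer action index in `1..length(p)`.
#' @export
select_action <- function(p) {
  if (abs(sum(p) - 1) > 1e-6 || any(p < -1e-12))
    stop("select_action: `p` must be a normalized probability vector")
  min(findInterval(stats::runif(1L), cumsum(p)) + 1L, length(p))
}
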