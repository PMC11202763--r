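# Core POMDP machinery shared by every agent: the categorical generative
# model, Dirichlet transition learning, state inference and the numeric
# primitives (softmax, entropy, free energy).

LOG_FLOOR <- 1e-16

#' Numerically safe logarithm
#'
#' Applies a floor of `1e-16` before taking the logarithm, so that structural
#' zeros in categorical distributions do not produce `-Inf`.
#'
#' @param x Numeric vector.
#' @return `log(pmax(x, 1e-16))`.
#' @keywords internal
safe_log <- function(x) log(pmax(x, LOG_FLOOR))

#' Softmax with an inverse-temperature (precision) parameter
#'
#' Returns the normalized exponential of `precision * x`, stabilized by
#' subtracting the maximum before exponentiation.  `precision = 0` gives the
#' uniform distribution; large precisions concentrate mass on the maximum of
#' `x`.  This is the sigma operator used to turn (negative) expected free
#' energies or log-mappings into action probabilities.
#'
#' @param x Finite numeric vector.
#' @param precision Non-negative scalar inverse temperature.
#' @return Probability vector summing to 1.
#' @examples
#' softmax_with_precision(c(-1, -2), 1)   # ~ (0.731, 0.269)
#' softmax_with_precision(c(5, 9, -2), 0) # uniform
#' @export
softmax_with_precision <- function(x, precision = 1) {
  if (!all(is.finite(x))) stop("softmax_with_precision: `x` must be finite")
  if (!is.numeric(precision) || length(precision) != 1L || precision < 0)
    stop("softmax_with_precision: `precision` must be a non-negative scalar")
  z <- precision * x
  e <- exp(z - max(z))
  e / sum(e)
}

#' Shannon entropy of a probability vector (nats)
#'
#' Computes \eqn{-\sum_i p_i \log p_i} with the convention
#' \eqn{0 \log 0 = 0}.  The input must be normalized to within `1e-6`.
#'
#' @param p Probability vector.
#' @return Non-negative scalar entropy in nats.
#' @examples
#' shannon_entropy(c(1, 0, 0))       # 0
#' shannon_entropy(rep(0.25, 4))     # log(4)
#' @export
shannon_entropy <- function(p) {
  if (abs(sum(p) - 1) > 1e-6 || any(p < -1e-12))
    stop("shannon_entropy: `p` must be a normalized probability vector")
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

normalize_columns <- function(m) {
  sweep(m, 2L, colSums(m), "/")
}

#' Construct a categorical POMDP generative model
#'
#' Bundles the agent's likelihood `A`, action-conditioned transitions `B`
#' (with the Dirichlet concentration counts `b_counts` underlying them),
#' outcome preferences `C`, initial-state prior `D` and action prior `E`.
#' All columns of `A` and of every `B` slice are probability distributions;
#' `C` is strictly positive.
#'
#' If `b_counts` is supplied and `B` is not, `B` is obtained by normalizing
#' the counts column-wise.  In the fully observable configuration `A` is the
#' identity and the number of observations equals the number of states.
#'
#' @param A Likelihood matrix (`n_obs` x `n_states`), column-stochastic.
#' @param B Transition array (`n_states` x `n_states` x `n_actions`);
#'   `B[s', s, u]` is the probability of moving to `s'` from `s` under `u`.
#' @param C Preference distribution over observations (strictly positive).
#' @param D Prior over the initial state.
#' @param E Prior over actions, used only for the very first action of an
#'   episode. Defaults to uniform.
#' @param b_counts Non-negative Dirichlet counts with the same shape as `B`.
#' @return Object of class `generative_model`.
#' @seealso [fully_observable_model()], [learn_transition()]
#' @export
generative_model <- function(A, B = NULL, C = NULL, D = NULL, E = NULL,
                             b_counts = NULL) {
  A <- as.matrix(A)
  n_states <- ncol(A)
  n_obs <- nrow(A)
  if (is.null(B) && is.null(b_counts))
    stop("generative_model: supply `B` or `b_counts`")
  if (is.null(b_counts)) {
    b_counts <- B
  }
  b_counts <- as.array(b_counts)
  if (length(dim(b_counts)) != 3L)
    stop("generative_model: `B`/`b_counts` must be a 3-d array")
  if (is.null(B)) {
    B <- b_counts
    for (u in seq_len(dim(B)[3L])) B[, , u] <- normalize_columns(B[, , u])
  }
  n_actions <- dim(B)[3L]
  if (is.null(C)) C <- rep(1 / n_obs, n_obs)
  if (is.null(D)) D <- rep(1 / n_states, n_states)
  if (is.null(E)) E <- rep(1 / n_actions, n_actions)
  m <- structure(
    list(A = A, B = B, b_counts = b_counts, C = C, D = D, E = E,
         n_states = n_states, n_obs = n_obs, n_actions = n_actions),
    class = "generative_model")
  validate_model(m)
  m
}

#' @export
print.generative_model <- function(x, ...) {
  cat(sprintf("<generative_model> %d states, %d observations, %d actions\n",
              x$n_states, x$n_obs, x$n_actions))
  cat(sprintf("  identity likelihood: %s\n", identical_likelihood(x)))
  invisible(x)
}

identical_likelihood <- function(model) {
  model$n_obs == model$n_states &&
    isTRUE(all.equal(model$A, diag(model$n_states), check.attributes = FALSE,
                     tolerance = 1e-12))
}

validate_model <- function(m) {
  stopifnot(m$n_states >= 1L, m$n_obs >= 1L, m$n_actions >= 1L)
  if (max(abs(colSums(m$A) - 1)) > 1e-9)
    stop("generative_model: columns of A must sum to 1")
  if (!identical(dim(m$B), dim(m$b_counts)))
    stop("generative_model: B and b_counts must have identical shape")
  if (dim(m$B)[1L] != m$n_states || dim(m$B)[2L] != m$n_states)
    stop("generative_model: B slices must be n_states x n_states")
  for (u in seq_len(m$n_actions)) {
    if (max(abs(colSums(m$B[, , u]) - 1)) > 1e-9)
      stop("generative_model: columns of each B slice must sum to 1")
  }
  if (any(m$b_counts < 0)) stop("generative_model: b_counts must be >= 0")
  if (any(m$C <= 0) || abs(sum(m$C) - 1) > 1e-9)
    stop("generative_model: C must be strictly positive and sum to 1")
  if (abs(sum(m$D) - 1) > 1e-9) stop("generative_model: D must sum to 1")
  if (abs(sum(m$E) - 1) > 1e-9) stop("generative_model: E must sum to 1")
  invisible(m)
}

#' Construct a fully observable generative model with a flat transition prior
#'
#' Convenience constructor for the common configuration in which the
#' likelihood is the identity (`n_obs == n_states`, observation = state) and
#' the transition counts start from a flat Dirichlet prior of `b_prior` per
#' entry.  The default prior concentration is `1/n_states` per entry (unit
#' mass per column), so that a single observed transition already dominates
#' the prior; see the methods vignette for the rationale.
#'
#' @param n_states,n_actions Positive integers.
#' @param C Preference distribution over observations; default uniform.
#' @param D Prior over initial state; default uniform.
#' @param b_prior Prior concentration per `b_counts` entry.
#' @return A `generative_model`.
#' @export
fully_observable_model <- function(n_states, n_actions, C = NULL, D = NULL,
                                   b_prior = 1 / n_states) {
  counts <- array(b_prior, dim = c(n_states, n_states, n_actions))
  generative_model(A = diag(n_states), b_counts = counts, C = C, D = D)
}

#' Posterior state inference from one observation
#'
#' Combines a prior belief with the likelihood of observation `o` under each
#' state: the posterior is proportional to
#' `exp(log(prior) + log(A[o, ]))`, with a floor of `1e-16` inside the
#' logarithms.  With an identity likelihood this returns a one-hot belief at
#' the observed state.
#'
#' @param prior Probability vector over states.
#' @param model A `generative_model`.
#' @param o Observation index.
#' @return Posterior probability vector over states.
#' @export
infer_state <- function(prior, model, o) {
  if (o < 1L || o > model$n_obs) stop("infer_state: observation out of range")
  q <- exp(safe_log(prior) + safe_log(model$A[o, ]))
  q / sum(q)
}

#' One-step belief prediction under an action
#'
#' Pushes a belief through the transition slice for action `u`:
#' `B[, , u] %*% belief`, renormalized.
#'
#' @param belief Probability vector over states.
#' @param model A `generative_model`.
#' @param u Action index.
#' @return Predicted probability vector over next states.
#' @export
predict_belief <- function(belief, model, u) {
  if (u < 1L || u > model$n_actions) stop("predict_belief: action out of range")
  q <- as.vector(model$B[, , u] %*% belief)
  q / sum(q)
}

#' Dirichlet update of the transition model from one observed transition
#'
#' Increments the concentration count for the transition
#' `(s_prev, u) -> s_next` by `rate` and renormalizes the affected column of
#' `B`.  Repeated updates accumulate evidence: with i.i.d. draws from a fixed
#' true transition column the learned column converges to the truth.
#'
#' @param model A `generative_model`.
#' @param s_prev,s_next State indices.
#' @param u Action index.
#' @param rate Positive learning rate (count increment).
#' @return The updated `generative_model`.
#' @export
learn_transition <- function(model, s_prev, u, s_next, rate = 1) {
  stopifnot(rate > 0)
  if (s_prev < 1L || s_prev > model$n_states || s_next < 1L ||
      s_next > model$n_states) stop("learn_transition: state out of range")
  if (u < 1L || u > model$n_actions) stop("learn_transition: action out of range")
  model$b_counts[s_next, s_prev, u] <- model$b_counts[s_next, s_prev, u] + rate
  col <- model$b_counts[, s_prev, u]
  model$B[, s_prev, u] <- col / sum(col)
  model
}

# Rebuild all of B from the current counts (used once per episode by the
# runner after batched count accumulation).
rebuild_transitions <- function(model) {
  for (u in seq_len(model$n_actions))
    model$B[, , u] <- normalize_columns(model$b_counts[, , u])
  model
}

#' Variational free energy of a belief sequence (diagnostic)
#'
#' Evaluates the mean-field variational free energy of a sequence of beliefs
#' `q_1..q_t` given the observations and actions of a trajectory:
#' \deqn{F = \sum_\tau q_\tau \cdot (\log q_\tau - \log A[o_\tau,\cdot])
#'   - q_1 \cdot \log D
#'   - \sum_{\tau>1} q_\tau^\top \log B_{u_{\tau-1}} q_{\tau-1}.}
#' This is an upper bound on the negative log evidence of the observations;
#' it is reported as a diagnostic and is non-increasing under
#' [refine_beliefs()] sweeps.  The Kullback-Leibler penalty on Dirichlet
#' parameters is constant in the beliefs and omitted.
#'
#' @param beliefs Matrix (`n_states` x `t`) of belief columns.
#' @param observations Integer vector of `t` observation indices.
#' @param actions Integer vector of `t - 1` action indices.
#' @param model A `generative_model`.
#' @return Scalar free energy (nats).
#' @export
variational_free_energy <- function(beliefs, observations, actions, model) {
  beliefs <- as.matrix(beliefs)
  t_len <- ncol(beliefs)
  if (t_len < 1L) stop("variational_free_energy: empty trajectory")
  if (length(observations) != t_len)
    stop("variational_free_energy: need one observation per belief")
  if (t_len > 1L && length(actions) != t_len - 1L)
    stop("variational_free_energy: need one action per transition")
  f <- 0
  for (tau in seq_len(t_len)) {
    q <- beliefs[, tau]
    f <- f + sum(q * (safe_log(q) - safe_log(model$A[observations[tau], ])))
    if (tau == 1L) {
      f <- f - sum(q * safe_log(model$D))
    } else {
      logB <- safe_log(model$B[, , actions[tau - 1L]])
      f <- f - as.numeric(q %*% logB %*% beliefs[, tau - 1L])
    }
  }
  f
}

#' Coordinate-ascent refinement of a belief sequence
#'
#' Performs `sweeps` passes of mean-field coordinate updates over the belief
#' sequence: each `q_tau` is set to the softmax of its log-likelihood plus
#' the log-messages from its temporal neighbours.  Each sweep leaves the
#' variational free energy of the sequence no larger than before.
#'
#' @inheritParams variational_free_energy
#' @param sweeps Number of full forward passes.
#' @return Updated belief matrix.
#' @export
refine_beliefs <- function(beliefs, observations, actions, model, sweeps = 1) {
  beliefs <- as.matrix(beliefs)
  t_len <- ncol(beliefs)
  for (k in seq_len(sweeps)) {
    for (tau in seq_len(t_len)) {
      lq <- safe_log(model$A[observations[tau], ])
      if (tau == 1L) {
        lq <- lq + safe_log(model$D)
      } else {
        logB <- safe_log(model$B[, , actions[tau - 1L]])
        lq <- lq + as.vector(logB %*% beliefs[, tau - 1L])
      }
      if (tau < t_len) {
        logB <- safe_log(model$B[, , actions[tau]])
        lq <- lq + as.vector(t(logB) %*% beliefs[, tau + 1L])
      }
      beliefs[, tau] <- softmax_with_precision(lq, 1)
    }
  }
  beliefs
}
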