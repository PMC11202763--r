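# Dynamic-programming expected-free-energy (EFE) planner.  Evaluates the
# EFE table G(tau, u, s) backward over a finite horizon and converts its
# first slice into per-state action distributions via a precision-weighted
# softmax.

#' Build a goal-peaked preference distribution
#'
#' Returns the softmax over observations of a vector that is `concentration`
#' at the goal observation and 0 elsewhere.  The result is strictly positive
#' and sums to 1; larger concentrations put more mass on the goal.
#'
#' @param goal_state Goal observation index.
#' @param n_obs Number of observations.
#' @param concentration Positive log-odds weight at the goal.
#' @return Preference probability vector.
#' @seealso [preference_concentration()] to pick a concentration from a
#'   target goal mass.
#' @export
build_preference <- function(goal_state, n_obs, concentration) {
  if (goal_state < 1L || goal_state > n_obs)
    stop("build_preference: goal index out of range")
  stopifnot(concentration > 0)
  x <- numeric(n_obs)
  x[goal_state] <- concentration
  softmax_with_precision(x, 1)
}

#' Concentration giving a target goal mass
#'
#' Inverse of [build_preference()] in terms of the mass held by the goal
#' entry: returns the concentration for which the goal observation holds
#' `goal_mass` of the preference distribution.
#'
#' @param n_obs Number of observations (must be >= 2).
#' @param goal_mass Desired probability at the goal, in (0, 1).
#' @export
preference_concentration <- function(n_obs, goal_mass = 0.99) {
  stopifnot(n_obs >= 2, goal_mass > 0, goal_mass < 1)
  log(goal_mass / (1 - goal_mass) * (n_obs - 1))
}

#' Plan by backward dynamic programming over expected free energy
#'
#' Fills the EFE table `G[tau, u, s]` for `tau = T .. 1` by the backward
#' recursion
#' \deqn{G_\tau(u,s) = \mathrm{KL}[A B_u(\cdot|s) \,\|\, C]
#'   + \sum_{s'} B_u(s'|s) H[A(\cdot|s')]
#'   + \sum_{s'} B_u(s'|s) \sum_{u'} w(u'|s')\, G_{\tau+1}(u', s'),}
#' with boundary \eqn{G_{T+1} = 0}.  The first term is the risk (divergence
#' of predicted observations from the preference `C`), the second the
#' ambiguity of the likelihood (zero for an identity likelihood), and the
#' third the expected continuation under the softmax weighting
#' \eqn{w(\cdot|s') = \sigma(-\alpha G_{\tau+1}(\cdot, s'))}
#' (or a hard argmin when `continuation = "argmin"`).
#'
#' The cost is linear in the horizon: exactly `T * n_actions * n_states`
#' per-entry evaluations are performed, reported in the `n_evals` field.
#'
#' @param model A `generative_model`.
#' @param horizon Planning horizon `T >= 1` (number of steps looked ahead).
#' @param alpha Action precision used in the continuation weighting and as
#'   the default precision of [action_distribution_dpefe()].
#' @param continuation `"softmax"` (default) or `"argmin"` weighting of the
#'   continuation term.
#' @return Object of class `efe_table` with fields `G` (array
#'   `horizon` x `n_actions` x `n_states`), `horizon`, `alpha`, `n_evals`.
#' @export
plan_efe <- function(model, horizon, alpha = 1,
                     continuation = c("softmax", "argmin")) {
  continuation <- match.arg(continuation)
  if (!is.numeric(horizon) || horizon < 1L) stop("plan_efe: horizon must be >= 1")
  horizon <- as.integer(horizon)
  stopifnot(alpha >= 0)
  S <- model$n_states; U <- model$n_actions
  identA <- identical_likelihood(model)
  # Horizon-independent stage cost: risk + ambiguity, per (u, s).
  stage <- matrix(0, U, S)
  if (identA) {
    logC <- safe_log(model$C)
    for (u in seq_len(U)) {
      Bu <- model$B[, , u]
      stage[u, ] <- colSums(Bu * (safe_log(Bu) - logC))
    }
  } else {
    logC <- safe_log(model$C)
    H_A <- apply(model$A, 2L, shannon_entropy)
    for (u in seq_len(U)) {
      Bu <- model$B[, , u]
      pred <- model$A %*% Bu                      # n_obs x S
      stage[u, ] <- colSums(pred * (safe_log(pred) - logC)) + colSums(Bu * H_A)
    }
  }
  G <- array(0, dim = c(horizon, U, S))
  G[horizon, , ] <- stage
  if (horizon > 1L) {
    for (tau in seq.int(horizon - 1L, 1L)) {
      Gnext <- matrix(G[tau + 1L, , ], U, S)
      cmin <- Gnext[1L, ]
      for (u in seq_len(U)[-1L]) cmin <- pmin(cmin, Gnext[u, ])
      if (continuation == "softmax") {
        W <- exp(-alpha * sweep(Gnext, 2L, cmin, "-"))
        V <- colSums(W * Gnext) / colSums(W)      # continuation value per s'
      } else {
        V <- cmin
      }
      for (u in seq_len(U)) {
        G[tau, u, ] <- stage[u, ] + as.vector(crossprod(model$B[, , u], V))
      }
    }
  }
  structure(list(G = G, horizon = horizon, alpha = alpha,
                 n_evals = horizon * U * S, continuation = continuation),
            class = "efe_table")
}

#' @export
print.efe_table <- function(x, ...) {
  cat(sprintf("<efe_table> horizon %d, %d actions x %d states, alpha = %g (%d evaluations)\n",
              x$horizon, dim(x$G)[2L], dim(x$G)[3L], x$alpha, x$n_evals))
  invisible(x)
}

#' Action distribution of the planner at a state
#'
#' Softmax of the negated first-step EFE column:
#' \eqn{P(u|s) = \sigma(-\alpha G_1(\cdot, s))}; actions with smaller
#' expected free energy are selected with larger probability.
#'
#' @param table An `efe_table` from [plan_efe()].
#' @param s State index.
#' @param alpha Optional precision override (defaults to the table's).
#' @return Probability vector over actions.
#' @export
action_distribution_dpefe <- function(table, s, alpha = table$alpha) {
  S <- dim(table$G)[3L]
  if (s < 1L || s > S) stop("action_distribution_dpefe: state out of range")
  softmax_with_precision(-table$G[1L, , s], alpha)
}

#' Planner policy for every state at once
#'
#' Column `s` holds \eqn{\sigma(-\alpha G_1(\cdot, s))}.  Used by the
#' experiment runner to avoid per-step softmax calls.
#'
#' @inheritParams action_distribution_dpefe
#' @return Matrix `n_actions` x `n_states` of action probabilities.
#' @export
dpefe_policy <- function(table, alpha = table$alpha) {
  G1 <- matrix(table$G[1L, , ], dim(table$G)[2L], dim(table$G)[3L])
  Z <- -alpha * G1
  Z <- sweep(Z, 2L, apply(Z, 2L, max), "-")
  W <- exp(Z)
  sweep(W, 2L, colSums(W), "/")
}
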