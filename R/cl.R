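# Counterfactual learning (CL): a risk-modulated state-action mapping
# learned from experience, with no planning component.  The scalar risk
# trace Gamma is reset to 0.9 on start / high-risk events and otherwise
# decays toward zero, faster when the goal time T_goal is still far ahead.

CL_FLOOR <- 1e-16

#' Construct the state of a counterfactual learner
#'
#' Holds the strictly positive state-action mapping `CL` (rows = actions,
#' columns = states, initialized to 1 so the starting policy is uniform),
#' the current risk `gamma`, and the goal-time bookkeeping `t_goal` (the
#' within-episode step index at which the last positive environmental signal
#' was received; it persists across episodes).
#'
#' @param n_states,n_actions Positive integers.
#' @param gamma_reset Reset value of the risk trace (0.9).
#' @param t_goal Initial goal time; conventionally the episode step budget
#'   until a success has actually been observed.
#' @param floor Lower bound kept on every `CL` entry.
#' @return Object of class `cl_state`.
#' @export
cl_state <- function(n_states, n_actions, gamma_reset = 0.9,
                     t_goal = n_states, floor = CL_FLOOR) {
  stopifnot(n_states >= 1, n_actions >= 1,
            gamma_reset >= 0, gamma_reset <= 1, floor > 0)
  structure(
    list(CL = matrix(1, n_actions, n_states),
         gamma = gamma_reset, gamma_reset = gamma_reset,
         t_goal = t_goal, step = 0L,
         n_states = n_states, n_actions = n_actions, floor = floor),
    class = "cl_state")
}

#' @export
print.cl_state <- function(x, ...) {
  cat(sprintf("<cl_state> %d actions x %d states, gamma = %.3f, t_goal = %s\n",
              x$n_actions, x$n_states, x$gamma, format(x$t_goal)))
  invisible(x)
}

#' Update the risk trace
#'
#' `event = "reset"` substitutes the reset value (0.9): used when the agent
#' is at the start position or when its action caused a high-risk outcome
#' (wall hit, failure, exhausted step budget).  `event = "decay"` divides
#' the previous risk by `max(t_goal - t, 1)` and clips to `[0, 1]`: the
#' further the expected goal time lies ahead, the faster the risk decays,
#' and a risk of zero is absorbing.
#'
#' @param state A `cl_state`.
#' @param event `"reset"` or `"decay"`.
#' @param t Current within-episode step index (>= 0).
#' @return The updated `cl_state`.
#' @export
update_risk <- function(state, event = c("reset", "decay"), t = state$step) {
  event <- match.arg(event)
  stopifnot(t >= 0)
  state$step <- t
  if (event == "reset") {
    state$gamma <- state$gamma_reset
  } else {
    g <- state$gamma / max(state$t_goal - t, 1)
    state$gamma <- min(max(g, 0), 1)
  }
  state
}

#' Batch update of the state-action mapping from a trajectory
#'
#' Applies the counterfactual update
#' \deqn{CL \leftarrow CL + t \,\langle (1 - 2\Gamma_\tau)\,
#'   (u_\tau \otimes s_{\tau-1}) \rangle,}
#' where the angle brackets average over the `t` steps of the trajectory and
#' the Kronecker product of one-hot vectors selects the visited
#' (action, state) entry.  Steps experienced under low risk
#' (\eqn{\Gamma < 0.5}) strengthen the visited entries; high-risk steps
#' (\eqn{\Gamma > 0.5}) weaken them.  Entries are floored afterwards so the
#' mapping stays strictly positive.
#'
#' @param state A `cl_state`.
#' @param s_prev Integer vector of states the actions were taken from.
#' @param u Integer vector of actions taken.
#' @param gamma Numeric vector of per-step risk values.
#' @return The updated `cl_state`.
#' @export
update_cl_mapping <- function(state, s_prev, u, gamma) {
  n <- length(u)
  if (n == 0L) stop("update_cl_mapping: empty trajectory")
  stopifnot(length(s_prev) == n, length(gamma) == n)
  # t * mean over the trajectory == sum over steps
  w <- 1 - 2 * gamma
  key <- (s_prev - 1L) * state$n_actions + u
  inc <- rowsum(w, group = key)
  idx <- as.integer(rownames(inc))
  state$CL[idx] <- pmax(state$CL[idx] + inc[, 1L], state$floor)
  state
}

#' Hindsight risk trace of one episode
#'
#' Reconstructs the per-step risk values \eqn{\Gamma_1..\Gamma_T} of an
#' episode, for the batch counterfactual update performed at the episode
#' end.  The trace starts from the reset value at the start position and
#' then, per step:
#' \itemize{
#'   \item a high-risk event (wall hit, failure, exhausted budget) resets
#'     the risk to `gamma_reset`;
#'   \item the step that receives the positive environmental signal drops
#'     the risk to zero (the sooner the desirable state is reached, the
#'     sooner the risk vanishes);
#'   \item while the next positive signal still lies `k` steps ahead the
#'     risk decays as \eqn{\Gamma_t = \Gamma_{t-1} / \max(T_{goal} - t, 1)}
#'     (clipped to `[0, 1]`);
#'   \item with no positive signal in sight the risk holds its value.
#' }
#' For episodic goals (mazes) the signal time is the episode's own goal
#' step, known in hindsight; for continuously rewarded tasks (cart-pole
#' balancing) the relevant horizon is the step budget the agent aims to
#' survive through.
#'
#' @param n_steps Episode length.
#' @param high_risk Logical vector flagging high-risk steps.
#' @param success_step Step index of the positive signal, or `NA` if the
#'   episode ended without one.
#' @param horizon Expected signal time when no success occurred (e.g. the
#'   step budget of a balancing task), or `NA` to hold the risk instead.
#' @param gamma_reset Reset value (0.9).
#' @return Numeric vector of `n_steps` risk values.
#' @export
risk_trace <- function(n_steps, high_risk, success_step = NA_integer_,
                       horizon = NA_integer_, gamma_reset = 0.9) {
  stopifnot(length(high_risk) == n_steps)
  g <- numeric(n_steps)
  cur <- gamma_reset                       # at the start position
  ahead <- if (!is.na(success_step)) success_step else horizon
  for (t in seq_len(n_steps)) {
    if (high_risk[t]) {
      cur <- gamma_reset
    } else if (!is.na(success_step) && t == success_step) {
      cur <- 0
    } else if (!is.na(ahead) && ahead > t) {
      cur <- min(max(cur / (ahead - t), 0), 1)
    }
    g[t] <- cur
  }
  g
}

#' Action distribution of the counterfactual learner at a state
#'
#' Unit-precision softmax of the log-mapping column,
#' \eqn{\sigma(\ln CL \cdot s)}, which is the column of `CL` normalized to
#' sum 1.  Scale-invariant: multiplying a column by a positive constant
#' leaves the distribution unchanged.
#'
#' @param state A `cl_state`.
#' @param s State index.
#' @return Probability vector over actions.
#' @export
action_distribution_cl <- function(state, s) {
  if (s < 1L || s > state$n_states)
    stop("action_distribution_cl: state out of range")
  col <- state$CL[, s]
  col / sum(col)
}
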