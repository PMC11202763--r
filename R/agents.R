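# Agent constructors.  Three agent types share one interface: the pure
# planner (DPEFE), the pure counterfactual learner (CL), and the mixed
# agent that arbitrates between the two via the per-state bias map.

#' Construct a DPEFE (planning) agent
#'
#' The agent holds a generative model whose transition counts are learned
#' from experience; at the start of every episode the transition slices are
#' rebuilt from the counts and the expected-free-energy table is recomputed
#' by [plan_efe()].  Actions are sampled from
#' \eqn{\sigma(-\alpha G_1(\cdot, s))}.
#'
#' @param model A `generative_model` (e.g. from [maze_model()]).
#' @param horizon Planning horizon `T`.
#' @param alpha Action precision (default 1).
#' @param continuation Continuation weighting passed to [plan_efe()].
#' @param replan_interval Steps between within-episode replans while the
#'   transition model is still being learned; defaults to `2 * n_states` count
#'   increments, after which the plan is considered stale.  The table is
#'   always recomputed at the episode start.
#' @return Object of class `c("dpefe_agent", "actinf_agent")`.
#' @export
dpefe_agent <- function(model, horizon, alpha = 1,
                        continuation = c("softmax", "argmin"),
                        replan_interval = 2L * model$n_states) {
  continuation <- match.arg(continuation)
  structure(
    list(type = "dpefe", model = model, horizon = as.integer(horizon),
         alpha = alpha, continuation = continuation, policy = NULL,
         plan_evals = 0, replan_interval = as.integer(replan_interval),
         n_states = model$n_states, n_actions = model$n_actions),
    class = c("dpefe_agent", "actinf_agent"))
}

#' Construct a CL (counterfactual learning) agent
#'
#' Learns a risk-modulated state-action mapping from experience and never
#' plans: its planning-evaluation count stays zero.  The risk trace resets
#' to `gamma_reset` at the episode start and on high-risk events and decays
#' toward zero otherwise; the mapping is updated once per episode from the
#' full trajectory.
#'
#' @param n_states,n_actions Environment dimensions.
#' @param gamma_reset Risk reset value (0.9).
#' @return Object of class `c("cl_agent", "actinf_agent")`.
#' @export
cl_agent <- function(n_states, n_actions, gamma_reset = 0.9) {
  structure(
    list(type = "cl",
         cl = cl_state(n_states, n_actions, gamma_reset = gamma_reset,
                       t_goal = NA_integer_),
         plan_evals = 0,
         n_states = as.integer(n_states), n_actions = as.integer(n_actions)),
    class = c("cl_agent", "actinf_agent"))
}

#' Construct a mixed (arbitrating) agent
#'
#' Carries both a planner arm (EFE table over `horizon` steps, precision
#' `efe_precision`) and a learner arm (the CL mapping), plus a per-state
#' bias initialized at 0.5.  At every step the bias of the visited state is
#' updated from the entropy difference of the two action distributions
#' before the action is drawn from their geometric mixture.
#'
#' @param model A `generative_model`.
#' @param horizon Planning horizon `N` of the planner arm.
#' @param alpha_norm Bias update scale (default 0.1).
#' @param efe_precision Precision applied to `G` in the planner arm
#'   (default 1).
#' @param beta_prior Initial bias (default 0.5).
#' @param gamma_reset Risk reset value (0.9).
#' @param continuation Continuation weighting passed to [plan_efe()].
#' @param replan_interval Steps between within-episode replans (see
#'   [dpefe_agent()]).
#' @return Object of class `c("mixed_agent", "actinf_agent")`.
#' @export
mixed_agent <- function(model, horizon, alpha_norm = 0.1, efe_precision = 1,
                        beta_prior = 0.5, gamma_reset = 0.9,
                        continuation = c("softmax", "argmin"),
                        replan_interval = 2L * model$n_states) {
  continuation <- match.arg(continuation)
  structure(
    list(type = "mixed", model = model, horizon = as.integer(horizon),
         continuation = continuation,
         replan_interval = as.integer(replan_interval),
         cl = cl_state(model$n_states, model$n_actions,
                       gamma_reset = gamma_reset, t_goal = NA_integer_),
         bias = bias_map(model$n_states, beta_prior = beta_prior,
                         alpha_norm = alpha_norm,
                         efe_precision = efe_precision),
         policy = NULL, plan_evals = 0,
         n_states = model$n_states, n_actions = model$n_actions),
    class = c("mixed_agent", "actinf_agent"))
}

#' @export
print.actinf_agent <- function(x, ...) {
  cat(sprintf("<%s_agent> %d states, %d actions", x$type, x$n_states,
              x$n_actions))
  if (!is.null(x$horizon)) cat(sprintf(", horizon %d", x$horizon))
  cat(sprintf(", %g planning evaluations so far\n", x$plan_evals))
  invisible(x)
}

#' Prepare an agent for a new episode
#'
#' Planner-carrying agents rebuild their transition slices from the learned
#' Dirichlet counts and recompute the EFE table (once per episode: the
#' model only changes through learning).  The CL agent's goal-time
#' bookkeeping is initialized to the environment's step budget if no
#' success has been observed yet.
#'
#' @param agent An `actinf_agent`.
#' @param env A `grid_world` or `cartpole_env`.
#' @return The prepared agent.
#' @export
begin_episode <- function(agent, env) {
  if (!is.null(agent$cl) && is.na(agent$cl$t_goal))
    agent$cl$t_goal <- env$step_budget
  if (agent$type %in% c("dpefe", "mixed")) {
    agent$model <- rebuild_transitions(agent$model)
    alpha <- if (agent$type == "dpefe") agent$alpha else
      agent$bias$efe_precision
    table <- plan_efe(agent$model, agent$horizon, alpha = alpha,
                      continuation = agent$continuation)
    agent$plan_evals <- agent$plan_evals + table$n_evals
    agent$policy <- dpefe_policy(table)
    agent$table <- table
  }
  agent
}

# Swap the task-defining parts of the agent's model (preferences, start
# prior) for a new environment variant while keeping everything learned
# (transition counts, CL mapping, bias map).  Used at mutation boundaries.
retarget_agent <- function(agent, env, goal_mass = 0.99) {
  if (env$n_actions != agent$n_actions ||
      env$n_states != agent$n_states)
    stop("retarget_agent: environment dimensions changed across mutation")
  if (!is.null(agent$model) && env$type == "grid") {
    S <- env$n_states
    agent$model$C <- build_preference(env$goal, S,
                                      preference_concentration(S, goal_mass))
    D <- numeric(S); D[env$start] <- 1
    agent$model$D <- D
  }
  agent
}

#' Build an agent from a declarative specification
#'
#' Used by the experiment runner and the command-line interface.  The
#' specification is a list with `type` (`"dpefe"`, `"cl"` or `"mixed"`) and
#' the optional fields `horizon`, `alpha`, `alpha_norm`, `efe_precision`,
#' `beta_prior`, `goal_mass`, `b_prior`, `continuation`.
#'
#' @param spec Named list.
#' @param env Environment the agent will act in.
#' @return An `actinf_agent`.
#' @export
make_agent <- function(spec, env) {
  type <- match.arg(spec$type, c("dpefe", "cl", "mixed"))
  goal_mass <- spec$goal_mass %||% 0.99
  if (type == "cl")
    return(cl_agent(env$n_states, env$n_actions,
                    gamma_reset = spec$gamma_reset %||% 0.9))
  model <- if (env$type == "grid") {
    maze_model(env, goal_mass = goal_mass,
               b_prior = spec$b_prior %||% (1 / env$n_states))
  } else {
    fully_observable_model(env$n_states, env$n_actions,
                           b_prior = spec$b_prior %||% (1 / env$n_states))
  }
  if (type == "dpefe") {
    dpefe_agent(model, horizon = spec$horizon %||% 25L,
                alpha = spec$alpha %||% 1,
                continuation = spec$continuation %||% "softmax",
                replan_interval = spec$replan_interval %||% (2L * env$n_states))
  } else {
    mixed_agent(model, horizon = spec$horizon %||% 25L,
                alpha_norm = spec$alpha_norm %||% 0.1,
                efe_precision = spec$efe_precision %||% 1,
                beta_prior = spec$beta_prior %||% 0.5,
                gamma_reset = spec$gamma_reset %||% 0.9,
                continuation = spec$continuation %||% "softmax",
                replan_interval = spec$replan_interval %||% (2L * env$n_states))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
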