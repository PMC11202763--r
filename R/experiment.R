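# Experiment orchestration: seeded episodes, the perceive-arbitrate-act-
# learn loop shared by all agent types, mutation schedules, and metric
# aggregation across seeds.

entropy_fast <- function(p) {
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

#' Deterministic child seed for a (trial, episode) pair
#'
#' Spawns reproducible per-episode seeds from one master seed by a counter
#' scheme: `(master %% 20000) * 100003 + trial * 731 + episode`, which is
#' unique for `trial <= 136` and `episode <= 730` and stays below `2^31`.
#'
#' @param master Master seed (integer).
#' @param trial Trial (seed-replicate) index, 1-based.
#' @param episode Episode index, 1-based.
#' @return Integer seed.
#' @export
child_seed <- function(master, trial, episode) {
  (as.integer(master) %% 20000L) * 100003L + trial * 731L + episode
}

#' Run a single episode of the agent-environment loop
#'
#' One loop iteration: perceive the (fully observed) state, form the action
#' distributions of the agent's scheme(s), update the per-state bias (mixed
#' agent), sample an action (from the action prior `E` at the very first
#' step), step the environment, update the risk trace, and accumulate
#' transition counts.  At the episode end the CL mapping is updated from
#' the whole trajectory.  Identical seed, agent and environment give an
#' identical record.
#'
#' @param agent An `actinf_agent`.
#' @param env A `grid_world` or `cartpole_env`.
#' @param seed Optional integer seed set before the episode.
#' @param record_dists Keep the per-step action distributions of all
#'   schemes in the record (off by default; the matrices grow with the
#'   step budget).
#' @return List with `agent` (updated) and `record`, the latter holding
#'   `length`, `goal_reached`, `score`, per-step `states`, `actions`,
#'   `obs`, `gamma`, `beta` (mixed agent), `wall_hits`, summary means and,
#'   when requested, the distribution matrices `p_dpefe`, `p_cl`, `p_mm`.
#' @export
run_episode <- function(agent, env, seed = NULL, record_dists = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (env$n_actions != agent$n_actions || env$n_states != agent$n_states)
    stop("run_episode: agent and environment dimensions differ")
  agent <- begin_episode(agent, env)
  budget <- env$step_budget
  is_grid <- env$type == "grid"
  U <- agent$n_actions
  has_model <- agent$type %in% c("dpefe", "mixed")
  has_cl <- !is.null(agent$cl)
  is_mixed <- agent$type == "mixed"

  states <- integer(budget); actions <- integer(budget)
  obs_log <- integer(budget); gammas <- numeric(budget)
  walls <- logical(budget)
  betas <- if (is_mixed) numeric(budget) else NULL
  if (record_dists) {
    m0 <- matrix(NA_real_, U, budget)
    pd_log <- m0; pc_log <- m0; pm_log <- m0
  }

  if (has_model) {
    counts <- agent$model$b_counts
    policy <- agent$policy
    E_prior <- agent$model$E
    replan_interval <- agent$replan_interval %||% (2L * agent$n_states)
    steps_since_plan <- 0L
  } else {
    E_prior <- rep(1 / U, U)
  }
  if (has_cl) {
    CL <- agent$cl$CL
    gamma_reset <- agent$cl$gamma_reset
    t_goal <- agent$cl$t_goal
  }
  if (is_mixed) {
    beta <- agent$bias$beta
    alpha_norm <- agent$bias$alpha_norm
  }

  if (is_grid) {
    s <- env$start
    succ <- env$succ; hitt <- env$hit; goal_cell <- env$goal
  } else {
    cont <- cartpole_reset(env)
    s <- discretize_cartpole(env, cont)
  }

  goal <- FALSE
  fail_step <- NA_integer_
  t <- 0L
  while (t < budget) {
    t <- t + 1L
    p_d <- if (has_model) policy[, s] else NULL
    p_c <- if (has_cl) { col <- CL[, s]; col / sum(col) } else NULL
    if (is_mixed) {
      b <- beta[s] + alpha_norm * (entropy_fast(p_c) - entropy_fast(p_d))
      b <- min(max(b, 0), 1)
      beta[s] <- b
      betas[t] <- b
      w <- exp((1 - b) * log(pmax(p_c, LOG_FLOOR)) +
                 b * log(pmax(p_d, LOG_FLOOR)))
      p_act <- w / sum(w)
    } else {
      p_act <- if (has_model) p_d else p_c
    }
    if (record_dists) {
      if (has_model) pd_log[, t] <- p_d
      if (has_cl) pc_log[, t] <- p_c
      pm_log[, t] <- if (is_mixed) p_act else
        if (has_model) p_d else p_c
    }
    if (t == 1L) p_act <- E_prior
    u <- min(findInterval(stats::runif(1L), cumsum(p_act)) + 1L, U)

    if (is_grid) {
      s2 <- succ[s, u]
      wall_hit <- hitt[s, u]
      failed <- FALSE
      reached <- s2 == goal_cell
    } else {
      stp <- cartpole_step(env, cont, u)
      cont <- stp$state
      s2 <- discretize_cartpole(env, cont)
      wall_hit <- FALSE
      failed <- stp$terminated
      reached <- FALSE
    }

    states[t] <- s
    actions[t] <- u
    obs_log[t] <- s2
    walls[t] <- wall_hit
    if (failed) fail_step <- t
    if (has_model) {
      counts[s2, s, u] <- counts[s2, s, u] + 1
      steps_since_plan <- steps_since_plan + 1L
      if (steps_since_plan >= replan_interval && t < budget) {
        # the plan has gone stale against the accumulated evidence
        agent$model$b_counts <- counts
        agent <- begin_episode(agent, env)
        policy <- agent$policy
        steps_since_plan <- 0L
      }
    }

    s <- s2
    if (is_grid && reached) {
      goal <- TRUE
      break
    }
    if (!is_grid && failed) break
  }
  t_end <- t
  if (budget == 0L) t_end <- 0L

  # Hindsight risk trace: high-risk steps are wall hits, the failure step
  # and an exhausted budget on an unsolved task; the positive signal is
  # reaching the goal (mazes) or balancing through the budget (cart-pole).
  if (has_cl && t_end > 0L) {
    high_risk <- walls[seq_len(t_end)]
    if (!is.na(fail_step)) high_risk[fail_step] <- TRUE
    success_step <- NA_integer_
    horizon <- NA_integer_
    if (is_grid) {
      if (goal) success_step <- t_end else high_risk[t_end] <- TRUE
    } else {
      horizon <- budget
      if (is.na(fail_step) && t_end == budget) success_step <- budget
    }
    gammas[seq_len(t_end)] <- risk_trace(t_end, high_risk, success_step,
                                         horizon, gamma_reset)
    if (!is.na(success_step)) t_goal <- success_step
  }

  keep <- seq_len(t_end)
  states <- states[keep]; actions <- actions[keep]
  obs_log <- obs_log[keep]; walls <- walls[keep]
  gammas <- if (has_cl) gammas[keep] else NULL
  betas <- if (is_mixed) betas[keep] else NULL

  # Batch counterfactual update over the full trajectory, then write the
  # working copies back into the agent.
  if (has_cl) {
    agent$cl$CL <- CL
    if (t_end > 0L)
      agent$cl <- update_cl_mapping(agent$cl, states, actions, gammas)
    agent$cl$gamma <- if (t_end > 0L) gammas[t_end] else agent$cl$gamma
    agent$cl$t_goal <- t_goal
    agent$cl$step <- t_end
  }
  if (has_model) agent$model$b_counts <- counts
  if (is_mixed) agent$bias$beta <- beta

  score <- if (is_grid) t_end else t_end  # episode length / balancing time
  record <- list(
    length = t_end, goal_reached = goal,
    score = score,
    states = states, actions = actions, obs = obs_log,
    wall_hits = walls,
    gamma = gammas, beta = betas,
    mean_gamma = if (has_cl && t_end > 0L) mean(gammas) else NA_real_,
    mean_beta = if (is_mixed && t_end > 0L) mean(betas) else NA_real_,
    beta_avg = if (is_mixed) mean(beta) else NA_real_,
    beta_start = if (is_mixed && is_grid) beta[env$start] else NA_real_,
    final_state = s, seed = seed)
  if (record_dists) {
    record$p_dpefe <- if (has_model) pd_log[, keep, drop = FALSE] else NULL
    record$p_cl <- if (has_cl) pc_log[, keep, drop = FALSE] else NULL
    record$p_mm <- pm_log[, keep, drop = FALSE]
  }
  list(agent = agent, record = record)
}

#' Declarative experiment configuration
#'
#' Validates and bundles everything [run_experiment()] needs.  All
#' violations are reported together.
#'
#' @param agent Agent specification list (see [make_agent()]).
#' @param env Initial environment (`grid_world` or `cartpole_env`).
#' @param n_episodes Episodes per trial.
#' @param n_seeds Number of independent trials (>= 1).
#' @param seed Master seed; per-episode seeds are spawned with
#'   [child_seed()].
#' @param mutations List of `list(episode = k, env = <environment>)`
#'   entries with strictly increasing episode indices: the environment is
#'   swapped in before episode `k + 1`, the agent keeps everything it has
#'   learned, and its preferences are re-targeted to the new goal.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(agent, env, n_episodes, n_seeds = 1L,
                              seed = 1L, mutations = list()) {
  problems <- character(0)
  if (is.null(agent$type) ||
      !agent$type %in% c("dpefe", "cl", "mixed"))
    problems <- c(problems, "agent$type must be 'dpefe', 'cl' or 'mixed'")
  if (!inherits(env, c("grid_world", "cartpole_env")))
    problems <- c(problems, "env must be a grid_world or cartpole_env")
  if (!is.numeric(n_episodes) || n_episodes < 1)
    problems <- c(problems, "n_episodes must be >= 1")
  if (!is.numeric(n_seeds) || n_seeds < 1)
    problems <- c(problems, "n_seeds must be >= 1")
  eps <- vapply(mutations, function(m) as.numeric(m$episode %||% NA), 1)
  if (length(eps) && (anyNA(eps) || any(diff(eps) <= 0) ||
                      any(eps < 1) || any(eps >= n_episodes)))
    problems <- c(problems,
                  "mutation episodes must be strictly increasing and inside 1..(n_episodes-1)")
  for (m in mutations) {
    if (!is.null(m$env) && inherits(env, "grid_world") &&
        (m$env$n_states != env$n_states || m$env$n_actions != env$n_actions))
      problems <- c(problems, "mutated environment changes the state space")
  }
  if (length(problems))
    stop("experiment_config: invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(list(agent = agent, env = env,
                 n_episodes = as.integer(n_episodes),
                 n_seeds = as.integer(n_seeds), seed = as.integer(seed),
                 mutations = mutations),
            class = "experiment_config")
}

#' Run a full seeded experiment
#'
#' For every trial a fresh agent is built from the specification and run
#' for `n_episodes` episodes, swapping the environment at the scheduled
#' mutation points (the agent keeps its learned transition counts, CL
#' mapping and bias map across mutations).  Each episode is seeded with
#' [child_seed()], so a re-run with the same configuration is
#' bit-identical.
#'
#' @param config An [experiment_config()].
#' @return Data frame with one row per (seed, episode): `agent`, `seed`,
#'   `episode`, `env_variant`, `length`, `score`, `goal`, `mean_gamma`,
#'   `mean_beta` (trajectory average), `beta_avg` (average over all states
#'   at the episode end), `beta_start`, `plan_evals`, `wall_hits`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  n_ep <- config$n_episodes; n_seeds <- config$n_seeds
  n <- n_ep * n_seeds
  out <- list(seed = integer(n), episode = integer(n),
              env_variant = integer(n), length = integer(n),
              score = numeric(n), goal = logical(n),
              mean_gamma = numeric(n), mean_beta = numeric(n),
              beta_avg = numeric(n),
              beta_start = numeric(n), plan_evals = numeric(n),
              wall_hits = integer(n))
  row <- 0L
  mut_eps <- vapply(config$mutations, function(m) as.integer(m$episode),
                    integer(1))
  for (trial in seq_len(n_seeds)) {
    env <- config$env
    agent <- make_agent(config$agent, env)
    variant <- 1L
    prev_evals <- 0
    for (ep in seq_len(n_ep)) {
      hit_mut <- which(mut_eps == ep - 1L)
      if (length(hit_mut)) {
        env <- config$mutations[[hit_mut]]$env
        agent <- retarget_agent(agent, env,
                                goal_mass = config$agent$goal_mass %||% 0.99)
        variant <- variant + 1L
      }
      res <- run_episode(agent, env,
                         seed = child_seed(config$seed, trial, ep))
      agent <- res$agent
      rec <- res$record
      row <- row + 1L
      out$seed[row] <- trial
      out$episode[row] <- ep
      out$env_variant[row] <- variant
      out$length[row] <- rec$length
      out$score[row] <- rec$score
      out$goal[row] <- rec$goal_reached
      out$mean_gamma[row] <- rec$mean_gamma %||% NA_real_
      out$mean_beta[row] <- rec$mean_beta %||% NA_real_
      out$beta_avg[row] <- rec$beta_avg %||% NA_real_
      out$beta_start[row] <- rec$beta_start %||% NA_real_
      out$plan_evals[row] <- agent$plan_evals - prev_evals
      prev_evals <- agent$plan_evals
      out$wall_hits[row] <- sum(rec$wall_hits)
    }
  }
  df <- as.data.frame(out)
  df$agent <- config$agent$type
  df[c("agent", setdiff(names(df), "agent"))]
}

#' Aggregate experiment metrics across seeds
#'
#' Per-episode mean, median, quartiles, standard deviation and standard
#' error across seeds, plus final-window averages (the last `final_window`
#' episodes of every seed) for asymptotic summaries.
#'
#' @param metrics Data frame from [run_experiment()] (or several
#'   row-bound together; rows are grouped by `agent`).
#' @param final_window Number of trailing episodes in the final window.
#' @return List with data frames `per_episode` and `final_window`.
#' @export
aggregate_metrics <- function(metrics, final_window = 50L) {
  if (nrow(metrics) == 0L) stop("aggregate_metrics: empty record set")
  vars <- intersect(c("length", "score", "mean_gamma", "mean_beta",
                      "beta_avg"),
                    names(metrics))
  agg_one <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(mean = NA, median = NA, q25 = NA, q75 = NA,
                             sd = NA, sem = NA))
    c(mean = mean(x), median = stats::median(x),
      q25 = unname(stats::quantile(x, 0.25)),
      q75 = unname(stats::quantile(x, 0.75)),
      sd = stats::sd(x), sem = stats::sd(x) / sqrt(length(x)))
  }
  per_ep <- do.call(rbind, lapply(
    split(metrics, list(metrics$agent, metrics$episode), drop = TRUE),
    function(d) {
      stats_block <- unlist(lapply(vars, function(v) {
        st <- agg_one(d[[v]])
        stats::setNames(st, paste(v, names(st), sep = "_"))
      }))
      cbind(data.frame(agent = d$agent[1L], episode = d$episode[1L]),
            as.data.frame(as.list(stats_block)))
    }))
  per_ep <- per_ep[order(per_ep$agent, per_ep$episode), ]
  rownames(per_ep) <- NULL

  fw <- do.call(rbind, lapply(split(metrics, metrics$agent), function(d) {
    last <- max(d$episode)
    dd <- d[d$episode > last - final_window, ]
    stats_block <- unlist(lapply(vars, function(v) {
      st <- agg_one(dd[[v]])
      stats::setNames(st, paste(v, names(st), sep = "_"))
    }))
    cbind(data.frame(agent = d$agent[1L],
                     episodes = paste0(max(1L, last - final_window + 1L),
                                       "-", last)),
          as.data.frame(as.list(stats_block)))
  }))
  rownames(fw) <- NULL
  list(per_episode = per_ep, final_window = fw)
}

#' Variational free energy of an episode record
#'
#' Convenience wrapper: turns the (fully observed) state trajectory of a
#' record into one-hot beliefs and evaluates
#' [variational_free_energy()] under the supplied model.
#'
#' @param record A record from [run_episode()].
#' @param model A `generative_model`.
#' @return Scalar free energy (nats).
#' @export
episode_free_energy <- function(record, model) {
  if (record$length == 0L) stop("episode_free_energy: empty trajectory")
  seq_states <- c(record$states[1L], record$obs)
  beliefs <- matrix(0, model$n_states, length(seq_states))
  beliefs[cbind(seq_states, seq_along(seq_states))] <- 1
  variational_free_energy(beliefs, seq_states, record$actions, model)
}
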