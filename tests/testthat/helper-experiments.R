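# Shared experiment runs for the acceptance-level tests.  Several criteria
# read different aspects of the same simulation, so runs are computed once
# per test session and cached.

.acceptance_cache <- new.env(parent = emptyenv())

cached <- function(name, fun) {
  if (!exists(name, envir = .acceptance_cache)) {
    assign(name, fun(), envir = .acceptance_cache)
  }
  get(name, envir = .acceptance_cache)
}

# Mutating cart-pole: CL agent, thresholds halve after episode 100.  The
# first 100 episodes are identical to a non-mutating run under the same
# master seed.
cartpole_cl_run <- function() cached("cartpole_cl", function() {
  env <- cartpole_env(step_budget = 200)
  hard <- cartpole_env(angle_limit_deg = 6, position_limit = 1.2,
                       step_budget = 200)
  cfg <- experiment_config(list(type = "cl"), env,
                           n_episodes = 140, n_seeds = 20, seed = 101,
                           mutations = list(list(episode = 100, env = hard)))
  run_experiment(cfg)
})

# Mutating maze schedule: easy 10x10 grid (optimal path 4) for 35
# episodes, then a hard variant (optimal path 14), mixed agents with
# planning depths 5 / 25 / 50.
mutating_maze_runs <- function() cached("mutating_maze", function() {
  pair <- mutating_maze_pair(10, 10, easy_path = 4, hard_target = 14,
                             seed = 2)
  rm_easy <- random_walk_mean(pair$easy, n_seeds = 40, seed = 3, cap = 2e4)
  budget <- min(as.integer(10 * rm_easy), 2500L)
  pair$easy$step_budget <- budget
  pair$hard$step_budget <- budget
  runs <- lapply(c(5L, 25L, 50L), function(N) {
    cfg <- experiment_config(
      list(type = "mixed", horizon = N), pair$easy,
      n_episodes = 80, n_seeds = 20, seed = 202,
      mutations = list(list(episode = 35, env = pair$hard)))
    run_experiment(cfg)
  })
  names(runs) <- c("N5", "N25", "N50")
  list(runs = runs, mutation_episode = 35L, pair = pair)
})

# Planner-vs-learner data efficiency on a 16x16 maze (optimal path 24).
# The learner gets a longer observation window because its first success
# arrives much later.
data_efficiency_runs <- function() cached("data_efficiency", function() {
  w <- generate_maze(16, 16, seed = 3, target_path_length = 24)
  rm_mean <- random_walk_mean(w, n_seeds = 40, seed = 5, cap = 5e4)
  w$step_budget <- min(as.integer(10 * rm_mean), 6000L)
  threshold <- 10L * shortest_path_length(w)
  specs <- list(dpefe = list(type = "dpefe", horizon = 25, n = 25L),
                mixed = list(type = "mixed", horizon = 25, n = 40L),
                cl = list(type = "cl", n = 100L))
  runs <- lapply(specs, function(sp) {
    cfg <- experiment_config(sp, w, n_episodes = sp$n, n_seeds = 20,
                             seed = 303)
    run_experiment(cfg)
  })
  list(runs = runs, threshold = threshold, world = w)
})

# First episode that starts three consecutive episodes at or below the
# threshold; censored runs report cap + 1.
first_success_episode <- function(lengths, threshold) {
  ok <- lengths <= threshold
  three <- ok & c(ok[-1], FALSE) & c(ok[-(1:2)], FALSE, FALSE)
  if (any(three)) which(three)[1L] else length(lengths) + 1L
}

# Synthetic 30x30 stand-in for the 900-state maze: optimal path exactly 47.
synthetic_maze_900 <- function() cached("maze900", function() {
  w <- generate_maze(30, 30, seed = 11, target_path_length = 47)
  w$step_budget <- 30000L
  w
})
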