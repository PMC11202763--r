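# Grid-world testbeds: ASCII maze parsing/writing, a procedural generator
# that can target an optimal-path length, deterministic stepping, and the
# baseline oracles (breadth-first search, random walk).
#
# Cell states are indexed 1-based, row-major: state = (row - 1) * width + col.
# Actions are 1 = Up, 2 = Down, 3 = Left, 4 = Right.

GRID_ACTIONS <- c("Up", "Down", "Left", "Right")

grid_index <- function(row, col, width) (row - 1L) * width + col

# Successor / wall-hit tables for all (state, action) pairs.  Moving into a
# wall or off-grid leaves the state unchanged and flags a wall hit.
grid_tables <- function(width, height, wall) {
  S <- width * height
  succ <- matrix(NA_integer_, S, 4L)
  hit <- matrix(FALSE, S, 4L)
  drow <- c(-1L, 1L, 0L, 0L)
  dcol <- c(0L, 0L, -1L, 1L)
  for (row in seq_len(height)) {
    for (col in seq_len(width)) {
      s <- grid_index(row, col, width)
      if (wall[s]) next
      for (u in 1:4) {
        r2 <- row + drow[u]; c2 <- col + dcol[u]
        if (r2 < 1L || r2 > height || c2 < 1L || c2 > width) {
          succ[s, u] <- s; hit[s, u] <- TRUE
        } else {
          s2 <- grid_index(r2, c2, width)
          if (wall[s2]) {
            succ[s, u] <- s; hit[s, u] <- TRUE
          } else {
            succ[s, u] <- s2
          }
        }
      }
    }
  }
  list(succ = succ, hit = hit)
}

new_grid_world <- function(width, height, wall, start, goal,
                           step_budget = 4L * width * height,
                           check_reachable = TRUE) {
  stopifnot(width >= 1, height >= 1, length(wall) == width * height)
  if (wall[start]) stop("grid_world: start cell is a wall")
  if (wall[goal]) stop("grid_world: goal cell is a wall")
  tabs <- grid_tables(width, height, wall)
  w <- structure(
    list(type = "grid", width = as.integer(width), height = as.integer(height),
         wall = wall, start = as.integer(start), goal = as.integer(goal),
         step_budget = as.integer(step_budget),
         n_states = as.integer(width * height), n_actions = 4L,
         succ = tabs$succ, hit = tabs$hit),
    class = "grid_world")
  if (check_reachable && is.na(bfs_distance(w)))
    stop("grid_world: goal is not reachable from start")
  w
}

#' Parse an ASCII maze into a grid world
#'
#' The dialect uses `#` for walls, `.` for free cells, `S` for the start and
#' `G` for the goal; rows must be equal length and exactly one `S` and one
#' `G` must be present.  The goal must be reachable from the start.  States
#' are indexed 1-based and row-major (`state = (row-1)*width + col`);
#' actions are Up, Down, Left, Right.
#'
#' @param text Either a single string containing newlines or a character
#'   vector of rows.
#' @param step_budget Maximum steps per episode (default `4 * width * height`).
#' @return Object of class `grid_world`.
#' @seealso [write_maze()], [read_maze()], [generate_maze()]
#' @examples
#' w <- parse_maze(c("S.#", "..#", ".#G"))
#' @export
parse_maze <- function(text, step_budget = NULL) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  text <- as.character(text)
  if (length(text) == 0L) stop("parse_maze: empty maze")
  widths <- nchar(text)
  if (length(unique(widths)) != 1L)
    stop("parse_maze: ragged rows (all rows must have equal length)")
  width <- widths[1L]
  height <- length(text)
  chars <- unlist(strsplit(text, "", fixed = TRUE), use.names = FALSE)
  bad <- setdiff(unique(chars), c("#", ".", "S", "G"))
  if (length(bad) > 0L)
    stop("parse_maze: unknown symbols: ", paste(bad, collapse = " "))
  if (sum(chars == "S") != 1L) stop("parse_maze: need exactly one start 'S'")
  if (sum(chars == "G") != 1L) stop("parse_maze: need exactly one goal 'G'")
  wall <- chars == "#"
  start <- which(chars == "S")
  goal <- which(chars == "G")
  if (is.null(step_budget)) step_budget <- 4L * width * height
  new_grid_world(width, height, wall, start, goal, step_budget)
}

#' Read a maze file
#'
#' @param path Path to a UTF-8, LF-terminated ASCII maze file.
#' @inheritParams parse_maze
#' @export
read_maze <- function(path, step_budget = NULL) {
  parse_maze(readLines(path), step_budget = step_budget)
}

#' Render a grid world back to its ASCII rows
#'
#' Inverse of [parse_maze()]: `parse_maze(format_maze(w))` reproduces the
#' same world, and [write_maze()] emits byte-stable files.
#'
#' @param world A `grid_world`.
#' @return Character vector of rows.
#' @export
format_maze <- function(world) {
  chars <- ifelse(world$wall, "#", ".")
  chars[world$start] <- "S"
  chars[world$goal] <- "G"
  apply(matrix(chars, world$height, world$width, byrow = TRUE), 1L,
        paste, collapse = "")
}

#' Write a grid world to an ASCII maze file (UTF-8, LF endings)
#'
#' @param world A `grid_world`.
#' @param path Output file path.
#' @export
write_maze <- function(world, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(format_maze(world), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @export
print.grid_world <- function(x, ...) {
  cat(sprintf("<grid_world> %dx%d (%d states), optimal path %d, budget %d\n",
              x$width, x$height, x$n_states, shortest_path_length(x),
              x$step_budget))
  cat(format_maze(x), sep = "\n")
  invisible(x)
}

# Breadth-first-search distance start -> goal; NA when unreachable.
bfs_distance <- function(world, from = world$start, to = world$goal) {
  S <- world$n_states
  dist <- rep(NA_integer_, S)
  dist[from] <- 0L
  queue <- integer(S); queue[1L] <- from
  head <- 1L; tail <- 1L
  while (head <= tail) {
    s <- queue[head]; head <- head + 1L
    if (s == to) return(dist[s])
    for (u in 1:4) {
      s2 <- world$succ[s, u]
      if (!is.na(s2) && is.na(dist[s2])) {
        dist[s2] <- dist[s] + 1L
        tail <- tail + 1L
        queue[tail] <- s2
      }
    }
  }
  NA_integer_
}

#' Length of the shortest start-to-goal path (moves)
#'
#' Breadth-first-search oracle used both to validate generated mazes and as
#' the optimality baseline for agents.
#'
#' @param world A `grid_world`.
#' @return Integer number of moves.
#' @export
shortest_path_length <- function(world) {
  d <- bfs_distance(world)
  if (is.na(d)) stop("shortest_path_length: goal unreachable")
  d
}

#' Generate a random grid world, optionally targeting an optimal-path length
#'
#' Without a target, walls are sampled independently at `wall_density`, the
#' start and goal are placed on random distinct free cells, and the layout
#' is resampled until the goal is reachable.  With `target_path_length`, the
#' generator places start and goal at a compatible Manhattan distance (same
#' parity, not exceeding the target) and then adds walls one at a time,
#' keeping only additions that leave the goal reachable without overshooting
#' the target, until the breadth-first-search length equals the target
#' (within `tolerance`).  Fixed seeds give reproducible mazes.
#'
#' @param width,height Grid dimensions (>= 2).
#' @param wall_density Fraction of cells sampled as walls (ignored during
#'   the targeted wall-addition phase).
#' @param seed Optional integer seed.
#' @param target_path_length Desired optimal path length, or `NULL`.
#' @param tolerance Accepted deviation from the target (default 0).
#' @param max_tries Restarts before giving up.
#' @param step_budget Episode step budget stored on the world.
#' @param start_goal_distance Optional exact Manhattan distance between
#'   start and goal during the targeted phase.  Setting it equal to the
#'   target yields an open (wall-free) layout; leaving it `NULL` samples a
#'   random compatible distance, which the wall-addition phase then
#'   stretches into a dense maze.
#' @return A `grid_world`.
#' @export
generate_maze <- function(width, height, wall_density = 0.25, seed = NULL,
                          target_path_length = NULL, tolerance = 0,
                          max_tries = 400L, step_budget = NULL,
                          start_goal_distance = NULL) {
  stopifnot(width >= 2, height >= 2)
  if (!is.null(seed)) set.seed(seed)
  S <- width * height
  if (is.null(step_budget)) step_budget <- 4L * S
  if (is.null(target_path_length)) {
    for (i in seq_len(max_tries)) {
      wall <- stats::runif(S) < wall_density
      free <- which(!wall)
      if (length(free) < 2L) next
      sg <- sample(free, 2L)
      w <- tryCatch(
        new_grid_world(width, height, wall, sg[1L], sg[2L], step_budget),
        error = function(e) NULL)
      if (!is.null(w)) return(w)
    }
    stop("generate_maze: no reachable layout after ", max_tries, " tries")
  }
  target <- as.integer(target_path_length)
  if (target < 1L) stop("generate_maze: target path length must be >= 1")
  for (try in seq_len(max_tries)) {
    w <- generate_maze_targeted(width, height, target, tolerance, step_budget,
                                start_goal_distance)
    if (!is.null(w)) return(w)
  }
  stop("generate_maze: could not reach target path length ", target,
       " after ", max_tries, " restarts")
}

generate_maze_targeted <- function(width, height, target, tolerance,
                                   step_budget, start_goal_distance = NULL) {
  S <- width * height
  rows <- (seq_len(S) - 1L) %/% width + 1L
  cols <- (seq_len(S) - 1L) %% width + 1L
  # Start/goal at a Manhattan distance of matching parity, no larger than
  # the target (walls can only lengthen the path).
  for (i in seq_len(500L)) {
    sg <- sample.int(S, 2L)
    d <- abs(rows[sg[1L]] - rows[sg[2L]]) + abs(cols[sg[1L]] - cols[sg[2L]])
    ok <- if (is.null(start_goal_distance)) {
      d >= 1L && d <= target && (target - d) %% 2L == 0L
    } else {
      d == start_goal_distance && (target - d) %% 2L == 0L
    }
    if (ok) break
    sg <- NULL
  }
  if (is.null(sg)) return(NULL)
  wall <- rep(FALSE, S)
  w <- new_grid_world(width, height, wall, sg[1L], sg[2L], step_budget,
                      check_reachable = FALSE)
  len <- bfs_distance(w)
  if (abs(len - target) <= tolerance) return(w)
  candidates <- sample(setdiff(seq_len(S), sg))
  for (cell in candidates) {
    wall2 <- wall
    wall2[cell] <- TRUE
    w2 <- tryCatch(
      new_grid_world(width, height, wall2, sg[1L], sg[2L], step_budget),
      error = function(e) NULL)
    if (is.null(w2)) next
    len2 <- bfs_distance(w2)
    if (len2 > target + tolerance) next
    wall <- wall2
    w <- w2
    len <- len2
    if (abs(len - target) <= tolerance) return(w)
  }
  NULL
}

#' Deterministic one-step grid transition
#'
#' Moving into a wall or off the grid leaves the state unchanged and flags a
#' wall hit.  The environment is fully observable, so the observation equals
#' the next state.
#'
#' @param world A `grid_world`.
#' @param s Current state index (must be a free cell).
#' @param u Action index (1 = Up, 2 = Down, 3 = Left, 4 = Right).
#' @return List with `s_next`, `obs`, `goal_reached`, `wall_hit`.
#' @export
grid_step <- function(world, s, u) {
  if (s < 1L || s > world$n_states) stop("grid_step: state out of range")
  if (world$wall[s]) stop("grid_step: state is a wall cell")
  if (u < 1L || u > 4L) stop("grid_step: action out of range")
  s2 <- world$succ[s, u]
  list(s_next = s2, obs = s2, goal_reached = s2 == world$goal,
       wall_hit = world$hit[s, u])
}

#' Steps taken by a uniform random walk to reach the goal
#'
#' Baseline oracle: repeatedly samples one of the four actions uniformly
#' until the goal is reached or `cap` steps have elapsed.
#'
#' @param world A `grid_world`.
#' @param seed Optional integer seed.
#' @param cap Step cap bounding runaway walks.
#' @return Integer step count; if the cap was hit, the cap itself with
#'   attribute `censored = TRUE`.
#' @export
random_walk_episode_length <- function(world, seed = NULL, cap = 1e6) {
  if (!is.null(seed)) set.seed(seed)
  s <- world$start
  goal <- world$goal
  succ <- world$succ
  steps <- 0L
  chunk <- 8192L
  while (steps < cap) {
    us <- sample.int(4L, chunk, replace = TRUE)
    for (i in seq_len(chunk)) {
      s <- succ[s, us[i]]
      steps <- steps + 1L
      if (s == goal) return(steps)
      if (steps >= cap) break
    }
  }
  structure(as.integer(cap), censored = TRUE)
}

#' Mean random-walk episode length over several seeds
#'
#' @inheritParams random_walk_episode_length
#' @param n_seeds Number of independent walks.
#' @param seed Base seed; walk `i` uses `seed + i`.
#' @return Mean step count (censored walks enter at the cap).
#' @export
random_walk_mean <- function(world, n_seeds = 100L, seed = 1L, cap = 1e6) {
  mean(vapply(seq_len(n_seeds), function(i)
    as.numeric(random_walk_episode_length(world, seed = seed + i, cap = cap)),
    numeric(1)))
}

#' Generative model for a grid world
#'
#' Builds the fully observable generative model an agent holds for a maze:
#' identity likelihood, flat transition prior (to be learned from
#' experience), preferences peaked on the goal observation and an
#' initial-state prior concentrated on the start cell.
#'
#' @param world A `grid_world`.
#' @param goal_mass Preference mass on the goal observation.
#' @param b_prior Prior Dirichlet concentration per transition count.
#' @return A `generative_model`.
#' @export
maze_model <- function(world, goal_mass = 0.99, b_prior = 1 / world$n_states) {
  S <- world$n_states
  C <- build_preference(world$goal, S, preference_concentration(S, goal_mass))
  D <- numeric(S); D[world$start] <- 1
  fully_observable_model(S, 4L, C = C, D = D, b_prior = b_prior)
}

#' Easy/hard maze pair for mutation experiments
#'
#' Generates two grid worlds of identical dimensions sharing a state space:
#' an easy variant whose optimal path is short (default 4 moves) and a hard
#' variant with a long optimal path, used as the before/after environments
#' of a scheduled mutation.
#'
#' @param width,height Shared grid dimensions.
#' @param easy_path Optimal path length of the easy variant.
#' @param hard_target Optimal path length targeted for the hard variant.
#' @param seed Integer seed.
#' @param step_budget Episode step budget stored on both worlds.
#' @return List with elements `easy` and `hard`.
#' @export
mutating_maze_pair <- function(width = 12L, height = 12L, easy_path = 4L,
                               hard_target = 18L, seed = 1L,
                               step_budget = NULL) {
  easy <- generate_maze(width, height, seed = seed,
                        target_path_length = easy_path,
                        step_budget = step_budget,
                        start_goal_distance = easy_path)
  hard <- generate_maze(width, height, seed = seed + 1L,
                        target_path_length = hard_target,
                        step_budget = step_budget)
  list(easy = easy, hard = hard)
}
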