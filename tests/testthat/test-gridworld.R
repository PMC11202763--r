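# Maze parsing/writing, procedural generation, deterministic stepping and
# the baseline oracles.

test_that("parse_maze handles minimal worlds and rejects malformed input", {
  w <- parse_maze("SG")
  expect_equal(c(w$width, w$height), c(2L, 1L))
  expect_equal(shortest_path_length(w), 1L)
  expect_error(parse_maze("S#G"), "not reachable")
  expect_error(parse_maze(c("S.", "...")), "ragged")
  expect_error(parse_maze("S.."), "exactly one goal")
  expect_error(parse_maze(c("SS", ".G")), "exactly one start")
  expect_error(parse_maze("SxG"), "unknown symbols")
})

test_that("open room has Manhattan-distance optimal path", {
  w <- parse_maze(c("S..", "...", "..G"))
  expect_equal(shortest_path_length(w), 4L)
})

test_that("mazes round-trip byte-identically through the writer", {
  rows <- c("S.#.", "..#.", "#..G")
  w <- parse_maze(rows)
  expect_identical(format_maze(w), rows)
  path <- tempfile(fileext = ".txt")
  write_maze(w, path)
  expect_identical(readBin(path, "raw", file.size(path)),
                   charToRaw(paste0(paste(rows, collapse = "\n"), "\n")))
  w2 <- read_maze(path)
  expect_identical(format_maze(w2), rows)
  expect_identical(w2$start, w$start)
  expect_identical(w2$goal, w$goal)
})

test_that("generator is reproducible and honors targets", {
  w1 <- generate_maze(8, 8, wall_density = 0.2, seed = 5)
  w2 <- generate_maze(8, 8, wall_density = 0.2, seed = 5)
  expect_identical(format_maze(w1), format_maze(w2))
  # density 0: path equals the Manhattan distance between start and goal
  w0 <- generate_maze(6, 6, wall_density = 0, seed = 9)
  rc <- function(s) c((s - 1) %/% 6 + 1, (s - 1) %% 6 + 1)
  manhattan <- sum(abs(rc(w0$start) - rc(w0$goal)))
  expect_equal(shortest_path_length(w0), manhattan)
  # targeted generation hits the requested optimal length exactly
  wt <- generate_maze(10, 10, seed = 3, target_path_length = 15)
  expect_equal(shortest_path_length(wt), 15L)
  wd <- generate_maze(10, 10, seed = 4, target_path_length = 6,
                      start_goal_distance = 6)
  expect_equal(shortest_path_length(wd), 6L)
  expect_equal(sum(wd$wall), 0L)
})

test_that("grid_step matches the hand-built table of an open 2x2 room", {
  w <- parse_maze(c("S.", ".G"))
  # states: 1 2 / 3 4; actions: 1 Up, 2 Down, 3 Left, 4 Right
  expected <- rbind(c(1, 3, 1, 2),   # from 1: up bounce, down 3, left bounce, right 2
                    c(2, 4, 1, 2),   # from 2
                    c(1, 3, 3, 4),   # from 3
                    c(2, 4, 3, 4))   # from 4
  for (s in 1:4) for (u in 1:4) {
    st <- grid_step(w, s, u)
    expect_identical(st$s_next, as.integer(expected[s, u]))
    expect_identical(st$obs, st$s_next)
    expect_identical(st$wall_hit, st$s_next == s)
    expect_identical(st$goal_reached, st$s_next == 4L)
  }
  expect_error(grid_step(parse_maze("S#G\n..."), 2, 1), "wall cell")
})

test_that("steps never teleport: successor is the cell itself or a 4-neighbour", {
  set.seed(13)
  w <- generate_maze(9, 7, wall_density = 0.3, seed = 13)
  for (s in which(!w$wall)) for (u in 1:4) {
    s2 <- grid_step(w, s, u)$s_next
    r1 <- (s - 1) %/% w$width; c1 <- (s - 1) %% w$width
    r2 <- (s2 - 1) %/% w$width; c2 <- (s2 - 1) %% w$width
    expect_lte(abs(r1 - r2) + abs(c1 - c2), 1)
  }
})

test_that("random walk oracle behaves on the trivial world and under caps", {
  w <- parse_maze("SG")
  lens <- vapply(1:200, function(i)
    as.numeric(random_walk_episode_length(w, seed = i)), numeric(1))
  # one of four actions succeeds per step: geometric with mean 4
  expect_equal(mean(lens), 4, tolerance = 0.75)
  capped <- random_walk_episode_length(parse_maze(c("S.", ".G")),
                                       seed = 1, cap = 1)
  expect_true(isTRUE(attr(capped, "censored")) || capped == 1)
})

test_that("maze generative model encodes goal preference and start prior", {
  w <- parse_maze(c("S..", "..G"))
  m <- maze_model(w, goal_mass = 0.95)
  expect_equal(m$C[w$goal], 0.95, tolerance = 1e-9)
  expect_equal(which.max(m$D), w$start)
  expect_equal(sum(m$D), 1)
  expect_true(identical(dim(m$B), c(6L, 6L, 4L)))
})

test_that("mutating pair shares dimensions with contrasting difficulty", {
  pair <- mutating_maze_pair(10, 10, easy_path = 4, hard_target = 14, seed = 6)
  expect_identical(pair$easy$n_states, pair$hard$n_states)
  expect_equal(shortest_path_length(pair$easy), 4L)
  expect_equal(shortest_path_length(pair$hard), 14L)
})
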