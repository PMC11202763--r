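# Generative model machinery: softmax, inference, Dirichlet learning,
# entropy and the free-energy diagnostic.

test_that("softmax_with_precision matches direct evaluation and limits", {
  expect_equal(softmax_with_precision(c(0, 0, 0), 7), rep(1 / 3, 3))
  expect_equal(softmax_with_precision(c(5, -2, 0.3), 0), rep(1 / 3, 3))
  expect_equal(softmax_with_precision(c(-1, -2), 1),
               c(exp(-1), exp(-2)) / (exp(-1) + exp(-2)),
               tolerance = 1e-12)
  expect_error(softmax_with_precision(c(1, NaN), 1), "finite")
  expect_error(softmax_with_precision(c(1, 2), -1), "non-negative")
})

test_that("softmax is shift-invariant and normalized for random inputs", {
  set.seed(42)
  for (i in 1:50) {
    x <- stats::rnorm(sample(2:8, 1), sd = 5)
    prec <- stats::runif(1, 0, 4)
    p <- softmax_with_precision(x, prec)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, softmax_with_precision(x + stats::rnorm(1, sd = 50), prec),
                 tolerance = 1e-9)
  }
})

test_that("shannon_entropy handles one-hot, uniform and generic cases", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4))
  expect_equal(shannon_entropy(c(0.75, 0.25)),
               -0.75 * log(0.75) - 0.25 * log(0.25), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(0.75, 0.25)), 0.5623, tolerance = 1e-4)
  expect_error(shannon_entropy(c(0.7, 0.2)), "normalized")
})

test_that("generative_model validates its invariants", {
  m <- fully_observable_model(3, 2)
  expect_equal(m$n_obs, m$n_states)
  expect_equal(m$A, diag(3))
  for (u in 1:2) expect_equal(colSums(m$B[, , u]), rep(1, 3))
  # normalizing counts reproduces B
  for (u in 1:2)
    expect_equal(sweep(m$b_counts[, , u], 2, colSums(m$b_counts[, , u]), "/"),
                 m$B[, , u], tolerance = 1e-9)
  expect_error(generative_model(diag(3), b_counts = m$b_counts,
                                C = c(0.5, 0.5, 0)),
               "strictly positive")
})

test_that("infer_state performs exact Bayes updates", {
  m <- fully_observable_model(4, 2)
  # identity likelihood: one-hot at the observed state
  post <- infer_state(rep(0.25, 4), m, 3)
  expect_equal(post, c(0, 0, 1, 0))
  # hand Bayes: prior (.5,.5), likelihoods (.9,.3) -> (.75,.25)
  A <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2)
  m2 <- generative_model(A, b_counts = array(1, c(2, 2, 1)))
  expect_equal(infer_state(c(0.5, 0.5), m2, 1), c(0.75, 0.25))
  # flat prior: posterior proportional to the likelihood row
  expect_equal(infer_state(c(0.5, 0.5), m2, 2),
               A[2, ] / sum(A[2, ]))
  expect_error(infer_state(c(0.5, 0.5), m2, 3), "out of range")
})

test_that("predict_belief pushes beliefs through the transition slice", {
  B <- array(0, c(2, 2, 1))
  B[, , 1] <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2)
  m <- generative_model(diag(2), b_counts = B)
  expect_equal(predict_belief(c(1, 0), m, 1), c(0.7, 0.3))
  # doubly stochastic slice preserves the uniform belief
  expect_equal(predict_belief(c(0.5, 0.5), m, 1), c(0.45, 0.55))
  Bd <- array(0, c(3, 3, 1)); Bd[, , 1] <- diag(3)[, c(2, 3, 1)]
  md <- generative_model(diag(3), b_counts = Bd + 1e-12)
  expect_equal(predict_belief(c(1, 0, 0), md, 1), c(0, 1, 0),
               tolerance = 1e-9)
})

test_that("learn_transition accumulates Dirichlet counts correctly", {
  m <- generative_model(diag(2), b_counts = array(1, c(2, 2, 1)))
  m1 <- learn_transition(m, s_prev = 1, u = 1, s_next = 1, rate = 1)
  expect_equal(m1$B[, 1, 1], c(2 / 3, 1 / 3))
  # two rate-1 updates equal one rate-2 update
  m2a <- learn_transition(m1, 1, 1, 1, rate = 1)
  m2b <- learn_transition(m, 1, 1, 1, rate = 2)
  expect_equal(m2a$b_counts, m2b$b_counts)
  expect_equal(m2a$B, m2b$B)
  # mode moves to the observed successor
  expect_gt(m1$B[1, 1, 1], m1$B[2, 1, 1])
  # untouched columns unchanged
  expect_equal(m1$B[, 2, 1], m$B[, 2, 1])
})

test_that("learned transition column converges to the truth in L1", {
  set.seed(7)
  truth <- c(0.6, 0.3, 0.1)
  m <- fully_observable_model(3, 1, b_prior = 1 / 3)
  draws <- sample.int(3, 1e4, replace = TRUE, prob = truth)
  for (s_next in draws) m <- learn_transition(m, 1, 1, s_next)
  expect_lt(sum(abs(m$B[, 1, 1] - truth)), 0.05)
})

test_that("all emitted distributions are normalized on random models", {
  set.seed(99)
  for (i in 1:20) {
    S <- sample(2:5, 1); U <- sample(1:3, 1)
    m <- random_model(S, U)
    q <- infer_state(rep(1 / S, S), m, sample.int(m$n_obs, 1))
    expect_equal(sum(q), 1, tolerance = 1e-9)
    expect_true(all(q >= 0))
    p <- predict_belief(q, m, sample.int(U, 1))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
})

test_that("inference tracks the true state of a deterministic observable chain", {
  # cyclic deterministic dynamics, identity likelihood
  Bd <- array(1e-12, c(3, 3, 1))
  for (s in 1:3) Bd[s %% 3 + 1, s, 1] <- 1
  m <- generative_model(diag(3), b_counts = Bd)
  q <- c(1, 0, 0)
  s <- 1L
  for (step in 1:6) {
    q <- predict_belief(q, m, 1)
    s <- s %% 3L + 1L
    q <- infer_state(q, m, s)
    expect_equal(q, as.numeric(seq_len(3) == s), tolerance = 1e-9)
  }
})

test_that("variational free energy matches the enumeration oracle", {
  set.seed(5)
  m <- random_model(2, 2)
  obs <- c(1, 2, 1)
  acts <- c(2, 1)
  beliefs <- matrix(stats::runif(6) + 0.1, 2, 3)
  beliefs <- sweep(beliefs, 2, colSums(beliefs), "/")
  expect_equal(variational_free_energy(beliefs, obs, acts, m),
               oracle_vfe(beliefs, obs, acts, m), tolerance = 1e-10)
  expect_error(variational_free_energy(matrix(1, 2, 0), integer(0),
                                       integer(0), m),
               "empty")
})

test_that("free energy is non-increasing under belief refinement sweeps", {
  set.seed(8)
  for (i in 1:5) {
    m <- random_model(3, 2)
    t_len <- 4
    obs <- sample.int(3, t_len, replace = TRUE)
    acts <- sample.int(2, t_len - 1, replace = TRUE)
    beliefs <- matrix(stats::runif(3 * t_len) + 0.05, 3, t_len)
    beliefs <- sweep(beliefs, 2, colSums(beliefs), "/")
    f_prev <- variational_free_energy(beliefs, obs, acts, m)
    for (sweep_i in 1:3) {
      beliefs <- refine_beliefs(beliefs, obs, acts, m, sweeps = 1)
      f_new <- variational_free_energy(beliefs, obs, acts, m)
      expect_lte(f_new, f_prev + 1e-9)
      f_prev <- f_new
    }
  }
})

test_that("exact posteriors make the free energy equal negative log evidence", {
  # single step: F at the true posterior is -log P(o)
  set.seed(3)
  m <- random_model(3, 1)
  o <- 2L
  post <- infer_state(m$D, m, o)
  f <- variational_free_energy(matrix(post, 3, 1), o, integer(0), m)
  evidence <- sum(m$A[o, ] * m$D)
  expect_equal(f, -log(evidence), tolerance = 1e-9)
})
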