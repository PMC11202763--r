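# Independent oracles used to validate the fast implementations.

# Scalar, definition-level recursion for the expected-free-energy table:
# no vectorization, no table reuse across (tau, u, s).  Deliberately slow.
oracle_efe <- function(model, horizon, alpha, continuation = "softmax") {
  S <- model$n_states; U <- model$n_actions
  logC <- log(pmax(model$C, 1e-16))
  H_A <- apply(model$A, 2L, function(col) {
    pos <- col > 0
    -sum(col[pos] * log(col[pos]))
  })
  g <- function(tau, u, s) {
    b_col <- model$B[, s, u]
    pred <- as.vector(model$A %*% b_col)
    risk <- sum(pred * (log(pmax(pred, 1e-16)) - logC))
    amb <- sum(b_col * H_A)
    cont <- 0
    if (tau < horizon) {
      for (sp in seq_len(S)) {
        if (b_col[sp] == 0) next
        gnext <- vapply(seq_len(U), function(up) g(tau + 1L, up, sp),
                        numeric(1))
        w <- if (continuation == "softmax") {
          e <- exp(-alpha * (gnext - min(gnext)))
          e / sum(e)
        } else {
          h <- gnext == min(gnext)
          h / sum(h)
        }
        cont <- cont + b_col[sp] * sum(w * gnext)
      }
    }
    risk + amb + cont
  }
  G <- array(NA_real_, dim = c(horizon, U, S))
  for (tau in seq_len(horizon))
    for (u in seq_len(U))
      for (s in seq_len(S))
        G[tau, u, s] <- g(tau, u, s)
  G
}

# Random categorical POMDP with strictly positive parameters.
random_model <- function(S, U, O = S, identity_A = FALSE) {
  A <- if (identity_A) diag(S) else {
    m <- matrix(stats::runif(O * S) + 0.1, O, S)
    sweep(m, 2L, colSums(m), "/")
  }
  counts <- array(stats::runif(S * S * U) + 0.1, dim = c(S, S, U))
  C <- stats::runif(O) + 0.1; C <- C / sum(C)
  D <- stats::runif(S) + 0.1; D <- D / sum(D)
  generative_model(A = A, b_counts = counts, C = C, D = D)
}

# Exact free energy of factorized beliefs by enumeration over all state
# sequences (exponential; only for tiny models).
oracle_vfe <- function(beliefs, observations, actions, model) {
  S <- model$n_states
  t_len <- ncol(beliefs)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(S)), t_len)))
  lfloor <- function(x) log(pmax(x, 1e-16))
  total <- 0
  for (i in seq_len(nrow(seqs))) {
    path <- seqs[i, ]
    q <- prod(beliefs[cbind(path, seq_len(t_len))])
    if (q == 0) next
    lq <- sum(lfloor(beliefs[cbind(path, seq_len(t_len))]))
    lo <- sum(lfloor(model$A[cbind(observations, path)]))
    lp <- lfloor(model$D[path[1L]])
    if (t_len > 1L)
      for (tau in 2:t_len)
        lp <- lp + lfloor(model$B[path[tau], path[tau - 1L],
                                  actions[tau - 1L]])
    total <- total + q * (lq - lo - lp)
  }
  total
}

# Breadth-first-search distances from the goal to every free cell, for
# checking that planner-greedy actions lie on shortest paths.
oracle_distances_to_goal <- function(world) {
  S <- world$n_states
  dist <- rep(NA_integer_, S)
  dist[world$goal] <- 0L
  queue <- c(world$goal)
  while (length(queue)) {
    s <- queue[[1L]]; queue <- queue[-1L]
    for (u in 1:4) {
      # predecessors: cells whose successor under u is s
      preds <- which(world$succ[, u] == s)
      for (p in preds) {
        if (p != s && is.na(dist[p])) {
          dist[p] <- dist[s] + 1L
          queue <- c(queue, p)
        }
      }
    }
  }
  dist
}
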