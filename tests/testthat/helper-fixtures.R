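# Small fixtures built in code; all tests seed explicitly where they draw.

# 3-agent open line with chosen labels/strategies
line3_state <- function(labels, strategies) {
  sim_state(build_line(3), labels = labels, strategies = strategies)
}

# uniform-random state on a small torus
random_torus_state <- function(width = 6, height = 6, p_green = 0.5, seed = 1) {
  g <- build_torus(width, height)
  set.seed(seed)
  sim_state(g, labels = as.integer(runif(g$n) < p_green),
            strategies = sample(1:4, g$n, replace = TRUE))
}

# exact single-event transition matrix over all 4^n strategy states of a
# small graph, built directly from the update rule definition (uniform focal
# agent, mutation uniform over all four strategies, imitation with
# probability proportional to exp(w * payoff)). Used as an independent
# oracle for the simulator: it shares no code with the C++ event loop.
exact_transition_matrix <- function(graph, labels, params) {
  n <- graph$n
  n_states <- 4L^n
  idx_of <- function(s) sum((s - 1L) * 4L^(0:(n - 1L))) + 1L
  state_of <- function(k) ((k - 1L) %/% 4L^(0:(n - 1L))) %% 4L + 1L
  act <- function(s, lab) (s == 1L) | (s == 2L & lab == 1L) | (s == 3L & lab == 0L)
  pay <- function(s, i) {
    nb <- graph$adj[[i]]
    sum(params$b * act(s[nb], labels[i]) - act(s[i], labels[nb]))
  }
  P <- matrix(0, n_states, n_states)
  for (k in seq_len(n_states)) {
    s <- state_of(k)
    for (i in seq_len(n)) {
      pf <- 1 / n
      # mutation branch
      for (snew in 1:4) {
        s2 <- s; s2[i] <- snew
        P[k, idx_of(s2)] <- P[k, idx_of(s2)] + pf * params$mu / 4
      }
      # imitation branch
      nb <- graph$adj[[i]]
      pv <- vapply(nb, function(j) pay(s, j), numeric(1))
      wts <- exp(params$w * (pv - max(pv)))
      wts <- wts / sum(wts)
      for (m in seq_along(nb)) {
        s2 <- s; s2[i] <- s[nb[m]]
        P[k, idx_of(s2)] <- P[k, idx_of(s2)] + pf * (1 - params$mu) * wts[m]
      }
    }
  }
  P
}

# stationary distribution of a stochastic matrix by power iteration
stationary_dist <- function(P, tol = 1e-12, max_iter = 20000) {
  v <- rep(1 / nrow(P), nrow(P))
  for (it in seq_len(max_iter)) {
    v2 <- as.vector(v %*% P)
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}
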