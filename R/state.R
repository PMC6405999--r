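#' Simulation state
#'
#' The only mutable object of the dynamics: a population graph together with
#' the per-agent labels (immutable), per-agent strategies, and the event
#' counter `t`. Following the usual R idiom, randomness is drawn from R's
#' global RNG stream; pass `seed` here (or call `set.seed()` yourself) to
#' make a run reproducible. Every stochastic operation consumes draws in a
#' fixed documented order (see [step_event()]), so equal seeds give
#' bit-identical trajectories.
#'
#' @param graph a `population_graph`.
#' @param labels integer (0/1) or character (`"B"`/`"G"`) label vector, one
#'   per agent. Labels never change during a simulation.
#' @param strategies integer strategy codes `1:4`, one per agent, or a single
#'   code recycled to all agents. Defaults to all-defectors, the
#'   initialisation of the scan protocol.
#' @param seed optional integer seed, forwarded to `set.seed()`.
#' @return An object of class `sim_state`.
#' @examples
#' g <- build_ring(8)
#' st <- sim_state(g, labels = rep(0, 8), strategies = 4, seed = 1)
#' @export
sim_state <- function(graph, labels, strategies = 4L, seed = NULL) {
  stopifnot(inherits(graph, "population_graph"))
  labels <- .as_label_codes(labels)
  if (length(labels) != graph$n) stop("need one label per agent")
  strategies <- as.integer(strategies)
  if (length(strategies) == 1L) strategies <- rep(strategies, graph$n)
  if (length(strategies) != graph$n) stop("need one strategy per agent")
  if (any(strategies < 1L | strategies > 4L)) stop("strategy codes must be in 1:4")
  if (!is.null(seed)) set.seed(seed)
  structure(list(graph = graph, labels = labels, strategies = strategies,
                 t = 0), class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  shares <- strategy_shares(x)
  cat(sprintf("sim_state: %d agents on a %s, t = %g events\n",
              x$graph$n, x$graph$topology, x$t))
  cat("  labels: ", sum(x$labels == 1L), " green / ", sum(x$labels == 0L),
      " blue\n", sep = "")
  cat("  strategy shares:",
      paste(sprintf("%s %.3f", names(shares), shares), collapse = ", "), "\n")
  invisible(x)
}

#' Donation-game payoff of one agent
#'
#' The payoff is recomputed from the current configuration (it never
#' accumulates over time): the sum over neighbours `j` of
#' `b * S_j(lambda_i) - S_i(lambda_j)`, i.e. donations received, scaled by
#' the benefit `b`, minus donations given. An isolated agent (possible only
#' in random graphs) has payoff 0.
#'
#' @param state a `sim_state`.
#' @param i agent index (1-based).
#' @param b cooperation benefit.
#' @return A single numeric payoff.
#' @examples
#' g <- build_ring(4)
#' st <- sim_state(g, labels = c(0, 0, 0, 0), strategies = 1)
#' payoff(st, 1, b = 5)  # 2 * (5 - 1)
#' @export
payoff <- function(state, i, b) {
  stopifnot(inherits(state, "sim_state"))
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > state$graph$n) stop("invalid agent index")
  stopifnot(is.numeric(b), length(b) == 1L, b > 1)
  nb <- state$graph$adj[[i]]
  if (length(nb) == 0L) return(0)
  sum(b * strategy_action(state$strategies[nb], state$labels[i]) -
        strategy_action(state$strategies[i], state$labels[nb]))
}

#' Payoffs of all agents at once
#'
#' @param state a `sim_state`.
#' @param b cooperation benefit.
#' @return Numeric vector of per-agent payoffs.
#' @export
payoffs <- function(state, b) {
  stopifnot(inherits(state, "sim_state"), is.numeric(b), length(b) == 1L, b > 1)
  payoffs_cpp(state$graph$ptr, state$graph$idx, state$labels,
              state$strategies, b)
}

#' Exponential fitness
#'
#' `fitness(p, w) = exp(w * p)`, strictly positive for all finite arguments,
#' which is what lets the model reach the deterministic high-`w` limit.
#' Raw exponentials can overflow at large `w * p`; all selection
#' probabilities inside the package are therefore computed from payoff
#' differences (`exp(w * (p - max(p)))`), which this function does not do —
#' it is the definition, not the numerically safe path.
#'
#' @param p payoff value(s).
#' @param w selection pressure, `>= 0`.
#' @return `exp(w * p)`, vectorised over `p`.
#' @export
fitness <- function(p, w) {
  stopifnot(is.numeric(p), is.numeric(w), length(w) == 1L, w >= 0)
  exp(w * p)
}

#' Imitation-target distribution over neighbours
#'
#' Probability that agent `i`, on an imitation event, copies each of its
#' neighbours: proportional to the neighbour's fitness `exp(w * p_j)`.
#' Computed shift-invariantly as a softmax of `w * (p_j - max_k p_k)`, so
#' adding any constant to all payoffs leaves the distribution unchanged. At
#' `w = Inf` the distribution is uniform over the maximal-payoff neighbours.
#'
#' @param state a `sim_state`.
#' @param i focal agent index.
#' @param params a [model_params()] object.
#' @return Named numeric vector of probabilities over the neighbours of `i`
#'   (names are the neighbour indices); sums to 1.
#' @export
imitation_probs <- function(state, i, params) {
  stopifnot(inherits(state, "sim_state"), inherits(params, "model_params"))
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > state$graph$n) stop("invalid agent index")
  nb <- state$graph$adj[[i]]
  if (length(nb) == 0L) stop("agent ", i, " has no neighbours; imitation undefined")
  p <- vapply(nb, function(j) payoff(state, j, params$b), numeric(1))
  wts <- .selection_weights(p, params$w)
  setNames(wts / sum(wts), nb)
}

# numerically safe softmax weights; w = Inf -> indicator of the argmax set
.selection_weights <- function(p, w) {
  if (is.infinite(w)) {
    as.numeric(p == max(p))
  } else {
    exp(w * (p - max(p)))
  }
}

#' Draw an imitation target
#'
#' Samples one neighbour of `i` from the distribution of
#' [imitation_probs()]; the focal agent itself is never returned. Consumes
#' exactly one uniform draw from the RNG stream.
#'
#' @inheritParams imitation_probs
#' @return A single neighbour index.
#' @export
choose_imitation_target <- function(state, i, params) {
  pr <- imitation_probs(state, i, params)
  nb <- as.integer(names(pr))
  nb[.pick_cumulative(pr, runif(1))]
}

# first index whose cumulative weight reaches u * total; mirrors the C++ loop
.pick_cumulative <- function(wts, u) {
  cum <- cumsum(wts)
  which(cum >= u * cum[length(cum)])[1L]
}

#' Advance the state by one update event
#'
#' One event: (draw 1) a focal agent is chosen uniformly among `active`
#' agents; (draw 2) a mutation coin with probability `mu`; (draw 3) on
#' mutation, a strategy uniform over all four codes (the current one
#' included), otherwise a neighbour drawn fitness-proportionally, whose
#' strategy the focal agent copies. Copying a neighbour with the same
#' strategy is a legal no-op event. Labels never change; `t` increases by 1.
#' The three draws are consumed in exactly this order, which is what makes
#' the R and C++ paths bit-identical under equal seeds.
#'
#' @param state a `sim_state`.
#' @param params a [model_params()] object.
#' @param active integer vector of agents eligible as focal (defaults to
#'   all); used by the boundary analysis to pin the strategies of the two
#'   end agents of a line.
#' @return The advanced `sim_state`.
#' @export
step_event <- function(state, params, active = seq_len(state$graph$n)) {
  stopifnot(inherits(state, "sim_state"), inherits(params, "model_params"))
  n_act <- length(active)
  u1 <- runif(1)
  f <- active[min(floor(u1 * n_act) + 1, n_act)]
  u2 <- runif(1)
  if (u2 < params$mu) {
    u3 <- runif(1)
    state$strategies[f] <- as.integer(min(floor(u3 * 4) + 1, 4))
  } else {
    nb <- state$graph$adj[[f]]
    if (length(nb) == 0L) stop("agent ", f, " has no neighbours; imitation undefined")
    p <- vapply(nb, function(j) payoff(state, j, params$b), numeric(1))
    wts <- .selection_weights(p, params$w)
    u3 <- runif(1)
    state$strategies[f] <- state$strategies[nb[.pick_cumulative(wts, u3)]]
  }
  state$t <- state$t + 1
  state
}

#' Run many events with periodic observable sampling
#'
#' Fast C++ path for long runs; event semantics and RNG draw order are
#' identical to repeated [step_event()] calls, so the two paths produce the
#' same trajectory from the same seed.
#'
#' @param state a `sim_state`.
#' @param params a [model_params()] object.
#' @param n_events number of update events to run.
#' @param sample_at increasing event counts (relative to the current `t`) at
#'   which to record observables; may be empty.
#' @param active integer vector of agents eligible as focal (default all).
#' @return The advanced `sim_state`, with a data frame of samples attached as
#'   `attr(, "samples")` (columns `t`, `payoff_norm`, `coop_all`,
#'   `coop_green`, `coop_blue`, `defect_all`).
#' @export
run_events <- function(state, params, n_events, sample_at = numeric(0),
                       active = seq_len(state$graph$n)) {
  stopifnot(inherits(state, "sim_state"), inherits(params, "model_params"),
            is.numeric(n_events), length(n_events) == 1L, n_events >= 0)
  sample_at <- as.numeric(sample_at)
  if (is.unsorted(sample_at, strictly = TRUE)) stop("sample_at must be strictly increasing")
  if (length(sample_at) && (sample_at[1] < 1 || sample_at[length(sample_at)] > n_events)) {
    stop("sample_at must lie in [1, n_events]")
  }
  res <- run_events_cpp(state$graph$ptr, state$graph$idx, state$labels,
                        state$strategies, as.integer(active) - 1L,
                        params$b, params$w, params$mu,
                        as.numeric(n_events), sample_at)
  state$strategies <- res$strategies
  state$t <- state$t + n_events
  counts <- res$sample_counts
  samples <- data.frame(t = state$t - n_events + res$sample_t,
                        payoff_norm = res$sample_payoff_norm)
  if (nrow(samples)) {
    sh <- counts / state$graph$n
    colnames(sh) <- names(strategy_codes())
    samples <- cbind(samples, as.data.frame(sh))
  }
  attr(state, "samples") <- samples
  state
}
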