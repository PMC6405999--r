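#' One-dimensional domain-boundary analysis
#'
#' On a line with the leftmost agent pinned to cooperate-with-all and the
#' rightmost pinned to cooperate-with-blue (mutation off), every state the
#' dynamics can reach is two single-strategy domains separated by one
#' boundary, and the whole system reduces to the integer position of that
#' boundary: a birth--death chain. `stepping_probabilities()` derives the
#' per-position move probabilities of that chain directly from the update
#' rule; `boundary_chain()` assembles the full chain with its
#' detailed-balance stationary weights; [stationary_ratio()],
#' [closed_form_ratio()], [transition_line()] and [monte_carlo_boundary()]
#' build on it.
#'
#' Boundary position `k` (for `k` in `1:(n - 1)`) means agents `1:k` hold
#' cooperate-with-all and agents `(k + 1):n` hold cooperate-with-blue. An
#' update event moves the boundary iff the uniformly chosen focal agent is
#' one of the two agents flanking the boundary and it copies, fitness
#' proportionally, its neighbour across the boundary; all other events leave
#' the boundary in place. Where every label in reach is blue the two
#' strategies act identically, payoffs match, and the walk is exactly
#' unbiased; the bias is confined to within three positions of a green
#' label.
#'
#' @param labels 1D label field (integer 0/1 or characters), length `>= 5`.
#' @param position boundary position, in `1:(length(labels) - 1)`.
#' @param b cooperation benefit.
#' @param w selection pressure (finite, `>= 0`).
#' @return `stepping_probabilities()`: named vector `(p_left, p_right,
#'   p_stay)` summing to 1. Moves off the line through the pinned end agents
#'   are impossible, so `p_left = 0` at position 1 and `p_right = 0` at
#'   position `n - 1`.
#' @examples
#' labs <- assign_labels_line(15, "single_minority")
#' stepping_probabilities(labs, 4, b = 5, w = 0.3)
#' @export
stepping_probabilities <- function(labels, position, b, w) {
  labels <- .as_label_codes(labels)
  n <- length(labels)
  if (n < 5L) stop("line too short for a boundary chain")
  k <- as.integer(position)
  if (is.na(k) || k < 1L || k > n - 1L) {
    stop("boundary position must be in 1:(n-1)")
  }
  .check_bw(b, w)
  lp <- .log_move_probs(labels, k, b, w, build_line(n))
  c(p_left = exp(lp[["left"]]), p_right = exp(lp[["right"]]),
    p_stay = 1 - exp(lp[["left"]]) - exp(lp[["right"]]))
}

.check_bw <- function(b, w) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b), b > 1,
            is.numeric(w), length(w) == 1L, is.finite(w), w >= 0)
}

# strategies of the two-domain line configuration with boundary at k
.boundary_config <- function(n, k) {
  c(rep(.S_COOP_ALL, k), rep(.S_COOP_BLUE, n - k))
}

# log move probabilities of the boundary at position k, computed from the
# update rule on the explicit configuration; returns -Inf where the move is
# blocked by a pinned end. log P(copy across) = -log(1 + exp(w * dp)) with a
# large-argument branch so very strong selection stays finite in log space.
.log_move_probs <- function(labels, k, b, w, graph) {
  n <- length(labels)
  n_act <- n - 2L
  st <- sim_state(graph, labels, strategies = .boundary_config(n, k))
  lse <- function(dp) {        # log(1 / (1 + exp(w * dp)))
    x <- w * dp
    if (x > 35) -x - log1p(exp(-x)) else -log1p(exp(x))
  }
  left <- if (k == 1L) -Inf else {
    # focal agent k copies agent k+1 (across) rather than k-1
    -log(n_act) + lse(payoff(st, k - 1L, b) - payoff(st, k + 1L, b))
  }
  right <- if (k == n - 1L) -Inf else {
    # focal agent k+1 copies agent k (across) rather than k+2
    -log(n_act) + lse(payoff(st, k + 2L, b) - payoff(st, k, b))
  }
  c(left = left, right = right)
}

#' Build the boundary birth--death chain
#'
#' Computes the move probabilities at every boundary position of a pinned
#' line and the stationary weights by detailed balance,
#' `pi(k+1) / pi(k) = p_right(k) / p_left(k+1)`, accumulated in log space so
#' strong selection cannot under- or overflow. The chain ends are
#' reflecting: the pinned end agents are never chosen as focal, so the
#' boundary cannot leave `1:(n - 1)`.
#'
#' @inheritParams stepping_probabilities
#' @return An object of class `boundary_chain`: list with `labels`, `b`,
#'   `w`, `positions`, `move_probs` (matrix with columns `p_left`,
#'   `p_right`, `p_stay`) and `log_weights` (unnormalised stationary log
#'   weights).
#' @examples
#' ch <- boundary_chain(assign_labels_line(21, "single_minority"), b = 5, w = 0.3)
#' stationary_ratio(ch)
#' @export
boundary_chain <- function(labels, b, w) {
  labels <- .as_label_codes(labels)
  n <- length(labels)
  if (n < 5L) stop("line too short for a boundary chain")
  .check_bw(b, w)
  graph <- build_line(n)
  pos <- seq_len(n - 1L)
  lp <- t(vapply(pos, function(k) .log_move_probs(labels, k, b, w, graph),
                 numeric(2)))
  # interior moves must be possible, otherwise parts of the chain are
  # unreachable and no stationary distribution exists on all of it
  bad <- which(!is.finite(lp[, "left"]) & pos != 1L |
                 !is.finite(lp[, "right"]) & pos != n - 1L)
  if (length(bad)) {
    stop("zero step probability at interior position(s) ",
         paste(bad, collapse = ", "))
  }
  lw <- numeric(n - 1L)
  for (k in seq_len(n - 2L)) {
    lw[k + 1L] <- lw[k] + lp[k, "right"] - lp[k + 1L, "left"]
  }
  move <- cbind(p_left = exp(lp[, "left"]), p_right = exp(lp[, "right"]))
  move <- cbind(move, p_stay = 1 - move[, "p_left"] - move[, "p_right"])
  structure(list(labels = labels, b = b, w = w, positions = pos,
                 move_probs = move, log_weights = lw),
            class = "boundary_chain")
}

#' @export
print.boundary_chain <- function(x, ...) {
  cat(sprintf("boundary chain: %d positions, b = %g, w = %g, %d green label(s)\n",
              length(x$positions), x$b, x$w, sum(x$labels == 1L)))
  biased <- which(abs(x$move_probs[, "p_left"] - x$move_probs[, "p_right"]) >
                    1e-14)
  biased <- setdiff(biased, c(1L, length(x$positions)))
  cat("  biased interior positions:",
      if (length(biased)) paste(biased, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Stationary odds of discrimination vs full cooperation
#'
#' For a single-green line, the stationary probability of finding the
#' boundary on the side where the asymmetric strategy covers the green agent
#' (discrimination dominates) divided by the probability of the other side
#' (full cooperation dominates). With the green agent at index `g`, the
#' boundary at `k <= g - 1` leaves the green agent inside the
#' cooperate-with-blue domain, so those positions count as
#' discrimination-dominant; `k >= g` (the green agent holds full
#' cooperation) counts as cooperation-dominant.
#'
#' `method = "mass"` aggregates the exact stationary weights of the finite
#' chain, reflecting ends included. `method = "plateau"` returns the
#' far-field weight ratio of the two unbiased plateaus flanking the green
#' agent — the infinite-line limit with equal side lengths, which is the
#' quantity the closed form [closed_form_ratio()] describes; it requires the
#' green agent to sit at least 5 positions from either end.
#'
#' @param chain a [boundary_chain()].
#' @param method `"mass"` or `"plateau"`.
#' @return A positive odds ratio.
#' @export
stationary_ratio <- function(chain, method = c("mass", "plateau")) {
  stopifnot(inherits(chain, "boundary_chain"))
  method <- match.arg(method)
  g <- which(chain$labels == .L_GREEN)
  if (length(g) != 1L) {
    stop("stationary_ratio needs a line with exactly one green label")
  }
  n <- length(chain$labels)
  lw <- chain$log_weights
  if (method == "mass") {
    disc <- lw[chain$positions <= g - 1L]
    coop <- lw[chain$positions >= g]
    if (!length(disc) || !length(coop)) stop("green agent too close to an end")
    return(exp(.logsumexp(disc) - .logsumexp(coop)))
  }
  if (g < 6L || g > n - 5L) {
    stop("plateau ratio needs the green agent >= 5 positions from both ends")
  }
  # plateaus: weights are constant outside the biased window around g and
  # away from the reflecting ends
  exp(lw[g - 4L] - lw[g + 2L])
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Closed-form stationary odds for the single-green line
#'
#' The infinite-line limit of [stationary_ratio()] on a line that is blue
#' except for one green agent: `exp(2 * w) / (tanh(w * b) + 1)`. Equal to 1
#' at `w = 0`; for `b >> 1` it reduces to `exp(2 * w) / 2`, which crosses 1
#' at `w = log(2) / 2`, the critical selection pressure above which
#' discrimination outcompetes full cooperation no matter how large the
#' benefit.
#'
#' @param w selection pressure, `>= 0`.
#' @param b cooperation benefit, `> 1`.
#' @return The odds ratio, vectorised over `w` and `b`.
#' @examples
#' closed_form_ratio(0.1, 5)
#' @export
closed_form_ratio <- function(w, b) {
  stopifnot(is.numeric(w), all(w >= 0), is.numeric(b), all(b > 1))
  exp(2 * w) / (tanh(w * b) + 1)
}

#' Critical benefit for a repeated label pattern
#'
#' For a line labelled by tiling `pattern`, the relative stationary weight
#' of the boundary at two bulk positions one period apart is a function of
#' `b` at fixed `w`; the transition sits where it equals 1. This solves for
#' that `b*` by bisection on `log` of the period weight ratio over
#' `b` in `bracket`, to an absolute tolerance of `1e-6`. When the ratio
#' never crosses 1 on the bracket (e.g. an all-blue "pattern", for which the
#' two strategies are indistinguishable and the walk globally unbiased), the
#' sentinel `NA` is returned with attribute `reason = "no_crossing"` and the
#' bracket endpoint values attached — distinguished from a numerical
#' failure, which errors.
#'
#' @param pattern label pattern (length 1 to 6) as integer 0/1 codes or
#'   characters `"G"`/`"B"`.
#' @param w selection pressure, `> 0`.
#' @param bracket search interval for `b`.
#' @param n_periods number of pattern repetitions on the working line (the
#'   period ratio is read in the middle of the line, far from the pinned
#'   ends).
#' @return The critical benefit `b*`, or `NA` with attributes when there is
#'   no crossing.
#' @examples
#' transition_line(c("G", "B"), w = 0.5)  # exactly 2
#' @export
transition_line <- function(pattern, w, bracket = c(1 + 1e-6, 64),
                            n_periods = NULL) {
  pat <- .as_label_codes(pattern)
  len <- length(pat)
  if (len < 1L || len > 6L) stop("pattern length must be 1 to 6")
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w), w > 0,
            length(bracket) == 2L, bracket[1] > 1, bracket[2] > bracket[1])
  if (is.null(n_periods)) n_periods <- max(ceiling(48 / len), 10L)
  labels <- rep_len(pat, len * n_periods)
  n <- length(labels)
  graph <- build_line(n)
  k0 <- len * (n_periods %/% 2L)   # bulk position aligned with the pattern
  f <- function(b) {               # log( pi(k0 + len) / pi(k0) )
    acc <- 0
    for (k in k0:(k0 + len - 1L)) {
      acc <- acc + .log_move_probs(labels, k, b, w, graph)[["right"]] -
        .log_move_probs(labels, k + 1L, b, w, graph)[["left"]]
    }
    acc
  }
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (!is.finite(flo) || !is.finite(fhi)) stop("period ratio not finite on the bracket")
  if (sign(flo) == sign(fhi)) {
    if (max(abs(flo), abs(fhi)) < 1e-12) {
      # flat ratio: the two strategies behave identically on this pattern
      out <- NA_real_
      attr(out, "reason") <- "no_crossing"
      attr(out, "bracket") <- c(b = bracket, log_ratio = c(flo, fhi))
      return(out)
    }
    out <- NA_real_
    attr(out, "reason") <- "no_crossing"
    attr(out, "bracket") <- c(b = bracket, log_ratio = c(flo, fhi))
    return(out)
  }
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Monte-Carlo oracle for the boundary occupancy ratio
#'
#' Simulates the full one-dimensional imitation dynamics (mutation must be
#' off) with the two end agents pinned — leftmost cooperate-with-all,
#' rightmost cooperate-with-blue, both excluded from focal selection — and
#' tallies on which side of the green agent the domain boundary sits at each
#' thinned sample. This is a direct, update-rule-level check of
#' [stationary_ratio()]: it shares no code path with the detailed-balance
#' computation beyond the payoff definition. Samples where the state is not
#' two clean domains are excluded from the tally and counted separately
#' (with mutation off such states cannot arise).
#'
#' @param labels 1D label field with exactly one green agent.
#' @param params a [model_params()] with `mu = 0`.
#' @param n_events total update events.
#' @param seed optional integer seed.
#' @param sample_every thinning interval in events between occupancy reads.
#' @param n_batches number of consecutive batches used for the batch-means
#'   standard error (thinned samples along one trajectory are correlated, so
#'   a binomial SE on raw counts would be optimistic).
#' @return An object of class `boundary_mc`: list with `ratio` (odds
#'   discrimination/cooperation side), `se` (delta-method batch-means SE of
#'   the ratio), `q` (discrimination-side occupancy), `se_q`, `n_samples`,
#'   `n_invalid`.
#' @export
monte_carlo_boundary <- function(labels, params, n_events = 1e6, seed = NULL,
                                 sample_every = 250, n_batches = 20) {
  labels <- .as_label_codes(labels)
  n <- length(labels)
  if (n < 7L) stop("line too short")
  stopifnot(inherits(params, "model_params"))
  if (params$mu != 0) stop("the boundary oracle requires mu = 0")
  g <- which(labels == .L_GREEN)
  if (length(g) != 1L) stop("need exactly one green label")
  graph <- build_line(n)
  st <- sim_state(graph, labels, strategies = .boundary_config(n, g),
                  seed = seed)
  active <- 2:(n - 1L)
  n_chunks <- floor(n_events / sample_every)
  if (n_chunks < n_batches) stop("too few samples for the requested batches")
  side <- integer(n_chunks)   # 1 disc side, 0 coop side, NA invalid
  for (ch in seq_len(n_chunks)) {
    st <- run_events(st, params, sample_every, active = active)
    s <- st$strategies
    k <- sum(s == .S_COOP_ALL)
    ok <- all(s[seq_len(k)] == .S_COOP_ALL) &&
      all(s[(k + 1L):n] == .S_COOP_BLUE)
    side[ch] <- if (!ok) NA_integer_ else as.integer(k <= g - 1L)
  }
  valid <- side[!is.na(side)]
  q <- mean(valid)
  batches <- split(valid, cut(seq_along(valid), n_batches, labels = FALSE))
  bm <- vapply(batches, mean, numeric(1))
  se_q <- sd(bm) / sqrt(length(bm))
  ratio <- q / (1 - q)
  se <- se_q / (1 - q)^2
  structure(list(ratio = ratio, se = se, q = q, se_q = se_q,
                 n_samples = length(valid), n_invalid = sum(is.na(side)),
                 n_events = n_chunks * sample_every, params = params),
            class = "boundary_mc")
}

#' @export
print.boundary_mc <- function(x, ...) {
  cat(sprintf(paste0("boundary MC oracle: ratio %.4f +/- %.4f ",
                     "(%d samples over %g events, %d invalid)\n"),
              x$ratio, x$se, x$n_samples, x$n_events, x$n_invalid))
  invisible(x)
}
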