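test_that("strategy action rules cover all four strategies", {
  lc <- label_codes(); sc <- strategy_codes()
  expect_equal(strategy_action(sc[["coop_all"]], lc), c(blue = 1L, green = 1L),
               ignore_attr = TRUE)
  expect_equal(strategy_action(sc[["defect_all"]], lc), c(0L, 0L),
               ignore_attr = TRUE)
  expect_equal(strategy_action(sc[["coop_green"]], lc), c(0L, 1L),
               ignore_attr = TRUE)
  expect_equal(strategy_action(sc[["coop_blue"]], lc), c(1L, 0L),
               ignore_attr = TRUE)
  expect_error(strategy_action(5L, 0L), "1:4")
  expect_error(strategy_action(1L, 2L), "0.*1")
})

test_that("payoff matches hand-enumerated donation sums", {
  # all defectors: nobody donates
  st <- random_torus_state(4, 4)
  st$strategies <- rep(4L, 16)
  expect_true(all(payoffs(st, b = 5) == 0))
  # all cooperators on a degree-4 torus: 4 * (b - 1) each
  st$strategies <- rep(1L, 16)
  expect_true(all(payoffs(st, b = 5) == 16))
  # 3-agent line: (blue coop_all) - (green coop_blue) - (blue defect), b = 3
  st3 <- line3_state(labels = c("B", "G", "B"), strategies = c(1L, 3L, 4L))
  expect_equal(payoff(st3, 2, b = 3), 1)   # receives 3 from left, gives 2
  expect_equal(payoff(st3, 1, b = 3), 2)   # receives b from mid, gives 1
  expect_equal(payoff(st3, 3, b = 3), 3)   # mid cooperates with blue; gives 0
  expect_error(payoff(st3, 4, b = 3), "invalid agent")
  # vectorised payoffs agree with the scalar definition everywhere
  st <- random_torus_state(5, 5, seed = 8)
  expect_equal(payoffs(st, b = 2.7),
               vapply(1:25, function(i) payoff(st, i, 2.7), numeric(1)))
})

test_that("payoff conservation: total payoff = (b - 1) x donations", {
  for (seed in 1:5) {
    st <- random_torus_state(6, 6, seed = seed)
    b <- 1 + seed
    d <- normalized_mean_payoff(st) * st$graph$ptr[st$graph$n + 1L]
    expect_equal(sum(payoffs(st, b)), (b - 1) * d)
  }
})

test_that("fitness is exp(w p), positive, and 1 at w = 0 or p = 0", {
  expect_equal(fitness(2, 0.5), exp(1))
  expect_equal(fitness(c(-3, 0, 7), 0), rep(1, 3))
  expect_equal(fitness(0, 123), 1)
  expect_true(all(fitness(c(-700, 700), 1) > 0))
})

test_that("imitation distribution is a softmax, shift-invariant, never self", {
  st3 <- line3_state(labels = c("B", "B", "G"), strategies = c(1L, 3L, 4L))
  # payoffs with b = 3: agent1 = 2, agent3 = 0; focal agent 2
  pr <- imitation_probs(st3, 2, model_params(b = 3, w = 1))
  expect_equal(names(pr), c("1", "3"))
  expect_equal(unname(pr[1]), exp(2) / (exp(2) + 1), tolerance = 1e-12)
  # shift invariance: softmax of payoffs equals softmax of payoffs + c
  p <- c(2, 0)
  for (shift in c(-50, 0, 300)) {
    ref <- exp(1 * (p + shift - max(p + shift)))
    expect_equal(unname(pr), ref / sum(ref), tolerance = 1e-12)
  }
  # w = Inf picks the unique maximal neighbour almost surely
  pr_inf <- imitation_probs(st3, 2, model_params(b = 3, w = Inf))
  expect_equal(unname(pr_inf), c(1, 0))
  set.seed(4)
  picks <- replicate(50, choose_imitation_target(st3, 2, model_params(3, Inf)))
  expect_true(all(picks == 1L))
  expect_false(any(picks == 2L))  # never the focal agent
})

test_that("neighbour choice frequencies match the softmax law", {
  # two neighbours with payoffs 2 and 0 at w = 1: P = e^2/(e^2+1) = 0.8808
  st3 <- line3_state(labels = c("B", "B", "G"), strategies = c(1L, 3L, 4L))
  params <- model_params(b = 3, w = 1)
  set.seed(42)
  picks <- replicate(1e5, choose_imitation_target(st3, 2, params))
  phat <- mean(picks == 1L)
  ptrue <- exp(2) / (exp(2) + 1)
  expect_lt(abs(phat - ptrue), 4 * sqrt(ptrue * (1 - ptrue) / 1e5))
})

test_that("at w = 0 neighbours are chosen uniformly (voter limit)", {
  st <- random_torus_state(5, 5, seed = 3)
  params <- model_params(b = 4, w = 0)
  set.seed(9)
  picks <- replicate(2e4, choose_imitation_target(st, 13, params))
  tab <- table(factor(picks, levels = st$graph$adj[[13]]))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("step semantics: mutation-only mixing and absorbing consensus", {
  g <- build_ring(10)
  # mu = 1: pure uniform resampling, shares -> 1/4 each
  st <- sim_state(g, labels = rep(0L, 10), strategies = 4L, seed = 1)
  st <- run_events(st, model_params(2, 5, mu = 1), 4e4)
  expect_true(all(abs(strategy_shares(st) - 0.25) < 0.1))
  expect_equal(st$t, 4e4)
  # mu = 0 with a single strategy present: absorbing forever
  st <- sim_state(g, labels = rep(0L, 10), strategies = 2L, seed = 2)
  st <- run_events(st, model_params(8, 1, mu = 0), 1e4)
  expect_true(all(st$strategies == 2L))
  # labels are never touched by the dynamics
  st <- random_torus_state(4, 4, seed = 6)
  labs0 <- st$labels
  st <- run_events(st, model_params(3, 2, 0.05), 5e3)
  expect_identical(st$labels, labs0)
})

test_that("R step_event and C++ run_events give identical trajectories", {
  g <- build_torus(5, 5)
  set.seed(21)
  labs <- as.integer(runif(25) < 0.5)
  strat0 <- sample(1:4, 25, replace = TRUE)
  for (params in list(model_params(4, 0.8, 0.01), model_params(3, 0, 0.1),
                      model_params(5, Inf, 0.005))) {
    set.seed(7)
    a <- sim_state(g, labs, strat0)
    for (i in 1:2000) a <- step_event(a, params)
    set.seed(7)
    b <- sim_state(g, labs, strat0)
    b <- run_events(b, params, 2000)
    expect_identical(a$strategies, b$strategies)
  }
})

test_that("label-swap symmetry: relabelling commutes with the dynamics", {
  # swapping green<->blue labels and coop_green<->coop_blue strategies is an
  # exact symmetry of the update rule; with mu = 0 the decision draws align
  # and trajectories must map onto each other event by event
  g <- build_torus(6, 6)
  set.seed(31)
  labs <- as.integer(runif(36) < 0.4)
  strat0 <- sample(1:4, 36, replace = TRUE)
  swap_strat <- function(s) c(1L, 3L, 2L, 4L)[s]
  params <- model_params(b = 4, w = 1.5, mu = 0)
  set.seed(11)
  a <- sim_state(g, labs, strat0)
  a <- run_events(a, params, 5000)
  set.seed(11)
  b <- sim_state(g, 1L - labs, swap_strat(strat0))
  b <- run_events(b, params, 5000)
  expect_identical(swap_strat(a$strategies), b$strategies)
})

test_that("strategy counts are a martingale under neutral drift", {
  # w = 0, mu = 0: the update is a 4-opinion voter model, so the expected
  # count of each strategy is conserved
  g <- build_ring(12)
  params <- model_params(b = 2, w = 0, mu = 0)
  init <- rep(1:4, each = 3)
  set.seed(17)
  counts <- replicate(400, {
    st <- sim_state(g, labels = as.integer(runif(12) < 0.5), strategies = init)
    st <- run_events(st, params, 300)
    tabulate(st$strategies, 4L)
  })
  m <- rowMeans(counts)
  se <- apply(counts, 1, sd) / sqrt(ncol(counts))
  expect_true(all(abs(m - 3) < 4 * se + 1e-9))
})

test_that("simulated long-run observables match the exact chain stationary law", {
  # independent oracle: enumerate all 4^5 strategy states of a 5-ring, build
  # the one-event transition matrix from the rule definition, power-iterate
  # to the stationary distribution, and compare exact stationary observables
  # with time averages from the C++ simulator
  g <- build_ring(5)
  labels <- c(0L, 1L, 0L, 0L, 1L)
  params <- model_params(b = 2.5, w = 0.7, mu = 0.05)
  P <- exact_transition_matrix(g, labels, params)
  expect_equal(rowSums(P), rep(1, 1024))
  pi_st <- stationary_dist(P)
  state_of <- function(k) ((k - 1L) %/% 4L^(0:4)) %% 4L + 1L
  obs <- vapply(seq_len(1024), function(k) {
    st <- sim_state(g, labels, state_of(k))
    c(pay = normalized_mean_payoff(st), coop = strategy_shares(st)[["coop_all"]])
  }, numeric(2))
  exact_pay <- sum(obs["pay", ] * pi_st)
  exact_coop <- sum(obs["coop", ] * pi_st)
  st <- sim_state(g, labels, strategies = 4L, seed = 5)
  st <- run_events(st, params, 4e5, sample_at = seq(2e4, 4e5, by = 190))
  s <- attr(st, "samples")
  bm <- function(x) {  # batch-means standard error of the mean
    b <- vapply(split(x, cut(seq_along(x), 20, labels = FALSE)), mean, numeric(1))
    sd(b) / sqrt(length(b))
  }
  expect_lt(abs(mean(s$payoff_norm) - exact_pay), 4 * bm(s$payoff_norm))
  expect_lt(abs(mean(s$coop_all) - exact_coop), 4 * bm(s$coop_all))
})
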