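test_that("boundary walk is exactly unbiased away from the green agent", {
  labs <- assign_labels_line(41, "single_minority")   # green at 21
  g <- 21
  for (k in c(5, 10, g - 4, g + 4, 30, 36)) {
    pr <- stepping_probabilities(labs, k, b = 5, w = 0.6)
    expect_identical(pr[["p_left"]], pr[["p_right"]])
  }
  # bias appears only within 3 positions of the green agent
  biased <- vapply((g - 3):(g + 3), function(k) {
    pr <- stepping_probabilities(labs, k, b = 5, w = 0.6)
    abs(pr[["p_left"]] - pr[["p_right"]]) > 1e-12
  }, logical(1))
  expect_true(any(biased))
  # at w = 0 imitation is fitness-blind: unbiased everywhere
  for (k in c(2, g - 1, g, g + 1)) {
    pr <- stepping_probabilities(labs, k, b = 5, w = 0)
    expect_equal(pr[["p_left"]], pr[["p_right"]])
  }
  # probabilities are a distribution and respect the pinned ends
  pr <- stepping_probabilities(labs, 1, b = 5, w = 0.6)
  expect_equal(pr[["p_left"]], 0)
  expect_equal(sum(pr), 1)
  expect_error(stepping_probabilities(labs, 41, b = 5, w = 0.6), "position")
})

test_that("chain stationary ratio reproduces the closed form", {
  labs <- assign_labels_line(41, "single_minority")
  for (w in c(0.1, 0.3, 0.5)) {
    for (b in c(2, 5, 10)) {
      ch <- boundary_chain(labs, b, w)
      expect_equal(stationary_ratio(ch, method = "plateau"),
                   closed_form_ratio(w, b), tolerance = 1e-12)
    }
  }
  # unbiased chain (w = 0): equal sides, ratio exactly 1
  ch0 <- boundary_chain(labs, b = 5, w = 0)
  expect_equal(stationary_ratio(ch0, method = "plateau"), 1)
  expect_equal(stationary_ratio(ch0, method = "mass"), 1, tolerance = 1e-12)
  # move probabilities are valid and weights finite even at strong selection
  ch <- boundary_chain(labs, b = 10, w = 4)
  expect_true(all(abs(rowSums(ch$move_probs) - 1) < 1e-12))
  expect_true(all(is.finite(ch$log_weights)))
})

test_that("closed-form ratio limits match the discrimination condition", {
  expect_equal(closed_form_ratio(0, 5), 1)
  expect_equal(closed_form_ratio(0.1, 5), exp(0.2) / (tanh(0.5) + 1),
               tolerance = 1e-15)
  expect_equal(closed_form_ratio(0.1, 5), 0.83537, tolerance = 1e-4)
  # b >> 1: ratio -> e^{2w}/2, crossing 1 at w = log(2)/2
  wc <- log(2) / 2
  expect_equal(closed_form_ratio(wc, 1e8), 1, tolerance = 1e-6)
  # the ratio is exp((2-b) w) cosh(w b): monotone increasing everywhere at
  # b = 2, and for b > 2 strictly increasing beyond its single minimum at
  # tanh(w b) = (b - 2)/b
  w <- seq(0.001, 2, length.out = 200)
  expect_true(all(diff(closed_form_ratio(w, 2)) > 0))
  for (b in c(5, 20)) {
    w_min <- atanh((b - 2) / b) / b
    rising <- w[w > w_min * 1.01]
    expect_true(all(diff(closed_form_ratio(rising, b)) > 0))
    falling <- w[w < w_min * 0.99]
    expect_true(all(diff(closed_form_ratio(falling, b)) < 0))
  }
})

test_that("critical selection pressure at large b is log(2)/2", {
  root <- uniroot(function(w) closed_form_ratio(w, 64) - 1,
                  c(0.01, 1), tol = 1e-10)$root
  expect_lt(abs(root - log(2) / 2), 1e-3)
})

test_that("transition line: alternating pattern sits at b = 2, flat in w", {
  for (w in c(0.1, 0.5, 1.0)) {
    expect_equal(transition_line(c("G", "B"), w), 2, tolerance = 1e-4)
  }
})

test_that("patterns with no green agent have no transition", {
  out <- transition_line("B", w = 0.5)
  expect_true(is.na(out))
  expect_equal(attr(out, "reason"), "no_crossing")
  expect_true(all(c("b1", "b2") %in% names(attr(out, "bracket"))))
})

test_that("Monte-Carlo oracle agrees with the chain stationary distribution", {
  # the oracle runs the full imitation dynamics; the chain solves detailed
  # balance. Compare the exact finite-chain mass ratio with the empirical
  # occupancy on a grid of (w, b), within 3 batch-means standard errors.
  labs <- assign_labels_line(41, "single_minority")
  for (w in c(0.1, 0.3, 0.5)) {
    for (b in c(2, 5, 10)) {
      ch <- stationary_ratio(boundary_chain(labs, b, w), method = "mass")
      mc <- monte_carlo_boundary(labs, model_params(b, w, mu = 0),
                                 n_events = 1e6, seed = 100 + round(100 * w + b))
      expect_equal(mc$n_invalid, 0)
      expect_lt(abs(mc$ratio - ch) / mc$se, 3)
    }
  }
})

test_that("oracle is unbiased at w = 0", {
  labs <- assign_labels_line(41, "single_minority")
  mc <- monte_carlo_boundary(labs, model_params(5, 0, mu = 0),
                             n_events = 1e6, seed = 3)
  expect_lt(abs(mc$ratio - 1) / mc$se, 3)
  expect_error(monte_carlo_boundary(labs, model_params(5, 0.2, mu = 0.001)),
               "mu = 0")
})
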