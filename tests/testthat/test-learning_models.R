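test_that("global decay regressor matches its closed form", {
  for (b in c(0.015, 0.3, log(2))) {
    g <- global_decay_regressor(5, b)
    expect_equal(g[1], 1)
    expect_equal(g, exp(-b * (0:4)))
    expect_true(all(diff(g) < 0))
  }
  expect_equal(global_decay_regressor(2, log(2))[2], 0.5)
  expect_equal(global_decay_regressor(4, 0), rep(1, 4))  # zero-rate limit
})

test_that("delta-rule predictions start at 0.16667 and update by hand-checkable steps", {
  sq <- toy_sequence(40, 2, seed = 4)
  p <- rl_predictions(sq, alpha = 0.5)
  expect_equal(p[1], 0.16667)
  # alpha -> 0: predictions never move
  expect_equal(rl_predictions(sq, alpha = 0), rep(0.16667, sum(sq$distractor_present)))
  # one delta-rule step by hand: after a distractor at l, that location is at
  # 0.16667 + 0.5 * (1 - 0.16667), all others at 0.5 * 0.16667
  states <- oracle_rl_states(sq, 0.5)
  first <- which(sq$distractor_present == 1)[1]
  l <- sq$distractor_location[first] + 1
  expect_equal(states[first, l], 0.583335)
  expect_equal(states[first, -l], rep(0.083335, 5))
})

test_that("accumulator predictions follow the saturating count transform", {
  sq <- toy_sequence(60, 2, seed = 9)
  # a location that has never hosted a distractor predicts 0
  expect_equal(accumulator_predictions(sq, 1)[1], 0)
  # three occurrences at rate 1 -> 1 - exp(-3)
  loc <- rep(2L, 4)
  mini <- data.frame(block = 1L, trial_in_block = 1:4, trial_global = 1:4,
                     distractor_present = 1L, distractor_location = loc)
  expect_equal(accumulator_predictions(mini, 1)[4], 1 - exp(-3))
  # per-block reset: the first present trial of each block predicts 0
  pr <- accumulator_predictions(sq, 0.7, reset_per_block = TRUE)
  pres_blocks <- sq$block[sq$distractor_present == 1]
  firsts <- !duplicated(pres_blocks)
  expect_true(all(pr[firsts] == 0))
})

test_that("categorical regressor applies the argmax-with-ties rule", {
  # all-zero initial state is a full tie -> 1
  sq <- toy_sequence(30, 1, seed = 2)
  expect_equal(categorical_regressor(sq)[1], 1)
  # counts (l2: 2, l5: 1): distractor at l2 -> 1, at l5 -> 0, then at a tied
  # pair either member -> 1
  mini <- data.frame(block = 1L, trial_in_block = 1:6, trial_global = 1:6,
                     distractor_present = 1L,
                     distractor_location = c(2L, 2L, 5L, 2L, 5L, 5L))
  # states before trials 4/5: counts l2 = 2, l5 = 1
  expect_equal(categorical_regressor(mini)[4], 1)  # at the max location
  expect_equal(categorical_regressor(mini)[5], 0)  # below the max
  # after one visit each, l1 and l3 are tied: either member counts as max
  tied <- function(third) {
    data.frame(block = 1L, trial_in_block = 1:3, trial_global = 1:3,
               distractor_present = 1L,
               distractor_location = c(1L, 3L, third))
  }
  expect_equal(categorical_regressor(tied(1L))[3], 1)
  expect_equal(categorical_regressor(tied(3L))[3], 1)
  expect_equal(categorical_regressor(tied(5L))[3], 0)  # off the tied pair
})

test_that("state machines agree exactly with straight-loop oracles", {
  for (s in 1:12) {
    sq <- toy_sequence(60, sample(1:3, 1), seed = s)
    b <- runif(1, 0.05, 2)
    a <- runif(1, 0.05, 0.95)
    for (reset in c(FALSE, TRUE)) {
      expect_equal(accumulator_predictions(sq, b, reset),
                   oracle_accumulator(sq, b, reset))
      expect_equal(categorical_regressor(sq, reset),
                   oracle_categorical(sq, reset))
      expect_equal(rl_predictions(sq, a, reset),
                   oracle_rl(sq, a, reset))
    }
  }
})

test_that("learning trajectories obey their monotonicity properties", {
  sq <- toy_sequence(80, 1, seed = 21)
  # accumulator: per-location predictions never decrease without resets
  for (b in c(0.1, 1)) {
    counts <- cumsum(c(0, head(sq$distractor_present, -1) *
                         (sq$distractor_location %in% 2)[-nrow(sq)]))
    p2 <- 1 - exp(-b * counts)
    expect_true(all(diff(p2) >= 0))
  }
  # RL: a location's prediction decreases only on present trials with the
  # distractor elsewhere
  states <- oracle_rl_states(sq, 0.4)
  for (l in 1:6) {
    drops <- which(diff(states[, l]) < 0) + 1L
    expect_true(all(sq$distractor_present[drops] == 1))
    expect_true(all(sq$distractor_location[drops] != l - 1))
  }
})

test_that("extreme location-decay makes the accumulator a visited-location indicator", {
  sq <- toy_sequence(60, 1, seed = 33)
  p <- accumulator_predictions(sq, 50)
  visited <- as.numeric(oracle_accumulator(sq, 1) > 0)
  expect_equal(p, visited, tolerance = 1e-12)
})

test_that("block-reset models equal their cross-block versions within one block", {
  sq <- toy_sequence(30, 1, seed = 14)  # a single block
  expect_equal(accumulator_predictions(sq, 0.5, TRUE),
               accumulator_predictions(sq, 0.5, FALSE))
  expect_equal(rl_predictions(sq, 0.3, TRUE), rl_predictions(sq, 0.3, FALSE))
  expect_equal(categorical_regressor(sq, TRUE), categorical_regressor(sq, FALSE))
})

test_that("priming regressors encode the three previous-trial types", {
  sq <- data.frame(block = 1L, trial_in_block = 1:5, trial_global = 1:5,
                   distractor_present = c(1L, 0L, 1L, 1L, 1L),
                   distractor_location = c(2L, NA, 4L, 4L, 1L))
  pr <- priming_regressors(sq)
  # rows follow present trials 1, 3, 4, 5
  expect_true(is.na(pr$prev_absent[1]))            # opens the block
  expect_equal(pr$prev_absent[2:4], c(1, 0, 0))
  expect_equal(pr$repetition[2:4], c(0, 1, 0))     # same loc / changed loc
})

test_that("free-parameter counts match the model definitions", {
  expect_equal(vapply(1:9, function(m) model_info(m)$n_params, integer(1)),
               c(6L, 6L, 5L, 6L, 6L, 5L, 5L, 4L, 4L))
  # transforms: rates exponentiated, learning rate squashed, betas identity
  nat <- transform_params(c(log(0.015), 0.9, 0.1, -0.04, 0), 3)
  expect_equal(nat$b_global, 0.015)
  expect_equal(nat$beta_intercept, 0.9)
  nat2 <- transform_params(rep(0, 6), 2)
  expect_equal(nat2$alpha, 0.5)
  expect_error(transform_params(rep(0, 4), 3), "expects 5")
})

test_that("design matrices apply exclusions and z-scoring as specified", {
  sub <- small_subject(model_id = 1, n_blocks = 3, seed = 6,
                       params = c(log(0.02), log(0.5), 0.9, 0.05, -0.03, 0.01))
  sq <- sub$sequence
  dm <- build_design_matrix(1, sq, c(log(0.02), log(0.5)),
                            sub$rt_ms, sub$accuracy)
  pres_first <- sum(sq$distractor_present == 1 & sq$trial_in_block == 1)
  inacc <- sum(sq$distractor_present == 1 & sq$trial_in_block != 1 &
                 sub$accuracy == 0)
  expect_equal(nrow(dm$X), sum(sq$distractor_present) - pres_first - inacc)
  # continuous columns standardized over included rows; dummies untouched
  expect_equal(mean(dm$X[, "global_decay"]), 0, tolerance = 1e-12)
  expect_equal(sd(dm$X[, "global_decay"]), 1, tolerance = 1e-12)
  expect_equal(sd(dm$X[, "distractor_prediction"]), 1, tolerance = 1e-12)
  expect_true(all(dm$X[, "prev_absent"] %in% c(0, 1)))
  dm3 <- build_design_matrix(3, sq, log(0.02), sub$rt_ms, sub$accuracy)
  expect_true(all(dm3$X[, "categorical"] %in% c(0, 1)))
  expect_equal(colnames(dm3$X),
               c("intercept", "global_decay", "categorical", "prev_absent"))
})

test_that("the linear predictor is a plain dot product in seconds", {
  X <- matrix(c(1, 1, 0, 0), 1, 4)
  expect_equal(predict_rt(X, c(0.9, -0.04, 0, 0)), 0.86)
  X0 <- cbind(rep(1, 5), 0, 0)
  expect_equal(predict_rt(X0, c(0.895, -1, 2)), rep(0.895, 5))
  expect_error(predict_rt(X0, c(1, 2)), "coefficients")
})

test_that("profiled-sigma log-likelihood equals the naive Gaussian sum", {
  set.seed(42)
  for (r in 1:10) {
    n <- sample(5:200, 1)
    y <- rnorm(n, 0.9, 0.1)
    mu <- y + rnorm(n, 0, 0.05)
    ll <- log_likelihood(y, mu)
    expect_equal(ll$sigma_hat, sqrt(sum((y - mu)^2) / n))
    naive <- sum(dnorm(y, mu, ll$sigma_hat, log = TRUE))
    expect_equal(ll$LL, naive, tolerance = 1e-10)
  }
  # closed form at n = 2 with residuals (+0.1, -0.1)
  ll2 <- log_likelihood(c(0.1, -0.1), c(0, 0))
  expect_equal(ll2$sigma_hat, 0.1)
  expect_equal(ll2$LL, -2 * (0.5 + log(0.1 * sqrt(2 * pi))))
  # scaling residuals by c shifts LL by -n log c; permutation leaves it fixed
  y <- c(0.8, 0.9, 1.0, 1.1)
  mu <- rep(0.95, 4)
  base <- log_likelihood(y, mu)
  scaled <- log_likelihood(mu + 3 * (y - mu), mu)
  expect_equal(scaled$LL, base$LL - 4 * log(3))
  expect_equal(scaled$sigma_hat, 3 * base$sigma_hat)
  perm <- sample(4)
  expect_equal(log_likelihood(y[perm], mu[perm])$LL, base$LL)
  expect_error(log_likelihood(y, y), "degenerate")
})
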