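test_that("MAP under a nearly flat prior reduces to the least-squares fit", {
  sub <- small_subject(model_id = 3, n_blocks = 3, seed = 7)
  fit <- fit_subject_map(3, sub, prior_mean = 0, prior_var = 1e8,
                         n_starts = 3, seed = 1)
  # OLS on the design matrix at the fitted decay rate is the Gaussian MLE
  dm <- build_design_matrix(3, sub$sequence, fit$raw, sub$rt_ms, sub$accuracy)
  ols <- unname(coef(lm(dm$y ~ dm$X - 1)))
  expect_equal(unname(fit$raw[-1]), ols, tolerance = 1e-4)
})

test_that("a degenerate prior pins the MAP to the prior mean", {
  sub <- small_subject(model_id = 3, n_blocks = 2, seed = 8)
  pm <- c(log(0.02), 0.9, 0.05, -0.02, 0.01)
  fit <- fit_subject_map(3, sub, prior_mean = pm, prior_var = 1e-8,
                         n_starts = 1, seed = 1)
  expect_equal(unname(fit$raw), pm, tolerance = 1e-3)
})

test_that("simulated parameters are recovered within posterior uncertainty", {
  gen <- c(log(0.015), 0.9, 0.09, -0.05, -0.01)
  sub <- small_subject(model_id = 3, n_blocks = 8, seed = 15,
                       noise_sd_ms = 10, params = gen)
  fit <- fit_subject_map(3, sub, n_starts = 3, seed = 2)
  sds <- sqrt(diag(fit$posterior_cov))
  expect_true(all(abs(fit$raw - gen) <= 2.5 * sds))
})

test_that("probability-calculus identities hold for the comparison outputs", {
  set.seed(31)
  for (r in 1:20) {
    K <- sample(2:6, 1)
    counts <- rgamma(K, 3) + 0.5
    bor <- runif(1)
    xp <- exceedance_prob(counts, n_samples = 2e4, method = "mc", seed = r)
    pxp <- protected_exceedance(counts, bor, xp = xp)
    expect_equal(sum(xp), 1, tolerance = 1e-12)
    expect_equal(sum(pxp), 1, tolerance = 1e-12)
    expect_equal(pxp, xp * (1 - bor) + bor / K, tolerance = 1e-12)
  }
  counts <- c(5, 2, 1)
  expect_equal(protected_exceedance(counts, 1, xp = c(0.8, 0.15, 0.05)),
               rep(1 / 3, 3))
  xp <- c(0.8, 0.15, 0.05)
  expect_equal(protected_exceedance(counts, 0, xp = xp), xp)
})

test_that("two-model exceedance from the Beta tail matches Monte Carlo", {
  for (counts in list(c(9, 1), c(3, 3), c(12.5, 4.5))) {
    closed <- exceedance_prob(counts, method = "beta")
    n <- 1e5
    mc <- exceedance_prob(counts, n_samples = n, method = "mc", seed = 5)
    se <- sqrt(closed[1] * (1 - closed[1]) / n)
    expect_lt(abs(mc[1] - closed[1]), 3 * max(se, 1e-4))
  }
  # counts (9, 1) puts nearly all mass on the first model being dominant
  expect_equal(exceedance_prob(c(9, 1), method = "beta")[1],
               1 - pbeta(0.5, 9, 1))
})

test_that("hierarchical t-statistics divide the mean by the hierarchical error", {
  expect_equal(hbi_ttest(0, 0.01, 18)$t, 0)
  expect_equal(hbi_ttest(0, 0.01, 18)$p, 1)
  tt <- hbi_ttest(0.092, 0.0123, 18)
  expect_equal(tt$t, 7.48, tolerance = 0.01)
  expect_lt(tt$p, 0.001)
  expect_equal(hbi_ttest(0.05, 0.02, 10)$t,
               2 * hbi_ttest(0.05, 0.04, 10)$t)
})

test_that("a single-candidate comparison is certain by normalization", {
  subs <- lapply(1:4, function(i) small_subject(3, n_blocks = 2, seed = 40 + i))
  fit <- fit_hierarchical(3, subs, max_iterations = 3, n_starts = 1,
                          seed = 9, mc_samples = 1e3)
  expect_equal(fit$pxp, 1)
  expect_true(all(fit$responsibilities == 1))
  expect_equal(unname(fit$models$model_3$dof),
               unname(fit$models$model_3$responsibility_sum + 1))
})

test_that("responsibilities are normalized and evidence gaps set their odds", {
  subs <- lapply(1:4, function(i) small_subject(3, n_blocks = 2, seed = 50 + i))
  fit <- fit_hierarchical(c(3, 7), subs, max_iterations = 2, n_starts = 1,
                          seed = 3, mc_samples = 1e3)
  expect_equal(unname(rowSums(fit$responsibilities)), rep(1, 4),
               tolerance = 1e-12)
  expect_equal(sum(fit$exceedance), 1, tolerance = 1e-10)
  expect_equal(sum(fit$pxp), 1, tolerance = 1e-10)
  expect_gte(fit$bor, 0)
  expect_lte(fit$bor, 1)
  expect_equal(fit$pxp,
               fit$exceedance * (1 - fit$bor) + fit$bor / 2,
               tolerance = 1e-12)
  # a log-evidence gap of ln 3 at equal frequencies gives 3:1 responsibility
  r <- exp(log(3)) / (exp(log(3)) + 1)
  w <- c(log(3), 0)
  expect_equal(exp(w - max(w))[1] / sum(exp(w - max(w))), r)
})

test_that("hierarchical fitting shrinks subject estimates toward the group", {
  subs <- lapply(1:5, function(i) small_subject(3, n_blocks = 2, seed = 60 + i,
                                                noise_sd_ms = 80))
  fit <- fit_hierarchical(3, subs, max_iterations = 8, n_starts = 2, seed = 4,
                          mc_samples = 1e3)
  gm <- fit$models$model_3$group_mean
  reg <- fit$models$model_3$subject_map
  mle <- t(sapply(subs, function(s) {
    fit_subject_map(3, s, prior_var = 1e8, n_starts = 2, seed = 1)$raw
  }))
  # regularized estimates sit closer to the group mean than the raw MLEs
  d_reg <- rowMeans(abs(sweep(reg, 2, gm)))
  d_mle <- rowMeans(abs(sweep(mle, 2, gm)))
  expect_lt(mean(d_reg), mean(d_mle))
})
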