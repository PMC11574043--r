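test_that("softening assigns 0.99 to the recommendation and a uniform remainder", {
  sp <- soften(constant_policy(0.5), p_top = 0.99)
  P <- policy_probs(sp, matrix(0, 3, 2))
  expect_equal(P[, 6], rep(0.99, 3))          # action 5 = (0.4, 0.5]
  expect_equal(unique(as.numeric(P[, -6])), 0.01 / 15)
  expect_equal(rowSums(P), rep(1, 3))
  ## p_top = 1 degenerates to the deterministic policy
  P1 <- policy_probs(soften(constant_policy(0.5), 1), matrix(0, 2, 2))
  expect_equal(P1[, 6], c(1, 1))
  expect_error(soften(constant_policy(0.5), 1 / 16), "p_top")
  expect_error(soften(constant_policy(0.5), 0.02), "p_top")
})

test_that("the behavior model recovers a deterministic dosing rule", {
  set.seed(2)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  S <- cbind(x = x, z = rnorm(n))
  a <- ifelse(x == 1, 4L, 9L)  # action decided by the binary feature
  tr <- make_batch(s = S, a = a, r = rep(0, n), sp = S, terminal = rep(FALSE, n))
  b <- fit_behavior_policy(tr, maxit = 200)
  P <- behavior_probs(b, S)
  expect_equal(rowSums(P), rep(1, n), tolerance = 1e-9)
  expect_true(all(P > 0))
  expect_gte(min(P[x == 1, 5]), 0.95)
  expect_gte(min(P[x == 0, 10]), 0.95)
  ## permuting rows leaves the fit unchanged
  perm <- sample.int(n)
  tr2 <- make_batch(s = S[perm, ], a = a[perm], r = rep(0, n),
                    sp = S[perm, ], terminal = rep(FALSE, n))
  b2 <- fit_behavior_policy(tr2, maxit = 200)
  expect_equal(coef(b$fit), coef(b2$fit), tolerance = 1e-4)
  ## single-action data are degenerate
  tr1 <- make_batch(s = S, a = rep(3L, n), r = rep(0, n), sp = S,
                    terminal = rep(FALSE, n))
  expect_error(fit_behavior_policy(tr1), "single action")
})

test_that("WIS against the behavior policy itself is the plain mean return", {
  tr <- simulate_transitions(small_config(), 80, seed = 21)
  tr$conf <- NULL
  b <- fit_behavior_policy(tr, maxit = 80)
  self_pol <- behavior_as_policy(b)
  res <- wis(self_pol, b, tr, gamma = 0.99, replicates = 50)
  G <- dexrl:::trajectory_returns(tr, 0.99)
  expect_equal(res$estimate, mean(G), tolerance = 1e-12)
  expect_equal(res$ess, length(G), tolerance = 1e-9)
})

test_that("single-trajectory WIS is self-normalized to the trajectory return", {
  tr <- simulate_transitions(small_config(), 30, seed = 22)
  tr$conf <- NULL
  b <- fit_behavior_policy(tr, maxit = 60)
  one <- dexrl:::subset_transitions(tr, unique(tr$traj)[1])
  res <- wis(soften(constant_policy(0.2), 0.9), b, one, gamma = 0.99)
  expect_equal(res$estimate, dexrl:::trajectory_returns(one, 0.99)[[1]])
})

test_that("WIS stays within the convex hull of observed returns", {
  tr <- simulate_transitions(small_config(), 120, seed = 23)
  tr$conf <- NULL
  b <- fit_behavior_policy(tr, maxit = 80)
  G <- dexrl:::trajectory_returns(tr, 0.99)
  for (p in list(soften(constant_policy(0.4), 0.9), random_policy())) {
    res <- wis(p, b, tr, gamma = 0.99, replicates = 50)
    expect_gte(res$estimate, min(G))
    expect_lte(res$estimate, max(G))
  }
})

test_that("effective sample size follows the Kish formula", {
  expect_equal(effective_sample_size(rep(2.5, 7)), 7)
  expect_equal(effective_sample_size(c(1, 0, 0)), 1)
  expect_equal(effective_sample_size(c(2, 1, 1)), 16 / 6)
  ## scale invariance
  expect_equal(effective_sample_size(c(2, 1, 1) * 1000),
               effective_sample_size(c(2, 1, 1)))
  expect_error(effective_sample_size(c(0, 0)), "weights")
  expect_error(effective_sample_size(c(-1, 1)), "weights")
})

test_that("bootstrap intervals behave on degenerate and nested levels", {
  x <- rnorm(100)
  cst <- bootstrap_ci(function(z) 42, x, replicates = 100, seed = 1)
  expect_equal(cst$lower, 42)
  expect_equal(cst$upper, 42)
  b95 <- bootstrap_ci(mean, x, replicates = 500, level = 0.95, seed = 2)
  b99 <- bootstrap_ci(mean, x, replicates = 500, level = 0.99, seed = 2)
  expect_lte(b99$lower, b95$lower)
  expect_gte(b99$upper, b95$upper)
  ## percentile interval brackets the point estimate
  expect_lte(b95$lower, mean(x))
  expect_gte(b95$upper, mean(x))
  expect_error(bootstrap_ci(mean, x[1]), "at least 2")
  expect_error(bootstrap_ci(function(z) stop("no"), x, replicates = 50),
               "replicates")
})

test_that("conservative policy comparison uses strict bound dominance", {
  ra <- dexrl:::new_ope_result("FQE", 0.390, 0.361, 0.420)
  rb <- dexrl:::new_ope_result("FQE", -0.051, -0.077, -0.025)
  expect_equal(compare_policies(ra, rb), "superior")
  expect_equal(compare_policies(ra, ra), "not separable")
  rc <- dexrl:::new_ope_result("FQE", 0.3, 0.2, 0.4)
  rd <- dexrl:::new_ope_result("FQE", 0.1, 0.0, 0.2)  # upper == lower(a)
  expect_equal(compare_policies(rc, rd), "not separable")
})

test_that("the random policy is uniform and its sampling seeded", {
  rp <- random_policy()
  P <- policy_probs(rp, matrix(0, 4, 3))
  expect_true(all(P == 1 / 16))
  set.seed(99)
  a1 <- policy_act(rp, matrix(0, 16000, 3))
  set.seed(99)
  a2 <- policy_act(rp, matrix(0, 16000, 3))
  expect_identical(a1, a2)
  tab <- table(factor(a1, levels = 0:15))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("FQE regresses terminal-only datasets onto the reward", {
  set.seed(31)
  n <- 240
  S <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("f1", "f2")))
  tr <- make_batch(s = S, a = sample(0:15, n, TRUE), r = rep(1, n),
                   sp = matrix(NA_real_, n, 2), terminal = rep(TRUE, n))
  res <- fqe(random_policy(), tr,
             fqe_config(hidden = c(16, 16), outer_iters = 5, inner_epochs = 80,
                        lr = 1e-2, replicates = 100, seed = 4))
  expect_lt(abs(res$estimate - 1), 0.05)
  expect_lte(res$lower, res$estimate)
  expect_gte(res$upper, res$estimate)
})

test_that("FQE estimates are stable across evaluator seeds", {
  tr <- simulate_transitions(cohort_config(n_patients = 200, seed = 41), 400,
                             seed = 41)
  pol <- soften(constant_policy(0.4), 0.9)
  f1 <- fqe(pol, tr, fqe_config(hidden = c(32, 32), outer_iters = 30,
                                inner_epochs = 3, replicates = 200, seed = 1))
  f2 <- fqe(pol, tr, fqe_config(hidden = c(32, 32), outer_iters = 30,
                                inner_epochs = 3, replicates = 200, seed = 2))
  expect_lt(max(f1$lower, f2$lower), min(f1$upper, f2$upper))  # CIs overlap
})
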