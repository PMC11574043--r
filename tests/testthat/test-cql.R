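# The constant-output networks from helper-fixtures.R make the loss values
# analytic: Q(s, .) equals the output bias everywhere.

batch_nonterminal <- function(n = 8, p = 2, seed = 1) {
  set.seed(seed)
  make_batch(s = matrix(rnorm(n * p), n, p), a = rep(0L, n), r = rep(0, n),
             sp = matrix(rnorm(n * p), n, p), terminal = rep(FALSE, n))
}

test_that("the conservative regularizer equals log |A| for constant Q", {
  for (c0 in c(0, 2.5)) {
    q <- const_qnet(rep(c0, 16))
    b <- batch_nonterminal()
    ## subtract the TD part: what remains is the conservative regularizer
    cfg1 <- training_config(alpha = 1, gamma = 0.99, seed = 1)
    td <- double_dqn_loss(b, q, q, gamma = 0.99)
    expect_equal(cql_loss(b, q, q, cfg1) - td, log(16), tolerance = 1e-12)
  }
})

test_that("a dominant logged action drives the regularizer to zero", {
  margins <- c(5, 10, 20)
  regs <- vapply(margins, function(m) {
    q <- const_qnet(c(m, rep(0, 15)))
    b <- batch_nonterminal()  # a_t = 0, the dominant action
    cql_loss(b, q, q, training_config(alpha = 1)) -
      double_dqn_loss(b, q, q, 0.99)
  }, numeric(1))
  expect_true(all(diff(regs) < 0))
  expect_lt(regs[3], 1e-6)
  expect_gt(regs[3], 0)
})

test_that("the loss is invariant to duplicating a batch and reduces to Double-DQN at alpha 0", {
  set.seed(4)
  spec <- qnet_spec(3, 16, hidden = c(8, 8))
  q <- dexrl:::qnet_init(spec); qt <- dexrl:::qnet_init(spec)
  b <- make_batch(s = matrix(rnorm(30), 10, 3), a = sample(0:15, 10, TRUE),
                  r = c(rep(0, 8), -1, 1),
                  sp = matrix(rnorm(30), 10, 3),
                  terminal = c(rep(FALSE, 8), TRUE, TRUE))
  b2 <- make_batch(s = rbind(b$s, b$s), a = c(b$a, b$a), r = c(b$r, b$r),
                   sp = rbind(b$sp, b$sp), terminal = c(b$terminal, b$terminal))
  cfg <- training_config(alpha = 1)
  expect_equal(cql_loss(b, q, qt, cfg), cql_loss(b2, q, qt, cfg))
  cfg0 <- training_config(alpha = 0)
  expect_identical(cql_loss(b, q, qt, cfg0), double_dqn_loss(b, q, qt, 0.99))
})

test_that("the regularizer is nonnegative on random batches and networks", {
  for (seed in 1:5) {
    set.seed(seed)
    spec <- qnet_spec(4, 16, hidden = 8)
    q <- dexrl:::qnet_init(spec); qt <- dexrl:::qnet_init(spec)
    b <- make_batch(s = matrix(rnorm(48), 12, 4), a = sample(0:15, 12, TRUE),
                    r = rep(0, 12), sp = matrix(rnorm(48), 12, 4),
                    terminal = rep(FALSE, 12))
    reg <- cql_loss(b, q, qt, training_config(alpha = 1)) -
      double_dqn_loss(b, q, qt, 0.99)
    expect_gte(reg, 0)
  }
})

test_that("Double-DQN handles terminal and bootstrap targets exactly", {
  ## terminal: target = r
  b1 <- make_batch(s = matrix(0, 1, 2), a = 0L, r = 1, sp = matrix(NA_real_, 1, 2),
                   terminal = TRUE)
  expect_equal(double_dqn_loss(b1, const_qnet(c(1, 0)), const_qnet(c(9, 9))), 0)
  b2 <- make_batch(s = matrix(0, 1, 2), a = 0L, r = -1,
                   sp = matrix(NA_real_, 1, 2), terminal = TRUE)
  expect_equal(double_dqn_loss(b2, const_qnet(c(0, 0)), const_qnet(c(9, 9))), 1)
  ## non-terminal: online net picks the action, target net values it
  q_online <- const_qnet(c(0.4, 0.3))   # Q(s_t, a_t=0) = 0.4; argmax at s' = 0
  q_target <- const_qnet(c(0.5, 0.9))   # valuation of action 0 = 0.5
  b3 <- make_batch(s = matrix(0, 1, 2), a = 0L, r = 0, sp = matrix(0, 1, 2),
                   terminal = FALSE)
  expect_equal(double_dqn_loss(b3, q_online, q_target, gamma = 0.99),
               (0.99 * 0.5 - 0.4)^2)  # 0.009025
})

test_that("analytic gradients agree with finite differences", {
  set.seed(7)
  spec <- qnet_spec(2, 4, hidden = 3)
  net <- dexrl:::qnet_init(spec)
  X <- matrix(rnorm(10), 5, 2)
  a <- c(0L, 1L, 2L, 3L, 0L)
  y <- rnorm(5)
  alpha <- 0.7
  loss_of <- function(net) {
    Q <- dexrl:::qnet_forward(net, X)$Q
    q_sa <- Q[cbind(1:5, a + 1L)]
    mean((q_sa - y)^2) + alpha * mean(dexrl:::row_logsumexp(Q) - q_sa)
  }
  fw <- dexrl:::qnet_forward(net, X, keep_cache = TRUE)
  Q <- fw$Q
  idx <- cbind(1:5, a + 1L)
  dQ <- matrix(0, 5, 4)
  dQ[idx] <- 2 * (Q[idx] - y) / 5
  P <- exp(Q - dexrl:::row_logsumexp(Q))
  P[idx] <- P[idx] - 1
  dQ <- dQ + alpha * P / 5
  grads <- dexrl:::qnet_backward(net, fw$cache, dQ)
  eps <- 1e-6
  for (l in seq_along(net$W)) {
    for (k in seq_len(min(4, length(net$W[[l]])))) {
      np <- net; np$W[[l]][k] <- np$W[[l]][k] + eps
      nm <- net; nm$W[[l]][k] <- nm$W[[l]][k] - eps
      fd <- (loss_of(np) - loss_of(nm)) / (2 * eps)
      expect_equal(grads$W[[l]][k], fd, tolerance = 1e-5)
    }
  }
})

test_that("training is seeded, finite, and logged per epoch", {
  tr <- simulate_transitions(small_config(), 60, seed = 3)
  cfg <- training_config(batch_size = 128, epochs = 2, lr = 1e-3,
                         checkpoint_every = 1, seed = 5)
  spec <- qnet_spec(ncol(tr$s), hidden = c(16, 16))
  f1 <- train_cql(tr, cfg, spec)
  f2 <- train_cql(tr, cfg, spec)
  expect_length(f1$loss_trace, 2)
  expect_true(all(is.finite(f1$loss_trace)))
  expect_identical(f1$final$net$W, f2$final$net$W)
  expect_identical(f1$final$net$b, f2$final$net$b)
})

test_that("CQL learns the rewarded arm of a bandit-like MDP", {
  set.seed(10)
  n <- 1500
  S <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  a <- sample(0:15, n, replace = TRUE)
  r <- ifelse(a == 3L, 1, -1)  # action 3 always precedes reward +1
  b <- make_batch(s = S, a = a, r = r, sp = matrix(NA_real_, n, 3),
                  terminal = rep(TRUE, n))
  fit <- train_cql(b, training_config(batch_size = 256, epochs = 30, lr = 2e-3,
                                      alpha = 1, seed = 2),
                   qnet_spec(3, hidden = c(16, 16)))
  greedy <- greedy_action(fit$final, S)
  expect_gte(mean(greedy == 3L), 0.9)
})

test_that("greedy actions take the lowest-index maximizer", {
  tp <- dexrl:::new_trained_policy(const_qnet(c(0, 2, 1, rep(0, 13))),
                                  scaler = NULL)
  expect_equal(greedy_action(tp, c(0, 0)), 1L)
  tp0 <- dexrl:::new_trained_policy(const_qnet(rep(0.3, 16)), scaler = NULL)
  expect_equal(greedy_action(tp0, c(0, 0)), 0L)
  ## perturbing a non-maximal entry below the max leaves the argmax unchanged
  tp2 <- dexrl:::new_trained_policy(const_qnet(c(0, 2, 1.9, rep(0, 13))),
                                   scaler = NULL)
  expect_equal(greedy_action(tp2, c(0, 0)), 1L)
})

test_that("checkpoint selection maximizes the validation lower bound", {
  cps <- list(dexrl:::new_trained_policy(const_qnet(rep(0, 16)), NULL,
                                         list(epoch = 1)),
              dexrl:::new_trained_policy(const_qnet(rep(1, 16)), NULL,
                                         list(epoch = 2)),
              dexrl:::new_trained_policy(const_qnet(rep(2, 16)), NULL,
                                         list(epoch = 3)))
  stub <- function(bounds) {
    i <- 0
    function(tp) {
      i <<- i + 1
      dexrl:::new_ope_result("FQE", bounds[i] + 0.1, bounds[i], bounds[i] + 0.2)
    }
  }
  sel <- select_checkpoint(cps, val_transitions = NULL,
                           evaluator = stub(c(0.1, 0.3, 0.2)))
  expect_equal(sel$meta$selected, 2)
  ## ties resolve to the earliest checkpoint
  sel2 <- select_checkpoint(cps, NULL, evaluator = stub(c(0.3, 0.3, 0.1)))
  expect_equal(sel2$meta$selected, 1)
  ## single checkpoint is returned as-is
  sel3 <- select_checkpoint(cps[1], NULL, evaluator = stub(0.5))
  expect_equal(sel3$meta$selected, 1)
  ## failures are excluded with a warning; all-failed aborts
  failing <- function(tp) stop("boom")
  expect_error(suppressWarnings(select_checkpoint(cps, NULL, evaluator = failing)),
               "every checkpoint")
})

test_that("trained policies round-trip through the JSON archive", {
  tr <- simulate_transitions(small_config(), 30, seed = 8)
  fit <- train_cql(tr, training_config(batch_size = 128, epochs = 1, lr = 1e-3,
                                       seed = 3),
                   qnet_spec(ncol(tr$s), hidden = 8))
  path <- withr::local_tempfile(fileext = ".json")
  write_trained_policy(fit$final, path)
  back <- read_trained_policy(path)
  expect_equal(q_values(back, tr$s[1:5, ]), q_values(fit$final, tr$s[1:5, ]),
               tolerance = 1e-12)
})
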