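#' Fit a multinomial behavior-policy model of clinician dosing
#'
#' Approximates the clinicians' dosing distribution with multinomial logistic
#' regression of the observed action on the state features plus static
#' confounders (age, sex, body-mass index, renal replacement, ventilation,
#' shock). Inputs are z-scored for numerical stability. Predicted per-row
#' probabilities are floored at `floor_prob` and renormalized so importance
#' ratios stay bounded.
#'
#' @param transitions A `dex_transitions` with a confounder matrix (`conf`),
#'   or `NULL` confounders to fit on states alone.
#' @param floor_prob Probability floor applied after prediction (default 1e-4).
#' @param maxit Maximum optimizer iterations passed to [nnet::multinom()].
#' @param n_actions Action-space size (default 16).
#' @return An object of class `behavior_policy`: the fitted model, scaler,
#'   action levels, and feature layout.
#' @export
fit_behavior_policy <- function(transitions, floor_prob = 1e-4, maxit = 200,
                                n_actions = 16L) {
  stopifnot(inherits(transitions, "dex_transitions"))
  X <- cbind(transitions$s, transitions$conf)
  a <- transitions$a
  if (length(unique(a)) < 2)
    stopf("degenerate behavior data: a single action was always taken")
  scaler <- fit_scaler(X)
  Z <- apply_scaler(scaler, X)
  colnames(Z) <- paste0("x", seq_len(ncol(Z)))
  df <- data.frame(a = factor(a, levels = 0:(n_actions - 1L)), Z)
  ## actions never taken are expected at desk scale; multinom drops them
  fit <- withCallingHandlers(
    nnet::multinom(a ~ ., data = df, maxit = maxit, trace = FALSE,
                   MaxNWts = 100000),
    warning = function(w) {
      if (grepl("group.*empty", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, scaler = scaler, n_actions = as.integer(n_actions),
                 n_state_features = ncol(transitions$s),
                 floor_prob = floor_prob),
            class = "behavior_policy")
}

#' Behavior-policy action probabilities
#'
#' @param behavior A `behavior_policy`.
#' @param states State matrix (raw units).
#' @param conf Confounder matrix aligned with `states` (omit if the model was
#'   fitted without confounders).
#' @return Matrix of floored, renormalized probabilities over all actions;
#'   rows sum to 1 and every entry is strictly positive.
#' @export
behavior_probs <- function(behavior, states, conf = NULL) {
  stopifnot(inherits(behavior, "behavior_policy"))
  X <- cbind(states, conf)
  Z <- apply_scaler(behavior$scaler, X)
  colnames(Z) <- paste0("x", seq_len(ncol(Z)))
  P <- predict(behavior$fit, newdata = as.data.frame(Z), type = "probs")
  lev_all <- behavior$fit$lev  # observed action levels, in model order
  if (is.null(dim(P))) {
    ## two observed classes: vector of P(second level); one row: named vector
    P <- if (length(lev_all) == 2 && length(P) == nrow(Z))
      cbind(1 - P, P) else matrix(P, nrow = nrow(Z), byrow = FALSE)
  }
  colnames(P) <- lev_all
  ## multinom drops unobserved levels from its output; re-expand
  full <- matrix(behavior$floor_prob, nrow(Z), behavior$n_actions)
  lev <- as.integer(colnames(P))
  full[, lev + 1L] <- pmax(P, behavior$floor_prob)
  n_floor <- sum(P < behavior$floor_prob)
  if (n_floor > 0)
    dexrl_log("debug", "behavior probabilities floored on %d cells", n_floor)
  full / rowSums(full)
}

#' Effective sample size of importance weights
#'
#' Kish's formula `(sum w)^2 / sum(w^2)`, invariant to rescaling of the
#' weights; equals `n` for equal weights and 1 when a single weight carries
#' all mass. A small value relative to the number of admissions signals that
#' the weighted estimate rests on very few trajectories.
#'
#' @param weights Nonnegative importance weights, not all zero.
#' @return Scalar in `[1, length(weights)]`.
#' @export
effective_sample_size <- function(weights) {
  if (any(weights < 0) || all(weights == 0))
    stopf("weights must be nonnegative and not all zero")
  sum(weights)^2 / sum(weights^2)
}

#' Percentile bootstrap confidence interval over trajectories
#'
#' Resamples trajectory units with replacement and recomputes the statistic
#' on each replicate; returns the percentile interval. Aborts if the
#' statistic fails on more than 10% of replicates.
#'
#' @param statistic Function of a resampled unit vector/list.
#' @param units Vector or list of trajectory-level units.
#' @param replicates Bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List with `lower`, `upper`, `replicates` (the replicate values).
#' @export
bootstrap_ci <- function(statistic, units, replicates = 1000, level = 0.95,
                         seed = 1L) {
  n <- if (is.list(units) && !is.data.frame(units)) length(units) else NROW(units)
  if (n < 2) stopf("bootstrap requires at least 2 trajectory units")
  set.seed(seed)
  take <- function(i) if (is.list(units) && !is.data.frame(units)) units[i]
                      else if (is.null(dim(units))) units[i]
                      else units[i, , drop = FALSE]
  vals <- rep(NA_real_, replicates)
  for (b in seq_len(replicates)) {
    vals[b] <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                        error = function(e) NA_real_)
  }
  if (mean(is.na(vals)) > 0.1)
    stopf("statistic failed on more than 10%% of bootstrap replicates")
  qs <- quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE,
                 names = FALSE)
  list(lower = qs[1], upper = qs[2], replicates = vals)
}

new_ope_result <- function(method, estimate, lower, upper, ess = NA_real_,
                           replicates = NA_integer_, n_traj = NA_integer_,
                           extra = list()) {
  structure(c(list(method = method, estimate = estimate, lower = lower,
                   upper = upper, ess = ess, replicates = replicates,
                   n_traj = n_traj), extra),
            class = "ope_result")
}

#' @export
print.ope_result <- function(x, ...) {
  cat(sprintf("<ope_result> %s: %.3f (95%% CI %.3f to %.3f)%s\n", x$method,
              x$estimate, x$lower, x$upper,
              if (is.finite(x$ess)) sprintf(", ESS %.2f of %d", x$ess, x$n_traj)
              else ""))
  invisible(x)
}

#' Configuration for fitted-Q evaluation
#'
#' @param hidden Hidden-layer widths of the evaluation Q-network.
#' @param outer_iters Target-refresh iterations (fitted-Q sweeps).
#' @param inner_epochs Regression epochs per sweep.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param gamma Discount factor.
#' @param replicates Bootstrap replicates for the confidence interval.
#' @param seed Integer seed.
#' @return An object of class `fqe_config`.
#' @export
fqe_config <- function(hidden = c(64, 64), outer_iters = 25, inner_epochs = 2,
                       batch_size = 1024, lr = 1e-3, gamma = 0.99,
                       replicates = 1000, seed = 1L) {
  structure(list(hidden = as.integer(hidden),
                 outer_iters = as.integer(outer_iters),
                 inner_epochs = as.integer(inner_epochs),
                 batch_size = as.integer(batch_size), lr = lr, gamma = gamma,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "fqe_config")
}

#' Fitted-Q evaluation of a dosing policy
#'
#' Model-based off-policy evaluation: fits an evaluation Q-network by
#' iterated regression onto the policy's Bellman targets
#' `r + gamma * sum_a pi(a | s') Q(s', a)` (terminal targets equal the
#' reward), then estimates the policy value as the mean over trajectories of
#' the initial-state value `sum_a pi(a | s_0) Q(s_0, a)`. The confidence
#' interval is a percentile bootstrap over trajectories of that initial-state
#' value.
#'
#' @param policy A `dex_policy`.
#' @param transitions A `dex_transitions` evaluation set.
#' @param config An [fqe_config()].
#' @param level Confidence level (default 0.95).
#' @return An `ope_result` with method `"FQE"` (per-trajectory values in
#'   `$v0`).
#' @export
fqe <- function(policy, transitions, config = fqe_config(), level = 0.95) {
  stopifnot(inherits(policy, "dex_policy"), inherits(transitions, "dex_transitions"))
  n <- length(transitions$a)
  if (!n) stopf("empty transition set")
  scaler <- fit_scaler(transitions$s)
  S <- apply_scaler(scaler, transitions$s)
  term <- transitions$terminal
  SPraw <- transitions$sp
  SPraw[term, ] <- 0
  SP <- apply_scaler(scaler, SPraw)
  ## policy probabilities at s' (raw units), fixed across sweeps
  Ppi <- matrix(0, n, policy$n_actions)
  if (any(!term)) Ppi[!term, ] <- policy_probs(policy, SPraw[!term, , drop = FALSE])

  set.seed(config$seed)
  spec <- qnet_spec(ncol(S), policy$n_actions, config$hidden)
  net <- qnet_init(spec)
  opt <- adam_init(net)
  for (it in seq_len(config$outer_iters)) {
    y <- transitions$r
    if (any(!term)) {
      Qp <- qnet_forward(net, SP[!term, , drop = FALSE])$Q
      y[!term] <- transitions$r[!term] +
        config$gamma * rowSums(Ppi[!term, , drop = FALSE] * Qp)
    }
    for (ep in seq_len(config$inner_epochs)) {
      ord <- sample.int(n)
      for (b in seq(1L, n, by = config$batch_size)) {
        take <- ord[b:min(b + config$batch_size - 1L, n)]
        fw <- qnet_forward(net, S[take, , drop = FALSE], keep_cache = TRUE)
        idx <- cbind(seq_along(take), transitions$a[take] + 1L)
        dQ <- matrix(0, length(take), spec$n_actions)
        dQ[idx] <- 2 * (fw$Q[idx] - y[take]) / length(take)
        st <- adam_step(net, qnet_backward(net, fw$cache, dQ), opt, config$lr)
        net <- st$net; opt <- st$opt
      }
    }
  }
  S0 <- transitions$s0
  P0 <- policy_probs(policy, S0)
  Q0 <- qnet_forward(net, apply_scaler(scaler, S0))$Q
  v0 <- rowSums(P0 * Q0)
  est <- mean(v0)
  vmax <- 1 / (1 - config$gamma + 1e-12)
  if (!is.finite(est) || abs(est) > vmax)
    stopf("FQE diverged: estimate %.3f outside [-%.1f, %.1f]", est, vmax, vmax)
  ci <- bootstrap_ci(mean, v0, replicates = config$replicates, level = level,
                     seed = derive_seed(config$seed, 17L))
  new_ope_result("FQE", est, ci$lower, ci$upper,
                 replicates = config$replicates, n_traj = length(v0),
                 extra = list(v0 = v0))
}

#' Weighted importance sampling evaluation of a dosing policy
#'
#' Model-free off-policy evaluation: each trajectory is weighted by the
#' product over its timesteps of the ratio of the evaluated policy's to the
#' behavior policy's probability of the logged action, and the estimate is
#' the weight-normalized mean of the discounted trajectory returns. Reports
#' the Kish effective sample size of the normalized weights and a percentile
#' bootstrap confidence interval over trajectories.
#'
#' @param policy A `dex_policy` (soften deterministic policies first so
#'   ratios stay finite).
#' @param behavior A `behavior_policy` from [fit_behavior_policy()].
#' @param transitions A `dex_transitions` evaluation set.
#' @param gamma Discount factor for the returns.
#' @param replicates Bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return An `ope_result` with method `"WIS"`, effective sample size in
#'   `$ess`, and per-trajectory log-weights and returns in `$log_w`, `$G`.
#' @export
wis <- function(policy, behavior, transitions, gamma = 0.99,
                replicates = 1000, level = 0.95, seed = 1L) {
  stopifnot(inherits(policy, "dex_policy"), inherits(behavior, "behavior_policy"),
            inherits(transitions, "dex_transitions"))
  pe <- policy_probs(policy, transitions$s)
  pb <- behavior_probs(behavior, transitions$s, transitions$conf)
  idx <- cbind(seq_along(transitions$a), transitions$a + 1L)
  lr_t <- log(pe[idx]) - log(pb[idx])
  by_traj <- split(seq_along(transitions$traj), transitions$traj)[
    transitions$s0_traj]
  log_w <- vapply(by_traj, function(i) sum(lr_t[i]), numeric(1))
  G <- vapply(by_traj, function(i) discounted_return(transitions$r[i], gamma),
              numeric(1))
  w <- exp(log_w - max(log_w))
  if (all(w == 0) || !any(is.finite(w)))
    stopf("all importance weights vanished; behavior coverage is inadequate")
  est <- sum(w * G) / sum(w)
  ess <- effective_sample_size(w)
  if (length(w) < 2)
    return(new_ope_result("WIS", est, est, est, ess = ess, replicates = 0L,
                          n_traj = 1L, extra = list(log_w = log_w, G = G)))
  units <- seq_along(w)
  stat <- function(i) sum(w[i] * G[i]) / sum(w[i])
  ci <- bootstrap_ci(stat, units, replicates = replicates, level = level,
                     seed = seed)
  new_ope_result("WIS", est, ci$lower, ci$upper, ess = ess,
                 replicates = replicates, n_traj = length(w),
                 extra = list(log_w = log_w, G = G,
                              boot_se = sd(ci$replicates, na.rm = TRUE)))
}

#' Conservative comparison of two evaluated policies
#'
#' Declares policy A superior only when its confidence interval's lower bound
#' strictly exceeds policy B's upper bound.
#'
#' @param result_a,result_b `ope_result`s carrying confidence bounds.
#' @return `"superior"` or `"not separable"`.
#' @export
compare_policies <- function(result_a, result_b) {
  stopifnot(is.finite(result_a$lower), is.finite(result_b$upper))
  if (result_a$lower > result_b$upper) "superior" else "not separable"
}

#' Summarize OPE results as a table
#'
#' @param results Named list of `ope_result`s (name = policy label).
#' @return `data.frame` with one row per result.
#' @export
ope_table <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(policy = nm, method = r$method, estimate = r$estimate,
               lower = r$lower, upper = r$upper, ess = r$ess,
               n_traj = r$n_traj)
  }))
}

#' Wrap a fitted behavior model as a stochastic dosing policy
#'
#' Turns the multinomial behavior model into a `dex_policy` over state
#' features alone, e.g. to roll the clinician-approximating policy out in a
#' simulator or to verify that importance sampling against itself reduces to
#' the plain mean return. Only valid for models fitted without confounders
#' unless the confounders are appended to the state matrix.
#'
#' @param behavior A `behavior_policy`.
#' @return A `dex_policy`.
#' @export
behavior_as_policy <- function(behavior) {
  stopifnot(inherits(behavior, "behavior_policy"))
  n_state <- behavior$n_state_features
  new_policy(function(S) {
    conf <- if (ncol(S) > n_state) S[, -(seq_len(n_state)), drop = FALSE]
    behavior_probs(behavior, S[, seq_len(n_state), drop = FALSE], conf)
  }, n_actions = behavior$n_actions, kind = "behavior-model")
}
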