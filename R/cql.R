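#' Training configuration for conservative Q-learning
#'
#' Full-scale defaults follow the study design this package implements: batch
#' size 4096, 2000 epochs, Adam at learning rate 6.25e-5, discount 0.99. The
#' conservatism weight `alpha` and the target-network synchronisation period
#' are configurable (defaults 1.0 and 100 gradient steps). For desk-scale
#' synthetic experiments much smaller budgets (e.g. 50 epochs, batch 512,
#' learning rate 1e-3) train adequately; see the package vignette.
#'
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (full passes over the transition set).
#' @param lr Adam learning rate.
#' @param gamma Discount factor in (0, 1].
#' @param alpha Conservatism weight on the log-sum-exp regularizer.
#' @param target_sync Gradient steps between target-network synchronisations.
#' @param checkpoint_every Epochs between checkpoints (default: `epochs / 10`,
#'   at least 1).
#' @param seed Integer seed controlling initialization and batch order.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 4096, epochs = 2000, lr = 6.25e-5,
                            gamma = 0.99, alpha = 1.0, target_sync = 100,
                            checkpoint_every = NULL, seed = 1L) {
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_number(epochs, "epochs", lower = 1, integer = TRUE)
  check_number(lr, "lr", lower = 1e-12)
  check_number(gamma, "gamma", lower = 1e-8, upper = 1)
  check_number(alpha, "alpha", lower = 0)
  check_number(target_sync, "target_sync", lower = 1, integer = TRUE)
  checkpoint_every <- checkpoint_every %||% max(1L, as.integer(epochs / 10))
  check_number(checkpoint_every, "checkpoint_every", lower = 1, integer = TRUE)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, gamma = gamma,
                 alpha = alpha, target_sync = as.integer(target_sync),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "training_config")
}

## Double-DQN regression targets for a batch: action selected by the online
## network, valued by the target network; terminal transitions regress onto
## the reward alone.
ddqn_targets <- function(net, net_target, sp, r, terminal, gamma) {
  y <- r
  nt <- which(!terminal)
  if (length(nt)) {
    Qo <- qnet_forward(net, sp[nt, , drop = FALSE])$Q
    a_star <- max.col(Qo, ties.method = "first")
    Qt <- qnet_forward(net_target, sp[nt, , drop = FALSE])$Q
    y[nt] <- r[nt] + gamma * Qt[cbind(seq_along(nt), a_star)]
  }
  y
}

#' Double-DQN temporal-difference loss
#'
#' Mean squared TD error with decoupled action selection and valuation:
#' target `r_{t+1} + gamma * Q_target(s_{t+1}, argmax_a Q(s_{t+1}, a))`, and
#' `r_{t+1}` alone for terminal transitions.
#'
#' @param batch A `dex_transitions` (states already in the networks' input
#'   space).
#' @param q,q_target Online and target `qnet`s sharing one spec.
#' @param gamma Discount factor.
#' @return Scalar loss.
#' @export
double_dqn_loss <- function(batch, q, q_target, gamma = 0.99) {
  stopifnot(identical(q$spec, q_target$spec))
  y <- ddqn_targets(q, q_target, batch$sp, batch$r, batch$terminal, gamma)
  Q <- qnet_forward(q, batch$s)$Q
  if (any(!is.finite(Q)))
    stopf("non-finite Q-values in double_dqn_loss; training diverged")
  q_sa <- Q[cbind(seq_along(batch$a), batch$a + 1L)]
  mean((y - q_sa)^2)
}

#' Conservative Q-learning loss
#'
#' The CQL objective: `alpha * mean(logsumexp_a Q(s_t, a) - Q(s_t, a_t))`
#' plus the Double-DQN TD loss. The regularizer penalizes Q-mass on actions
#' outside the data distribution (log-sum-exp over all actions) while
#' anchoring the value of the action the clinicians actually took; it is
#' nonnegative for every batch and vanishes only in the limit where the
#' logged action dominates all alternatives. With `alpha = 0` the loss
#' reduces exactly to the Double-DQN loss.
#'
#' @inheritParams double_dqn_loss
#' @param config A [training_config()] (supplies `alpha` and `gamma`).
#' @return Scalar loss.
#' @export
cql_loss <- function(batch, q, q_target, config = training_config()) {
  if (!length(batch$a)) stopf("empty batch")
  Q <- qnet_forward(q, batch$s)$Q
  if (any(!is.finite(Q)))
    stopf("non-finite Q-values in cql_loss; aborting with diagnostics: max |W1| = %g",
          max(abs(q$W[[1]])))
  q_sa <- Q[cbind(seq_along(batch$a), batch$a + 1L)]
  reg <- mean(row_logsumexp(Q) - q_sa)
  config$alpha * reg + double_dqn_loss(batch, q, q_target, config$gamma)
}

## One CQL gradient step on a minibatch. Returns updated net/optimizer and
## the batch loss.
cql_step <- function(net, net_target, opt, s, a, r, sp, terminal, config) {
  n <- length(a)
  y <- ddqn_targets(net, net_target, sp, r, terminal, config$gamma)
  fw <- qnet_forward(net, s, keep_cache = TRUE)
  Q <- fw$Q
  if (any(!is.finite(Q)))
    stopf("training diverged: non-finite Q-values")
  idx <- cbind(seq_len(n), a + 1L)
  q_sa <- Q[idx]
  td <- q_sa - y
  ## dL/dQ: TD term on the taken action, CQL term softmax - onehot
  dQ <- matrix(0, n, ncol(Q))
  dQ[idx] <- 2 * td / n
  if (config$alpha > 0) {
    P <- exp(Q - row_logsumexp(Q))
    P[idx] <- P[idx] - 1
    dQ <- dQ + config$alpha * P / n
  }
  grads <- qnet_backward(net, fw$cache, dQ)
  st <- adam_step(net, grads, opt, config$lr)
  loss <- mean(td^2) + config$alpha * mean(row_logsumexp(Q) - q_sa)
  list(net = st$net, opt = st$opt, loss = loss)
}

#' Train a dosing Q-function with conservative Q-learning
#'
#' Minimizes the CQL objective (log-sum-exp regularizer plus Double-DQN TD
#' loss) by minibatch Adam over the offline transition set. States are
#' z-scored with a scaler fitted on the training transitions; the scaler
#' travels with every checkpoint so policies accept raw-unit states. The
#' target network is synchronized with the online network every
#' `config$target_sync` gradient steps. Fully deterministic given
#' `config$seed`.
#'
#' @param transitions A `dex_transitions` training set.
#' @param config A [training_config()].
#' @param spec A [qnet_spec()]; default: three hidden layers of 256 units
#'   over the transition feature width.
#' @return An object of class `cql_fit`: list with `checkpoints` (each a
#'   `trained_policy`), `final` (`trained_policy` at the last epoch),
#'   `loss_trace` (per-epoch mean loss), `config`.
#' @export
train_cql <- function(transitions, config = training_config(), spec = NULL) {
  stopifnot(inherits(transitions, "dex_transitions"))
  n <- length(transitions$a)
  if (!n) stopf("empty transition set")
  spec <- spec %||% qnet_spec(ncol(transitions$s))
  if (spec$n_features != ncol(transitions$s))
    stopf("qnet spec width %d does not match %d state features",
          spec$n_features, ncol(transitions$s))
  scaler <- fit_scaler(transitions$s)
  S <- apply_scaler(scaler, transitions$s)
  SP <- transitions$sp
  SP[transitions$terminal, ] <- 0  # placeholder rows, never used in targets
  SP <- apply_scaler(scaler, SP)

  set.seed(config$seed)
  net <- qnet_init(spec)
  net_target <- net
  opt <- adam_init(net)
  step <- 0L
  loss_trace <- numeric(config$epochs)
  checkpoints <- list()
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (b in starts) {
      take <- ord[b:min(b + config$batch_size - 1L, n)]
      st <- cql_step(net, net_target, opt,
                     S[take, , drop = FALSE], transitions$a[take],
                     transitions$r[take], SP[take, , drop = FALSE],
                     transitions$terminal[take], config)
      net <- st$net; opt <- st$opt
      ep_loss <- ep_loss + st$loss * length(take)
      step <- step + 1L
      if (step %% config$target_sync == 0L) net_target <- net
    }
    loss_trace[ep] <- ep_loss / n
    if (!is.finite(loss_trace[ep]))
      stopf("training diverged at epoch %d (non-finite loss)", ep)
    if (ep %% config$checkpoint_every == 0L || ep == config$epochs) {
      checkpoints[[length(checkpoints) + 1L]] <-
        new_trained_policy(net, scaler, list(epoch = ep, loss = loss_trace[ep],
                                             config = config))
      dexrl_log("debug", "epoch %d: loss %.5f", ep, loss_trace[ep])
    }
  }
  structure(list(checkpoints = checkpoints,
                 final = checkpoints[[length(checkpoints)]],
                 loss_trace = loss_trace, config = config),
            class = "cql_fit")
}

new_trained_policy <- function(net, scaler, meta = list()) {
  structure(list(net = net, scaler = scaler, meta = meta),
            class = "trained_policy")
}

#' Extract a trained policy from a CQL fit
#' @param fit A `cql_fit`.
#' @param which Checkpoint index (default: the final checkpoint).
#' @return A `trained_policy`.
#' @export
as_trained_policy <- function(fit, which = NULL) {
  stopifnot(inherits(fit, "cql_fit"))
  if (is.null(which)) fit$final else fit$checkpoints[[which]]
}

#' Q-values and greedy action of a trained policy
#'
#' `greedy_action()` returns the lowest-index maximizer of the Q-values
#' (0-based action index); ties break toward the lower dose.
#'
#' @param trained A `trained_policy`.
#' @param state State vector or matrix in raw feature units.
#' @return `q_values()`: a matrix of Q-values; `greedy_action()`: integer
#'   action indices.
#' @export
q_values <- function(trained, state) {
  stopifnot(inherits(trained, "trained_policy"))
  if (is.null(dim(state))) state <- matrix(state, nrow = 1)
  qnet_forward(trained$net, apply_scaler(trained$scaler, state))$Q
}

#' @rdname q_values
#' @export
greedy_action <- function(trained, state) {
  Q <- q_values(trained, state)
  max.col(Q, ties.method = "first") - 1L
}

#' Select a checkpoint by validation lower bound
#'
#' Evaluates each checkpoint's greedy policy on the validation trajectories
#' with fitted-Q evaluation and returns the checkpoint with the highest
#' bootstrap 95% lower confidence bound of the estimated return; ties go to
#' the earliest checkpoint. Checkpoints whose evaluation fails are excluded
#' with a warning.
#'
#' @param fit A `cql_fit` (or list of `trained_policy` checkpoints).
#' @param val_transitions Validation `dex_transitions`.
#' @param fqe_config An [fqe_config()] controlling the evaluator.
#' @param level Confidence level for the lower bound (default 0.95).
#' @param evaluator Evaluation routine `function(trained_policy)` returning an
#'   `ope_result`; defaults to fitted-Q evaluation of the greedy policy on the
#'   validation transitions.
#' @return The selected `trained_policy`, with the winning bound and
#'   per-checkpoint diagnostics in `$meta`.
#' @export
select_checkpoint <- function(fit, val_transitions,
                              fqe_config = fqe_config(), level = 0.95,
                              evaluator = NULL) {
  cps <- if (inherits(fit, "cql_fit")) fit$checkpoints else fit
  if (!length(cps)) stopf("no checkpoints to select from")
  evaluator <- evaluator %||% function(tp)
    fqe(policy_greedy(tp), val_transitions, fqe_config, level = level)
  bounds <- rep(NA_real_, length(cps))
  for (i in seq_along(cps)) {
    res <- tryCatch(evaluator(cps[[i]]),
                    error = function(e) {
                      warning(sprintf("checkpoint %d excluded: %s", i,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    if (!is.null(res)) bounds[i] <- res$lower
  }
  if (all(is.na(bounds))) stopf("off-policy evaluation failed on every checkpoint")
  best <- which(bounds == max(bounds, na.rm = TRUE))[1]  # earliest on ties
  out <- cps[[best]]
  out$meta$validation_lower_bound <- bounds[best]
  out$meta$checkpoint_bounds <- bounds
  out$meta$selected <- best
  out
}

#' @export
print.trained_policy <- function(x, ...) {
  cat(sprintf("<trained_policy> %d -> %d Q-network (hidden: %s)%s\n",
              x$net$spec$n_features, x$net$spec$n_actions,
              paste(x$net$spec$hidden, collapse = "x"),
              if (!is.null(x$meta$epoch)) sprintf(", epoch %d", x$meta$epoch) else ""))
  invisible(x)
}

#' Serialize a trained policy to a portable archive
#'
#' Writes the network weights and scaler as JSON with a metadata sidecar.
#'
#' @param trained A `trained_policy`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_trained_policy <- function(trained, path) {
  meta <- trained$meta[setdiff(names(trained$meta), "checkpoint_bounds")]
  if (!is.null(meta$config)) meta$config <- unclass(meta$config)
  obj <- list(spec = unclass(trained$net$spec),
              W = lapply(trained$net$W, function(m) list(dim = dim(m),
                                                         data = as.numeric(m))),
              b = trained$net$b, scaler = trained$scaler,
              meta = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trained policy written by [write_trained_policy()]
#' @param path Path to the JSON archive.
#' @return A `trained_policy`.
#' @export
read_trained_policy <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  spec <- qnet_spec(obj$spec$n_features, obj$spec$n_actions,
                    num(obj$spec$hidden))
  W <- lapply(obj$W, function(w) matrix(num(w$data), w$dim[[1]], w$dim[[2]]))
  net <- structure(list(W = W, b = lapply(obj$b, num), spec = spec),
                   class = "qnet")
  scaler <- if (!is.null(obj$scaler))
    list(center = num(obj$scaler$center), scale = num(obj$scaler$scale))
  new_trained_policy(net, scaler, lapply(obj$meta, function(m)
    if (is.list(m)) lapply(m, unlist) else unlist(m)))
}
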