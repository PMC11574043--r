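#' Gradient-boosted surrogate model of a dosing policy
#'
#' Fits a multiclass gradient-boosted tree model predicting action indices
#' from state features. The surrogate mimics a policy (the clinicians' logged
#' actions, or a learned policy's recommendations) so that tree-based Shapley
#' attributions can explain which features drive the dosing decision.
#' A 20% held-out accuracy is logged and stored.
#'
#' @param states State matrix (rows = patient-steps, named columns).
#' @param actions Integer 0-based action indices, one per row.
#' @param nrounds,max_depth,eta Boosting parameters.
#' @param seed Integer seed (controls the held-out split and boosting).
#' @return An object of class `action_surrogate`.
#' @export
fit_action_surrogate <- function(states, actions, nrounds = 60, max_depth = 4,
                                 eta = 0.3, seed = 1L) {
  lev <- sort(unique(actions))
  if (length(lev) < 2) stopf("surrogate fitting needs at least 2 distinct actions")
  ## compact class coding over observed actions
  y <- match(actions, lev) - 1L
  set.seed(seed)
  n <- nrow(states)
  hold <- sample.int(n, max(1L, round(0.2 * n)))
  dtrain <- xgboost::xgb.DMatrix(states[-hold, , drop = FALSE],
                                 label = y[-hold])
  params <- list(objective = "multi:softprob", num_class = length(lev),
                 max_depth = max_depth, eta = eta, nthread = 1,
                 seed = seed)
  fit <- xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                            verbose = 0)
  ph <- predict(fit, states[hold, , drop = FALSE])
  ph <- matrix(ph, ncol = length(lev), byrow = length(dim(ph)) < 2)
  acc <- mean(lev[max.col(ph)] == actions[hold])
  dexrl_log("info", "surrogate held-out accuracy: %.3f", acc)
  structure(list(fit = fit, levels = lev, features = colnames(states),
                 holdout_accuracy = acc),
            class = "action_surrogate")
}

#' @export
print.action_surrogate <- function(x, ...) {
  cat(sprintf("<action_surrogate> %d classes over %d features; held-out accuracy %.3f\n",
              length(x$levels), length(x$features), x$holdout_accuracy))
  invisible(x)
}

## Per-sample Shapley contributions: array [n, class, feature+bias].
surrogate_shap <- function(surrogate, states) {
  ct <- predict(surrogate$fit, states, predcontrib = TRUE)
  if (is.list(ct)) ct <- simplify2array(ct)  # older return shape
  if (length(dim(ct)) == 2) ct <- array(ct, c(nrow(ct), 1L, ncol(ct)),
                                        dimnames = list(NULL, NULL, colnames(ct)))
  ct
}

#' Shapley-value feature importance of a policy surrogate
#'
#' Computes exact tree-Shapley contributions per sample and class, aggregates
#' across classes by the mean absolute value, and ranks features by their
#' mean absolute attribution. Per sample and class, contributions plus the
#' bias term reproduce the model margin exactly (additivity).
#'
#' @param surrogate An `action_surrogate`.
#' @param states State matrix to explain.
#' @return `data.frame` with `feature` and `mean_abs_shap`, sorted
#'   descending; per-sample contributions in attribute `"contrib"`.
#' @export
shap_importance <- function(surrogate, states) {
  ct <- surrogate_shap(surrogate, states)
  feats <- dimnames(ct)[[3]]
  feats <- feats[feats != "BIAS" & feats != "(Intercept)"]
  fi <- match(feats, dimnames(ct)[[3]])
  m <- apply(abs(ct[, , fi, drop = FALSE]), 3, mean)
  out <- data.frame(feature = feats, mean_abs_shap = as.numeric(m))
  out <- out[order(-out$mean_abs_shap), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contrib") <- ct
  out
}

#' Stratify admissions by policy agreement and delirium occurrence
#'
#' Computes each case's mean absolute dosing difference (in mcg/kg/h, via the
#' bins' representative doses) between the learned and clinician policies
#' across all timesteps, splits cases at the first quartile of those means
#' (at or below = "matched", above = "unmatched"), and crosses the split with
#' delirium occurrence into four subgroups.
#'
#' @param traj_id Trajectory id per timestep.
#' @param aid_actions,clin_actions Aligned 0-based action sequences.
#' @param delirium Named logical (per trajectory id) or logical vector per
#'   timestep.
#' @return `data.frame` with one row per case: `traj`, `mean_abs_diff`,
#'   `matched`, `delirium`, `subgroup`; the quartile threshold in attribute
#'   `"threshold"`.
#' @export
stratify_subgroups <- function(traj_id, aid_actions, clin_actions, delirium) {
  stopifnot(length(aid_actions) == length(clin_actions),
            length(traj_id) == length(aid_actions))
  d <- abs(dose_from_action(aid_actions) - dose_from_action(clin_actions))
  means <- tapply(d, traj_id, mean)
  if (length(delirium) == length(traj_id))
    delirium <- tapply(delirium, traj_id, any)[names(means)]
  else delirium <- delirium[names(means)]
  thr <- quantile(means, 0.25, names = FALSE)  # linear interpolation
  matched <- means <= thr
  out <- data.frame(traj = names(means), mean_abs_diff = as.numeric(means),
                    matched = as.logical(matched),
                    delirium = as.logical(delirium))
  out$subgroup <- paste0(ifelse(out$matched, "matched", "unmatched"), "-",
                         ifelse(out$delirium, "delirium", "no-delirium"))
  empty <- setdiff(c("matched-delirium", "matched-no-delirium",
                     "unmatched-delirium", "unmatched-no-delirium"),
                   unique(out$subgroup))
  if (length(empty))
    dexrl_log("info", "empty subgroups: %s", paste(empty, collapse = ", "))
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' PCA-based Shapley attribution of a dosing policy
#'
#' Standardizes the state features, retains the smallest set of principal
#' components whose cumulative explained variance reaches
#' `variance_threshold`, fits an action surrogate on the component scores,
#' and returns the mean absolute Shapley value per component together with
#' the component loading matrix, so feature combinations driving the policy
#' can be read off the top-ranked components.
#'
#' @param states State matrix (named columns).
#' @param actions 0-based action indices per row (the surrogate target).
#' @param variance_threshold Cumulative explained-variance cutoff in (0, 1].
#' @param ... Passed to [fit_action_surrogate()].
#' @return List with `importance` (component ranking), `loadings`
#'   (orthonormal, features x retained components), `explained_variance`
#'   (fractions for all components), `n_components`, and the fitted
#'   `surrogate`.
#' @export
pca_shap <- function(states, actions, variance_threshold = 0.90, ...) {
  if (!is.numeric(variance_threshold) || variance_threshold <= 0 ||
      variance_threshold > 1)
    stopf("variance_threshold must lie in (0, 1]")
  if (ncol(states) < 2) stopf("PCA needs at least 2 features")
  pc <- prcomp(states, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) >= variance_threshold - 1e-12)[1]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  surrogate <- fit_action_surrogate(scores, actions, ...)
  imp <- shap_importance(surrogate, scores)
  names(imp)[1] <- "component"
  list(importance = imp,
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev, n_components = k, surrogate = surrogate)
}
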