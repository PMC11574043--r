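#' Default end-to-end pipeline configuration
#'
#' Desk-scale settings: a few hundred synthetic admissions, a compact
#' Q-network, and reduced training/evaluation budgets that run on one CPU in
#' minutes. Any entry can be overridden via the `config` argument of
#' [run_pipeline()] (or a YAML/JSON file with the same structure). The
#' full-scale defaults of the underlying constructors
#' ([training_config()], [qnet_spec()]) remain available by setting those
#' values explicitly.
#'
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohort = list(n_patients = 300),
    split = list(k = 5, fractions = c(0.7, 0.1, 0.2)),
    train = list(hidden = c(64, 64), batch_size = 512, epochs = 40,
                 lr = 1e-3, alpha = 1.0, target_sync = 100,
                 checkpoint_every = 10),
    evaluate = list(fqe = list(hidden = c(64, 64), outer_iters = 20,
                               inner_epochs = 2, batch_size = 1024, lr = 1e-3,
                               replicates = 500),
                    wis = list(replicates = 500, p_top = 0.99),
                    behavior = list(floor_prob = 1e-4, maxit = 150)),
    explain = list(nrounds = 40, max_depth = 4, variance_threshold = 0.90),
    gamma = 0.99
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- if (grepl("[.]ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), c(names(base)))
  if (length(unknown))
    stopf("unknown configuration section(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(base, config)
}

#' Run the dosing-policy pipeline
#'
#' Orchestrates the full analysis: `simulate` (synthetic cohort),
#' `preprocess` (6-h state grid), `train` (conservative Q-learning with
#' validation checkpoint selection on fold 1 of the patient-level split),
#' `evaluate` (FQE and WIS for the learned, clinician and random policies,
#' with effective sample size and conservative bound comparison), `explain`
#' (SHAP surrogates, subgroup stratification, PCA attributions), `report`
#' (cohort descriptives and dose comparisons), or `all`. Artifacts are
#' written under `out` with a JSON manifest recording the configuration and
#' seeds; each step reads its inputs from `out`, so partial runs can resume.
#'
#' @param subcommand One of `"simulate"`, `"preprocess"`, `"train"`,
#'   `"evaluate"`, `"explain"`, `"report"`, `"all"`.
#' @param config Configuration list or path to a YAML/JSON file; merged over
#'   [default_pipeline_config()].
#' @param out Output (run) directory.
#' @param seed Master seed; one stream per module is derived from it.
#' @param log_level `"debug"`, `"info"`, or `"warn"`.
#' @return Invisibly, a list of the artifacts produced by the step(s).
#' @export
run_pipeline <- function(subcommand = "all", config = list(), out = "dexrl-run",
                         seed = NULL, log_level = "info") {
  subcommand <- match.arg(subcommand, c("all", "simulate", "preprocess",
                                        "train", "evaluate", "explain",
                                        "report"))
  old <- options(dexrl.log_level = log_level)
  on.exit(options(old), add = TRUE)
  cfg <- read_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(config = cfg, package_version =
                              as.character(utils::packageVersion("dexrl")),
                            created = format(Sys.time(), tz = "UTC")),
                       file.path(out, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  steps <- if (subcommand == "all")
    c("simulate", "preprocess", "train", "evaluate", "explain", "report")
  else subcommand
  art <- list()
  for (s in steps) {
    dexrl_log("info", "step: %s", s)
    art[[s]] <- switch(s,
      simulate = step_simulate(cfg, out),
      preprocess = step_preprocess(cfg, out),
      train = step_train(cfg, out),
      evaluate = step_evaluate(cfg, out),
      explain = step_explain(cfg, out),
      report = step_report(cfg, out))
  }
  invisible(art)
}

step_simulate <- function(cfg, out) {
  cc <- do.call(cohort_config, utils::modifyList(
    cfg$cohort, list(seed = derive_seed(cfg$seed, 11L), gamma = cfg$gamma)))
  cohort <- generate_cohort(cc)
  write_cohort(cohort, file.path(out, "cohort"))
  cohort
}

step_preprocess <- function(cfg, out) {
  cohort <- read_cohort(file.path(out, "cohort"))
  dg <- preprocess_cohort(cohort)
  write_grid(dg, file.path(out, "grid"))
  dg
}

load_grid <- function(out) {
  g <- read_tsv(file.path(out, "grid", "state_grid.tsv"))
  man <- jsonlite::read_json(file.path(out, "grid", "grid_manifest.json"),
                             simplifyVector = TRUE)
  structure(list(grid = g, manifest = man,
                 rejections = read_tsv(file.path(out, "grid", "rejections.tsv"))),
            class = "dex_grid")
}

step_train <- function(cfg, out) {
  dg <- load_grid(out)
  tr <- make_transitions(dg)
  plan <- split_patients(dg$grid$patient_id[!duplicated(dg$grid$admission_id)],
                         k = cfg$split$k, fractions = cfg$split$fractions,
                         seed = derive_seed(cfg$seed, 13L))
  write_split_plan(plan, file.path(out, "split_plan.json"))
  fold <- plan$folds[[1]]
  pat_of <- setNames(dg$grid$patient_id, dg$grid$admission_id)
  adm_in <- function(pats) unique(dg$grid$admission_id[dg$grid$patient_id %in% pats])
  tcfg <- do.call(training_config, utils::modifyList(
    cfg$train[setdiff(names(cfg$train), "hidden")],
    list(gamma = cfg$gamma, seed = derive_seed(cfg$seed, 17L))))
  spec <- qnet_spec(ncol(tr$s), hidden = cfg$train$hidden)
  fit <- train_cql(subset_transitions(tr, adm_in(fold$train)), tcfg, spec)
  fcfg <- do.call(fqe_config, utils::modifyList(
    cfg$evaluate$fqe, list(gamma = cfg$gamma, seed = derive_seed(cfg$seed, 19L))))
  pol <- select_checkpoint(fit, subset_transitions(tr, adm_in(fold$validation)),
                           fcfg)
  write_trained_policy(pol, file.path(out, "policy.json"))
  loss <- data.frame(epoch = seq_along(fit$loss_trace), loss = fit$loss_trace)
  write_tsv(loss, file.path(out, "training_loss.tsv"))
  pol
}

step_evaluate <- function(cfg, out) {
  dg <- load_grid(out)
  tr <- make_transitions(dg)
  plan <- jsonlite::read_json(file.path(out, "split_plan.json"),
                              simplifyVector = FALSE)
  test_pats <- unlist(plan$folds[[1]]$test)
  test_adm <- unique(dg$grid$admission_id[dg$grid$patient_id %in% test_pats])
  tr_test <- subset_transitions(tr, test_adm)
  pol <- read_trained_policy(file.path(out, "policy.json"))

  fcfg <- do.call(fqe_config, utils::modifyList(
    cfg$evaluate$fqe, list(gamma = cfg$gamma, seed = derive_seed(cfg$seed, 23L))))
  ## propensity model (with confounders) for importance weights; a
  ## state-only model to represent the clinicians' policy as an evaluable rule
  behavior <- do.call(fit_behavior_policy, c(list(tr), cfg$evaluate$behavior))
  tr_state <- tr
  tr_state$conf <- NULL
  behavior_state <- do.call(fit_behavior_policy,
                            c(list(tr_state), cfg$evaluate$behavior))
  clin_soft <- soften(behavior_modal_policy(behavior_state),
                      cfg$evaluate$wis$p_top)
  aid_soft <- soften(policy_greedy(pol), cfg$evaluate$wis$p_top)
  rand <- random_policy()

  results <- list(
    aid_fqe = fqe(policy_greedy(pol), tr_test, fcfg),
    clinicians_fqe = fqe(clin_soft, tr_test, fcfg),
    random_fqe = fqe(rand, tr_test, fcfg),
    aid_wis = wis(aid_soft, behavior, tr_test, gamma = cfg$gamma,
                  replicates = cfg$evaluate$wis$replicates,
                  seed = derive_seed(cfg$seed, 29L)),
    clinicians_wis = wis(clin_soft, behavior, tr_test, gamma = cfg$gamma,
                         replicates = cfg$evaluate$wis$replicates,
                         seed = derive_seed(cfg$seed, 31L)),
    random_wis = wis(rand, behavior, tr_test, gamma = cfg$gamma,
                     replicates = cfg$evaluate$wis$replicates,
                     seed = derive_seed(cfg$seed, 37L))
  )
  tab <- ope_table(results)
  tab$verdict_vs_clinicians <- c(
    compare_policies(results$aid_fqe, results$clinicians_fqe), "", "",
    compare_policies(results$aid_wis, results$clinicians_wis), "", "")
  write_tsv(tab, file.path(out, "ope_results.tsv"))
  jsonlite::write_json(lapply(results, function(r)
    r[c("method", "estimate", "lower", "upper", "ess", "n_traj")]),
    file.path(out, "ope_results.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  results
}

## Deterministic policy following the behavior model's modal action.
behavior_modal_policy <- function(behavior) {
  n_state <- behavior$n_state_features
  new_policy(function(S) {
    conf <- if (ncol(S) > n_state) S[, -(seq_len(n_state)), drop = FALSE]
    P <- behavior_probs(behavior, S[, seq_len(n_state), drop = FALSE], conf)
    a <- max.col(P, ties.method = "first")
    out <- matrix(0, nrow(S), behavior$n_actions)
    out[cbind(seq_len(nrow(S)), a)] <- 1
    out
  }, n_actions = behavior$n_actions, kind = "behavior-modal",
  deterministic = TRUE)
}

step_explain <- function(cfg, out) {
  dg <- load_grid(out)
  tr <- make_transitions(dg)
  pol <- read_trained_policy(file.path(out, "policy.json"))
  S <- tr$s
  aid_a <- greedy_action(pol, S)
  seed <- derive_seed(cfg$seed, 41L)
  sur_clin <- fit_action_surrogate(S, tr$a, nrounds = cfg$explain$nrounds,
                                   max_depth = cfg$explain$max_depth,
                                   seed = seed)
  sur_aid <- fit_action_surrogate(S, aid_a, nrounds = cfg$explain$nrounds,
                                  max_depth = cfg$explain$max_depth,
                                  seed = seed)
  imp_clin <- shap_importance(sur_clin, S)
  imp_aid <- shap_importance(sur_aid, S)
  write_tsv(imp_clin, file.path(out, "shap_clinicians.tsv"))
  write_tsv(imp_aid, file.path(out, "shap_aid.tsv"))
  del <- tapply(dg$grid$delirium, dg$grid$admission_id, any)
  sub <- stratify_subgroups(tr$traj, aid_a, tr$a, del)
  write_tsv(sub, file.path(out, "subgroups.tsv"))
  pca <- pca_shap(S, aid_a, cfg$explain$variance_threshold,
                  nrounds = cfg$explain$nrounds, seed = seed)
  write_tsv(pca$importance, file.path(out, "pca_shap_importance.tsv"))
  write_tsv(cbind(feature = rownames(pca$loadings),
                  as.data.frame(pca$loadings)),
            file.path(out, "pca_loadings.tsv"))
  list(clinicians = imp_clin, aid = imp_aid, subgroups = sub, pca = pca)
}

step_report <- function(cfg, out) {
  dg <- load_grid(out)
  g <- dg$grid
  del_by_adm <- tapply(g$delirium, g$admission_id, any)
  adm <- g[!duplicated(g$admission_id), ]
  tab <- cohort_table(adm, del_by_adm[adm$admission_id],
                      continuous = c("age", "bmi", "heart_rate", "gcs", "rass"),
                      categorical = c("sex", "vent", "shock", "rrt"))
  del_steps <- g$admission_id %in% names(del_by_adm)[del_by_adm]
  cmp <- compare_dose_distributions(g$dose[del_steps], g$dose[!del_steps],
                                    seed = derive_seed(cfg$seed, 43L))
  write_tsv(tab$continuous, file.path(out, "cohort_continuous.tsv"))
  if (!is.null(tab$categorical))
    write_tsv(tab$categorical, file.path(out, "cohort_categorical.tsv"))
  jsonlite::write_json(list(
    dose_comparison = cmp,
    delirium_incidence = mean(del_by_adm)),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
  list(table = tab, dose_comparison = cmp,
       delirium_incidence = mean(del_by_adm))
}
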