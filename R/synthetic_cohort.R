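#' Default state-feature schema for the synthetic ICU cohort
#'
#' Sixteen bedside features: vital signs, ventilatory and laboratory values,
#' the summed Glasgow Coma Scale, the Richmond Agitation-Sedation Scale, and
#' the dexmedetomidine rate administered over the previous 6-h step. Each row
#' carries the generative parameters (`mu`, `load`, `sd`: feature value =
#' `mu + load * severity + noise`), observation noise, physiological
#' plausibility bounds used for outlier removal, the expected number of
#' measurements per 6-h step (`rate`), and the probability that a step has no
#' measurement at all (`miss_prob`).
#'
#' `gcs` is observed as its three components (eye/verbal/motor) in raw
#' records and summed during preprocessing; `dex_prev` is derived from the
#' dose history rather than measured. All generative parameters are artifact
#' choices of this package: the real registry cohorts the analysis was
#' designed for are not redistributable, so the schema emulates their
#' structure, not their marginals.
#'
#' @return A `data.frame`, one row per feature.
#' @export
default_feature_schema <- function() {
  sch <- data.frame(
    name     = c("heart_rate", "sbp", "resp_rate", "spo2", "body_temp",
                 "fio2", "ph", "lactate", "creatinine", "bilirubin",
                 "platelet", "wbc", "hemoglobin", "gcs", "rass", "dex_prev"),
    mu       = c(86, 118, 18, 97, 36.9, 0.45, 7.38, 1.8, 1.1, 1.0,
                 180, 10, 10.5, 13, 0, 0),
    load     = c(10, -8, 3, -1.5, 0.3, 0.08, -0.03, 0.9, 0.5, 0.6,
                 -40, 2.5, -0.8, 0, 0, 0),
    sd       = c(8, 10, 3, 1.5, 0.3, 0.06, 0.03, 0.5, 0.3, 0.4,
                 30, 2, 0.8, 1, 0.8, 0),
    obs_sd   = c(2, 3, 1, 0.5, 0.1, 0.02, 0.01, 0.1, 0.05, 0.08,
                 5, 0.4, 0.2, 0, 0, 0),
    lower    = c(20, 30, 4, 50, 30, 0.21, 6.8, 0.1, 0.1, 0.05,
                 1, 0.1, 3, 3, -5, 0),
    upper    = c(300, 300, 60, 100, 43, 1.0, 7.8, 20, 15, 30,
                 1000, 100, 20, 15, 4, 1.5),
    rate     = c(2, 2, 2, 2, 1, 1, 0.4, 0.3, 0.3, 0.25,
                 0.25, 0.3, 0.3, 1, 1, NA),
    miss_prob = c(0.02, 0.02, 0.02, 0.02, 0.05, 0.10, 0.55, 0.60, 0.55, 0.65,
                  0.55, 0.55, 0.55, 0.10, 0.05, NA),
    digits   = c(0, 0, 0, 0, 1, 2, 2, 1, 2, 2, 0, 1, 1, 0, 0, 1),
    kind     = c(rep("dynamic", 13), "gcs", "rass", "dex_prev"),
    stringsAsFactors = FALSE
  )
  sch
}

## Features whose standardized deviations define the latent severity score
## that drives both the delirium hazard and the state-dependent optimal dose.
severity_features <- function() {
  c(heart_rate = 1, fio2 = 1, lactate = 1, wbc = 1, platelet = -1,
    hemoglobin = -1)
}

#' Configuration of the synthetic ICU cohort generator
#'
#' Defines the study conditions the simulator emulates: cohort size, the 6-h
#' grid horizon, the feature schema, the per-step delirium hazard model, the
#' clinician-like dosing behavior rule, and the discharge process.
#'
#' The per-step delirium hazard is
#' `plogis(intercept + dose_dev * (dose - d*(state))^2 + severity * sev +
#' deep_sedation * 1[RASS <= -3])`, where `d*(state)` is a state-dependent
#' optimal dose `clip(base + severity_gain * sev, min, max)`. Both
#' under-dosing and over-dosing therefore raise the hazard. The defaults give
#' roughly a 30% delirium incidence under the clinician behavior rule, an
#' average stay around 10 six-hour steps, and a clinician policy that
#' systematically doses about 0.2 mcg/kg/h above the optimum while titrating
#' in 0.1 mcg/kg/h increments.
#'
#' @param n_patients Number of patients; about 5% contribute two admissions.
#' @param max_timesteps Maximum trajectory length in 6-h steps (>= 2).
#' @param feature_schema Feature schema, see [default_feature_schema()].
#' @param hazard_params List: `intercept`, `dose_dev`, `severity`,
#'   `deep_sedation` (log-odds scale).
#' @param behavior_params List: `bias` (clinician systematic offset from the
#'   optimal dose, mcg/kg/h), `clinician_sd` (between-admission spread of
#'   that offset), `step_sd` (per-step target jitter), `inertia` (probability
#'   of leaving the previous rate unchanged), `titration` (adjustment
#'   increment, mcg/kg/h).
#' @param optimal_dose List: `base`, `severity_gain`, `min`, `max` defining
#'   `d*(state)` in mcg/kg/h.
#' @param discharge_hazard Per-step probability of ICU discharge.
#' @param readmission_prob Probability a patient has a second admission.
#' @param gamma Discount factor used for returns.
#' @param outlier_prob Probability a raw measurement is corrupted by a
#'   decimal-place error (exercises plausibility-bound outlier removal).
#' @param verbal_missing_prob Probability the verbal GCS component is not
#'   assessable (e.g. intubation), exercising the conversion table.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 500,
                          max_timesteps = 20,
                          feature_schema = default_feature_schema(),
                          hazard_params = list(intercept = -4.0, dose_dev = 10,
                                               severity = 0.6, deep_sedation = 0.4),
                          behavior_params = list(bias = 0.2, clinician_sd = 0.15,
                                                 step_sd = 0.05, inertia = 0.25,
                                                 titration = 0.1),
                          optimal_dose = list(base = 0.35, severity_gain = 0.25,
                                              min = 0, max = 1.2),
                          discharge_hazard = 0.08,
                          readmission_prob = 0.05,
                          gamma = 0.99,
                          outlier_prob = 0.002,
                          verbal_missing_prob = 0.3,
                          seed = 1L) {
  check_number(n_patients, "n_patients", lower = 1, integer = TRUE)
  check_number(max_timesteps, "max_timesteps", lower = 2, integer = TRUE)
  check_number(discharge_hazard, "discharge_hazard", lower = 0, upper = 1)
  check_number(readmission_prob, "readmission_prob", lower = 0, upper = 1)
  check_number(gamma, "gamma", lower = 1e-8, upper = 1)
  check_number(outlier_prob, "outlier_prob", lower = 0, upper = 1)
  check_number(verbal_missing_prob, "verbal_missing_prob", lower = 0, upper = 1)
  check_number(seed, "seed", integer = TRUE)
  for (f in c("intercept", "dose_dev", "severity", "deep_sedation"))
    check_number(hazard_params[[f]] %||% NA, paste0("hazard_params$", f))
  for (f in c("bias", "clinician_sd", "step_sd", "inertia", "titration"))
    check_number(behavior_params[[f]] %||% NA, paste0("behavior_params$", f))
  check_number(behavior_params$inertia, "behavior_params$inertia", 0, 1)
  for (f in c("base", "severity_gain", "min", "max"))
    check_number(optimal_dose[[f]] %||% NA, paste0("optimal_dose$", f))
  sch <- feature_schema
  need <- c("name", "lower", "upper", "rate", "miss_prob", "kind")
  if (!is.data.frame(sch) || !all(need %in% names(sch)))
    stopf("configuration field 'feature_schema' must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  if (any(sch$lower >= sch$upper))
    stopf("configuration field 'feature_schema' has lower >= upper for: %s",
          paste(sch$name[sch$lower >= sch$upper], collapse = ", "))
  mp <- sch$miss_prob[!is.na(sch$miss_prob)]
  if (any(mp < 0 | mp > 1))
    stopf("configuration field 'feature_schema$miss_prob' must lie in [0,1]")
  structure(list(n_patients = as.integer(n_patients),
                 max_timesteps = as.integer(max_timesteps),
                 feature_schema = sch, hazard_params = hazard_params,
                 behavior_params = behavior_params, optimal_dose = optimal_dose,
                 discharge_hazard = discharge_hazard,
                 readmission_prob = readmission_prob, gamma = gamma,
                 outlier_prob = outlier_prob,
                 verbal_missing_prob = verbal_missing_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

snap_dose <- function(x) pmin(1.5, pmax(0, round(x * 10) / 10))

## Severity score from a state matrix (columns in schema order): a weighted
## mean of standardized deviations of the marker features, normalized so the
## score tracks the latent severity with unit gain.
severity_score <- function(X, schema) {
  w <- severity_features()
  idx <- match(names(w), schema$name)
  Z <- sweep(X[, idx, drop = FALSE], 2, schema$mu[idx], "-")
  Z <- sweep(Z, 2, schema$sd[idx], "/")
  gain <- mean(abs(schema$load[idx] / schema$sd[idx]))
  as.numeric(Z %*% w) / (length(w) * gain)
}

optimal_dose_of <- function(sev_score, od) {
  pmin(od$max, pmax(od$min, od$base + od$severity_gain * sev_score))
}

step_hazard <- function(dose, d_star, sev_score, rass, hp) {
  plogis(hp$intercept + hp$dose_dev * (dose - d_star)^2 +
           hp$severity * sev_score + hp$deep_sedation * (rass <= -3))
}

## Core trajectory engine, vectorized across admissions. Generates the true
## 6-h grid (no measurement noise / missingness). When `policy` is NULL the
## clinician behavior rule doses; otherwise the supplied policy is applied to
## the current state matrix. With `disable_events = TRUE` no absorption is
## sampled (full-horizon "ghost" paths with hazards recorded), which supports
## analytic integration of the delirium incidence.
sim_engine <- function(config, n, seed, policy = NULL, disable_events = FALSE,
                       statics = NULL) {
  set.seed(seed)
  sch <- config$feature_schema
  H <- config$max_timesteps
  p <- nrow(sch)
  hp <- config$hazard_params
  bp <- config$behavior_params
  dh <- config$discharge_hazard
  dyn <- which(sch$kind == "dynamic")
  i_gcs <- which(sch$name == "gcs"); i_rass <- which(sch$name == "rass")
  i_prev <- which(sch$name == "dex_prev")

  if (is.null(statics)) statics <- sim_statics(n)
  sev <- rnorm(n) + 0.3 * statics$shock + 0.2 * statics$rrt

  states <- array(NA_real_, c(n, p, H),
                  dimnames = list(NULL, sch$name, NULL))
  doses <- matrix(NA_real_, n, H)
  hazards <- matrix(NA_real_, n, H)
  dstars <- matrix(NA_real_, n, H)
  term_step <- rep(NA_integer_, n)
  onset_step <- rep(NA_integer_, n)
  clin_eta <- rnorm(n, 0, bp$clinician_sd)
  dose_prev <- rep(0, n)
  sev_t <- sev

  for (t in seq_len(H)) {
    live <- is.na(term_step) | term_step >= t
    if (!any(live)) break
    nl <- sum(live)
    if (t > 1L) sev_t[live] <- 0.9 * sev_t[live] + sqrt(1 - 0.81) * rnorm(nl)
    X <- matrix(0, nl, p, dimnames = list(NULL, sch$name))
    for (j in dyn)
      X[, j] <- pmin(sch$upper[j], pmax(sch$lower[j],
        sch$mu[j] + sch$load[j] * sev_t[live] + rnorm(nl, 0, sch$sd[j])))
    dp <- dose_prev[live]
    X[, i_rass] <- pmin(4, pmax(-5, round(0.8 - 2.8 * dp + 0.5 * sev_t[live] +
                                            rnorm(nl, 0, 0.8))))
    X[, i_gcs] <- pmin(15, pmax(3, round(14 - 3.0 * dp - 0.8 * pmax(sev_t[live], 0) +
                                           rnorm(nl, 0, 1))))
    X[, i_prev] <- dp
    states[live, , t] <- X

    ## rows reaching their scheduled terminal step stop here
    decide <- live & (is.na(term_step))
    if (!any(decide)) next
    Xd <- states[decide, , t, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(Xd))) Xd <- matrix(Xd, nrow = 1, dimnames = list(NULL, sch$name))
    sc <- severity_score(Xd, sch)
    d_star <- optimal_dose_of(sc, config$optimal_dose)
    nd <- nrow(Xd)

    if (is.null(policy)) {
      target <- pmin(1.5, pmax(0, d_star + bp$bias + clin_eta[decide] +
                                 rnorm(nd, 0, bp$step_sd)))
      if (t == 1L) {
        dose <- pmax(bp$titration, snap_dose(target))
      } else {
        prev <- dose_prev[decide]
        keep <- runif(nd) < bp$inertia
        want <- snap_dose(target)
        move <- sign(want - prev) * pmin(abs(want - prev), bp$titration)
        dose <- ifelse(keep, prev, snap_dose(prev + move))
      }
    } else {
      a <- policy_act(policy, Xd)
      dose <- a / 10
    }
    doses[decide, t] <- dose
    haz <- step_hazard(dose, d_star, sc, Xd[, i_rass], hp)
    hazards[decide, t] <- haz
    dstars[decide, t] <- d_star
    dose_prev[decide] <- dose

    if (!disable_events) {
      u1 <- runif(nd); u2 <- runif(nd)
      del <- u1 < haz
      if (t == H - 1L) {
        term_step[decide] <- H
        onset_step[decide][del] <- H
      } else if (t < H - 1L) {
        disch <- !del & (u2 < dh)
        idx <- which(decide)
        term_step[idx[del | disch]] <- t + 1L
        onset_step[idx[del]] <- t + 1L
      }
    }
  }
  if (disable_events) term_step <- rep(H, n)
  ## terminal-step doses (clinicians keep the last rate; never used in a
  ## transition)
  for (i in seq_len(n)) doses[i, term_step[i]] <- doses[i, term_step[i] - 1L]
  list(states = states, doses = doses, end_step = term_step,
       onset_step = onset_step, statics = statics, sev0 = sev,
       hazards = hazards, d_star = dstars)
}

sim_statics <- function(n) {
  age <- round(rnorm(n, 65, 12))
  age <- pmin(95, pmax(21, age))
  minors <- runif(n) < 0.005
  age[minors] <- sample(15:17, sum(minors), replace = TRUE)
  sex <- ifelse(runif(n) < 0.63, "male", "female")
  height <- round(rnorm(n, ifelse(sex == "male", 170, 158), 7), 1)
  weight <- round(pmax(35, rnorm(n, 62, 12)), 1)
  data.frame(age = age, sex = sex, height_cm = height, weight_kg = weight,
             bmi = round(weight / (height / 100)^2, 1),
             vent = as.integer(runif(n) < 0.85),
             shock = as.integer(runif(n) < 0.4),
             rrt = as.integer(runif(n) < 0.2),
             ecmo = as.integer(runif(n) < 0.01))
}

#' Generate a synthetic ICU cohort as raw bedside records
#'
#' Simulates admissions on the true 6-h grid and then emits irregularly
#' timed, noisy, partially missing raw records: an observations table
#' (feature measurements with timestamps in hours from first dexmedetomidine
#' administration), a dose table (infusion rate per 6-h step), a medication
#' table (binary co-medication flags; antipsychotic administration marks
#' delirium treatment), and an admissions table with static covariates and
#' outcome times.
#'
#' @param config A [cohort_config()].
#' @param keep_truth If `TRUE`, attach the generative ground truth (per-step
#'   hazards, optimal doses, latent severity) as attribute `"truth"`.
#' @return An object of class `dex_cohort`: a list with elements
#'   `observations`, `doses`, `meds`, `admissions`, and `config`.
#' @export
generate_cohort <- function(config, keep_truth = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, 1L))
  n_extra <- rbinom(1, config$n_patients, config$readmission_prob)
  pat_ids <- sprintf("pt%05d", seq_len(config$n_patients))
  adm_pat <- c(seq_len(config$n_patients),
               sample(config$n_patients, n_extra, replace = FALSE))
  n <- length(adm_pat)
  statics_pat <- sim_statics(config$n_patients)
  statics <- statics_pat[adm_pat, , drop = FALSE]
  rownames(statics) <- NULL

  eng <- sim_engine(config, n, seed = derive_seed(config$seed, 2L),
                    statics = statics)
  set.seed(derive_seed(config$seed, 3L))
  sch <- config$feature_schema
  adm_ids <- sprintf("adm%05d", seq_len(n))

  obs <- emit_observations(eng, config, adm_ids)
  dose_rows <- lapply(seq_len(n), function(i) {
    T_i <- eng$end_step[i]
    data.frame(admission_id = adm_ids[i], time_h = 6 * (seq_len(T_i) - 1),
               dose = eng$doses[i, seq_len(T_i)])
  })
  doses <- do.call(rbind, dose_rows)

  onset_h <- ifelse(is.na(eng$onset_step), NA_real_,
                    6 * (eng$onset_step - 1L) + runif(n, 0.5, 5.5))
  meds <- data.frame(admission_id = character(0), med = character(0),
                     time_h = numeric(0))
  got <- which(!is.na(onset_h))
  if (length(got))
    meds <- rbind(meds, data.frame(
      admission_id = adm_ids[got],
      med = sample(c("haloperidol", "quetiapine"), length(got), replace = TRUE),
      time_h = onset_h[got]))
  prop <- which(runif(n) < 0.3)
  if (length(prop))
    meds <- rbind(meds, data.frame(
      admission_id = adm_ids[prop], med = "propofol",
      time_h = runif(length(prop), 0, 6 * (eng$end_step[prop] - 1) + 3)))
  meds <- meds[order(meds$admission_id, meds$time_h), , drop = FALSE]
  rownames(meds) <- NULL

  followup_d <- eng$end_step * 0.25
  los <- round(followup_d + rexp(n, 1) + rexp(n, 0.5), 1)
  los <- los + ifelse(runif(n) < 0.01, 28, 0)
  admissions <- cbind(
    data.frame(admission_id = adm_ids, patient_id = pat_ids[adm_pat]),
    statics,
    data.frame(delirium_onset_h = onset_h,
               discharge_h = 6 * eng$end_step,
               icu_los_days = pmax(los, followup_d))
  )
  out <- structure(list(observations = obs, doses = doses, meds = meds,
                        admissions = admissions, config = config),
                   class = "dex_cohort")
  if (keep_truth)
    attr(out, "truth") <- list(hazards = eng$hazards, d_star = eng$d_star,
                               end_step = eng$end_step,
                               onset_step = eng$onset_step, sev0 = eng$sev0,
                               states = eng$states, doses = eng$doses)
  out
}

## Expand the true grid into noisy, irregularly timed measurement rows.
emit_observations <- function(eng, config, adm_ids) {
  sch <- config$feature_schema
  n <- length(adm_ids)
  rows <- vector("list", nrow(sch) + 2L)
  k <- 0L
  grid <- data.table::data.table(
    i = rep(seq_len(n), times = eng$end_step),
    step = unlist(lapply(eng$end_step, seq_len)) - 1L
  )
  for (j in seq_len(nrow(sch))) {
    if (sch$kind[j] == "dex_prev") next
    truev <- eng$states[cbind(grid$i, j, grid$step + 1L)]
    present <- runif(nrow(grid)) >= sch$miss_prob[j]
    nme <- ifelse(present, 1L + rpois(nrow(grid), max(sch$rate[j] - 1, 0)), 0L)
    idx <- rep(seq_len(nrow(grid)), nme)
    if (!length(idx)) next
    tt <- 6 * grid$step[idx] + runif(length(idx), 0, 6 - 1e-9)
    if (sch$kind[j] == "gcs") {
      g <- truev[idx]
      eye <- pmin(4, pmax(1, round(g * 4 / 15)))
      motor <- pmin(6, pmax(1, round(g * 6 / 15)))
      verbal <- pmin(5, pmax(1, g - eye - motor))
      vmiss <- runif(length(idx)) < config$verbal_missing_prob
      comp <- data.frame(
        admission_id = rep(adm_ids[grid$i[idx]], 3),
        feature = rep(c("gcs_eye", "gcs_verbal", "gcs_motor"), each = length(idx)),
        time_h = rep(tt, 3),
        value = c(eye, ifelse(vmiss, NA_real_, verbal), motor))
      comp <- comp[!is.na(comp$value), , drop = FALSE]
      k <- k + 1L; rows[[k]] <- comp
    } else {
      val <- truev[idx] + rnorm(length(idx), 0, sch$obs_sd[j])
      gross <- runif(length(idx)) < config$outlier_prob
      val[gross] <- val[gross] * 10
      val <- round(val, sch$digits[j])
      k <- k + 1L
      rows[[k]] <- data.frame(admission_id = adm_ids[grid$i[idx]],
                              feature = sch$name[j], time_h = tt, value = val)
    }
  }
  obs <- do.call(rbind, rows[seq_len(k)])
  obs <- obs[order(obs$admission_id, obs$feature, obs$time_h), , drop = FALSE]
  rownames(obs) <- NULL
  obs
}

#' Monte-Carlo ground-truth value of a dosing policy
#'
#' Rolls the synthetic environment forward under a given policy and returns
#' the mean discounted return with its Monte-Carlo standard error. Because
#' each trajectory carries exactly one nonzero reward (-1 at delirium onset,
#' +1 at a delirium-free terminal step), the per-rollout return is
#' `gamma^(T-2) * r_last` for a trajectory of `T` grid steps.
#'
#' @param policy A `dex_policy` (see [policy_probs()]); `NULL` evaluates the
#'   built-in clinician behavior rule.
#' @param config A [cohort_config()]; `config$gamma` supplies the discount.
#' @param n_rollouts Number of simulated admissions (>= 2).
#' @param seed Integer seed for the rollouts.
#' @return List with `value`, `se`, `n`, and the per-rollout `returns`.
#' @export
true_policy_value <- function(policy = NULL, config, n_rollouts = 5000,
                              seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  check_number(n_rollouts, "n_rollouts", lower = 2, integer = TRUE)
  eng <- sim_engine(config, n_rollouts, seed = seed, policy = policy)
  r_last <- ifelse(is.na(eng$onset_step), 1, -1)
  G <- config$gamma^(eng$end_step - 2L) * r_last
  list(value = mean(G), se = sd(G) / sqrt(n_rollouts), n = n_rollouts,
       returns = G)
}

#' Analytically integrated delirium incidence of the behavior policy
#'
#' Simulates full-horizon state/dose paths with event sampling disabled and
#' integrates the per-step delirium hazard against the discharge process,
#' giving the model-implied incidence independently of sampled delirium
#' events. Used as an oracle to validate the event sampler.
#'
#' @param config A [cohort_config()].
#' @param n Number of integrated paths.
#' @param seed Integer seed.
#' @return List with `incidence` (mean probability of delirium per admission)
#'   and `se` (Monte-Carlo standard error over paths).
#' @export
expected_incidence <- function(config, n = 2000, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  eng <- sim_engine(config, n, seed = seed, disable_events = TRUE)
  H <- config$max_timesteps
  dh <- config$discharge_hazard
  surv <- rep(1, n)
  pdel <- rep(0, n)
  for (t in seq_len(H - 1L)) {
    p <- eng$hazards[, t]
    pdel <- pdel + surv * p
    if (t < H - 1L) surv <- surv * (1 - p) * (1 - dh)
  }
  list(incidence = mean(pdel), se = sd(pdel) / sqrt(n))
}

#' Write a synthetic cohort to delimited files
#'
#' Writes `observations.tsv`, `doses.tsv`, `meds.tsv`, `admissions.tsv` and a
#' `cohort_config.json` sidecar echoing the generator configuration and seed.
#'
#' @param cohort A `dex_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dex_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$observations, file.path(dir, "observations.tsv"))
  write_tsv(cohort$doses, file.path(dir, "doses.tsv"))
  write_tsv(cohort$meds, file.path(dir, "meds.tsv"))
  write_tsv(cohort$admissions, file.path(dir, "admissions.tsv"))
  cfg <- unclass(cohort$config)
  cfg$feature_schema <- as.list(cfg$feature_schema)
  jsonlite::write_json(cfg, file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir Directory containing the cohort tables.
#' @return A `dex_cohort` (config restored from the JSON sidecar).
#' @export
read_cohort <- function(dir) {
  cfg_path <- file.path(dir, "cohort_config.json")
  if (!file.exists(cfg_path)) stopf("input file not found: %s", cfg_path)
  cfgj <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  cfgj$feature_schema <- as.data.frame(cfgj$feature_schema,
                                       stringsAsFactors = FALSE)
  cfg <- do.call(cohort_config, cfgj[setdiff(names(cfgj), NULL)])
  structure(list(observations = read_tsv(file.path(dir, "observations.tsv")),
                 doses = read_tsv(file.path(dir, "doses.tsv")),
                 meds = read_tsv(file.path(dir, "meds.tsv")),
                 admissions = read_tsv(file.path(dir, "admissions.tsv")),
                 config = cfg),
            class = "dex_cohort")
}

#' @export
print.dex_cohort <- function(x, ...) {
  cat(sprintf("<dex_cohort> %d admissions, %d observation rows, %d delirium onsets\n",
              nrow(x$admissions), nrow(x$observations),
              sum(!is.na(x$admissions$delirium_onset_h))))
  invisible(x)
}

#' Simulate grid-level MDP transitions directly
#'
#' Runs the trajectory engine and assembles transitions without the raw
#' record emission / preprocessing round trip: states are the true grid
#' values, actions the administered dose bins, rewards the terminal reward
#' scheme. Useful for simulation studies at scales where record-level
#' preprocessing adds nothing.
#'
#' @param config A [cohort_config()].
#' @param n Number of admissions.
#' @param seed Integer seed.
#' @param policy Optional `dex_policy` replacing the clinician behavior rule.
#' @return A `dex_transitions` with static confounders (age, sex, bmi, rrt,
#'   vent, shock) attached.
#' @export
simulate_transitions <- function(config, n, seed = 1L, policy = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  eng <- sim_engine(config, n, seed = seed, policy = policy)
  sch <- config$feature_schema
  p <- nrow(sch)
  ids <- sprintf("sim%06d", seq_len(n))
  Ts <- eng$end_step
  n_tr <- Ts - 1L
  i_adm <- rep(seq_len(n), n_tr)
  t_src <- unlist(lapply(n_tr, seq_len))           # source step per transition
  s <- matrix(eng$states[cbind(rep(i_adm, each = p),
                               rep(seq_len(p), length(i_adm)),
                               rep(t_src, each = p))],
              ncol = p, byrow = TRUE, dimnames = list(NULL, sch$name))
  sp <- matrix(eng$states[cbind(rep(i_adm, each = p),
                                rep(seq_len(p), length(i_adm)),
                                rep(t_src + 1L, each = p))],
               ncol = p, byrow = TRUE, dimnames = list(NULL, sch$name))
  terminal <- t_src == (Ts[i_adm] - 1L)
  sp[terminal, ] <- NA_real_
  r <- numeric(length(i_adm))
  r[terminal] <- ifelse(is.na(eng$onset_step[i_adm[terminal]]), 1, -1)
  a <- discretize_dose(eng$doses[cbind(i_adm, t_src)])
  st <- eng$statics
  conf <- cbind(age = st$age, sex = as.integer(st$sex == "male"),
                bmi = st$bmi, rrt = st$rrt, vent = st$vent,
                shock = st$shock)[i_adm, , drop = FALSE]
  first <- !duplicated(i_adm)
  structure(list(s = s, a = a, r = r, sp = sp, terminal = terminal,
                 traj = ids[i_adm], conf = conf,
                 s0 = s[first, , drop = FALSE], s0_traj = ids[i_adm][first],
                 features = sch$name),
            class = "dex_transitions")
}
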