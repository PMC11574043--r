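test_that("cohort generation is deterministic given config and seed", {
  cfg <- cohort_config(n_patients = 10, seed = 1)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$observations, c2$observations)
  expect_identical(c1$doses, c2$doses)
  expect_identical(c1$meds, c2$meds)
  expect_identical(c1$admissions, c2$admissions)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(max_timesteps = 1), "max_timesteps")
  expect_error(cohort_config(discharge_hazard = 1.5), "discharge_hazard")
  expect_error(cohort_config(hazard_params = list(intercept = -4)),
               "hazard_params")
  sch <- default_feature_schema()
  sch$lower[1] <- sch$upper[1] + 1
  expect_error(cohort_config(feature_schema = sch), "lower >= upper")
})

test_that("zero missingness yields a fully observed measurement grid", {
  sch <- default_feature_schema()
  sch$miss_prob[!is.na(sch$miss_prob)] <- 0
  cfg <- cohort_config(n_patients = 5, max_timesteps = 6, feature_schema = sch,
                       outlier_prob = 0, verbal_missing_prob = 0, seed = 3)
  co <- generate_cohort(cfg)
  g <- bin_to_grid(co)
  measured <- setdiff(attr(g, "features"), "dex_prev")
  expect_false(anyNA(g[, measured]))
})

test_that("generated doses lie on the 0.1 mcg/kg/h grid within [0, 1.5]", {
  co <- generate_cohort(small_config())
  d <- co$doses$dose
  expect_true(all(d >= 0 & d <= 1.5))
  expect_true(all(abs(d * 10 - round(d * 10)) < 1e-9))
})

test_that("sampled delirium incidence matches the integrated hazard", {
  cfg <- cohort_config(n_patients = 500, seed = 7)
  co <- generate_cohort(cfg)
  inc_emp <- mean(!is.na(co$admissions$delirium_onset_h))
  n <- nrow(co$admissions)
  oracle <- expected_incidence(cfg, n = 4000, seed = 1234)
  se <- sqrt(inc_emp * (1 - inc_emp) / n + oracle$se^2)
  expect_lt(abs(inc_emp - oracle$incidence), 3 * se)
})

test_that("delirium onset is the first antipsychotic administration", {
  co <- generate_cohort(small_config(), keep_truth = TRUE)
  lab <- label_delirium(co)
  truth <- attr(co, "truth")
  onset_steps <- lab$onset_step[match(sprintf("adm%05d", seq_along(truth$onset_step)),
                                      lab$admission_id)]
  expect_equal(onset_steps, as.integer(truth$onset_step - 1L))
})

test_that("policy value is exact in degenerate environments", {
  ## no hazard, no discharge: every trajectory runs the full horizon and
  ## collects +1 on its last transition
  cfg0 <- cohort_config(n_patients = 10, max_timesteps = 6,
                        hazard_params = list(intercept = -50, dose_dev = 0,
                                             severity = 0, deep_sedation = 0),
                        discharge_hazard = 0, seed = 2)
  v0 <- true_policy_value(constant_policy(0.4), cfg0, n_rollouts = 50, seed = 5)
  expect_equal(v0$value, 0.99^4)
  expect_equal(v0$se, 0)

  ## certain delirium at the first decision: single transition, reward -1
  cfg1 <- cohort_config(n_patients = 10,
                        hazard_params = list(intercept = 50, dose_dev = 0,
                                             severity = 0, deep_sedation = 0),
                        seed = 2)
  v1 <- true_policy_value(constant_policy(0.4), cfg1, n_rollouts = 50, seed = 5)
  expect_equal(v1$value, -1)
})

test_that("Monte-Carlo value estimates are seed-consistent", {
  cfg <- cohort_config(n_patients = 100, seed = 4)
  a <- true_policy_value(NULL, cfg, n_rollouts = 10000, seed = 10)
  b <- true_policy_value(NULL, cfg, n_rollouts = 10000, seed = 20)
  expect_lt(abs(a$value - b$value), 4 * sqrt(a$se^2 + b$se^2))
  expect_error(true_policy_value(NULL, cfg, n_rollouts = 1), "n_rollouts")
})

test_that("stronger dose-deviation hazard raises delirium incidence", {
  mismatched <- constant_policy(1.2)
  hp <- function(k) list(intercept = -4, dose_dev = k, severity = 0.6,
                         deep_sedation = 0.4)
  cfg_lo <- cohort_config(n_patients = 100, hazard_params = hp(4), seed = 6)
  cfg_hi <- cohort_config(n_patients = 100, hazard_params = hp(12), seed = 6)
  lo <- true_policy_value(mismatched, cfg_lo, n_rollouts = 600, seed = 8)
  hi <- true_policy_value(mismatched, cfg_hi, n_rollouts = 600, seed = 9)
  inc <- function(v) mean(v$returns < 0)
  se <- sqrt(inc(lo) * (1 - inc(lo)) / 600 + inc(hi) * (1 - inc(hi)) / 600)
  expect_gt(inc(hi) - inc(lo), 3 * se)
})

test_that("cohort round-trips through delimited files", {
  co <- generate_cohort(cohort_config(n_patients = 8, seed = 5))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$admissions$admission_id, co$admissions$admission_id)
  expect_equal(back$doses$dose, co$doses$dose)
  expect_equal(back$config$seed, co$config$seed)
  expect_equal(nrow(back$observations), nrow(co$observations))
})

test_that("simulated transitions satisfy the MDP contract", {
  cfg <- small_config()
  tr <- simulate_transitions(cfg, 100, seed = 12)
  expect_false(anyNA(tr$s))
  expect_true(all(is.na(tr$sp[tr$terminal, ])))
  expect_false(anyNA(tr$sp[!tr$terminal, ]))
  expect_true(all(tr$a %in% 0:15))
  ## one nonzero terminal reward per trajectory
  expect_true(all(tapply(abs(tr$r), tr$traj, sum) == 1))
  expect_true(all(tr$r[tr$terminal] %in% c(-1, 1)))
  expect_true(all(tr$r[!tr$terminal] == 0))
})
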