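test_that("binning takes within-window medians with half-open windows", {
  g <- bin_to_grid(toy_records(), features = "heart_rate")
  ## window 0 holds {2,4,9} (median 4); the measurement at exactly hour 6
  ## belongs to window 1, so window 1 holds {2,4} (even-count median 3)
  expect_equal(g$heart_rate[g$step == 0], 4)
  expect_equal(g$heart_rate[g$step == 1], 3)
  expect_equal(g$heart_rate[g$step == 2], 7)
  expect_equal(nrow(g), 3)
})

test_that("negative record times are rejected", {
  rec <- toy_records()
  rec$observations$time_h[1] <- -1
  expect_error(bin_to_grid(rec, features = "heart_rate"), "negative")
})

test_that("dex_prev is the previous window's administered dose", {
  rec <- toy_records()
  g <- bin_to_grid(rec, features = c("heart_rate", "dex_prev"))
  expect_equal(g$dex_prev, c(0, 0.2, 0.3))
})

test_that("outlier removal uses closed plausibility intervals", {
  vals <- c(950, 60, 300, 20, 10)
  g <- toy_grid(vals, "heart_rate")
  out <- remove_outliers(g, data.frame(name = "heart_rate", lower = 20, upper = 300))
  expect_equal(is.na(out$heart_rate), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(attr(out, "n_removed"), 2L)
})

test_that("outlier removal counts exactly the implausible cells", {
  set.seed(1)
  g <- data.frame(admission_id = "a1", step = 0:9,
                  f1 = runif(10, 40, 60), f2 = runif(10, 40, 60))
  g$f1[c(2, 7)] <- c(500, -10)
  g$f2[4] <- 900
  attr(g, "features") <- c("f1", "f2")
  out <- remove_outliers(g, data.frame(name = c("f1", "f2"), lower = 0, upper = 100))
  expect_equal(attr(out, "n_removed"), 3L)
})

test_that("interior gaps are filled by inverse-time-distance interpolation", {
  g1 <- toy_grid(c(10, NA, 20), extra = list(f2 = c(1, 2, 3)))
  out1 <- impute_grid(g1, bounds = NULL)
  expect_equal(out1$f1[2], 15)

  g2 <- toy_grid(c(10, NA, NA, 22), extra = list(f2 = c(1, 2, 3, 4)))
  out2 <- impute_grid(g2, bounds = NULL)
  ## gap at t=1: neighbours at t=0 (distance 1) and t=3 (distance 2),
  ## weights 2/3 and 1/3 -> 10 * 2/3 + 22 * 1/3 = 14
  expect_equal(out2$f1[2], 14)
})

test_that("imputation is the identity on complete grids and never touches observed cells", {
  g <- toy_grid(c(10, 12, 14), extra = list(f2 = c(5, 6, 7)))
  expect_equal(impute_grid(g, bounds = NULL), g, ignore_attr = TRUE)

  gm <- toy_grid(c(NA, 12, NA, 18), extra = list(f2 = c(5, 6, 7, 8)))
  out <- impute_grid(gm, bounds = NULL)
  expect_equal(out$f1[c(2, 4)], c(12, 18))
  expect_false(anyNA(out$f1))
})

test_that("a feature never observed anywhere raises a schema error", {
  g <- toy_grid(c(NA, NA, NA), extra = list(f2 = c(1, 2, 3)))
  expect_error(impute_grid(g, bounds = NULL), "never observed")
})

test_that("GCS summation handles complete and single-missing assessments", {
  tab <- gcs_conversion_table()
  expect_equal(sum_gcs(4, 5, 6, tab), 15L)
  expect_equal(sum_gcs(1, 1, 1, tab), 3L)
  ## missing verbal estimated from (eye 4, motor 6) -> 5
  expect_equal(sum_gcs(4, NA, 6, tab), 15L)
  expect_error(sum_gcs(4, NA, NA, tab), "two or more")
})

test_that("dose discretization has 15 uniform positive bins and a zero action", {
  expect_equal(discretize_dose(0), 0L)
  expect_equal(discretize_dose(1.5), 15L)
  expect_equal(discretize_dose(0.25), 3L)  # 0.25 in (0.2, 0.3]
  expect_equal(discretize_dose(0.1), 1L)   # upper edge stays in its bin
  expect_equal(discretize_dose(0.1000001), 2L)
  ## round trip over the whole action space
  expect_equal(discretize_dose(dose_from_action(0:15)), 0:15)
  expect_error(discretize_dose(1.6), "outside")
  expect_error(discretize_dose(-0.1), "outside")
})

test_that("delirium is labelled at the first antipsychotic administration", {
  rec <- toy_records()
  rec$meds <- data.frame(admission_id = c("a1", "a1"),
                         med = c("haloperidol", "quetiapine"),
                         time_h = c(6 * 5 + 1, 6 * 9 + 1))
  lab <- label_delirium(rec)
  expect_equal(lab$onset_step, 5L)
  expect_true(is.na(label_delirium(toy_records())$onset_step))
})

test_that("follow-up rules reject and truncate admissions as specified", {
  mk_adm <- function(id, age = 60, los = 7, ecmo = 0)
    data.frame(admission_id = id, age = age, icu_los_days = los, ecmo = ecmo)
  mk_grid <- function(id, T, dose = 0.3, rass = -1) {
    g <- data.frame(admission_id = id, step = 0:(T - 1),
                    heart_rate = 80, rass = rass, dose = dose)
    attr(g, "features") <- c("heart_rate", "rass")
    g
  }
  lab <- function(id, onset = NA_integer_)
    data.frame(admission_id = id, onset_step = onset)

  ## 31-day stay
  fu <- build_followup(mk_grid("x", 5), mk_adm("x", los = 31), lab("x"))
  expect_equal(fu$rejections$reason, "length-of-stay")

  ## no dexmedetomidine exposure
  fu <- build_followup(mk_grid("x", 5, dose = 0), mk_adm("x"), lab("x"))
  expect_equal(fu$rejections$reason, "no-exposure")

  ## delirium before follow-up start
  fu <- build_followup(mk_grid("x", 5), mk_adm("x"), lab("x", 0L))
  expect_equal(fu$rejections$reason, "prior-delirium")

  ## under-age and ECMO
  expect_equal(build_followup(mk_grid("x", 5), mk_adm("x", age = 17),
                              lab("x"))$rejections$reason, "age")
  expect_equal(build_followup(mk_grid("x", 5), mk_adm("x", ecmo = 1),
                              lab("x"))$rejections$reason, "ecmo")

  ## delirium at step 4 of 10 truncates to steps 0..4
  fu <- build_followup(mk_grid("x", 10), mk_adm("x"), lab("x", 4L))
  expect_equal(nrow(fu$grid), 5)
  expect_equal(fu$grid$delirium, c(rep(FALSE, 4), TRUE))

  ## prolonged deep sedation: 5 consecutive RASS -5 windows end the follow-up
  g <- mk_grid("x", 12, rass = c(rep(-1, 4), rep(-5, 6), -1, -1))
  fu <- build_followup(g, mk_adm("x"), lab("x"))
  expect_equal(max(fu$grid$step), 4)
})

test_that("exactly one nonzero terminal reward is assigned per trajectory", {
  g4 <- toy_grid(c(1, 2, 3, 4))
  g4$delirium <- FALSE
  r4 <- assign_rewards(g4)
  expect_equal(r4$reward, c(0, 0, 1, NA))

  g4$delirium <- c(FALSE, FALSE, FALSE, TRUE)
  expect_equal(assign_rewards(g4)$reward, c(0, 0, -1, NA))

  g2 <- toy_grid(c(1, 2))
  g2$delirium <- c(FALSE, TRUE)
  expect_equal(assign_rewards(g2)$reward, c(-1, NA))
})

test_that("the full preprocessing chain yields a complete, bounded grid", {
  co <- generate_cohort(small_config())
  dg <- preprocess_cohort(co)
  feats <- dg$manifest$features
  expect_false(anyNA(dg$grid[, feats]))
  sch <- co$config$feature_schema
  for (f in feats) {
    b <- sch[sch$name == f, ]
    expect_true(all(dg$grid[[f]] >= b$lower - 1e-9 &
                      dg$grid[[f]] <= b$upper + 1e-9), label = f)
  }
  expect_true(all(dg$grid$action %in% 0:15))
  ## reward invariant across the cohort
  nz <- tapply(abs(dg$grid$reward), dg$grid$admission_id,
               function(r) sum(r, na.rm = TRUE))
  expect_true(all(nz == 1))
  ## preprocessing a clean grid is the identity
  again <- impute_grid(remove_outliers(dg$grid, sch[, c("name", "lower", "upper")]),
                       bounds = sch[, c("name", "lower", "upper")])
  expect_equal(again[, feats], dg$grid[, feats])
})
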