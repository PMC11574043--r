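#' Discretize a dexmedetomidine dose into the 16-action space
#'
#' Positive doses in (0, 1.5] mcg/kg/h are segmented into 15 uniform
#' intervals of 0.1 mcg/kg/h: action `k` covers `(0.1*(k-1), 0.1*k]`. Action
#' 0 is the explicit no-drug action. [dose_from_action()] inverts the mapping
#' to the bin's upper edge, so `discretize_dose(dose_from_action(k)) == k`
#' for every action.
#'
#' @param dose Numeric vector of doses in [0, 1.5] mcg/kg/h.
#' @return Integer vector of 0-based action indices in 0..15.
#' @export
discretize_dose <- function(dose) {
  if (any(!is.finite(dose)) || any(dose < -1e-9 | dose > 1.5 + 1e-9))
    stopf("dose outside [0, 1.5] mcg/kg/h; remove implausible doses upstream")
  a <- as.integer(ceiling(pmax(dose, 0) * 10 - 1e-9))
  pmin(a, 15L)
}

#' @rdname discretize_dose
#' @param action Integer vector of action indices in 0..15.
#' @export
dose_from_action <- function(action) {
  if (any(action != round(action)) || any(action < 0 | action > 15))
    stopf("action indices must be integers in 0..15")
  action / 10
}

#' Glasgow Coma Scale summation with single-component conversion
#'
#' Sums the eye (1-4), verbal (1-5) and motor (1-6) components. When exactly
#' one component is missing it is estimated from a conversion table before
#' summation; two or more missing components make the assessment unusable.
#'
#' @param eye,verbal,motor Component scores (vectors; `NA` = missing).
#' @param conversion_table Conversion table as returned by
#'   [gcs_conversion_table()].
#' @return Integer vector of total scores in 3..15.
#' @export
sum_gcs <- function(eye, verbal, motor, conversion_table = gcs_conversion_table()) {
  n <- length(eye)
  stopifnot(length(verbal) == n, length(motor) == n)
  nmiss <- is.na(eye) + is.na(verbal) + is.na(motor)
  if (any(nmiss >= 2))
    stopf("unusable GCS assessment: two or more components missing")
  tab <- conversion_table
  ## direct lookups, one missing component at a time
  est_lookup <- function(missing_comp, a_name, a, b_name, b) {
    sel <- tab[tab$missing == missing_comp, ]
    idx <- match(paste(a, b), paste(sel[[a_name]], sel[[b_name]]))
    if (any(is.na(idx)))
      stopf("GCS conversion table has no row for %s with (%s=%s, %s=%s)",
            missing_comp, a_name, a[is.na(idx)][1], b_name, b[is.na(idx)][1])
    sel[[missing_comp]][idx]
  }
  i <- which(is.na(verbal))
  if (length(i)) verbal[i] <- est_lookup("verbal", "eye", eye[i], "motor", motor[i])
  i <- which(is.na(eye))
  if (length(i)) eye[i] <- est_lookup("eye", "verbal", verbal[i], "motor", motor[i])
  i <- which(is.na(motor))
  if (length(i)) motor[i] <- est_lookup("motor", "eye", eye[i], "verbal", verbal[i])
  tot <- as.integer(eye + verbal + motor)
  if (any(tot < 3 | tot > 15)) stopf("GCS total outside 3..15")
  tot
}

#' Load the GCS single-component conversion table
#'
#' A synthetic stand-in for published conversion tables: the missing
#' component is estimated by proportional allocation of the observed subtotal
#' to the component's maximum (e.g. eye 4 + motor 6 gives estimated verbal
#' `round(10 * 5/10) = 5`), clipped to the component's range. Shipped as
#' `extdata/gcs_conversion_synthetic.csv`.
#'
#' @return A `data.frame` with columns `missing`, `eye`, `verbal`, `motor`.
#' @export
gcs_conversion_table <- function() {
  path <- system.file("extdata", "gcs_conversion_synthetic.csv",
                      package = "dexrl", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

## Collapse raw GCS component rows into summed 'gcs' observations. Components
## recorded at the same timestamp form one assessment.
collapse_gcs <- function(obs, conversion_table = gcs_conversion_table()) {
  comp <- c("gcs_eye", "gcs_verbal", "gcs_motor")
  is_comp <- obs$feature %in% comp
  if (!any(is_comp)) return(obs)
  DT <- data.table::as.data.table(obs[is_comp, ])
  W <- data.table::dcast(DT, admission_id + time_h ~ feature,
                         value.var = "value", fun.aggregate = median)
  for (cc in comp) if (!cc %in% names(W)) W[[cc]] <- NA_real_
  usable <- (is.na(W$gcs_eye) + is.na(W$gcs_verbal) + is.na(W$gcs_motor)) <= 1
  W <- W[usable, ]
  g <- sum_gcs(W$gcs_eye, W$gcs_verbal, W$gcs_motor, conversion_table)
  rbind(obs[!is_comp, , drop = FALSE],
        data.frame(admission_id = W$admission_id, feature = "gcs",
                   time_h = W$time_h, value = as.numeric(g)))
}

#' Bin raw records onto the 6-hourly state grid
#'
#' Assigns every timestamped measurement to a half-open window
#' `[t*interval, (t+1)*interval)` and summarizes multiple measurements within
#' a window by their median (the median of an even count is the mean of the
#' two central values). GCS components are summed per assessment (see
#' [sum_gcs()]) before binning. The grid extent per admission is taken from
#' the dose records; the `dex_prev` feature is derived as the previous
#' window's administered dose (0 at the first window). Cells with no
#' measurement are `NA`.
#'
#' @param records A `dex_cohort` or a list with elements `observations`
#'   (`admission_id`, `feature`, `time_h`, `value`) and `doses`
#'   (`admission_id`, `time_h`, `dose`).
#' @param interval_hours Window width in hours (default 6).
#' @param features Feature columns the grid must contain (default: the
#'   `dex_cohort` schema, or all observed features).
#' @param conversion_table GCS conversion table.
#' @return A `data.frame` ("state grid") with columns `admission_id`, `step`,
#'   one column per feature, and `dose`; attribute `"features"` records the
#'   feature order.
#' @export
bin_to_grid <- function(records, interval_hours = 6, features = NULL,
                        conversion_table = gcs_conversion_table()) {
  obs <- records$observations
  doses <- records$doses
  if (any(obs$time_h < 0) || any(doses$time_h < 0))
    stopf("negative record times are not allowed")
  if (is.null(features)) {
    features <- if (inherits(records, "dex_cohort"))
      records$config$feature_schema$name
    else unique(c(setdiff(obs$feature, c("gcs_eye", "gcs_verbal", "gcs_motor")),
                  if (any(grepl("^gcs_", obs$feature))) "gcs"))
  }
  obs <- collapse_gcs(obs, conversion_table)
  DT <- data.table::as.data.table(obs)
  DT <- DT[!is.na(DT$value)]
  DT[, step := as.integer(time_h %/% interval_hours)]
  M <- DT[, list(value = median(value)), by = c("admission_id", "feature", "step")]

  DD <- data.table::as.data.table(doses)
  DD[, step := as.integer(time_h %/% interval_hours)]
  DD <- DD[, list(dose = median(dose)), by = c("admission_id", "step")]
  ext <- DD[, list(n_steps = max(step) + 1L), by = "admission_id"]
  skel <- ext[, list(step = seq_len(n_steps) - 1L), by = "admission_id"]

  W <- data.table::dcast(M, admission_id + step ~ feature, value.var = "value")
  G <- merge(skel, W, by = c("admission_id", "step"), all.x = TRUE)
  G <- merge(G, DD, by = c("admission_id", "step"), all.x = TRUE)
  data.table::setorderv(G, c("admission_id", "step"))
  ## carry the infusion rate forward across windows without a dose record
  G[, dose := {
    d <- dose
    for (i in seq_along(d)) if (is.na(d[i])) d[i] <- if (i > 1) d[i - 1] else 0
    d
  }, by = "admission_id"]
  if ("dex_prev" %in% features)
    G[, dex_prev := data.table::shift(dose, fill = 0), by = "admission_id"]
  for (f in setdiff(features, names(G))) G[[f]] <- NA_real_
  out <- as.data.frame(G[, c("admission_id", "step", features, "dose"),
                         with = FALSE])
  attr(out, "features") <- features
  attr(out, "interval_hours") <- interval_hours
  out
}

#' Remove physiologically implausible cells
#'
#' Cells strictly outside the closed plausibility interval `[lower, upper]`
#' of their feature are marked absent; boundary values are retained.
#'
#' @param grid State grid from [bin_to_grid()].
#' @param bounds `data.frame` with columns `name`, `lower`, `upper` (defaults
#'   to the bounds of [default_feature_schema()]).
#' @return The grid with implausible cells set to `NA`; attribute
#'   `"n_removed"` counts the removed cells.
#' @export
remove_outliers <- function(grid, bounds = default_feature_schema()[, c("name", "lower", "upper")]) {
  feats <- intersect(attr(grid, "features") %||% setdiff(names(grid),
            c("admission_id", "step", "dose")), bounds$name)
  removed <- 0L
  for (f in feats) {
    b <- bounds[bounds$name == f, ]
    bad <- !is.na(grid[[f]]) & (grid[[f]] < b$lower | grid[[f]] > b$upper)
    removed <- removed + sum(bad)
    grid[[f]][bad] <- NA_real_
  }
  dexrl_log("debug", "outlier removal: %d cells set absent", removed)
  a <- attributes(grid)
  attr(grid, "n_removed") <- removed
  attr(grid, "features") <- a$features
  grid
}

## Inverse-time-distance interpolation of interior gaps for one series.
interp_interior <- function(v) {
  obs <- which(!is.na(v))
  if (length(obs) < 1L) return(v)
  for (i in which(is.na(v))) {
    lo <- obs[obs < i]; hi <- obs[obs > i]
    if (!length(lo) || !length(hi)) next  # leading/trailing gap
    l <- max(lo); h <- min(hi)
    wl <- 1 / (i - l); wh <- 1 / (h - i)
    v[i] <- (v[l] * wl + v[h] * wh) / (wl + wh)
  }
  v
}

#' Impute missing grid cells
#'
#' Interior gaps are filled by time-weighted interpolation: the two nearest
#' observed values of the same feature within the same admission are averaged
#' with weights inversely proportional to their time distance. Leading and
#' trailing gaps, which have no bracketing observations, are filled by a
#' chained-equations regression model: starting from cohort medians, each
#' feature with remaining gaps is regressed on all other features over the
#' originally observed cells and its gaps replaced by predictions, iterating
#' a fixed number of rounds. Observed cells are never altered.
#'
#' @param grid State grid (after outlier removal).
#' @param n_iter Chained-regression rounds (default 10).
#' @param bounds Optional plausibility bounds to clip imputed values.
#' @return The grid with no missing feature cells.
#' @export
impute_grid <- function(grid, n_iter = 10,
                        bounds = default_feature_schema()[, c("name", "lower", "upper")]) {
  feats <- attr(grid, "features") %||% setdiff(names(grid),
            c("admission_id", "step", "dose"))
  never <- feats[vapply(feats, function(f) all(is.na(grid[[f]])), logical(1))]
  if (length(never))
    stopf("schema error: feature(s) never observed in the cohort: %s",
          paste(never, collapse = ", "))
  a <- attributes(grid)
  for (f in feats)
    grid[[f]] <- stats::ave(grid[[f]], grid$admission_id, FUN = interp_interior)

  X <- as.matrix(grid[, feats, drop = FALSE])
  miss <- is.na(X)
  if (any(miss)) {
    med <- apply(X, 2, median, na.rm = TRUE)
    Xf <- X
    for (j in seq_along(feats)) Xf[miss[, j], j] <- med[j]
    for (it in seq_len(n_iter)) {
      for (j in seq_along(feats)) {
        mj <- miss[, j]
        if (!any(mj)) next
        fit <- lm.fit(cbind(1, Xf[!mj, -j, drop = FALSE]), X[!mj, j])
        pred <- cbind(1, Xf[mj, -j, drop = FALSE]) %*% fit$coefficients
        pred[!is.finite(pred)] <- med[j]
        Xf[mj, j] <- pred
      }
    }
    if (!is.null(bounds)) {
      for (j in seq_along(feats)) {
        b <- bounds[bounds$name == feats[j], ]
        if (nrow(b) == 1)
          Xf[, j] <- pmin(b$upper, pmax(b$lower, Xf[, j]))
      }
    }
    X <- ifelse(miss, Xf, X)
    grid[, feats] <- X
  }
  attributes(grid) <- utils::modifyList(attributes(grid), a[c("features", "interval_hours", "n_removed")])
  grid
}

#' Label delirium onset from medication records
#'
#' Delirium is identified by administration of an antipsychotic used to treat
#' it (medication-record criterion); onset is the first such administration.
#'
#' @param records A `dex_cohort` or list with a `meds` table (`admission_id`,
#'   `med`, `time_h`).
#' @param antipsychotics Drug names counting as delirium treatment.
#' @param interval_hours Grid window width.
#' @return `data.frame` with `admission_id` and 0-based `onset_step` (`NA`
#'   when no delirium-indicating medication occurs).
#' @export
label_delirium <- function(records,
                           antipsychotics = c("haloperidol", "quetiapine", "clonidine"),
                           interval_hours = 6) {
  meds <- records$meds
  adms <- unique(records$doses$admission_id)
  hit <- meds[meds$med %in% antipsychotics, , drop = FALSE]
  first <- tapply(hit$time_h, hit$admission_id, min)
  onset <- as.integer(floor(first[adms] / interval_hours))
  data.frame(admission_id = adms, onset_step = unname(onset))
}

#' Build follow-up windows and apply inclusion rules
#'
#' The follow-up window runs from the first dexmedetomidine administration
#' (grid step 0) to ICU discharge, the start of prolonged deep sedation
#' (RASS -4/-5 sustained for more than 24 h, i.e. 5 or more consecutive 6-h
#' windows), or delirium onset, whichever comes first. Admissions violating
#' the inclusion rules are rejected with a reason code rather than an error:
#' `"age"` (< 18 years), `"length-of-stay"` (< 1 or > 30 days), `"ecmo"`,
#' `"no-exposure"` (never received dexmedetomidine), `"prior-delirium"`
#' (onset at or before the first window).
#'
#' @param grid State grid (binned, outlier-screened).
#' @param admissions Admissions table with `age`, `icu_los_days`, `ecmo`.
#' @param labels Output of [label_delirium()].
#' @return List with `grid` (truncated; extra logical column `delirium` true
#'   on the onset row) and `rejections` (`admission_id`, `reason`).
#' @export
build_followup <- function(grid, admissions, labels) {
  a <- attributes(grid)
  lab <- setNames(labels$onset_step, labels$admission_id)
  rej <- list()
  keep <- list()
  for (ad in unique(grid$admission_id)) {
    g <- grid[grid$admission_id == ad, , drop = FALSE]
    st <- admissions[admissions$admission_id == ad, , drop = FALSE]
    onset <- unname(lab[ad])
    reason <- NULL
    if (nrow(st) == 1) {
      if (st$age < 18) reason <- "age"
      else if (st$icu_los_days < 1 || st$icu_los_days > 30) reason <- "length-of-stay"
      else if (isTRUE(st$ecmo == 1)) reason <- "ecmo"
    }
    if (is.null(reason) && !any(g$dose > 0)) reason <- "no-exposure"
    if (is.null(reason) && !is.na(onset) && onset <= 0) reason <- "prior-delirium"
    if (!is.null(reason)) {
      rej[[ad]] <- data.frame(admission_id = ad, reason = reason)
      next
    }
    end <- max(g$step)
    if (!is.na(onset)) end <- min(end, onset)
    ## prolonged deep sedation: first run of >=5 consecutive RASS <= -4 steps
    if ("rass" %in% names(g)) {
      deep <- !is.na(g$rass) & g$rass <= -4
      run <- 0L
      for (i in seq_along(deep)) {
        run <- if (deep[i]) run + 1L else 0L
        if (run >= 5L) { end <- min(end, g$step[i] - run + 1L); break }
      }
    }
    g <- g[g$step <= end, , drop = FALSE]
    g$delirium <- !is.na(onset) & g$step == onset & onset <= end
    keep[[ad]] <- g
  }
  out <- if (length(keep)) do.call(rbind, keep) else
    cbind(grid[0, , drop = FALSE], delirium = logical(0))
  rownames(out) <- NULL
  attr(out, "features") <- a$features
  attr(out, "interval_hours") <- a$interval_hours
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(admission_id = character(0), reason = character(0))
  rownames(rejections) <- NULL
  dexrl_log("info", "follow-up: kept %d admissions, rejected %d",
            length(keep), nrow(rejections))
  list(grid = out, rejections = rejections)
}

#' Assign terminal rewards to a follow-up grid
#'
#' Each trajectory carries exactly one nonzero reward on its final
#' transition: -1 when the trajectory ends at delirium onset, +1 when it ends
#' delirium-free (discharge or truncation). All other transitions have reward
#' 0. The reward is stored on the source row of each transition (`NA` on the
#' terminal row, which has no outgoing transition).
#'
#' @param grid Follow-up grid from [build_followup()] (needs the `delirium`
#'   column).
#' @return The grid with a `reward` column.
#' @export
assign_rewards <- function(grid) {
  a <- attributes(grid)
  stopifnot("delirium" %in% names(grid))
  grid <- grid[order(grid$admission_id, grid$step), , drop = FALSE]
  grid$reward <- stats::ave(as.numeric(grid$delirium), grid$admission_id,
    FUN = function(d) {
      T <- length(d)
      r <- rep(0, T)
      r[T] <- NA
      if (T >= 2) r[T - 1] <- if (d[T] > 0) -1 else 1
      r
    })
  attr(grid, "features") <- a$features
  attr(grid, "interval_hours") <- a$interval_hours
  grid
}

#' Preprocess a raw cohort into a complete 6-hourly state grid
#'
#' Runs the full preprocessing chain: median binning onto the 6-h grid,
#' plausibility-bound outlier removal, delirium labelling from medication
#' records, follow-up construction with inclusion rules, imputation
#' (time-weighted interpolation, then chained-equation regression for
#' boundary gaps), dose discretization into the 16-action space, and terminal
#' reward assignment. Static confounders (age, sex, BMI, ventilation, shock,
#' renal replacement) are joined onto the grid.
#'
#' @param cohort A `dex_cohort` (from [generate_cohort()] or [read_cohort()]).
#' @param antipsychotics Delirium-indicating drug set.
#' @return An object of class `dex_grid`: list with `grid` (complete state
#'   grid with `action`, `reward`, `delirium`, confounder columns),
#'   `rejections`, and `manifest` (feature order, action-bin edges, counts).
#' @export
preprocess_cohort <- function(cohort,
                              antipsychotics = c("haloperidol", "quetiapine", "clonidine")) {
  sch <- cohort$config$feature_schema
  bounds <- sch[, c("name", "lower", "upper")]
  g <- bin_to_grid(cohort)
  g <- remove_outliers(g, bounds)
  n_removed <- attr(g, "n_removed")
  labels <- label_delirium(cohort, antipsychotics)
  fu <- build_followup(g, cohort$admissions, labels)
  g <- impute_grid(fu$grid, bounds = bounds)
  g$action <- discretize_dose(pmin(pmax(g$dose, 0), 1.5))
  g <- assign_rewards(g)
  conf <- cohort$admissions[, c("admission_id", "patient_id", "age", "sex",
                                "bmi", "vent", "shock", "rrt")]
  conf$sex <- as.integer(conf$sex == "male")
  g <- merge(g, conf, by = "admission_id", sort = FALSE)
  g <- g[order(g$admission_id, g$step), , drop = FALSE]
  rownames(g) <- NULL
  attr(g, "features") <- sch$name
  attr(g, "interval_hours") <- 6
  manifest <- list(features = sch$name,
                   confounders = c("age", "sex", "bmi", "rrt", "vent", "shock"),
                   interval_hours = 6,
                   action_bin_edges = seq(0, 1.5, by = 0.1),
                   n_admissions = length(unique(g$admission_id)),
                   n_rejected = nrow(fu$rejections),
                   n_outlier_cells_removed = n_removed)
  structure(list(grid = g, rejections = fu$rejections, manifest = manifest),
            class = "dex_grid")
}

#' @export
print.dex_grid <- function(x, ...) {
  cat(sprintf("<dex_grid> %d admissions x %d rows (%d rejected; %d outlier cells removed)\n",
              x$manifest$n_admissions, nrow(x$grid), x$manifest$n_rejected,
              x$manifest$n_outlier_cells_removed))
  invisible(x)
}

#' Write a preprocessed grid cohort to disk
#' @param dgrid A `dex_grid`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_grid <- function(dgrid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(dgrid$grid, file.path(dir, "state_grid.tsv"))
  write_tsv(dgrid$rejections, file.path(dir, "rejections.tsv"))
  jsonlite::write_json(dgrid$manifest, file.path(dir, "grid_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
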