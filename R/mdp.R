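#' Assemble MDP transitions from a preprocessed state grid
#'
#' A trajectory of `T` grid steps yields `T - 1` transitions
#' `(s_t, a_t, r_{t+1}, s_{t+1}, terminal)`; the last transition of each
#' trajectory is terminal and carries the trajectory's single nonzero reward.
#' Single-step trajectories produce no transitions and are dropped with a
#' logged count.
#'
#' @param dgrid A `dex_grid` from [preprocess_cohort()], or a bare grid
#'   `data.frame` with `admission_id`, `step`, feature columns, `action`,
#'   `reward`.
#' @param features Feature column names (default: the grid manifest).
#' @param confounders Confounder column names to carry along for behavior
#'   modelling (default: the grid manifest; may be absent).
#' @return An object of class `dex_transitions`: list with matrices `s`,
#'   `sp` (`NA` rows where terminal), integer `a` (0-based), numeric `r`,
#'   logical `terminal`, `traj` (admission id per transition), `conf`
#'   (confounder matrix or `NULL`), and `s0`/`s0_traj` (one initial state per
#'   trajectory).
#' @export
make_transitions <- function(dgrid, features = NULL, confounders = NULL) {
  if (inherits(dgrid, "dex_grid")) {
    grid <- dgrid$grid
    features <- features %||% dgrid$manifest$features
    confounders <- confounders %||% intersect(dgrid$manifest$confounders,
                                              names(grid))
  } else {
    grid <- dgrid
    features <- features %||% attr(grid, "features")
  }
  stopifnot(!is.null(features), all(features %in% names(grid)))
  grid <- grid[order(grid$admission_id, grid$step), , drop = FALSE]
  id <- grid$admission_id
  n_by <- table(id)[unique(id)]
  short <- names(n_by)[n_by < 2]
  if (length(short))
    dexrl_log("info", "dropping %d single-timestep trajectories", length(short))
  keep <- !(id %in% short)
  grid <- grid[keep, , drop = FALSE]
  id <- grid$admission_id
  if (!nrow(grid))
    return(structure(list(s = matrix(0, 0, length(features),
                                     dimnames = list(NULL, features)),
                          a = integer(0), r = numeric(0),
                          sp = matrix(0, 0, length(features)),
                          terminal = logical(0), traj = character(0),
                          conf = NULL, s0 = matrix(0, 0, length(features)),
                          s0_traj = character(0), features = features),
                     class = "dex_transitions"))
  X <- as.matrix(grid[, features, drop = FALSE])
  last <- c(id[-1] != id[-length(id)], TRUE)   # last row of each trajectory
  src <- !last                                  # rows emitting a transition
  nxt <- which(src) + 1L
  s <- X[src, , drop = FALSE]
  sp <- X[nxt, , drop = FALSE]
  terminal <- last[nxt]
  sp[terminal, ] <- NA_real_
  conf <- NULL
  if (length(confounders) && all(confounders %in% names(grid)))
    conf <- as.matrix(grid[src, confounders, drop = FALSE])
  first <- c(TRUE, id[-1] != id[-length(id)])
  structure(list(s = s, a = as.integer(grid$action[src]),
                 r = as.numeric(grid$reward[src]), sp = sp,
                 terminal = terminal, traj = id[src], conf = conf,
                 s0 = X[first, , drop = FALSE], s0_traj = id[first],
                 features = features),
            class = "dex_transitions")
}

#' @export
print.dex_transitions <- function(x, ...) {
  cat(sprintf("<dex_transitions> %d transitions, %d trajectories, %d features\n",
              length(x$a), length(x$s0_traj), ncol(x$s)))
  invisible(x)
}

## Subset transitions by trajectory ids (used for splits and bootstrap).
subset_transitions <- function(tr, traj_ids) {
  sel <- tr$traj %in% traj_ids
  sel0 <- tr$s0_traj %in% traj_ids
  structure(list(s = tr$s[sel, , drop = FALSE], a = tr$a[sel], r = tr$r[sel],
                 sp = tr$sp[sel, , drop = FALSE], terminal = tr$terminal[sel],
                 traj = tr$traj[sel],
                 conf = if (!is.null(tr$conf)) tr$conf[sel, , drop = FALSE],
                 s0 = tr$s0[sel0, , drop = FALSE],
                 s0_traj = tr$s0_traj[sel0], features = tr$features),
            class = "dex_transitions")
}

#' Discounted return of one trajectory
#'
#' Computes the discounted sum of the rewards along a trajectory's
#' transitions, discounting from the first transition
#' (`sum_t gamma^t * r_{t+1}`, `t` starting at 0).
#'
#' @param rewards Reward sequence, one entry per transition.
#' @param gamma Discount factor in (0, 1].
#' @return Scalar return.
#' @export
discounted_return <- function(rewards, gamma = 0.99) {
  check_number(gamma, "gamma", lower = 1e-12, upper = 1)
  sum(gamma^(seq_along(rewards) - 1) * rewards)
}

## Per-trajectory discounted returns of a transition set, in s0_traj order.
trajectory_returns <- function(tr, gamma = 0.99) {
  vapply(split(seq_along(tr$traj), tr$traj)[tr$s0_traj],
         function(i) discounted_return(tr$r[i], gamma), numeric(1))
}

#' Patient-level cross-validation split plan
#'
#' Partitions patients into `k` disjoint test folds tiling the cohort (20%
#' each for `k = 5`); within each fold the remaining patients are split into
#' training and validation so the overall fractions match `fractions`
#' (70/10/20 by default). All admissions of one patient share a partition.
#'
#' @param patient_ids Character/factor vector of patient ids, one per
#'   admission (duplicates allowed).
#' @param k Number of folds (>= 2).
#' @param fractions Train/validation/test fractions summing to 1; the test
#'   fraction is implied by `1/k`.
#' @param seed Integer seed.
#' @return An object of class `split_plan`: list of `k` folds, each with
#'   `train`, `validation`, `test` patient-id vectors.
#' @export
split_patients <- function(patient_ids, k = 5, fractions = c(0.7, 0.1, 0.2),
                           seed = 1L) {
  check_number(k, "k", lower = 2, integer = TRUE)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stopf("fractions must be three numbers summing to 1")
  pts <- unique(as.character(patient_ids))
  if (length(pts) < k) stopf("need at least k = %d patients", k)
  set.seed(seed)
  perm <- sample(pts)
  fold_of <- rep(seq_len(k), length.out = length(perm))
  folds <- vector("list", k)
  val_share <- fractions[2] / (fractions[1] + fractions[2])
  for (f in seq_len(k)) {
    test <- perm[fold_of == f]
    rest <- perm[fold_of != f]
    rest <- sample(rest)  # seeded reshuffle per fold
    n_val <- round(length(rest) * val_share)
    folds[[f]] <- list(train = sort(rest[seq_len(length(rest) - n_val)]),
                       validation = sort(rest[seq(length(rest) - n_val + 1,
                                                  length(rest))]),
                       test = sort(test))
  }
  structure(list(folds = folds, k = k, fractions = fractions, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) lengths(f[c("train", "validation", "test")]),
                  numeric(3))
  cat(sprintf("<split_plan> %d folds; train/val/test sizes per fold:\n", x$k))
  print(t(sizes))
  invisible(x)
}

#' Serialize a split plan to JSON
#' @param plan A `split_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
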