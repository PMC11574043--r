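# Shared fixtures: tiny raw-record sets, constant-output Q-networks, and
# hand-built transition batches.

# A qnet whose output is a constant row (all weights zero, output bias = q_row).
const_qnet <- function(q_row, n_features = 2L, hidden = 4L) {
  spec <- qnet_spec(n_features, n_actions = length(q_row), hidden = hidden)
  set.seed(1)
  net <- dexrl:::qnet_init(spec)
  for (l in seq_along(net$W)) {
    net$W[[l]][] <- 0
    net$b[[l]][] <- 0
  }
  net$b[[length(net$b)]] <- as.numeric(q_row)
  net
}

# Minimal dex_transitions batch from explicit components.
make_batch <- function(s, a, r, sp, terminal, traj = NULL) {
  s <- as.matrix(s); sp <- as.matrix(sp)
  traj <- traj %||% as.character(seq_along(a))
  first <- !duplicated(traj)
  structure(list(s = s, a = as.integer(a), r = as.numeric(r), sp = sp,
                 terminal = as.logical(terminal), traj = traj, conf = NULL,
                 s0 = s[first, , drop = FALSE], s0_traj = traj[first],
                 features = colnames(s)),
            class = "dex_transitions")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Toy raw records: one admission, heart-rate measurements exercising the
# median and window conventions.
toy_records <- function() {
  list(
    observations = data.frame(
      admission_id = "a1",
      feature = "heart_rate",
      time_h = c(1, 2, 3, 6, 8, 13),
      value = c(2, 4, 9, 2, 4, 7)),
    doses = data.frame(admission_id = "a1", time_h = c(0, 6, 12),
                       dose = c(0.2, 0.3, 0.3)),
    meds = data.frame(admission_id = character(0), med = character(0),
                      time_h = numeric(0))
  )
}

# Bare state grid with explicit feature attributes.
toy_grid <- function(values, feature = "f1", extra = NULL) {
  g <- data.frame(admission_id = "a1", step = seq_along(values) - 1L,
                  f1 = values)
  names(g)[3] <- feature
  feats <- feature
  if (!is.null(extra)) {
    for (nm in names(extra)) g[[nm]] <- extra[[nm]]
    feats <- c(feature, names(extra))
  }
  g$dose <- 0.2
  attr(g, "features") <- feats
  attr(g, "interval_hours") <- 6
  g
}

# Small cohort config used across simulator tests.
small_config <- function(...) cohort_config(n_patients = 50, seed = 11, ...)
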