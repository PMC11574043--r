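#' Compare dose distributions between delirium and no-delirium groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of whether the dose
#' distribution differs between patients who developed delirium and those who
#' did not, with group means and percentile-bootstrap 95% confidence
#' intervals. Constant pooled input is reported as degenerate with p = 1.
#'
#' @param doses_delirium,doses_no_delirium Numeric dose vectors (mcg/kg/h).
#' @param replicates Bootstrap replicates for the mean CIs.
#' @param seed Integer seed.
#' @return List with `statistic` (rank-sum W), `p_value`, per-group `mean`,
#'   `ci`, `n`, and a `degenerate` flag.
#' @export
compare_dose_distributions <- function(doses_delirium, doses_no_delirium,
                                       replicates = 1000, seed = 1L) {
  if (!length(doses_delirium) || !length(doses_no_delirium))
    stopf("both dose groups must be nonempty")
  pooled <- c(doses_delirium, doses_no_delirium)
  degenerate <- length(unique(pooled)) == 1L
  if (degenerate) {
    w <- NA_real_; p <- 1
  } else {
    ht <- suppressWarnings(wilcox.test(doses_delirium, doses_no_delirium,
                                       alternative = "two.sided", exact = FALSE))
    w <- unname(ht$statistic); p <- ht$p.value
  }
  ci_of <- function(x, off) {
    if (length(x) < 2) return(c(NA_real_, NA_real_))
    b <- bootstrap_ci(mean, x, replicates = replicates, seed = derive_seed(seed, off))
    c(b$lower, b$upper)
  }
  list(statistic = w, p_value = p, degenerate = degenerate,
       delirium = list(mean = mean(doses_delirium),
                       ci = ci_of(doses_delirium, 1L),
                       n = length(doses_delirium)),
       no_delirium = list(mean = mean(doses_no_delirium),
                          ci = ci_of(doses_no_delirium, 2L),
                          n = length(doses_no_delirium)))
}

#' Cohort descriptive table by delirium status
#'
#' Medians with interquartile ranges for continuous variables (compared by
#' t-test or Wilcoxon rank-sum), counts and percentages for categorical
#' variables (chi-squared, or Fisher's exact test when any expected cell
#' count is below 5), plus the Pearson correlation matrix of the state
#' variables.
#'
#' @param data Admission-level `data.frame`.
#' @param delirium Logical vector, one entry per row of `data`.
#' @param continuous,categorical Column names to summarize.
#' @param continuous_test `"wilcoxon"` (default) or `"t"`.
#' @param correlations Columns for the correlation matrix (default: the
#'   continuous variables).
#' @return List with `continuous` and `categorical` summary data.frames and
#'   the `correlation` matrix.
#' @export
cohort_table <- function(data, delirium, continuous, categorical = character(0),
                         continuous_test = c("wilcoxon", "t"),
                         correlations = continuous) {
  continuous_test <- match.arg(continuous_test)
  stopifnot(length(delirium) == nrow(data))
  qfmt <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
  }
  cont <- do.call(rbind, lapply(continuous, function(v) {
    x1 <- data[[v]][delirium]; x0 <- data[[v]][!delirium]
    p <- if (continuous_test == "t") t.test(x1, x0)$p.value
         else suppressWarnings(wilcox.test(x1, x0, exact = FALSE))$p.value
    data.frame(variable = v, with_delirium = qfmt(x1),
               without_delirium = qfmt(x0), p_value = p, test = continuous_test)
  }))
  cat_rows <- lapply(categorical, function(v) {
    tab <- table(factor(data[[v]]), factor(delirium, levels = c(TRUE, FALSE)))
    expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    use_fisher <- any(expct < 5)
    p <- if (use_fisher) fisher.test(tab)$p.value
         else suppressWarnings(chisq.test(tab))$p.value
    pct <- function(col) sprintf("%d (%.1f)", tab[, col],
                                 100 * tab[, col] / sum(tab[, col]))
    data.frame(variable = paste(v, rownames(tab), sep = ": "),
               with_delirium = pct("TRUE"), without_delirium = pct("FALSE"),
               p_value = p, test = if (use_fisher) "fisher" else "chi-squared")
  })
  catg <- if (length(cat_rows)) do.call(rbind, cat_rows) else NULL
  corr <- if (length(correlations) >= 2)
    cor(as.matrix(data[, correlations, drop = FALSE]),
        use = "pairwise.complete.obs") else NULL
  list(continuous = cont, categorical = catg, correlation = corr)
}
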