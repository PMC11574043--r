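#' @import data.table
#' @importFrom stats median rnorm runif rbinom plogis quantile sd lm predict
#'   coef prcomp wilcox.test chisq.test fisher.test t.test cor rexp rpois
#'   setNames complete.cases lm.fit ave
#' @importFrom utils write.table read.table head
NULL

## Row-wise log-sum-exp, numerically stable.
row_logsumexp <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx + log(rowSums(exp(M - mx)))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## Derive a reproducible child seed from a master seed. Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) %% 50021L) * 7919 + 104729 * (offset %% 1000L)) %% 2147483597L + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, field, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("configuration field '%s' must be a single finite number", field)
  if (x < lower || x > upper)
    stopf("configuration field '%s' must be in [%s, %s]", field, lower, upper)
  if (integer && x != round(x))
    stopf("configuration field '%s' must be an integer", field)
  invisible(TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  data.table::fread(path, sep = "\t", data.table = FALSE)
}

## Lightweight leveled logger used across the pipeline.
dexrl_log <- function(level = c("info", "debug", "warn"), fmt, ...) {
  level <- match.arg(level)
  threshold <- getOption("dexrl.log_level", "info")
  ranks <- c(debug = 1L, info = 2L, warn = 3L)
  if (ranks[[level]] >= ranks[[threshold]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}
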