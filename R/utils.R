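# internal helpers shared across modules

#' @import data.table
#' @importFrom methods new is validObject slot
#' @importFrom stats rnbinom rbinom rpois runif rnorm rlnorm t.test fisher.test
#'   chisq.test p.adjust ppois dpois dbinom dnbinom cor median quantile setNames
#' @importFrom utils read.table write.table
NULL

.xiLogEnv <- new.env(parent = emptyenv())
.xiLogEnv$con <- NULL

#' Direct xiseq log output
#'
#' Filtering and classification steps log their input/output record counts at
#' INFO level so that survivor counts can be audited. By default messages go
#' through [message()] only when `options(xiseq.verbose = TRUE)`; a log file
#' connection set here additionally captures every record.
#'
#' @param path file path to append log lines to, or `NULL` to detach.
#' @return invisibly, the previous path (or `NULL`).
#' @export
xiLogTo <- function(path = NULL) {
  old <- .xiLogEnv$con
  .xiLogEnv$con <- path
  invisible(old)
}

xiLog <- function(fmt, ...) {
  line <- sprintf(fmt, ...)
  if (!is.null(.xiLogEnv$con)) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "INFO", line, "\n",
        file = .xiLogEnv$con, append = TRUE)
  }
  if (isTRUE(getOption("xiseq.verbose", FALSE))) message(line)
  invisible(line)
}

.assertCols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

.isCount <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0)

# Welch (default) or pooled two-sample two-tailed t; returns NA p with a flag
# when a group is degenerate rather than erroring, since callers run thousands
# of these on simulated replicates.
.safeT <- function(x, y, pooled = FALSE, paired = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (paired) {
    if (length(x) != length(y) || length(x) < 2L) {
      return(list(p = NA_real_, flag = "too_few"))
    }
    d <- x - y
    if (stats::sd(d) == 0) {
      return(list(p = if (all(d == 0)) 1 else 0,
                  flag = if (all(d == 0)) "zero_diff" else "degenerate"))
    }
    return(list(p = stats::t.test(x, y, paired = TRUE)$p.value, flag = "ok"))
  }
  if (length(x) < 2L || length(y) < 2L) return(list(p = NA_real_, flag = "too_few"))
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    return(list(p = if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0,
                flag = if (isTRUE(all.equal(mean(x), mean(y)))) "constant_equal"
                       else "degenerate"))
  }
  list(p = stats::t.test(x, y, var.equal = pooled)$p.value, flag = "ok")
}

# derive a stream-specific seed from a master seed, staying in 32-bit range
# (double arithmetic: products can exceed .Machine$integer.max)
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 30269) %% 2147483399)
}
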