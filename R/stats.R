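#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value under the "sum of small p"
#' convention: the sum of probabilities of all tables with the observed
#' margins whose point probability does not exceed that of the observed table
#' (the convention that reproduces standard software output; mid-p and
#' doubling conventions differ). Probabilities are accumulated in log space
#' so large margins neither overflow nor underflow to 0.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = condition,
#'   columns = outcome: `rbind(c(a, b), c(c, d))`. Alternatively pass a 2x2
#'   matrix as `a`.
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x2(56, 6, 62, 0)   # 0.028 at three decimals
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  m <- a + b            # row 1 margin
  n <- c + d            # row 2 margin
  k <- a + c            # column 1 margin
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0)
    stop("undefined test: a margin of the 2x2 table is zero")
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  obs <- logp[x == a]
  keep <- logp <= obs + 1e-7          # relative slack for fp-equal tables
  # log-sum-exp over the kept tables
  mx <- max(logp[keep])
  p <- exp(mx) * sum(exp(logp[keep] - mx))
  min(1, p)
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Computes rho as the Pearson correlation of average ranks (ties receive
#' their average rank), with a confidence interval from the Fisher z
#' transform, `atanh(rho) +/- z * 1/sqrt(n - 3)`. The interval method is
#' recorded in the result (`ci_method = "fisher-z"`) because published
#' Spearman intervals computed by other methods (e.g. bootstrap) are not
#' directly comparable.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return A list of class `correlation_result`: `rho`, `n`, `ci_low`,
#'   `ci_high`, `ci_method`, `level`.
#' @export
#' @examples
#' r <- spearman_rho_ci(1:10, (1:10)^2)
#' r$rho  # 1: rank correlation is invariant under monotone transforms
spearman_rho_ci <- function(x, y, level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: an input vector is constant")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  rx <- rank(x); ry <- rank(y)
  # Pearson correlation of the average ranks, written out
  mx <- mean(rx); my <- mean(ry)
  rho <- sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  rho <- max(-1, min(1, rho))
  zcrit <- stats::qnorm((1 + level) / 2)
  if (abs(rho) >= 1) {
    lo <- hi <- rho
  } else {
    z <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    lo <- tanh(z - zcrit * se)
    hi <- tanh(z + zcrit * se)
  }
  structure(list(rho = rho, n = n, ci_low = lo, ci_high = hi,
                 ci_method = "fisher-z", level = level),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("Spearman's rho = ", format(x$rho, digits = 3), " (n = ", x$n, "; ",
      format(100 * x$level), "% CI ", format(x$ci_low, digits = 3), " to ",
      format(x$ci_high, digits = 3), ", ", x$ci_method, ")\n", sep = "")
  invisible(x)
}

#' Ingest a trainee-session ratings table
#'
#' Documented CSV-ingest hook for externally deposited trainee datasets: the
#' caller supplies the column names holding the initial-test and retest
#' measurements (the deposited schema is not fixed, so the mapping is
#' explicit). Returns the paired vectors ready for [spearman_rho_ci()], e.g.
#' for test-retest reliability of confidence ratings.
#'
#' @param path CSV file path.
#' @param initial_col,retest_col Names of the two paired columns.
#' @return A data frame with columns `initial` and `retest`, complete pairs
#'   only.
#' @export
read_trainee_pairs <- function(path, initial_col, retest_col) {
  if (!file.exists(path)) stop("trainee CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (colname in c(initial_col, retest_col))
    if (!colname %in% names(df))
      stop("column '", colname, "' not present in ", path,
           " (available: ", paste(names(df), collapse = ", "), ")")
  out <- data.frame(initial = as.numeric(df[[initial_col]]),
                    retest = as.numeric(df[[retest_col]]))
  out[stats::complete.cases(out), , drop = FALSE]
}
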