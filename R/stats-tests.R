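#' Mann-Whitney U test with exact small-sample p-value and effect size
#'
#' Computes the Mann-Whitney U statistic (for `x`, with midranks for ties).
#' When the combined sample size is at most `exactMax` and there are no
#' ties, the two-sided p-value is exact: the U null distribution is obtained
#' by enumerating all rank splits and the two-sided p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`. Otherwise the normal
#' approximation with tie correction and a 0.5 continuity correction is
#' used, and the effect size `r = |Z| / sqrt(n_x + n_y)` is reported.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exactMax largest combined sample size for which the exact
#'   enumeration is used (default 12).
#' @return A list of class `"stressTest"` with elements `statistic` (U for
#'   `x`), `p.value` (two-sided), `effect.size.r` (`NA` on the exact path),
#'   and `method`.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))$p.value  # exact 1/3
#' @export
mannWhitneyU <- function(x, y, exactMax = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n <= exactMax) {
    dist <- .uNullDistribution(nx, ny)
    p <- min(1, 2 * min(sum(dist$prob[dist$u <= u + 1e-9]),
                        sum(dist$prob[dist$u >= u - 1e-9])))
    res <- list(statistic = u, p.value = p, effect.size.r = NA_real_,
                method = "Mann-Whitney U (exact enumeration)")
  } else {
    mu <- nx * ny / 2
    tieTab <- table(pooled)
    tieTerm <- sum(tieTab^3 - tieTab)
    sigma2 <- nx * ny / 12 * ((n^3 - n - tieTerm) / (n * (n - 1)))
    if (sigma2 <= 0) {
      res <- list(statistic = u, p.value = 1, effect.size.r = 0,
                  method = "Mann-Whitney U (normal approximation, degenerate)")
    } else {
      z <- (u - mu)
      z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity corr.
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      res <- list(statistic = u, p.value = p,
                  effect.size.r = abs(z) / sqrt(n),
                  method = "Mann-Whitney U (normal approximation, tie and continuity corrected)")
    }
  }
  class(res) <- "stressTest"
  res
}

# Exact null distribution of U for group sizes nx, ny (no ties): enumerate
# all C(n, nx) rank assignments.
.uNullDistribution <- function(nx, ny) {
  n <- nx + ny
  splits <- utils::combn(n, nx)
  us <- colSums(splits) - nx * (nx + 1) / 2
  tab <- table(us)
  list(u = as.numeric(names(tab)), prob = as.numeric(tab) / ncol(splits))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities (margins fixed) of all tables whose
#' probability does not exceed that of the observed table (within a small
#' relative tolerance, as in common statistical software).
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return A `"stressTest"` list with `statistic` (sample odds ratio,
#'   possibly `Inf`), `p.value`, and `method`.
#' @examples
#' fisherExact2x2(matrix(c(0, 4, 3, 0), 2))$p.value  # 1/35
#' @export
fisherExact2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop("a 2x2 table is required", call. = FALSE)
  if (anyNA(m) || any(m < 0) || any(abs(m - round(m)) > 1e-8))
    stop("table entries must be non-negative integers", call. = FALSE)
  m <- round(m)
  if (sum(m) == 0) stop("table total must be positive", call. = FALSE)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  k <- lo:hi
  probs <- stats::dhyper(k, c1, n - c1, r1)
  pObs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  orNum <- m[1, 1] * m[2, 2]; orDen <- m[1, 2] * m[2, 1]
  res <- list(statistic = if (orDen == 0) Inf else orNum / orDen,
              p.value = p, effect.size.r = NA_real_,
              method = "Fisher exact test (2x2, minimum-likelihood two-sided)")
  class(res) <- "stressTest"
  res
}

#' Fisher's exact test for an RxC table by full enumeration
#'
#' Enumerates every non-negative integer table with the observed margins,
#' computes each table's multivariate hypergeometric probability, and sums
#' the probabilities of tables no more probable than the observed one.
#'
#' @param table RxC matrix of non-negative integers (R, C >= 2).
#' @param maxTotal refuse enumeration above this grand total (default 60);
#'   larger tables need a Monte-Carlo approach, which is out of scope here.
#' @return A `"stressTest"` list with `p.value` and `method`; `statistic` is
#'   the log-probability of the observed table.
#' @export
fisherExactRxC <- function(table, maxTotal = 60L) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("at least 2 rows and 2 columns required", call. = FALSE)
  if (anyNA(m) || any(m < 0) || any(abs(m - round(m)) > 1e-8))
    stop("table entries must be non-negative integers", call. = FALSE)
  m <- round(m)
  n <- sum(m)
  if (n == 0) stop("table total must be positive", call. = FALSE)
  if (n > maxTotal)
    stop("table total ", n, " exceeds the exact-enumeration bound (",
         maxTotal, "); a Monte-Carlo test would be required", call. = FALSE)
  rs <- rowSums(m); cs <- colSums(m)
  logConst <- sum(.lfact(rs)) + sum(.lfact(cs)) - .lfact(n)
  logpObs <- logConst - sum(.lfact(m))
  acc <- new.env(parent = emptyenv())
  acc$total <- 0
  .enumTables(rs, cs, matrix(0L, nrow(m), ncol(m)), 1L, logConst, logpObs, acc)
  res <- list(statistic = logpObs, p.value = min(1, acc$total),
              effect.size.r = NA_real_,
              method = "Fisher exact test (RxC, full enumeration)")
  class(res) <- "stressTest"
  res
}

# Depth-first enumeration over rows of all tables with the given margins.
.enumTables <- function(rs, cs, cur, row, logConst, logpObs, acc) {
  R <- length(rs); C <- length(cs)
  if (row > R) {
    logp <- logConst - sum(.lfact(cur))
    if (logp <= logpObs + 1e-7) acc$total <- acc$total + exp(logp)
    return(invisible())
  }
  remain <- cs - if (row == 1L) 0L else colSums(cur[seq_len(row - 1L), ,
                                                    drop = FALSE])
  # rows after this one still need sum(rs[(row+1):R]) spread over columns
  later <- if (row < R) sum(rs[(row + 1L):R]) else 0L
  fillRow <- function(col, left) {
    if (col == C) {
      if (left <= remain[C]) {
        cur[row, C] <<- left
        .enumTables(rs, cs, cur, row + 1L, logConst, logpObs, acc)
      }
      return(invisible())
    }
    lo <- max(0L, left - sum(remain[(col + 1L):C]))
    hi <- min(remain[col], left)
    if (hi >= lo) for (v in lo:hi) {
      cur[row, col] <<- v
      fillRow(col + 1L, left - v)
    }
  }
  fillRow(1L, rs[row])
  invisible()
}

#' Two-sample pooled-variance Student t-test
#'
#' Two-sided t-test with the pooled-variance statistic on
#' `n_x + n_y - 2` degrees of freedom. Degenerate inputs follow explicit
#' conventions: zero pooled variance with equal means gives p = 1; zero
#' pooled variance with unequal means gives p = 0 with a warning.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return A `"stressTest"` list with `statistic` (t), `p.value`, `df`, and
#'   `method`.
#' @export
studentT <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  pooled <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  dm <- mean(x) - mean(y)
  if (pooled <= 0) {
    if (abs(dm) < 1e-12) {
      res <- list(statistic = 0, p.value = 1, df = df,
                  method = "Student t (pooled variance; degenerate, equal means)")
    } else {
      warning("zero pooled variance with unequal means; p set to 0")
      res <- list(statistic = sign(dm) * Inf, p.value = 0, df = df,
                  method = "Student t (pooled variance; degenerate, unequal means)")
    }
  } else {
    t <- dm / sqrt(pooled * (1 / nx + 1 / ny))
    res <- list(statistic = t, p.value = 2 * stats::pt(-abs(t), df), df = df,
                method = "Student t (pooled variance, two-sided)")
  }
  res$effect.size.r <- NA_real_
  class(res) <- "stressTest"
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]); output order matches input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, elementwise >= `p` and <= 1.
#' @export
bhAdjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' @export
print.stressTest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g, p = %.6g", x$statistic, x$p.value))
  if (!is.null(x$effect.size.r) && !is.na(x$effect.size.r))
    cat(sprintf(", r = %.3f", x$effect.size.r))
  cat("\n")
  invisible(x)
}
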