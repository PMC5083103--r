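# Exact nonparametric test kernel.
#
# These tests back every p-value in the pipeline: the paired signed-rank test
# for per-probe transcriptome changes, the rank-sum test for two-group
# fold-change comparisons, Fisher's exact test for over-representation, and
# Kendall's tau-b for the cross-omics concordance association. Each test runs
# an exact enumeration within a small-sample regime (tie-capable, unlike the
# base-R equivalents) and a tie-corrected normal approximation above it.

.newTestResult <- function(statistic, p, method, n, exact,
                           degenerate = FALSE, ...) {
  res <- list(statistic = unname(statistic), p.value = unname(p),
              method = method, n = n, exact = exact,
              degenerate = degenerate, ...)
  class(res) <- "adjTestResult"
  res
}

#' @export
print.adjTestResult <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      ", p = ", format(x$p.value),
      ", n = ", x$n,
      if (x$exact) " (exact)" else " (approximate)",
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

.twoSidedFromTails <- function(lower, upper) min(1, 2 * min(lower, upper))

#' Exact Wilcoxon signed-rank test for paired differences
#'
#' Tests symmetry of paired differences about zero. Zero differences are
#' dropped (Wilcoxon's original treatment); ties among absolute differences
#' receive mid-ranks. For \code{n <= exactMax} the null distribution of the
#' positive-rank sum is enumerated exactly over all \eqn{2^n} sign patterns
#' (via a generating-polynomial convolution, so ties are handled exactly);
#' above that a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x numeric vector of differences, or first member of pairs if
#'   \code{y} is given.
#' @param y optional numeric vector; differences are \code{x - y}.
#' @param exactMax largest n (after dropping zeros) for exact enumeration.
#' @return An \code{adjTestResult} list: \code{statistic} (positive-rank sum
#'   W+), two-sided \code{p.value}, \code{n}, \code{exact}, \code{degenerate}.
#' @examples
#' wilcoxonSignedRank(c(1.2, 0.8, 2.1, 0.4, 1.7))$p.value  # 2/32
#' @export
wilcoxonSignedRank <- function(x, y = NULL, exactMax = 25) {
  d <- if (is.null(y)) x else x - y
  stopifnot(is.numeric(d))
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(.newTestResult(0, 1, "Wilcoxon signed-rank", 0, TRUE,
                          degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exactMax) {
    # doubled ranks are integers even with mid-ranks
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    dist <- numeric(tot + 1L)  # dist[k+1] = #patterns with doubled W = k
    dist[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(tot + 1L - ri)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    w2 <- as.integer(round(2 * w))
    lower <- sum(dist[seq_len(w2 + 1L)])
    upper <- sum(dist[seq.int(w2 + 1L, tot + 1L)])
    p <- .twoSidedFromTails(lower, upper)
    return(.newTestResult(w, p, "Wilcoxon signed-rank", n, TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  .newTestResult(w, p, "Wilcoxon signed-rank", n, FALSE)
}

#' Exact Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test that two samples come from the same distribution, based on
#' the rank sum of the first group with mid-ranks for ties. For combined
#' sample sizes \code{<= exactMax} the permutation null of the rank sum is
#' enumerated over all assignments of group labels; above that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param exactMax largest combined n for exact enumeration.
#' @return An \code{adjTestResult}; \code{statistic} is the rank sum of
#'   \code{x}.
#' @examples
#' wilcoxonRankSum(c(1, 2, 3, 4), c(10, 11, 12, 13))$p.value  # 2/70
#' @export
wilcoxonRankSum <- function(x, y, exactMax = 20) {
  stopifnot(is.numeric(x), is.numeric(y))
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    .stopf("both groups must be non-empty")
  }
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (N <= exactMax) {
    r2 <- as.integer(round(2 * r))
    sums <- combn(r2, nx, FUN = sum)
    w2 <- as.integer(round(2 * w))
    lower <- mean(sums <= w2)
    upper <- mean(sums >= w2)
    p <- .twoSidedFromTails(lower, upper)
    return(.newTestResult(w, p, "Wilcoxon rank-sum", N, TRUE))
  }
  mu <- nx * (N + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  .newTestResult(w, p, "Wilcoxon rank-sum", N, FALSE)
}

#' Fisher's exact test on a 2x2 table with odds ratio
#'
#' Exact hypergeometric test of independence in a 2x2 contingency table. The
#' two-sided p sums all point probabilities not exceeding the observed
#' table's (the \code{fisher.test} convention); one-sided alternatives sum
#' the corresponding tail. The sample odds ratio is \eqn{ad/bc}; tables with
#' a zero in the off-diagonal (or diagonal) product report \code{Inf} (or 0)
#' and are flagged.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   \code{rbind(c(a, b), c(c, d))}.
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (enrichment of cell \code{a}), or \code{"less"}.
#' @return An \code{adjTestResult} with \code{odds.ratio} and
#'   \code{or.flagged} fields; \code{statistic} is the odds ratio.
#' @examples
#' fisherExactTest(rbind(c(5, 5), c(15, 75)))$odds.ratio  # 5
#' @export
fisherExactTest <- function(table,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) .stopf("table must be 2x2")
  if (any(tb < 0) || any(!.isWholeNumber(tb))) {
    .stopf("table cells must be non-negative integers")
  }
  a <- tb[1, 1]; b <- tb[1, 2]; cc <- tb[2, 1]; dd <- tb[2, 2]
  m <- a + b; nn <- cc + dd; k <- a + cc
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  pObs <- dhyper(a, m, nn, k)
  p <- switch(alternative,
    two.sided = sum(probs[probs <= pObs * (1 + 1e-7)]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]))
  p <- min(1, p)
  num <- a * dd; den <- b * cc
  flagged <- (num == 0) || (den == 0)
  orr <- if (num == 0 && den == 0) NaN else if (den == 0) Inf else num / den
  .newTestResult(orr, p, paste0("Fisher exact (", alternative, ")"),
                 sum(tb), TRUE, odds.ratio = orr, or.flagged = flagged)
}

# Concordant/discordant pair counts and tie terms from a cross-tabulation of
# two ordinal vectors; O(r*c) in the number of distinct value pairs.
.kendallCounts <- function(x, y) {
  tab <- table(factor(x, levels = sort(unique(x))),
               factor(y, levels = sort(unique(y))))
  r <- nrow(tab); cl <- ncol(tab)
  C <- 0; D <- 0
  for (i in seq_len(r)) {
    for (j in seq_len(cl)) {
      nij <- tab[i, j]
      if (nij == 0) next
      if (i < r && j < cl) {
        C <- C + nij * sum(tab[(i + 1):r, (j + 1):cl])
      }
      if (i < r && j > 1) {
        D <- D + nij * sum(tab[(i + 1):r, 1:(j - 1)])
      }
    }
  }
  list(C = C, D = D,
       t = rowSums(tab)[rowSums(tab) > 0],
       u = colSums(tab)[colSums(tab) > 0])
}

#' Kendall's tau-b rank correlation with significance
#'
#' Tau-b with tie corrections in both margins. Significance comes from exact
#' enumeration over all permutations of \code{y} for \code{n <= exactMax},
#' otherwise from the normal approximation of S = C - D with the standard
#' tie-term variance. Constant input vectors make tau undefined; such calls
#' are flagged degenerate with p = 1.
#'
#' @param x,y equal-length numeric (ordinal) vectors.
#' @param exactMax largest n for the exact permutation null.
#' @return An \code{adjTestResult}; \code{statistic} is tau-b, with fields
#'   \code{S} (C - D) and \code{tau}.
#' @export
kendallTauB <- function(x, y, exactMax = 8) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) .stopf("need at least 2 paired observations")
  kc <- .kendallCounts(x, y)
  n0 <- n * (n - 1) / 2
  Tt <- sum(kc$t * (kc$t - 1) / 2)
  Uu <- sum(kc$u * (kc$u - 1) / 2)
  if (n0 - Tt <= 0 || n0 - Uu <= 0) {
    return(.newTestResult(NA_real_, 1, "Kendall tau-b", n, TRUE,
                          degenerate = TRUE, S = 0, tau = NA_real_))
  }
  S <- kc$C - kc$D
  tau <- S / sqrt((n0 - Tt) * (n0 - Uu))
  if (n <= exactMax) {
    perms <- .permutations(n)
    sx <- sign(outer(x, x, "-"))
    sy <- sign(outer(y, y, "-"))
    up <- upper.tri(sx)
    sObs <- abs(S)
    hits <- 0L
    for (i in seq_len(nrow(perms))) {
      pp <- perms[i, ]
      sPerm <- sum(sx[up] * sy[pp, pp][up])
      if (abs(sPerm) >= sObs - 1e-9) hits <- hits + 1L
    }
    p <- hits / nrow(perms)
    return(.newTestResult(tau, p, "Kendall tau-b", n, TRUE, S = S, tau = tau))
  }
  t <- kc$t; u <- kc$u
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(t * (t - 1) * (2 * t + 5))
  vu <- sum(u * (u - 1) * (2 * u + 5))
  v1 <- sum(t * (t - 1)) * sum(u * (u - 1)) / (2 * n * (n - 1))
  v2 <- sum(t * (t - 1) * (t - 2)) * sum(u * (u - 1) * (u - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(varS)
  p <- min(1, 2 * pnorm(-abs(z)))
  .newTestResult(tau, p, "Kendall tau-b", n, FALSE, S = S, tau = tau)
}

#' Two-tailed Student's t test (pooled variance)
#'
#' Classic equal-variance two-sample t test, the form used for targeted
#' confirmation assays comparing stimulated samples with unstimulated
#' controls.
#'
#' @param x,y numeric vectors, each with at least 2 values.
#' @return An \code{adjTestResult}; \code{statistic} is t with
#'   \code{df = nx + ny - 2}.
#' @export
tTestTwoTailed <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) .stopf("each group needs n >= 2")
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 <= 0) {
    return(.newTestResult(0, 1, "Student t (pooled)", nx + ny, FALSE,
                          degenerate = TRUE, df = df))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  p <- 2 * pt(-abs(tstat), df)
  .newTestResult(tstat, p, "Student t (pooled)", nx + ny, FALSE, df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate; the
#' adjustment behind every "FDR < 5%" call in the pipeline.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return numeric vector of adjusted values, same length and order.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
fdrAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
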