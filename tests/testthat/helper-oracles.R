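# Brute-force enumeration oracles, independent of the package's
# implementations: used to pin the exact-test and clustering contracts.

# Signed-rank: enumerate all 2^n sign patterns over the observed |d| ranks.
oracleSignedRank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, p = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ws <- apply(patterns, 1, function(s) sum(r[unlist(s)]))
  lower <- mean(Ws <= W + 1e-9)
  upper <- mean(Ws >= W - 1e-9)
  list(W = W, p = min(1, 2 * min(lower, upper)))
}

# Rank-sum: enumerate all assignments of nx labels among N observations.
oracleRankSum <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  W <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(r), nx)
  Ws <- apply(combos, 2, function(idx) sum(r[idx]))
  lower <- mean(Ws <= W + 1e-9)
  upper <- mean(Ws >= W - 1e-9)
  list(W = W, p = min(1, 2 * min(lower, upper)))
}

# Fisher: hypergeometric point probabilities from binomial coefficients.
oracleFisher <- function(a, b, cc, dd) {
  m <- a + b; nn <- cc + dd; k <- a + cc
  support <- max(0, k - nn):min(k, m)
  probs <- choose(m, support) * choose(nn, k - support) / choose(m + nn, k)
  pObs <- choose(m, a) * choose(nn, k - a) / choose(m + nn, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Kendall: S = C - D by explicit double loop; exact p over all
# permutations of y.
oracleTauS <- function(x, y) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  S
}

oracleTauExactP <- function(x, y) {
  perms <- allPerms(length(y))
  sObs <- abs(oracleTauS(x, y))
  hits <- 0L
  for (i in seq_len(nrow(perms))) {
    if (abs(oracleTauS(x, y[perms[i, ]])) >= sObs - 1e-9) hits <- hits + 1L
  }
  hits / nrow(perms)
}

allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(seq_len(n)[-k][sub], nrow(sub)))
  }))
}

# Exhaustive greedy Ward: at every step recompute, from the original
# distance matrix, the Ward.D2 merge cost for every pair of current
# clusters using the centroid identity
#   D^2(A, B) = 2 |A||B| / (|A| + |B|) * (M_AB - V_A - V_B)
# with M_AB the mean squared between-cluster distance and V_A the
# within-cluster dispersion (1/(2|A|^2)) * sum of squared distances.
oracleWard <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  clusters <- lapply(seq_len(n), identity)
  ids <- seq_len(n)
  merges <- list()
  heights <- numeric()
  vOf <- function(A) sum(d2[A, A]) / (2 * length(A)^2)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- NULL; bestVal <- Inf
    for (i in seq_len(k - 1)) {
      for (j in seq.int(i + 1, k)) {
        A <- clusters[[i]]; B <- clusters[[j]]
        mAB <- mean(d2[A, B])
        val <- 2 * length(A) * length(B) / (length(A) + length(B)) *
          (mAB - vOf(A) - vOf(B))
        if (val < bestVal - 1e-12) {
          bestVal <- val; best <- c(i, j)
        } else if (abs(val - bestVal) <= 1e-12) {
          pair <- sort(c(ids[i], ids[j]))
          cur <- sort(c(ids[best[1]], ids[best[2]]))
          if (pair[1] < cur[1] || (pair[1] == cur[1] && pair[2] < cur[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    merges[[step]] <- as.integer(sort(c(ids[i], ids[j])))
    heights[step] <- sqrt(max(0, bestVal))
    clusters <- c(clusters[-c(i, j)],
                  list(c(clusters[[i]], clusters[[j]])))
    ids <- c(ids[-c(i, j)], n + step)
  }
  list(merges = merges, heights = heights)
}

# Translate an hclust merge matrix into the oracle's (id, id) pairs, where
# leaves are 1..n and merge k creates id n + k.
hclustMergeIds <- function(h) {
  n <- nrow(h$merge) + 1
  lapply(seq_len(nrow(h$merge)), function(k) {
    as.integer(sort(vapply(h$merge[k, ], function(v) {
      if (v < 0) -v else n + v
    }, numeric(1))))
  })
}
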