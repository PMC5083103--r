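# Two-way agglomerative clustering of the condition x protein fold-change
# matrix: Pearson correlation distance with Ward's minimum-variance
# aggregation (Ward.D2 semantics: Lance-Williams recursion on squared
# distances), with a deterministic tie-break so the dendrogram is a
# reproducible contract, not an implementation accident.

#' Pearson correlation distance between rows or columns
#'
#' d(u, v) = 1 - r(u, v) with r the Pearson correlation, so d lies in
#' [0, 2], 0 for identical profiles and 2 for exactly anti-correlated ones.
#'
#' @param x numeric matrix.
#' @param axis cluster \code{"rows"} or \code{"columns"}.
#' @return full symmetric distance matrix with zero diagonal.
#' @export
pearsonDistance <- function(x, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- if (axis == "rows") t(as.matrix(x)) else as.matrix(x)
  if (ncol(m) < 2) .stopf("need >= 2 vectors to compute distances")
  if (nrow(m) < 2) .stopf("each vector needs length >= 2")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    .stopf("zero-variance %s: %s (filter constant profiles first)",
           axis, paste(colnames(m)[sds == 0], collapse = ", "))
  }
  d <- 1 - cor(m)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Ward's minimum-variance agglomerative clustering
#'
#' Agglomerates by the Ward.D2 criterion via the Lance-Williams update on
#' squared cluster distances. Ties on the merge criterion are broken by the
#' lexicographically smallest pair of cluster indices (leaves are 1..n in
#' input order; merged clusters take indices n+1, n+2, ... in formation
#' order). Within each merge the subtree containing the smaller minimal
#' original leaf index is placed first, which fixes the leaf order.
#'
#' @param d square symmetric non-negative distance matrix with zero
#'   diagonal (e.g. from \link{pearsonDistance}).
#' @return An object of class \code{"hclust"} (fields \code{merge},
#'   \code{height}, \code{order}, \code{labels}), usable with
#'   \code{stats::cutree}, \code{cophenetic}, plotting, etc.
#' @export
wardCluster <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) .stopf("need >= 2 items to cluster")
  if (!isSymmetric(unname(d), tol = 1e-10) || any(d < 0) ||
      any(abs(diag(d)) > 1e-12)) {
    .stopf("distance matrix must be symmetric, non-negative, zero-diagonal")
  }
  labels <- rownames(d)
  D2 <- d^2
  active <- seq_len(n)              # current cluster ids (1..n leaves, then n+k)
  sizes <- rep(1, n)
  members <- as.list(seq_len(n))    # original leaf indices per cluster
  hcIndex <- -seq_len(n)            # hclust merge coding: negative = leaf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  nodeOrder <- vector("list", n)    # leaf order within each cluster
  nodeOrder[seq_len(n)] <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    # find minimal D2 with deterministic lexicographic tie-break on ids
    best <- c(NA, NA); bestVal <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        v <- D2[i, j]
        if (v < bestVal - 1e-12) {
          bestVal <- v; best <- c(i, j)
        } else if (abs(v - bestVal) <= 1e-12) {
          # tie: smaller (id_i, id_j) pair wins
          ids <- sort(c(active[i], active[j]))
          cur <- sort(c(active[best[1]], active[best[2]]))
          if (ids[1] < cur[1] || (ids[1] == cur[1] && ids[2] < cur[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    height[step] <- sqrt(max(0, bestVal))
    merge[step, ] <- {
      a <- hcIndex[i]; b <- hcIndex[j]
      if (a < 0 && b < 0) sort(c(a, b), decreasing = TRUE)  # (-small,-large)
      else if (a < 0) c(a, b) else if (b < 0) c(b, a) else sort(c(a, b))
    }
    # leaf order: subtree with smaller minimal original index first
    mi <- min(members[[i]]); mj <- min(members[[j]])
    newOrder <- if (mi <= mj) c(nodeOrder[[i]], nodeOrder[[j]])
                else c(nodeOrder[[j]], nodeOrder[[i]])
    # Lance-Williams (ward.D2) update of squared distances
    ni <- sizes[i]; nj <- sizes[j]
    newD2 <- vapply(seq_len(k), function(h) {
      if (h == i || h == j) return(NA_real_)
      nh <- sizes[h]
      ((ni + nh) * D2[i, h] + (nj + nh) * D2[j, h] - nh * D2[i, j]) /
        (ni + nj + nh)
    }, numeric(1))
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- D2[keep, keep, drop = FALSE]
    D2 <- rbind(cbind(D2, newD2[keep]), c(newD2[keep], 0))
    active <- c(active[keep], n + step)
    sizes <- c(sizes[keep], ni + nj)
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    nodeOrder <- c(nodeOrder[keep], list(newOrder))
    hcIndex <- c(hcIndex[keep], step)
  }
  structure(list(merge = merge, height = height,
                 order = nodeOrder[[1]],
                 labels = labels, method = "ward.D2",
                 dist.method = "pearson", call = match.call()),
            class = "hclust")
}

#' Two-way hierarchical clustering of a z-scored fold-change matrix
#'
#' Rows (proteins) and columns (conditions) are clustered independently
#' with \link{pearsonDistance} + \link{wardCluster}; the heatmap matrix is
#' reordered by both leaf orders. Rows must be non-constant (apply the
#' inclusion filter and drop constant rows first).
#'
#' @param x z-scored numeric matrix (e.g. \code{zscoreRows} of the
#'   condition-level log2 fold-change summary).
#' @return list of class \code{"TwoWayClustering"}: \code{rows} and
#'   \code{columns} (\code{hclust} trees; \code{rows} is NULL for a 1-row
#'   matrix), and \code{matrix}, the input reordered by both leaf orders.
#' @export
twoWayCluster <- function(x) {
  x <- as.matrix(x)
  colDist <- if (nrow(x) == 1) {
    # single-protein matrix: correlation between scalar columns is
    # undefined; fall back to absolute differences
    as.matrix(dist(t(x)))
  } else {
    pearsonDistance(x, "columns")
  }
  colTree <- wardCluster(colDist)
  rowTree <- NULL
  rowOrder <- seq_len(nrow(x))
  if (nrow(x) >= 2) {
    rowTree <- wardCluster(pearsonDistance(x, "rows"))
    rowOrder <- rowTree$order
  }
  out <- list(rows = rowTree, columns = colTree,
              matrix = x[rowOrder, colTree$order, drop = FALSE])
  class(out) <- "TwoWayClustering"
  out
}

#' @export
print.TwoWayClustering <- function(x, ...) {
  cat("TwoWayClustering:", nrow(x$matrix), "rows x", ncol(x$matrix),
      "columns\n  column leaf order:",
      paste(colnames(x$matrix), collapse = ", "), "\n")
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights (parent height minus child
#' height; leaves sit at height 0).
#'
#' @param h an \code{"hclust"} object.
#' @return single-element character vector, semicolon-terminated.
#' @export
hclustToNewick <- function(h) {
  labels <- if (is.null(h$labels)) as.character(seq_len(nrow(h$merge) + 1))
            else h$labels
  build <- function(node) {
    if (node < 0) return(list(str = labels[-node], h = 0))
    a <- build(h$merge[node, 1])
    b <- build(h$merge[node, 2])
    hh <- h$height[node]
    list(str = sprintf("(%s:%.12g,%s:%.12g)", a$str, hh - a$h,
                       b$str, hh - b$h),
         h = hh)
  }
  paste0(build(nrow(h$merge))$str, ";")
}
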