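# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rpois rnbinom rbinom median pnorm pt dhyper
#'   phyper cor sd p.adjust setNames complete.cases quantile var
#' @importFrom utils combn read.delim write.table head
#' @importFrom tools md5sum
NULL

# Round-half-up to integer percent; reproduces 617/1519 -> 41, 565/1717 -> 33.
.roundHalfUp <- function(x) floor(x + 0.5)

# Deterministic substream seed: one user seed fans out to named streams so
# adding a stage never perturbs earlier draws. Kept below 2^31.
.substreamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 2017) %% 2147483647)
}

# Evaluate expr under a local RNG state; global stream untouched.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Strict TSV writer: tab-only, no quoting, '.' decimal, UTF-8.
.writeTsv <- function(df, path, rowFirstColName = NULL) {
  if (!is.null(rowFirstColName)) {
    df <- cbind(setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                         rowFirstColName),
                as.data.frame(df, check.names = FALSE))
    rownames(df) <- NULL
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# All permutations of 1..n as an (n! x n) matrix; n <= 9.
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    idx <- seq.int(row, row + nrow(sub) - 1L)
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}
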