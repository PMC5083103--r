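# Preprocessing for the cluster analysis: half-minimum imputation of
# undetected cells, total-count normalization to the largest sample, protein
# length normalization, per-subject fold changes against the paired control,
# and row z-scoring of the condition-level log2 fold-change summary.
#
# Missing vs zero: a missing cell means "not detected/reported"; a literal
# 0 means zero spectra were exported for a detected-elsewhere protein. Both
# denote absence of spectral evidence, so the experiment-level imputation
# floors both to the half-minimum (keeping fold-change denominators
# positive — the point of the imputation), while detection calls in the
# filter module always use the raw counts.

#' Impute missing spectral counts with the data set's half-minimum
#'
#' Every missing (undetected) cell is set to half the minimum positive
#' observed count of the whole data set — 0.5 when the minimum observed
#' count is 1 — which floors all values above zero so later fold-change
#' ratios never divide by zero. Observed cells (including literal zeros) are
#' untouched.
#'
#' For a \code{SpectralCountExperiment} the result gains an \code{"imputed"}
#' assay plus a logical \code{"observed"} assay, and the imputation value is
#' recorded in \code{metadata(x)$imputed_value}. In that method observed
#' zero counts are floored to the same half-minimum by default
#' (\code{floorZeros = TRUE}): a zero-spectra cell carries no more
#' detection evidence than an absent one, and the floor is what keeps the
#' later fold-change denominators positive. The matrix method never touches
#' observed cells.
#'
#' @param x numeric matrix with NA for missing cells, or a
#'   \code{SpectralCountExperiment}.
#' @param floorZeros experiment method only: also floor observed zeros.
#' @return Same class as the input.
#' @export
setGeneric("imputeHalfMin",
           function(x, floorZeros = TRUE) standardGeneric("imputeHalfMin"))

#' @rdname imputeHalfMin
#' @export
setMethod("imputeHalfMin", "matrix", function(x, floorZeros = FALSE) {
  obs <- x[!is.na(x)]
  pos <- obs[obs > 0]
  if (!length(pos)) .stopf("cannot impute: no positive observed count")
  half <- min(pos) / 2
  x[is.na(x)] <- half
  if (floorZeros) x[x == 0] <- half
  attr(x, "imputed_value") <- half
  x
})

#' @rdname imputeHalfMin
#' @export
setMethod("imputeHalfMin", "SpectralCountExperiment",
          function(x, floorZeros = TRUE) {
  cts <- assay(x, "counts")
  imp <- imputeHalfMin(cts, floorZeros = floorZeros)
  assay(x, "observed") <- !is.na(cts)
  attr(imp, "imputed_value") <- NULL
  assay(x, "imputed") <- imp
  metadata(x)$imputed_value <- min(cts[!is.na(cts) & cts > 0]) / 2
  x
})

#' Normalize samples to the maximum total spectral count
#'
#' Each sample's values are multiplied by (maximum column total across
#' samples) / (that sample's column total), so all column totals equal the
#' pre-scaling maximum. Idempotent.
#'
#' @param x numeric matrix with no missing cells (impute first), or a
#'   \code{SpectralCountExperiment} carrying an \code{"imputed"} assay.
#' @param byAge for the experiment method: normalize within each age cohort
#'   separately (default, each cohort forms its own data set) or jointly.
#' @return Matrix with a \code{"norm_factors"} attribute, or the experiment
#'   with a \code{"normalized"} assay and \code{norm_factor} column in
#'   \code{colData}.
#' @export
setGeneric("normalizeTotalSpc",
           function(x, byAge = TRUE) standardGeneric("normalizeTotalSpc"))

#' @rdname normalizeTotalSpc
#' @export
setMethod("normalizeTotalSpc", "matrix", function(x, byAge = TRUE) {
  if (any(is.na(x))) .stopf("matrix has missing cells; impute first")
  totals <- colSums(x)
  zero <- totals <= 0
  if (any(zero)) {
    .stopf("zero-total sample(s): %s",
           paste(colnames(x)[zero], collapse = ", "))
  }
  f <- max(totals) / totals
  out <- sweep(x, 2, f, `*`)
  attr(out, "norm_factors") <- f
  out
})

#' @rdname normalizeTotalSpc
#' @export
setMethod("normalizeTotalSpc", "SpectralCountExperiment",
          function(x, byAge = TRUE) {
  if (!"imputed" %in% assayNames(x)) x <- imputeHalfMin(x)
  imp <- assay(x, "imputed")
  norm <- imp
  factors <- numeric(ncol(imp))
  names(factors) <- colnames(imp)
  groups <- if (byAge) split(seq_len(ncol(x)), sampleInfo(x)$age_group)
            else list(all = seq_len(ncol(x)))
  for (idx in groups) {
    sub <- normalizeTotalSpc(imp[, idx, drop = FALSE])
    norm[, idx] <- sub
    factors[idx] <- attr(sub, "norm_factors")
  }
  assay(x, "normalized") <- norm
  colData(x)$norm_factor <- factors
  x
})

#' Divide each protein's values by its length in amino acids
#'
#' Produces counts per residue, the length-normalized quantity the
#' differential model compares (inside the model itself, length enters the
#' exposure offset so the likelihood stays on integer counts).
#'
#' @param x numeric matrix (proteins x samples).
#' @param lengths named numeric vector of protein lengths covering every row
#'   of \code{x}, or a data.frame with \code{accession}/\code{length}.
#' @return matrix of the same shape.
#' @export
lengthNormalize <- function(x, lengths) {
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$accession)
  }
  miss <- setdiff(rownames(x), names(lengths))
  if (length(miss)) {
    .stopf("protein(s) without length: %s",
           paste(head(miss, 5), collapse = ", "))
  }
  len <- lengths[rownames(x)]
  if (any(!is.finite(len) | len < 1)) .stopf("lengths must be >= 1")
  sweep(x, 1, len, `/`)
}

#' Per-subject fold changes and condition-level log2 summaries
#'
#' For each treated sample with a same-subject, same-age control, the
#' fold change per protein is normalized treated / normalized control;
#' the condition summary is the arithmetic mean of log2 fold changes across
#' that condition's subjects. Subjects lacking a control are excluded (with
#' the design's warning at \code{validateDesign} time).
#'
#' @param x a \code{SpectralCountExperiment} carrying a \code{"normalized"}
#'   assay (run \code{normalizeTotalSpc} first), or a plain normalized
#'   matrix.
#' @param design a \link{PairedDesign} from \code{validateDesign}.
#' @return A list of class \code{"FoldChangeMatrix"}:
#'   \describe{
#'     \item{fc}{proteins x pairs matrix of fold changes (> 0)}
#'     \item{pairs}{data.frame describing each pair column}
#'     \item{log2_summary}{proteins x condition matrix of mean log2 FC,
#'       condition names \code{"<age>.<treatment>"}}
#'   }
#' @export
foldChange <- function(x, design) {
  stopifnot(is(design, "PairedDesign"))
  m <- if (is(x, "SpectralCountExperiment")) {
    if (!"normalized" %in% assayNames(x)) {
      .stopf("run normalizeTotalSpc() before foldChange()")
    }
    assay(x, "normalized")
  } else {
    as.matrix(x)
  }
  pr <- design@pairs
  missing <- setdiff(c(pr$control_sample, pr$treated_sample), colnames(m))
  if (length(missing)) {
    .stopf("design references sample(s) absent from matrix: %s",
           paste(missing, collapse = ", "))
  }
  ctrl <- m[, pr$control_sample, drop = FALSE]
  trt <- m[, pr$treated_sample, drop = FALSE]
  if (any(ctrl <= 0)) {
    .stopf("control values must be positive; impute missing cells first")
  }
  fc <- trt / ctrl
  colnames(fc) <- paste(pr$age_group, pr$treatment, pr$subject_id, sep = ".")
  cond <- paste(pr$age_group, pr$treatment, sep = ".")
  condLevels <- unique(cond)
  l2 <- log2(fc)
  summary <- vapply(condLevels, function(cl) {
    rowMeans(l2[, cond == cl, drop = FALSE])
  }, numeric(nrow(fc)))
  if (nrow(fc) == 1L) summary <- matrix(summary, nrow = 1,
                                        dimnames = list(rownames(fc),
                                                        condLevels))
  out <- list(fc = fc, pairs = pr, log2_summary = summary)
  class(out) <- "FoldChangeMatrix"
  out
}

#' @export
print.FoldChangeMatrix <- function(x, ...) {
  cat("FoldChangeMatrix:", nrow(x$fc), "proteins x", ncol(x$fc),
      "subject pairs;", ncol(x$log2_summary), "condition summaries\n")
  invisible(x)
}

#' Z-score each row of a matrix
#'
#' Centers each row to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). Constant rows map to all zeros so the matrix shape
#' is stable; such rows are excluded from clustering by the inclusion filter
#' anyway.
#'
#' @param x numeric matrix with >= 2 columns.
#' @return matrix of the same shape.
#' @export
zscoreRows <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) .stopf("z-scoring needs >= 2 columns")
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  out <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  out[sdv == 0, ] <- 0
  out
}
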