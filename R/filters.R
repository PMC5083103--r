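# Inclusion/exclusion rules and the condition-overlap (Venn) accounting.
# "Detected" always means observed (non-missing) and > 0 in the raw counts;
# imputed half-minimum cells never count as detection. Each rule is
# evaluated on the raw evidence, independently of the other rules.

.detectionMatrix <- function(x) {
  cts <- spcCounts(x)
  !is.na(cts) & cts > 0
}

.conditionOf <- function(x) {
  cd <- sampleInfo(x)
  paste(cd$age_group, cd$treatment, sep = ".")
}

#' Exclude singleton single-spectrum proteins
#'
#' Flags proteins whose entire detection evidence is a single count of
#' exactly 1, in one sample of one condition; such proteins are excluded
#' from all downstream analyses.
#'
#' @param x a \code{SpectralCountExperiment}.
#' @return data.frame per protein: \code{n_detections}, \code{max_count},
#'   \code{n_conditions}, \code{excluded}.
#' @export
exclusionFilter <- function(x) {
  det <- .detectionMatrix(x)
  cts <- spcCounts(x)
  cond <- .conditionOf(x)
  nDet <- rowSums(det)
  maxCount <- apply(ifelse(det, cts, NA), 1, function(v) {
    if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
  })
  nCond <- apply(det, 1, function(d) length(unique(cond[d])))
  data.frame(
    accession = rownames(x),
    n_detections = nDet,
    max_count = maxCount,
    n_conditions = nCond,
    excluded = nDet == 1 & maxCount == 1,
    row.names = rownames(x),
    stringsAsFactors = FALSE)
}

#' Cluster-analysis inclusion filter
#'
#' A protein enters the clustering for a treatment condition iff, within
#' that condition's treated samples, (a) its total raw spectra are >= 2,
#' (b) it is detected in >= 2 biological samples, and (c) its per-subject
#' fold change is >= \code{fcMin} in strictly more than half of that
#' condition's replicates (ties at exactly half fail).
#'
#' @param x a \code{SpectralCountExperiment}.
#' @param fc a \code{"FoldChangeMatrix"} from \link{foldChange}.
#' @param fcMin fold-change threshold (default 2).
#' @param minSpectra total-spectra threshold (default 2).
#' @param perSample if TRUE, rule (a) instead requires one sample alone to
#'   reach \code{minSpectra} (the stricter per-sample reading).
#' @return list of class \code{"InclusionReport"}: \code{pass} (proteins x
#'   conditions logical), plus per-rule matrices \code{spectra_ok},
#'   \code{samples_ok}, \code{fc_ok}.
#' @export
clusterInclusionFilter <- function(x, fc, fcMin = 2, minSpectra = 2,
                                   perSample = FALSE) {
  stopifnot(inherits(fc, "FoldChangeMatrix"))
  det <- .detectionMatrix(x)
  cts <- spcCounts(x)
  cd <- sampleInfo(x)
  pr <- fc$pairs
  cond <- paste(pr$age_group, pr$treatment, sep = ".")
  condLevels <- unique(cond)
  res <- lapply(condLevels, function(cl) {
    treatedSamples <- pr$treated_sample[cond == cl]
    sub <- cts[, treatedSamples, drop = FALSE]
    subDet <- det[, treatedSamples, drop = FALSE]
    totalSpectra <- rowSums(ifelse(subDet, sub, 0))
    spectraOk <- if (perSample) {
      apply(ifelse(subDet, sub, 0), 1, max) >= minSpectra
    } else {
      totalSpectra >= minSpectra
    }
    samplesOk <- rowSums(subDet) >= 2
    fcCols <- fc$fc[, cond == cl, drop = FALSE]
    nRep <- ncol(fcCols)
    fcOk <- rowSums(fcCols >= fcMin) > nRep / 2   # strictly more than half
    cbind(spectra = spectraOk, samples = samplesOk, fold = fcOk)
  })
  pass <- vapply(res, function(m) m[, "spectra"] & m[, "samples"] & m[, "fold"],
                 logical(nrow(cts)))
  spectraOk <- vapply(res, function(m) m[, "spectra"], logical(nrow(cts)))
  samplesOk <- vapply(res, function(m) m[, "samples"], logical(nrow(cts)))
  fcOk <- vapply(res, function(m) m[, "fold"], logical(nrow(cts)))
  dn <- list(rownames(cts), condLevels)
  dimnames(pass) <- dimnames(spectraOk) <- dimnames(samplesOk) <-
    dimnames(fcOk) <- dn
  out <- list(pass = pass, spectra_ok = spectraOk, samples_ok = samplesOk,
              fc_ok = fcOk, fc_min = fcMin, min_spectra = minSpectra)
  class(out) <- "InclusionReport"
  out
}

#' @export
print.InclusionReport <- function(x, ...) {
  cat("InclusionReport:", nrow(x$pass), "proteins x", ncol(x$pass),
      "conditions;", sum(rowSums(x$pass) > 0),
      "protein(s) pass in >= 1 condition\n")
  invisible(x)
}

#' Integer percentage, rounded half-up
#'
#' The percentage convention of the condition-overlap summaries:
#' \code{overlapPercent(617, 1519)} is 41 and \code{overlapPercent(565,
#' 1717)} is 33.
#'
#' @param count,total non-negative numbers, \code{total > 0}.
#' @return integer percent.
#' @export
overlapPercent <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  .roundHalfUp(100 * count / total)
}

#' Condition-overlap (Venn) summary per age group
#'
#' For each age group, computes per-condition protein detection sets, the
#' intersection over all conditions (with its integer percentage of the
#' nonredundant total), per-condition unique counts, and their mean and mean
#' percentage.
#'
#' @param x a \code{SpectralCountExperiment}.
#' @param applyExclusion drop proteins failing \link{exclusionFilter} first
#'   (default TRUE).
#' @param includeControl count the control condition as one of the sets
#'   (default TRUE).
#' @return list per age group, each with \code{total}, \code{common},
#'   \code{common_pct}, \code{per_condition} (named detection counts),
#'   \code{unique_counts}, \code{mean_unique}, \code{mean_unique_pct}.
#' @export
conditionOverlap <- function(x, applyExclusion = TRUE,
                             includeControl = TRUE) {
  det <- .detectionMatrix(x)
  if (applyExclusion) {
    keep <- !exclusionFilter(x)$excluded
    det <- det[keep, , drop = FALSE]
  }
  cd <- sampleInfo(x)
  out <- list()
  for (age in unique(cd$age_group)) {
    sel <- cd$age_group == age
    if (!includeControl) sel <- sel & cd$treatment != controlLabel(x)
    treatments <- unique(cd$treatment[sel])
    if (length(treatments) < 2) {
      .stopf("age group '%s' has < 2 conditions", age)
    }
    memb <- vapply(treatments, function(tr) {
      cols <- which(sel & cd$treatment == tr)
      rowSums(det[, cols, drop = FALSE]) > 0
    }, logical(nrow(det)))
    inAny <- rowSums(memb) > 0
    total <- sum(inAny)
    common <- sum(rowSums(memb) == length(treatments))
    uniqueCounts <- vapply(seq_along(treatments), function(j) {
      sum(memb[, j] & rowSums(memb) == 1)
    }, numeric(1))
    names(uniqueCounts) <- treatments
    meanUnique <- mean(uniqueCounts)
    out[[age]] <- list(
      total = total,
      common = common,
      common_pct = overlapPercent(common, total),
      per_condition = colSums(memb),
      unique_counts = uniqueCounts,
      mean_unique = meanUnique,
      mean_unique_pct = overlapPercent(meanUnique, total))
  }
  class(out) <- "OverlapSummary"
  out
}

#' @export
print.OverlapSummary <- function(x, ...) {
  for (age in names(x)) {
    s <- x[[age]]
    cat(sprintf("%s: %d nonredundant; %d (%d%%) common to all conditions; mean unique %.1f (%d%%)\n",
                age, s$total, s$common, s$common_pct, s$mean_unique,
                s$mean_unique_pct))
  }
  invisible(x)
}
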