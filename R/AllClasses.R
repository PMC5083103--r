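#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames assays colData rowData colData<- rowData<-
NULL

#' SpectralCountExperiment: proteins x samples spectral counts
#'
#' The pipeline's central container, a
#' \link[SummarizedExperiment]{SummarizedExperiment} whose \code{"counts"}
#' assay holds non-negative integer spectral counts with \code{NA} marking
#' cells where a protein was not detected/reported (kept distinct from a
#' literal 0, because undetected cells are later imputed with the data set's
#' half-minimum count). \code{colData} is the sample sheet (\code{age_group},
#' \code{treatment}, \code{subject_id}, \code{replicate}); \code{rowData}
#' carries protein metadata (\code{gene_symbol}, \code{length} in amino
#' acids). The control treatment label is stored in
#' \code{metadata(x)$control}.
#'
#' @slot .. see \link[SummarizedExperiment]{SummarizedExperiment}.
#' @aliases SpectralCountExperiment-class
#' @export
setClass("SpectralCountExperiment", contains = "SummarizedExperiment")

setValidity("SpectralCountExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object)) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    cts <- assay(object, "counts")
    vals <- cts[!is.na(cts)]
    if (length(vals) && (any(vals < 0) || any(!.isWholeNumber(vals)))) {
      msg <- c(msg, "counts must be non-negative integers where present")
    }
  }
  need <- c("age_group", "treatment", "subject_id")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss)) {
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(rownames(object))) {
    msg <- c(msg, "duplicate protein accessions")
  }
  if (anyDuplicated(colnames(object))) {
    msg <- c(msg, "duplicate sample ids")
  }
  ctrl <- metadata(object)$control
  if (is.null(ctrl) || length(ctrl) != 1L) {
    msg <- c(msg, "metadata(x)$control must name the single control treatment")
  } else if ("treatment" %in% colnames(colData(object)) &&
             !ctrl %in% colData(object)$treatment) {
    msg <- c(msg, sprintf("control treatment '%s' absent from sample sheet",
                          ctrl))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectralCountExperiment
#'
#' @param counts numeric matrix (proteins x samples), integer counts with
#'   \code{NA} for undetected cells; must have row and column names.
#' @param sampleData data.frame with one row per sample (matched by
#'   \code{sample_id} column or rownames) carrying \code{age_group},
#'   \code{treatment}, \code{subject_id} and optionally \code{replicate}.
#' @param proteinData optional data.frame keyed by accession (column
#'   \code{accession} or rownames) with \code{gene_symbol} and \code{length}.
#' @param control label of the control (vehicle) treatment.
#' @return A \code{SpectralCountExperiment}.
#' @examples
#' cts <- matrix(c(3L, NA, 2L, 4L), 2, 2,
#'               dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"),
#'                     age_group = "adult", treatment = c("control", "Alum"),
#'                     subject_id = "S1")
#' sce <- SpectralCountExperiment(cts, sheet)
#' @export
SpectralCountExperiment <- function(counts, sampleData, proteinData = NULL,
                                    control = "control") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    .stopf("counts must have protein rownames and sample colnames")
  }
  sampleData <- as.data.frame(sampleData)
  if ("sample_id" %in% colnames(sampleData)) {
    rownames(sampleData) <- sampleData$sample_id
  }
  miss <- setdiff(colnames(counts), rownames(sampleData))
  if (length(miss)) {
    .stopf("sample(s) in count matrix absent from sample sheet: %s",
           paste(miss, collapse = ", "))
  }
  sampleData <- sampleData[colnames(counts), , drop = FALSE]
  if (!"replicate" %in% colnames(sampleData)) sampleData$replicate <- 1L
  rd <- if (is.null(proteinData)) {
    DataFrame(row.names = rownames(counts))
  } else {
    proteinData <- as.data.frame(proteinData)
    if ("accession" %in% colnames(proteinData)) {
      rownames(proteinData) <- proteinData$accession
    }
    missp <- setdiff(rownames(counts), rownames(proteinData))
    if (length(missp)) {
      .stopf("protein(s) missing from protein info: %s",
             paste(head(missp, 5), collapse = ", "))
    }
    DataFrame(proteinData[rownames(counts), , drop = FALSE])
  }
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(sampleData),
    rowData = rd,
    metadata = list(control = control))
  new("SpectralCountExperiment", se)
}

#' @describeIn SpectralCountExperiment raw spectral-count assay.
#' @param x a \code{SpectralCountExperiment}.
#' @export
spcCounts <- function(x) assay(x, "counts")

#' @describeIn SpectralCountExperiment sample sheet as a data.frame.
#' @export
sampleInfo <- function(x) as.data.frame(colData(x))

#' @describeIn SpectralCountExperiment protein metadata as a data.frame.
#' @export
proteinInfo <- function(x) as.data.frame(rowData(x))

#' @describeIn SpectralCountExperiment the control treatment label.
#' @export
controlLabel <- function(x) metadata(x)$control

setMethod("show", "SpectralCountExperiment", function(object) {
  cts <- assay(object, "counts")
  cat("SpectralCountExperiment:", nrow(object), "proteins x",
      ncol(object), "samples\n")
  cat("  treatments:",
      paste(unique(colData(object)$treatment), collapse = ", "),
      "(control:", metadata(object)$control, ")\n")
  cat("  age groups:",
      paste(unique(colData(object)$age_group), collapse = ", "), "\n")
  cat(sprintf("  missing cells: %d (%.1f%%); assays: %s\n",
              sum(is.na(cts)), 100 * mean(is.na(cts)),
              paste(assayNames(object), collapse = ", ")))
  invisible(NULL)
})

#' PairedDesign: resolved subject-level control/treated pairing
#'
#' Maps every treated sample to its same-subject, same-age control. Subjects
#' lacking a control (e.g. the study design's one unpaired newborn) are kept
#' but flagged incomplete and excluded from per-subject fold changes and the
#' paired count model.
#'
#' @slot pairs data.frame: \code{age_group}, \code{treatment},
#'   \code{subject_id}, \code{control_sample}, \code{treated_sample}.
#' @slot incomplete character, subject ids lacking a control sample.
#' @slot control control treatment label.
#' @export
setClass("PairedDesign",
         representation(pairs = "data.frame", incomplete = "character",
                        control = "character"))

setMethod("show", "PairedDesign", function(object) {
  cat("PairedDesign:", nrow(object@pairs), "treated/control pairs;",
      length(unique(object@pairs$subject_id)), "complete subject(s);",
      length(object@incomplete), "incomplete subject(s)\n")
  invisible(NULL)
})

#' DifferentialResult: per-protein paired count-model statistics
#'
#' A \link[S4Vectors]{DataFrame} subclass with one row per protein for one
#' (age group, treatment) contrast: \code{log2FC}, \code{SE} (natural-log
#' scale), moderated \code{Z}, two-sided \code{p}, BH \code{fdr},
#' \code{significant} (fdr < threshold), \code{direction} and a
#' \code{flag} column (\code{"ok"}, \code{"uninformative"},
#' \code{"boundary"}). Contrast metadata lives in \code{metadata()}.
#'
#' @aliases DifferentialResult-class
#' @export
setClass("DifferentialResult", contains = "DFrame")

setMethod("show", "DifferentialResult", function(object) {
  md <- metadata(object)
  cat(sprintf(
    "DifferentialResult: %s / %s vs %s; %d proteins, %d significant at FDR < %g\n",
    md$age_group, md$treatment, md$control, nrow(object),
    sum(object$significant), md$fdr_threshold))
  callNextMethod()
})
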