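# Readers/writers for the pipeline's tables: strict TSV (tab-only, no
# quoting, '.' decimal), GMT gene sets, and design validation. Readers
# reject malformed input with file/line/field coordinates rather than
# coercing.

#' Read a spectral-count matrix from TSV
#'
#' First column (header \code{"id"} or anything else) holds protein
#' accessions; remaining columns are samples. Empty cells and the
#' \code{missing} sentinel parse as missing (NA); every other cell must be a
#' non-negative integer.
#'
#' @param path TSV file.
#' @param missing character sentinel(s) treated as missing besides the empty
#'   cell.
#' @return numeric matrix with NA for missing cells.
#' @export
readSpcMatrix <- function(path, missing = "NA") {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "",
                   na.strings = NULL, fileEncoding = "UTF-8")
  if (ncol(df) < 2) .stopf("%s: need an id column plus >= 1 sample", path)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    .stopf("%s: duplicate protein id(s): %s", path,
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) .stopf("%s: duplicate sample id(s)", path)
  m <- matrix(NA_real_, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    cell <- df[[j + 1]]
    isMissing <- is.na(cell) | cell == "" | cell %in% missing
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!isMissing & (is.na(val) | !.isWholeNumber(val) | val < 0))
    if (length(bad)) {
      .stopf("%s: non-integer count '%s' at row %d (protein %s), column '%s'",
             path, cell[bad[1]], bad[1], ids[bad[1]], samples[j])
    }
    val[isMissing] <- NA_real_
    m[, j] <- val
  }
  m
}

#' Write a spectral-count matrix to TSV
#'
#' Missing cells are written as the empty string so the file round-trips
#' through \code{readSpcMatrix}.
#'
#' @param m matrix with protein rownames and sample colnames.
#' @param path output file.
#' @export
writeSpcMatrix <- function(m, path) {
  df <- as.data.frame(m, check.names = FALSE)
  df[] <- lapply(df, function(v) ifelse(is.na(v), "", format(v, trim = TRUE,
                                                             scientific = FALSE)))
  .writeTsv(df, path, rowFirstColName = "id")
}

#' Read a sample sheet TSV
#'
#' Requires columns \code{sample_id}, \code{age_group}, \code{treatment},
#' \code{subject_id}; \code{replicate} defaults to 1.
#'
#' @param path TSV file.
#' @return data.frame keyed by \code{sample_id}.
#' @export
readSampleSheet <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   quote = "", fileEncoding = "UTF-8",
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "age_group", "treatment", "subject_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    .stopf("%s: sample sheet lacks column(s): %s", path,
           paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) .stopf("%s: duplicate sample_id", path)
  if (!"replicate" %in% colnames(df)) df$replicate <- 1L
  key <- paste(df$age_group, df$subject_id, df$treatment, df$replicate)
  if (anyDuplicated(key)) {
    .stopf("%s: (subject, treatment, replicate) duplicated within age group",
           path)
  }
  rownames(df) <- df$sample_id
  df
}

#' Read a protein info TSV
#'
#' Requires columns \code{accession}, \code{gene_symbol}, \code{length}
#' (amino acids, positive integer).
#'
#' @param path TSV file.
#' @return data.frame keyed by accession.
#' @export
readProteinInfo <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   quote = "", fileEncoding = "UTF-8",
                   stringsAsFactors = FALSE)
  need <- c("accession", "gene_symbol", "length")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    .stopf("%s: protein info lacks column(s): %s", path,
           paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$accession)) .stopf("%s: duplicate accession", path)
  if (any(!.isWholeNumber(df$length) | df$length < 1)) {
    .stopf("%s: protein lengths must be positive integers", path)
  }
  rownames(df) <- df$accession
  df
}

#' Read a GMT gene-set file
#'
#' Standard GMT: per line, set name, description, then members, all
#' tab-separated. Duplicated members within a set are removed, keeping first
#' occurrence order.
#'
#' @param path GMT file.
#' @return named list of character member vectors, with a
#'   \code{"descriptions"} attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      .stopf("%s: line %d has %d field(s); GMT needs name, description, >= 1 member",
             path, i, length(fields))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) .stopf("%s: line %d: empty member list", path, i)
    sets[[fields[1]]] <- members
    desc[fields[1]] <- fields[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors (optionally with a
#'   \code{"descriptions"} attribute).
#' @param path output file.
#' @export
writeGmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a numeric (expression) matrix from TSV
#'
#' First column is the row id; remaining cells must be finite numbers
#' (missing not permitted for the expression arm).
#'
#' @param path TSV file.
#' @return numeric matrix.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   quote = "", fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(!is.finite(m))) {
    .stopf("%s: expression matrix contains missing/non-numeric cells", path)
  }
  m
}

#' Read an id-mapping TSV (source_id, target_id)
#'
#' Many-to-many rows are permitted; fully duplicated rows are dropped.
#'
#' @param path TSV file with >= 2 columns.
#' @return data.frame with columns \code{source_id}, \code{target_id}.
#' @export
readIdMap <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   quote = "", fileEncoding = "UTF-8",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stopf("%s: id map needs >= 2 columns", path)
  out <- data.frame(source_id = as.character(df[[1]]),
                    target_id = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  out[!duplicated(out), , drop = FALSE]
}

#' Resolve the paired control/treated design of an experiment
#'
#' For every non-control sample, finds the same-subject, same-age control.
#' Subjects without a control are retained but flagged incomplete (the study
#' design this models had six paired subjects per age plus one unpaired
#' newborn), with a warning.
#'
#' @param x a \code{SpectralCountExperiment}.
#' @return A \link{PairedDesign}.
#' @export
validateDesign <- function(x) {
  stopifnot(is(x, "SpectralCountExperiment"))
  cd <- sampleInfo(x)
  ctrl <- controlLabel(x)
  key <- paste(cd$age_group, cd$subject_id)
  ctrlRows <- cd[cd$treatment == ctrl, , drop = FALSE]
  dupCtrl <- duplicated(paste(ctrlRows$age_group, ctrlRows$subject_id))
  if (any(dupCtrl)) {
    .stopf("subject(s) with two control samples: %s",
           paste(unique(ctrlRows$subject_id[dupCtrl]), collapse = ", "))
  }
  ctrlOf <- setNames(ctrlRows$sample_id,
                     paste(ctrlRows$age_group, ctrlRows$subject_id))
  treated <- cd[cd$treatment != ctrl, , drop = FALSE]
  hasCtrl <- paste(treated$age_group, treated$subject_id) %in% names(ctrlOf)
  incomplete <- unique(treated$subject_id[!hasCtrl])
  if (length(incomplete)) {
    .warnf("subject(s) without a control sample (kept, flagged incomplete): %s",
           paste(incomplete, collapse = ", "))
  }
  tt <- treated[hasCtrl, , drop = FALSE]
  pairs <- data.frame(
    age_group = tt$age_group,
    treatment = tt$treatment,
    subject_id = tt$subject_id,
    control_sample = unname(ctrlOf[paste(tt$age_group, tt$subject_id)]),
    treated_sample = tt$sample_id,
    stringsAsFactors = FALSE)
  new("PairedDesign", pairs = pairs, incomplete = as.character(incomplete),
      control = ctrl)
}
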