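# Cross-omics extrapolation: quantile-normalize the paired-timepoint
# expression matrix, call per-gene changes with the exact paired
# signed-rank test (min-p probe collapses a gene's probes), map genes to
# secretome proteins, and test direction concordance of the two layers by
# Kendall's tau-b against a fixed background of measurable genes.

#' Quantile-normalize an expression matrix
#'
#' Classic quantile normalization: each column's ranks are mapped onto the
#' cross-column mean of order statistics, after which every column shares
#' the same multiset of values (up to tie averaging; tied values receive
#' the mean of their would-be reference quantiles). Missing values are an
#' error — imputation is not defined for the expression arm.
#'
#' @param e numeric probes x samples matrix.
#' @return matrix of the same shape.
#' @export
quantileNormalize <- function(e) {
  e <- as.matrix(e)
  if (any(is.na(e))) .stopf("expression matrix has missing values")
  if (ncol(e) < 2) return(e)
  out <- limma::normalizeQuantiles(e, ties = TRUE)
  dimnames(out) <- dimnames(e)
  out
}

#' Call per-gene expression changes between two timepoints
#'
#' Per probe, runs the exact paired Wilcoxon signed-rank test on
#' (to - from) across participants having both timepoints; the direction is
#' the sign of the median paired difference. Each gene keeps its minimum-p
#' probe as unique representative; significance is called at p <
#' \code{alpha}. Probes not mapped to any gene are retained under their own
#' id with a warning.
#'
#' @param e numeric probes x samples matrix (normalized).
#' @param samples data.frame with \code{sample_id}, \code{participant},
#'   \code{timepoint}.
#' @param probeMap data.frame \code{source_id} (probe), \code{target_id}
#'   (gene).
#' @param from_tp,to_tp timepoint labels compared (default T1 vs T2).
#' @param alpha per-gene significance threshold (default 0.05).
#' @return data.frame, one row per gene: \code{gene_id}, \code{probe_id}
#'   (representative), \code{p}, \code{direction} (\code{"up"}/\code{"down"}),
#'   \code{significant}.
#' @export
callGeneChanges <- function(e, samples, probeMap, from_tp = "T1",
                            to_tp = "T2", alpha = 0.05) {
  rownames(samples) <- samples$sample_id
  fromS <- samples[samples$timepoint == from_tp, ]
  toS <- samples[samples$timepoint == to_tp, ]
  common <- intersect(fromS$participant, toS$participant)
  if (length(common) < 2) {
    .stopf("need both timepoints for >= 2 participants")
  }
  fromCols <- fromS$sample_id[match(common, fromS$participant)]
  toCols <- toS$sample_id[match(common, toS$participant)]
  diffs <- e[, toCols, drop = FALSE] - e[, fromCols, drop = FALSE]
  probes <- rownames(e)
  pv <- numeric(length(probes))
  dir <- character(length(probes))
  for (i in seq_along(probes)) {
    d <- diffs[i, ]
    res <- wilcoxonSignedRank(d)
    pv[i] <- res$p.value
    md <- median(d)
    dir[i] <- if (md > 0) "up" else if (md < 0) "down"
              else if (mean(d) >= 0) "up" else "down"
  }
  geneOf <- setNames(probeMap$target_id, probeMap$source_id)
  gene <- geneOf[probes]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    .warnf("%d probe(s) unmapped to a gene; retained under their own ids",
           sum(unmapped))
    gene[unmapped] <- probes[unmapped]
  }
  tab <- data.frame(gene_id = unname(gene), probe_id = probes, p = pv,
                    direction = dir, stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene_id, tab$p, tab$probe_id), ]
  tab <- tab[!duplicated(tab$gene_id), ]       # min-p probe per gene
  tab$significant <- tab$p < alpha
  rownames(tab) <- tab$gene_id
  tab
}

#' Match transcriptome genes with secretome proteins
#'
#' Inner join of a gene-call table with a differential result through a
#' gene-to-protein id map; many-to-many mappings yield one row per distinct
#' (gene, protein) pair. Unmatched molecule counts are attached as
#' attributes.
#'
#' @param genes gene-call table from \link{callGeneChanges}.
#' @param prot a \link{DifferentialResult}.
#' @param map data.frame \code{source_id} (gene), \code{target_id}
#'   (protein accession).
#' @return data.frame per matched pair: gene and protein ids, each layer's
#'   p, direction and significance.
#' @export
matchMolecules <- function(genes, prot, map) {
  map <- map[!duplicated(map[, c("source_id", "target_id")]), , drop = FALSE]
  m <- map[map$source_id %in% genes$gene_id &
             map$target_id %in% rownames(prot), , drop = FALSE]
  if (nrow(m) == 0) {
    .warnf("no molecule matched between gene calls and differential result")
  }
  gi <- match(m$source_id, genes$gene_id)
  pi <- match(m$target_id, rownames(prot))
  out <- data.frame(
    gene_id = m$source_id,
    accession = m$target_id,
    gene_p = genes$p[gi],
    gene_direction = genes$direction[gi],
    gene_significant = genes$significant[gi],
    protein_fdr = prot$fdr[pi],
    protein_direction = prot$direction[pi],
    protein_significant = prot$significant[pi],
    stringsAsFactors = FALSE)
  attr(out, "unmatched_genes") <- sum(!genes$gene_id %in% m$source_id)
  attr(out, "unmatched_proteins") <- sum(!rownames(prot) %in% m$target_id)
  out
}

#' Concordance test of secretome and transcriptome calls
#'
#' Encodes each layer's call per matched molecule as ternary (-1 not
#' significant-down, 0 not significant, +1 significant-up), pads both
#' vectors with (0, 0) for the background molecules measurable but not
#' matched (default background: the 12,893 unique genes of the array
#' platform this models), and tests association with Kendall's tau-b.
#' Also reports the concordant-molecule count: significant in both layers
#' with equal sign.
#'
#' @param matched data.frame from \link{matchMolecules}.
#' @param background_n size of the background set (>= matched rows).
#' @return list of class \code{"ConcordanceResult"}: \code{n_matched},
#'   \code{n_concordant}, \code{background_n}, \code{tau_b}, \code{p},
#'   \code{calls} (the ternary call table).
#' @export
concordanceTest <- function(matched, background_n = 12893) {
  if (background_n < nrow(matched)) {
    .stopf("background_n (%d) < matched molecules (%d)", background_n,
           nrow(matched))
  }
  tern <- function(sig, dir) {
    ifelse(sig, ifelse(dir == "up", 1, -1), 0)
  }
  sCall <- tern(matched$protein_significant, matched$protein_direction)
  tCall <- tern(matched$gene_significant, matched$gene_direction)
  pad <- background_n - nrow(matched)
  xx <- c(sCall, rep(0, pad))
  yy <- c(tCall, rep(0, pad))
  kt <- kendallTauB(xx, yy, exactMax = 8)
  nConc <- sum(sCall != 0 & tCall != 0 & sCall == tCall)
  out <- list(n_matched = nrow(matched), n_concordant = nConc,
              background_n = background_n,
              tau_b = kt$tau, p = kt$p.value,
              degenerate = kt$degenerate,
              calls = data.frame(gene_id = matched$gene_id,
                                 accession = matched$accession,
                                 secretome = sCall, transcriptome = tCall,
                                 stringsAsFactors = FALSE))
  class(out) <- "ConcordanceResult"
  out
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf(
    "ConcordanceResult: %d matched molecules, %d concordant; tau-b = %s, p = %s (background %d)\n",
    x$n_matched, x$n_concordant, format(x$tau_b, digits = 3),
    format(x$p, digits = 3), x$background_n))
  invisible(x)
}

#' GO-term co-occurrence fraction
#'
#' Fraction of the secretome's significant terms also significant in the
#' transcriptome data set: |intersection| / |secretome terms|.
#'
#' @param secretomeTerms non-empty character vector of terms.
#' @param transcriptomeTerms character vector of terms.
#' @return list: \code{fraction}, \code{n_overlap}, \code{n_secretome},
#'   \code{n_transcriptome}.
#' @export
goOverlapFraction <- function(secretomeTerms, transcriptomeTerms) {
  secretomeTerms <- unique(secretomeTerms)
  transcriptomeTerms <- unique(transcriptomeTerms)
  if (!length(secretomeTerms)) .stopf("secretome term set is empty")
  ov <- intersect(secretomeTerms, transcriptomeTerms)
  list(fraction = length(ov) / length(secretomeTerms),
       n_overlap = length(ov),
       n_secretome = length(secretomeTerms),
       n_transcriptome = length(transcriptomeTerms))
}
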