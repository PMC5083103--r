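# Stage runner: drives the whole pipeline (or one stage) over a flat
# configuration, writing TSV/GMT/JSON artifacts plus a machine-readable run
# manifest (input hashes, seed, thresholds) per stage. Deterministic given
# the same inputs and seed; single-threaded by design. The thin Rscript
# wrapper in inst/scripts/secretome-pipeline.R exposes the same stages from
# a shell.

#' Default pipeline configuration
#'
#' Flat key-value configuration mirroring the thresholds the method
#' defines: FDR 0.05, fold change 2, per-probe p 0.05, concordance
#' background 12893. Any subset can be overridden via \code{...} or loaded
#' from a YAML file with \link{readPipelineConfig}.
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    n_subjects_per_age = 6,
    n_proteins = 500,
    frac_responsive = 0.2,
    effect_log2fc = 2,
    dropout_rate = 0.15,
    unpaired_newborn = FALSE,
    fdr = 0.05,
    fc = 2.0,
    p = 0.05,
    background_n = 12893,
    frac_concordant = 0.5,
    timepoints = 4,
    n_participants = 24,
    n_genesets = 20,
    normalize_by_age = TRUE,
    overlap_after_exclusion = TRUE)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) .stopf("unknown configuration key(s): %s",
                          paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$fdr <= 0 || cfg$fdr >= 1) .stopf("config error: fdr must be in (0,1)")
  if (cfg$p <= 0 || cfg$p >= 1) .stopf("config error: p must be in (0,1)")
  if (cfg$fc < 1) .stopf("config error: fc must be >= 1")
  cfg
}

#' Read a flat YAML pipeline configuration
#'
#' @param path YAML file of key: value pairs (same keys as
#'   \link{pipelineConfig}).
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.stageFile <- function(outDir, name) file.path(outDir, name)

.requireArtifacts <- function(outDir, files, neededBy, producedBy) {
  missing <- files[!file.exists(file.path(outDir, files))]
  if (length(missing)) {
    .stopf("stage '%s' needs artifact(s) %s; run stage '%s' first",
           neededBy, paste(missing, collapse = ", "), producedBy)
  }
}

.writeManifest <- function(outDir, stage, cfg, outputs) {
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    thresholds = cfg[c("fdr", "fc", "p", "background_n")],
    outputs = lapply(setNames(outputs, outputs), function(f) {
      unname(tools::md5sum(file.path(outDir, f)))
    }))
  jsonlite::write_json(manifest,
                       file.path(outDir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.loadStudy <- function(outDir) {
  m <- readSpcMatrix(.stageFile(outDir, "counts.tsv"))
  sheet <- readSampleSheet(.stageFile(outDir, "samples.tsv"))
  info <- readProteinInfo(.stageFile(outDir, "proteins.tsv"))
  SpectralCountExperiment(m, sheet, proteinData = info)
}

#' Run the pipeline end-to-end or stage by stage
#'
#' Stages: \code{simulate} (write the synthetic fixture set),
#' \code{normalize} (impute + total-count normalize), \code{filter}
#' (exclusion/inclusion rules + condition overlap), \code{cluster}
#' (two-way Ward/Pearson clustering, Newick export), \code{diffexp}
#' (paired count model per contrast), \code{enrich} (over-representation
#' of significant proteins), \code{concord} (transcriptome concordance) or
#' \code{all}. Each stage checks its prerequisites' artifacts and writes a
#' manifest with file hashes, the seed and thresholds.
#'
#' @param stage one stage name or \code{"all"}.
#' @param outDir artifact directory (created if absent).
#' @param config configuration from \link{pipelineConfig}.
#' @return invisibly, the artifact directory.
#' @export
runPipeline <- function(stage = c("all", "simulate", "normalize", "filter",
                                  "cluster", "diffexp", "enrich", "concord"),
                        outDir, config = pipelineConfig()) {
  stage <- match.arg(stage)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") {
    c("simulate", "normalize", "filter", "cluster", "diffexp", "enrich",
      "concord")
  } else {
    stage
  }
  for (st in stages) {
    switch(st,
      simulate = .stageSimulate(outDir, config),
      normalize = .stageNormalize(outDir, config),
      filter = .stageFilter(outDir, config),
      cluster = .stageCluster(outDir, config),
      diffexp = .stageDiffexp(outDir, config),
      enrich = .stageEnrich(outDir, config),
      concord = .stageConcord(outDir, config))
  }
  invisible(outDir)
}

.stageSimulate <- function(outDir, cfg) {
  sim <- simulationConfig(
    n_subjects_per_age = cfg$n_subjects_per_age,
    n_proteins = cfg$n_proteins,
    frac_responsive = cfg$frac_responsive,
    effect_log2fc = cfg$effect_log2fc,
    dropout_rate = cfg$dropout_rate,
    unpaired_newborn = cfg$unpaired_newborn,
    seed = cfg$seed)
  study <- simulateSpcExperiment(sim)
  tx <- simulateTranscriptome(sim, timepoints = cfg$timepoints,
                              frac_concordant = cfg$frac_concordant,
                              n_participants = cfg$n_participants)
  writeSpcMatrix(spcCounts(study@sce), .stageFile(outDir, "counts.tsv"))
  .writeTsv(sampleInfo(study@sce), .stageFile(outDir, "samples.tsv"))
  .writeTsv(proteinInfo(study@sce), .stageFile(outDir, "proteins.tsv"))
  .writeTsv(study@truth, .stageFile(outDir, "truth.tsv"))
  .writeTsv(as.data.frame(tx$expr, check.names = FALSE),
            .stageFile(outDir, "expression.tsv"), rowFirstColName = "id")
  .writeTsv(tx$samples, .stageFile(outDir, "expression_samples.tsv"))
  .writeTsv(tx$probe_map, .stageFile(outDir, "probe_map.tsv"))
  .writeTsv(tx$gene_map, .stageFile(outDir, "gene_map.tsv"))
  .writeTsv(tx$truth, .stageFile(outDir, "expression_truth.tsv"))
  truthResponsive <- unique(study@truth$accession[study@truth$responsive])
  gs <- simulateGenesets(rownames(study@sce), truthResponsive,
                         n_sets = cfg$n_genesets, seed = cfg$seed)
  writeGmt(gs, .stageFile(outDir, "gene_sets.gmt"))
  .writeManifest(outDir, "simulate", cfg,
                 c("counts.tsv", "samples.tsv", "proteins.tsv", "truth.tsv",
                   "expression.tsv", "expression_samples.tsv",
                   "probe_map.tsv", "gene_map.tsv", "expression_truth.tsv",
                   "gene_sets.gmt"))
}

.stageNormalize <- function(outDir, cfg) {
  .requireArtifacts(outDir, c("counts.tsv", "samples.tsv", "proteins.tsv"),
                    "normalize", "simulate")
  sce <- .loadStudy(outDir)
  sce <- normalizeTotalSpc(imputeHalfMin(sce), byAge = cfg$normalize_by_age)
  norm <- assay(sce, "normalized")
  .writeTsv(as.data.frame(round(norm, 6), check.names = FALSE),
            .stageFile(outDir, "normalized.tsv"), rowFirstColName = "id")
  audit <- data.frame(sample_id = colnames(sce),
                      norm_factor = colData(sce)$norm_factor,
                      total_raw = colSums(spcCounts(sce), na.rm = TRUE))
  .writeTsv(audit, .stageFile(outDir, "normalization_audit.tsv"))
  .writeManifest(outDir, "normalize", cfg,
                 c("normalized.tsv", "normalization_audit.tsv"))
}

.stageFilter <- function(outDir, cfg) {
  .requireArtifacts(outDir, "normalized.tsv", "filter", "normalize")
  sce <- .loadStudy(outDir)
  sce <- normalizeTotalSpc(imputeHalfMin(sce), byAge = cfg$normalize_by_age)
  excl <- exclusionFilter(sce)
  design <- suppressWarnings(validateDesign(sce))
  fc <- foldChange(sce, design)
  incl <- clusterInclusionFilter(sce, fc, fcMin = cfg$fc)
  report <- data.frame(accession = rownames(sce),
                       excluded = excl$excluded,
                       included_conditions = rowSums(incl$pass))
  .writeTsv(report, .stageFile(outDir, "filter_report.tsv"))
  ov <- conditionOverlap(sce, applyExclusion = cfg$overlap_after_exclusion)
  jsonlite::write_json(lapply(unclass(ov), function(s) {
    lapply(s, function(v) if (length(v) > 1) as.list(v) else v)
  }), .stageFile(outDir, "overlap.json"), auto_unbox = TRUE, pretty = TRUE,
     digits = NA)
  .writeManifest(outDir, "filter", cfg,
                 c("filter_report.tsv", "overlap.json"))
}

.stageCluster <- function(outDir, cfg) {
  .requireArtifacts(outDir, "filter_report.tsv", "cluster", "filter")
  sce <- .loadStudy(outDir)
  sce <- normalizeTotalSpc(imputeHalfMin(sce), byAge = cfg$normalize_by_age)
  design <- suppressWarnings(validateDesign(sce))
  fc <- foldChange(sce, design)
  incl <- clusterInclusionFilter(sce, fc, fcMin = cfg$fc)
  keep <- rowSums(incl$pass) > 0
  z <- zscoreRows(fc$log2_summary[keep, , drop = FALSE])
  z <- z[apply(z, 1, sd) > 0, , drop = FALSE]
  cl <- twoWayCluster(z)
  writeLines(hclustToNewick(cl$columns),
             .stageFile(outDir, "columns.newick"))
  if (!is.null(cl$rows)) {
    writeLines(hclustToNewick(cl$rows), .stageFile(outDir, "rows.newick"))
  }
  .writeTsv(as.data.frame(round(cl$matrix, 6), check.names = FALSE),
            .stageFile(outDir, "heatmap_matrix.tsv"), rowFirstColName = "id")
  .writeManifest(outDir, "cluster", cfg,
                 c("columns.newick", "heatmap_matrix.tsv"))
}

.stageDiffexp <- function(outDir, cfg) {
  .requireArtifacts(outDir, "normalized.tsv", "diffexp", "normalize")
  sce <- .loadStudy(outDir)
  design <- suppressWarnings(validateDesign(sce))
  fits <- fitAllContrasts(sce, design, fdrThreshold = cfg$fdr)
  for (nm in names(fits)) {
    .writeTsv(as.data.frame(fits[[nm]]),
              .stageFile(outDir, sprintf("diffexp_%s.tsv", nm)))
  }
  byTreat <- split(names(fits),
                   sub("^[^.]+\\.", "", names(fits)))
  ageRows <- list()
  for (tr in names(byTreat)) {
    nb <- fits[[paste0("newborn.", tr)]]
    ad <- fits[[paste0("adult.", tr)]]
    if (!is.null(nb) && !is.null(ad)) {
      calls <- classifyAgeSpecificity(nb, ad)
      counts <- attr(calls, "counts")
      ageRows[[tr]] <- data.frame(treatment = tr,
                                  t(as.matrix(counts)))
    }
  }
  if (length(ageRows)) {
    .writeTsv(do.call(rbind, ageRows),
              .stageFile(outDir, "age_specificity.tsv"))
  }
  .writeManifest(outDir, "diffexp", cfg,
                 c(sprintf("diffexp_%s.tsv", names(fits)),
                   if (length(ageRows)) "age_specificity.tsv"))
}

.stageEnrich <- function(outDir, cfg) {
  .requireArtifacts(outDir, "gene_sets.gmt", "enrich", "simulate")
  first <- list.files(outDir, pattern = "^diffexp_.*\\.tsv$")
  if (!length(first)) {
    .stopf("stage 'enrich' needs diffexp results; run stage 'diffexp' first")
  }
  sets <- readGmt(.stageFile(outDir, "gene_sets.gmt"))
  rows <- list()
  for (f in first) {
    de <- read.delim(.stageFile(outDir, f), stringsAsFactors = FALSE)
    query <- de$accession[de$significant == "TRUE" | de$significant == TRUE]
    if (length(query) == 0) next
    er <- enrich(query, sets, universe = de$accession)
    er$contrast <- sub("^diffexp_(.*)\\.tsv$", "\\1", f)
    rows[[f]] <- er
  }
  if (!length(rows)) {
    .warnf("no contrast had significant proteins; empty enrichment output")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), p = numeric())
  .writeTsv(out, .stageFile(outDir, "enrichment.tsv"))
  .writeManifest(outDir, "enrich", cfg, "enrichment.tsv")
}

.stageConcord <- function(outDir, cfg) {
  .requireArtifacts(outDir, c("expression.tsv", "expression_samples.tsv",
                              "probe_map.tsv", "gene_map.tsv"),
                    "concord", "simulate")
  deFile <- "diffexp_adult.MPLA.tsv"
  if (!file.exists(.stageFile(outDir, deFile))) {
    .stopf("stage 'concord' needs artifact(s) %s; run stage 'diffexp' first",
           deFile)
  }
  e <- quantileNormalize(readExpressionMatrix(.stageFile(outDir,
                                                         "expression.tsv")))
  samples <- read.delim(.stageFile(outDir, "expression_samples.tsv"),
                        stringsAsFactors = FALSE)
  probeMap <- readIdMap(.stageFile(outDir, "probe_map.tsv"))
  geneMap <- readIdMap(.stageFile(outDir, "gene_map.tsv"))
  genes <- callGeneChanges(e, samples, probeMap, alpha = cfg$p)
  de <- read.delim(.stageFile(outDir, deFile), stringsAsFactors = FALSE)
  prot <- DataFrame(de, row.names = de$accession)
  matched <- matchMolecules(genes, prot, geneMap)
  res <- concordanceTest(matched, background_n = cfg$background_n)
  .writeTsv(genes, .stageFile(outDir, "gene_calls.tsv"))
  .writeTsv(matched, .stageFile(outDir, "matched_molecules.tsv"))
  jsonlite::write_json(list(n_matched = res$n_matched,
                            n_concordant = res$n_concordant,
                            background_n = res$background_n,
                            tau_b = res$tau_b, p = res$p),
                       .stageFile(outDir, "concordance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .writeManifest(outDir, "concord", cfg,
                 c("gene_calls.tsv", "matched_molecules.tsv",
                   "concordance.json"))
}
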