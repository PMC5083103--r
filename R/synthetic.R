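# Synthetic paired-design study generator with known ground truth.
#
# Emulates the statistical structure of the deposited data this pipeline
# targets: paired newborn/adult monocyte spectral-count experiments under
# {control, Alum, MPLA, R848} with treatment effects, subject-level
# baselines, mild count overdispersion and detection-limited (MNAR)
# dropout; and paired multi-timepoint PBMC expression arrays with a
# concordant gene subset, 2-3 probes per gene. A single user seed fans out
# to named substreams (proteins, truth, counts, dropout, expression,
# genesets) so adding a stage never perturbs earlier draws.

#' Simulation configuration
#'
#' Validated parameter set for the synthetic study. Defaults are the
#' package's study conditions: 6 paired subjects per age group (the design
#' this emulates had six paired subjects plus one optional unpaired
#' newborn), treatments control/Alum/MPLA/R848, 20% responsive proteins
#' with mean true log2 fold change 2, mild negative-binomial overdispersion
#' and detection-limited dropout. The two TLR-agonist treatments share 80%
#' of their responsive proteins with equal effects while the Alum-like set
#' is drawn independently, mirroring the clustering structure of the
#' modelled study.
#'
#' @param n_subjects_per_age paired subjects per age group.
#' @param treatments treatment labels; must contain \code{control} exactly
#'   once.
#' @param control the control label.
#' @param n_proteins number of proteins.
#' @param frac_responsive fraction of proteins responsive per treatment.
#' @param effect_log2fc mean true log2 fold-change magnitude of responsive
#'   proteins (direction set by \code{direction_up_prob}).
#' @param effect_sd SD of true log2 fold changes around the signed mean.
#' @param direction_up_prob probability a responsive protein is
#'   up-regulated. Up-regulated proteins are drawn from the below-median
#'   baseline pool (induced mediators start near the detection floor) and
#'   down-regulated ones from the above-median pool (suppression of
#'   constitutively secreted abundant proteins), which keeps per-sample
#'   totals — the differential model's exposure offsets — stable.
#' @param baseline_dispersion dispersion of the protein-by-subject gamma
#'   baseline heterogeneity (shared across one subject's treatment columns,
#'   as donor-level biology is); marginal counts are negative binomial with
#'   this dispersion (variance mu + dispersion * mu^2), Poisson at 0.
#' @param dropout_rate probability that a cell is subjected to a detection
#'   limit draw; low counts below the drawn limit become missing (MNAR).
#' @param protein_length_range integer range of protein lengths (aa).
#' @param baseline_mean_spc geometric-mean baseline spectral count.
#' @param protein_sd_log SD of log protein baselines.
#' @param subject_sd_log SD of log subject baseline factors.
#' @param tlr_shared_frac fraction of the R848-responsive set shared (with
#'   equal effects) with the MPLA set, when both labels are present.
#' @param unpaired_newborn add one extra newborn subject without a control
#'   sample (the 7-vs-6 design).
#' @param seed integer RNG seed.
#' @return list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_subjects_per_age = 6,
                             treatments = c("control", "Alum", "MPLA", "R848"),
                             control = "control",
                             n_proteins = 500,
                             frac_responsive = 0.2,
                             effect_log2fc = 2,
                             effect_sd = 0.25,
                             direction_up_prob = 0.7,
                             baseline_dispersion = 0.05,
                             dropout_rate = 0.15,
                             protein_length_range = c(100L, 1500L),
                             baseline_mean_spc = 5,
                             protein_sd_log = 1,
                             subject_sd_log = 0.3,
                             tlr_shared_frac = 0.8,
                             unpaired_newborn = FALSE,
                             seed = 1L) {
  cfg <- list(n_subjects_per_age = n_subjects_per_age,
              treatments = treatments, control = control,
              n_proteins = n_proteins, frac_responsive = frac_responsive,
              effect_log2fc = effect_log2fc, effect_sd = effect_sd,
              direction_up_prob = direction_up_prob,
              baseline_dispersion = baseline_dispersion,
              dropout_rate = dropout_rate,
              protein_length_range = protein_length_range,
              baseline_mean_spc = baseline_mean_spc,
              protein_sd_log = protein_sd_log,
              subject_sd_log = subject_sd_log,
              tlr_shared_frac = tlr_shared_frac,
              unpaired_newborn = unpaired_newborn,
              seed = seed)
  .checkField <- function(cond, field, what) {
    if (!cond) .stopf("invalid configuration field '%s': %s", field, what)
  }
  .checkField(is.numeric(cfg$n_subjects_per_age) &&
                cfg$n_subjects_per_age >= 1 &&
                .isWholeNumber(cfg$n_subjects_per_age),
              "n_subjects_per_age", "must be a positive integer")
  .checkField(sum(cfg$treatments == cfg$control) == 1 &&
                length(cfg$treatments) >= 2,
              "treatments", "must include exactly one control label")
  .checkField(!anyDuplicated(cfg$treatments), "treatments",
              "labels must be unique")
  .checkField(cfg$n_proteins >= 1 && .isWholeNumber(cfg$n_proteins),
              "n_proteins", "must be a positive integer")
  for (f in c("frac_responsive", "dropout_rate", "tlr_shared_frac",
              "direction_up_prob")) {
    .checkField(is.numeric(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
                f, "must lie in [0, 1]")
  }
  .checkField(cfg$effect_log2fc >= 0, "effect_log2fc", "must be >= 0")
  .checkField(cfg$baseline_dispersion >= 0, "baseline_dispersion",
              "must be >= 0")
  .checkField(length(cfg$protein_length_range) == 2 &&
                all(cfg$protein_length_range >= 1) &&
                cfg$protein_length_range[1] <= cfg$protein_length_range[2],
              "protein_length_range", "must be an increasing positive pair")
  .checkField(is.numeric(cfg$seed) && .isWholeNumber(cfg$seed),
              "seed", "must be an integer")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' SyntheticStudy: simulated experiment plus ground truth
#'
#' @slot sce the simulated \link{SpectralCountExperiment}.
#' @slot truth data.frame: one row per protein x non-control treatment with
#'   \code{responsive} flag and true \code{log2fc}.
#' @slot config the \code{SimulationConfig} used.
#' @export
setClass("SyntheticStudy",
         representation(sce = "SpectralCountExperiment", truth = "data.frame",
                        config = "list"))

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy (seed", object@config$seed, "):\n")
  show(object@sce)
  cat("  truth:", sum(object@truth$responsive), "responsive protein-treatment",
      "flags over", nrow(object@truth), "rows\n")
  invisible(NULL)
})

.simProteins <- function(cfg) {
  .withSeed(.substreamSeed(cfg$seed, "proteins"), {
    acc <- sprintf("PROT%04d", seq_len(cfg$n_proteins))
    base <- cfg$baseline_mean_spc *
      exp(rnorm(cfg$n_proteins, 0, cfg$protein_sd_log))
    len <- sample(seq(cfg$protein_length_range[1],
                      cfg$protein_length_range[2]),
                  cfg$n_proteins, replace = TRUE)
    data.frame(accession = acc,
               gene_symbol = sprintf("GENE%04d", seq_len(cfg$n_proteins)),
               length = as.integer(len), baseline = base,
               row.names = acc, stringsAsFactors = FALSE)
  })
}

.simTruth <- function(cfg, prot) {
  treatments <- setdiff(cfg$treatments, cfg$control)
  k <- round(cfg$frac_responsive * cfg$n_proteins)
  lowPool <- which(prot$baseline <= median(prot$baseline))
  highPool <- which(prot$baseline > median(prot$baseline))
  if (!length(highPool)) highPool <- lowPool
  .withSeed(.substreamSeed(cfg$seed, "truth"), {
    sets <- list()
    effects <- list()
    # signed effects; up-regulated proteins from the low-baseline pool,
    # down-regulated from the high-baseline pool (see simulationConfig)
    drawSet <- function(kUp, kDown, exclude = integer()) {
      pick <- function(pool, n) pool[sample.int(length(pool), n)]
      up <- pick(setdiff(lowPool, exclude), kUp)
      down <- pick(setdiff(highPool, c(exclude, up)), kDown)
      list(idx = c(up, down),
           eff = c(rnorm(kUp, cfg$effect_log2fc, cfg$effect_sd),
                   rnorm(kDown, -cfg$effect_log2fc, cfg$effect_sd)))
    }
    kUp <- round(cfg$direction_up_prob * k)
    for (tr in treatments) {
      if (tr == "R848" && "MPLA" %in% names(sets) && k > 0) {
        nShared <- round(cfg$tlr_shared_frac * k)
        shared <- sets[["MPLA"]][seq_len(nShared)]
        sharedEff <- effects[["MPLA"]][seq_len(nShared)]
        nUpShared <- sum(sharedEff > 0)
        fresh <- drawSet(max(0, kUp - nUpShared),
                         max(0, (k - kUp) - (nShared - nUpShared)),
                         exclude = shared)
        sets[[tr]] <- c(shared, fresh$idx)
        effects[[tr]] <- c(sharedEff, fresh$eff)
      } else if (k > 0) {
        ds <- drawSet(kUp, k - kUp)
        sets[[tr]] <- ds$idx
        effects[[tr]] <- ds$eff
      } else {
        sets[[tr]] <- integer()
        effects[[tr]] <- numeric()
      }
    }
    truth <- do.call(rbind, lapply(treatments, function(tr) {
      resp <- seq_len(cfg$n_proteins) %in% sets[[tr]]
      l2 <- numeric(cfg$n_proteins)
      l2[sets[[tr]]] <- effects[[tr]]
      data.frame(accession = sprintf("PROT%04d", seq_len(cfg$n_proteins)),
                 treatment = tr, responsive = resp, log2fc = l2,
                 stringsAsFactors = FALSE)
    }))
    rownames(truth) <- NULL
    truth
  })
}

#' Simulate a paired spectral-count experiment
#'
#' Counts are negative-binomial (Poisson when dispersion is 0) around
#' subject-specific baselines shared across each subject's treatment
#' columns (the paired structure); responsive proteins are shifted by their
#' true log2 effect under their treatment; detection-limited dropout masks
#' low counts as missing.
#'
#' @param config a \code{SimulationConfig} from \link{simulationConfig}.
#' @return A \link{SyntheticStudy}.
#' @examples
#' study <- simulateSpcExperiment(simulationConfig(n_proteins = 50, seed = 7))
#' study
#' @export
simulateSpcExperiment <- function(config) {
  if (!inherits(config, "SimulationConfig")) {
    config <- do.call(simulationConfig, config)
  }
  cfg <- config
  prot <- .simProteins(cfg)
  truth <- .simTruth(cfg, prot)
  effMat <- matrix(0, cfg$n_proteins, length(cfg$treatments),
                   dimnames = list(prot$accession, cfg$treatments))
  for (tr in setdiff(cfg$treatments, cfg$control)) {
    sub <- truth[truth$treatment == tr, ]
    effMat[sub$accession, tr] <- sub$log2fc
  }
  ages <- c("newborn", "adult")
  sheet <- do.call(rbind, lapply(ages, function(age) {
    nSubj <- cfg$n_subjects_per_age +
      (age == "newborn" && cfg$unpaired_newborn)
    do.call(rbind, lapply(seq_len(nSubj), function(s) {
      trs <- cfg$treatments
      if (age == "newborn" && cfg$unpaired_newborn &&
          s == nSubj) {
        trs <- setdiff(trs, cfg$control)  # the unpaired subject: no control
      }
      data.frame(
        sample_id = sprintf("%s_S%02d_%s",
                            ifelse(age == "newborn", "NB", "AD"), s, trs),
        age_group = age, treatment = trs,
        subject_id = sprintf("%s_S%02d",
                             ifelse(age == "newborn", "NB", "AD"), s),
        replicate = 1L, stringsAsFactors = FALSE)
    }))
  }))
  rownames(sheet) <- sheet$sample_id
  counts <- .withSeed(.substreamSeed(cfg$seed, "counts"), {
    subj <- unique(sheet$subject_id)
    subjFactor <- setNames(exp(rnorm(length(subj), 0, cfg$subject_sd_log)),
                           subj)
    # protein x subject baseline heterogeneity: gamma(mean 1, var
    # baseline_dispersion) shared across a subject's treatment columns, so
    # marginal counts are negative binomial around the subject baseline
    # while the paired structure is preserved
    hetero <- matrix(1, cfg$n_proteins, length(subj),
                     dimnames = list(prot$accession, subj))
    if (cfg$baseline_dispersion >= 1e-12) {
      shape <- 1 / cfg$baseline_dispersion
      hetero[] <- stats::rgamma(length(hetero), shape = shape,
                                rate = shape)
    }
    m <- matrix(0, cfg$n_proteins, nrow(sheet),
                dimnames = list(prot$accession, sheet$sample_id))
    for (j in seq_len(nrow(sheet))) {
      mu <- prot$baseline * subjFactor[sheet$subject_id[j]] *
        hetero[, sheet$subject_id[j]] *
        2^effMat[, sheet$treatment[j]]
      m[, j] <- rpois(cfg$n_proteins, mu)
    }
    m
  })
  if (cfg$dropout_rate > 0) {
    counts <- .withSeed(.substreamSeed(cfg$seed, "dropout"), {
      sel <- matrix(runif(length(counts)) < cfg$dropout_rate,
                    nrow(counts))
      lim <- matrix(sample(c(1, 2, 3), length(counts), replace = TRUE,
                           prob = c(0.6, 0.3, 0.1)), nrow(counts))
      counts[sel & counts < lim] <- NA
      counts
    })
  }
  sce <- SpectralCountExperiment(counts, sheet,
                                 proteinData = prot[, c("accession",
                                                        "gene_symbol",
                                                        "length")],
                                 control = cfg$control)
  new("SyntheticStudy", sce = sce, truth = truth, config = unclass(cfg))
}

#' Simulate a paired multi-timepoint transcriptome
#'
#' Generates probe x sample log2 intensities for paired participants at
#' timepoints T1..Tk, with 2-3 probes per gene sharing a gene-level signal
#' plus probe noise. One gene is emitted per protein of the companion
#' spectral-count simulation (same seed substreams, so the two arms agree
#' without passing objects around). A chosen fraction of the genes mapped
#' to responsive proteins of the reference treatment shift at T2 in the
#' direction of the protein's true effect (decaying at later timepoints);
#' these are the ground-truth concordant genes.
#'
#' @param config a \code{SimulationConfig}.
#' @param timepoints number of timepoints (>= 2), labelled T1..Tk.
#' @param frac_concordant fraction of responsive-protein genes made
#'   concordant.
#' @param n_participants paired participants.
#' @param ref_treatment treatment whose truth drives concordance (default
#'   \code{"MPLA"} when present, else the first non-control label).
#' @param delta_log2 T2 shift magnitude of concordant genes.
#' @param probe_noise SD of per-observation probe noise.
#' @return list of class \code{"SyntheticTranscriptome"}: \code{expr}
#'   (probes x samples), \code{samples} (sample_id, participant,
#'   timepoint), \code{probe_map} (probe_id -> gene_id), \code{gene_map}
#'   (gene_id -> protein accession), \code{truth} (gene_id, concordant,
#'   direction).
#' @export
simulateTranscriptome <- function(config, timepoints = 4,
                                  frac_concordant = 0.5,
                                  n_participants = 24,
                                  ref_treatment = NULL,
                                  delta_log2 = 1,
                                  probe_noise = 0.25) {
  if (!inherits(config, "SimulationConfig")) {
    config <- do.call(simulationConfig, config)
  }
  cfg <- config
  if (timepoints < 2) .stopf("timepoints must be >= 2")
  if (frac_concordant < 0 || frac_concordant > 1) {
    .stopf("frac_concordant must lie in [0, 1]")
  }
  prot <- .simProteins(cfg)
  truth <- .simTruth(cfg, prot)
  if (is.null(ref_treatment)) {
    nonCtrl <- setdiff(cfg$treatments, cfg$control)
    ref_treatment <- if ("MPLA" %in% nonCtrl) "MPLA" else nonCtrl[1]
  }
  refTruth <- truth[truth$treatment == ref_treatment, ]
  responsive <- refTruth$accession[refTruth$responsive]
  geneOf <- setNames(prot$gene_symbol, prot$accession)
  .withSeed(.substreamSeed(cfg$seed, "expression"), {
    nConc <- round(frac_concordant * length(responsive))
    concProteins <- if (nConc > 0) sample(responsive, nConc) else character()
    dirOf <- setNames(sign(refTruth$log2fc[match(concProteins,
                                                 refTruth$accession)]),
                      concProteins)
    dirOf[dirOf == 0] <- 1
    genes <- prot$gene_symbol
    nProbes <- sample(2:3, length(genes), replace = TRUE)
    probeMap <- data.frame(
      probe_id = unlist(mapply(function(g, k) sprintf("%s_at%d", g, seq_len(k)),
                               genes, nProbes, SIMPLIFY = FALSE)),
      gene_id = rep(genes, nProbes), stringsAsFactors = FALSE)
    tps <- sprintf("T%d", seq_len(timepoints))
    samples <- expand.grid(participant = sprintf("P%02d",
                                                 seq_len(n_participants)),
                           timepoint = tps, stringsAsFactors = FALSE)
    samples$sample_id <- paste(samples$participant, samples$timepoint,
                               sep = "_")
    geneBase <- setNames(rnorm(length(genes), 7, 1), genes)
    probeOff <- setNames(rnorm(nrow(probeMap), 0, 0.3), probeMap$probe_id)
    partOff <- setNames(rnorm(n_participants, 0, 0.2),
                        unique(samples$participant))
    # timepoint shift profile for concordant genes: full at T2, decaying
    shiftProfile <- c(0, delta_log2 * 2^-(seq_len(timepoints - 1) - 1))
    names(shiftProfile) <- tps
    concGenes <- unname(geneOf[concProteins])
    shiftOfGene <- setNames(rep(0, length(genes)), genes)
    shiftOfGene[concGenes] <- unname(dirOf)
    expr <- matrix(0, nrow(probeMap), nrow(samples),
                   dimnames = list(probeMap$probe_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      g <- probeMap$gene_id
      mu <- geneBase[g] + probeOff[probeMap$probe_id] +
        partOff[samples$participant[j]] +
        shiftOfGene[g] * shiftProfile[samples$timepoint[j]]
      expr[, j] <- mu + rnorm(nrow(probeMap), 0, probe_noise)
    }
    geneTruth <- data.frame(
      gene_id = genes,
      protein = prot$accession,
      concordant = genes %in% concGenes,
      direction = ifelse(genes %in% concGenes,
                         ifelse(shiftOfGene[genes] > 0, "up", "down"), "none"),
      stringsAsFactors = FALSE)
    out <- list(expr = expr,
                samples = samples[, c("sample_id", "participant", "timepoint")],
                probe_map = data.frame(source_id = probeMap$probe_id,
                                       target_id = probeMap$gene_id,
                                       stringsAsFactors = FALSE),
                gene_map = data.frame(source_id = genes,
                                      target_id = prot$accession,
                                      stringsAsFactors = FALSE),
                truth = geneTruth,
                ref_treatment = ref_treatment)
    class(out) <- "SyntheticTranscriptome"
    out
  })
}

#' Simulate a gene-set collection with one loaded set
#'
#' Draws random member sets over the protein universe and designates one
#' set (\code{"SET_ENRICHED"}) loaded with responsive proteins at the
#' requested overlap fraction, for exercising the over-representation
#' module with known truth.
#'
#' @param proteins character vector of all protein accessions (the
#'   universe).
#' @param responsive character vector of truly responsive accessions.
#' @param n_sets number of random background sets (>= 1).
#' @param enriched_set_overlap fraction of the responsive proteins placed
#'   in the designated set.
#' @param seed integer seed.
#' @param set_size_range size range of the random sets.
#' @return named list of member vectors (GMT-writable via \link{writeGmt}),
#'   designated set first.
#' @export
simulateGenesets <- function(proteins, responsive, n_sets = 20,
                             enriched_set_overlap = 1, seed = 1L,
                             set_size_range = c(15, 50)) {
  if (n_sets < 1) .stopf("n_sets must be >= 1")
  if (enriched_set_overlap < 0 || enriched_set_overlap > 1) {
    .stopf("enriched_set_overlap must lie in [0, 1]")
  }
  .withSeed(.substreamSeed(seed, "genesets"), {
    nIn <- round(enriched_set_overlap * length(responsive))
    loaded <- if (nIn > 0) sample(responsive, nIn) else character()
    fill <- sample(setdiff(proteins, loaded),
                   max(0, max(set_size_range[1], nIn + 5) - length(loaded)))
    sets <- list(SET_ENRICHED = c(loaded, fill))
    for (i in seq_len(n_sets)) {
      sz <- sample(seq(set_size_range[1], set_size_range[2]), 1)
      sets[[sprintf("SET_RANDOM%03d", i)]] <- sample(proteins, sz)
    }
    attr(sets, "descriptions") <-
      setNames(c("synthetic enriched set",
                 rep("synthetic random set", n_sets)), names(sets))
    sets
  })
}
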