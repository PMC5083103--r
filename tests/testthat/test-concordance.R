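# Quantile normalization, gene-change calls, molecule matching and the
# tau-b concordance procedure.

test_that("quantile normalization forces a shared value distribution", {
  set.seed(701)
  # permuted columns end up identical multisets (here: identical columns)
  v <- sort(rexp(20))
  e <- cbind(a = v, b = sample(v), c = sample(v))
  q <- quantileNormalize(e)
  expect_equal(sort(q[, "b"]), sort(q[, "a"]), tolerance = 1e-12)
  # rank-preserving within each column
  expect_equal(order(q[, "b"]), order(e[, "b"]))
  # random matrix: column-sorted values identical across columns
  m <- matrix(rnorm(40), 10, 4)
  qm <- quantileNormalize(m)
  srt <- apply(qm, 2, sort)
  expect_lt(max(abs(srt - srt[, 1])), 1e-12)
  # idempotent
  expect_equal(quantileNormalize(qm), qm, tolerance = 1e-12)
  # single column: identity; missing values rejected
  one <- matrix(rnorm(5), 5, 1)
  expect_equal(quantileNormalize(one), one)
  m[2, 2] <- NA
  expect_error(quantileNormalize(m), "missing")
})

test_that("gene calls use the min-p probe and the paired signed-rank test", {
  participants <- sprintf("P%02d", 1:8)
  samples <- data.frame(
    sample_id = c(paste0(participants, "_T1"), paste0(participants, "_T2")),
    participant = rep(participants, 2),
    timepoint = rep(c("T1", "T2"), each = 8),
    stringsAsFactors = FALSE)
  base <- rnorm(8, 7, 0.1)
  e <- rbind(
    g1_up   = c(base, base + 2),            # strong shift up
    g1_weak = c(base, base + rnorm(8, 0, 1.5)),  # noisy probe of same gene
    g2_flat = c(base, base))                # unchanged
  colnames(e) <- samples$sample_id
  probeMap <- data.frame(source_id = rownames(e),
                         target_id = c("G1", "G1", "G2"),
                         stringsAsFactors = FALSE)
  calls <- callGeneChanges(e, samples, probeMap)
  expect_equal(nrow(calls), 2)
  # representative probe is the smaller-p probe of G1
  pUp <- wilcoxonSignedRank(rep(2, 8))$p.value
  expect_equal(calls["G1", "probe_id"], "g1_up")
  expect_equal(calls["G1", "p"], pUp)
  expect_equal(calls["G1", "direction"], "up")
  expect_true(calls["G1", "significant"])
  # an unchanged gene is not significant
  expect_false(calls["G2", "significant"])
  # unmapped probes survive under their own id, with a warning
  expect_warning(
    calls2 <- callGeneChanges(e, samples, probeMap[1:2, , drop = FALSE]),
    "unmapped")
  expect_true("g2_flat" %in% calls2$gene_id)
})

test_that("molecule matching equals a brute-force nested-loop join", {
  genes <- data.frame(gene_id = c("G1", "G2", "G3"),
                      probe_id = paste0("pr", 1:3),
                      p = c(0.01, 0.2, 0.04),
                      direction = c("up", "down", "up"),
                      significant = c(TRUE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  prot <- S4Vectors::DataFrame(
    fdr = c(0.01, 0.3, 0.02),
    direction = c("up", "up", "down"),
    significant = c(TRUE, FALSE, TRUE),
    row.names = c("A1", "A2", "A3"))
  map <- data.frame(source_id = c("G1", "G1", "G2", "G3", "GX"),
                    target_id = c("A1", "A3", "A2", "AX", "A1"),
                    stringsAsFactors = FALSE)
  matched <- matchMolecules(genes, prot, map)
  # brute force
  expected <- 0
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(prot))) {
    hit <- any(map$source_id == genes$gene_id[i] &
                 map$target_id == rownames(prot)[j])
    expected <- expected + hit
  }
  expect_equal(nrow(matched), expected)        # G1-A1, G1-A3, G2-A2
  expect_setequal(paste(matched$gene_id, matched$accession),
                  c("G1 A1", "G1 A3", "G2 A2"))
  # one gene mapped to two isoforms yields two rows
  expect_equal(sum(matched$gene_id == "G1"), 2)
})

test_that("concordance counts and tau-b match direct computation", {
  matched <- data.frame(
    gene_id = paste0("G", 1:6),
    accession = paste0("A", 1:6),
    gene_p = c(0.01, 0.01, 0.2, 0.01, 0.03, 0.01),
    gene_direction = c("up", "down", "up", "up", "down", "up"),
    gene_significant = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    protein_fdr = 0.01,
    protein_direction = c("up", "down", "up", "down", "up", "up"),
    protein_significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  res <- concordanceTest(matched, background_n = 100)
  # brute-force double loop over molecules
  nConc <- 0
  for (i in seq_len(nrow(matched))) {
    si <- matched$protein_significant[i]
    ti <- matched$gene_significant[i]
    sd <- matched$protein_direction[i]
    td <- matched$gene_direction[i]
    if (si && ti && sd == td) nConc <- nConc + 1
  }
  expect_equal(res$n_concordant, nConc)   # G1 up/up and G2 down/down
  expect_equal(res$n_concordant, 2)
  # tau-b equals the independent computation on the padded ternary vectors
  tern <- function(sig, dir) ifelse(sig, ifelse(dir == "up", 1, -1), 0)
  xx <- c(tern(matched$protein_significant, matched$protein_direction),
          rep(0, 94))
  yy <- c(tern(matched$gene_significant, matched$gene_direction),
          rep(0, 94))
  expect_equal(res$tau_b, unname(cor(xx, yy, method = "kendall")),
               tolerance = 1e-12)
  expect_error(concordanceTest(matched, background_n = 3), "background_n")
  # all molecules significant-up in both layers: maximal concordance
  allUp <- matched
  allUp$gene_significant <- allUp$protein_significant <- TRUE
  allUp$gene_direction <- allUp$protein_direction <- "up"
  resUp <- concordanceTest(allUp, background_n = 100)
  expect_equal(resUp$n_concordant, 6)
  expect_lt(resUp$p, 0.05)
  # nothing significant anywhere: degenerate, p = 1
  none <- matched
  none$gene_significant <- none$protein_significant <- FALSE
  resNone <- concordanceTest(none, background_n = 100)
  expect_true(resNone$degenerate)
  expect_equal(resNone$p, 1)
})

test_that("tau-b p from the module equals the exact enumeration on toy backgrounds", {
  matched <- data.frame(
    gene_id = c("G1", "G2"), accession = c("A1", "A2"),
    gene_p = 0.01, gene_direction = c("up", "down"),
    gene_significant = TRUE,
    protein_fdr = 0.01, protein_direction = c("up", "down"),
    protein_significant = TRUE, stringsAsFactors = FALSE)
  res <- concordanceTest(matched, background_n = 7)
  x <- c(1, -1, 0, 0, 0, 0, 0)
  y <- c(1, -1, 0, 0, 0, 0, 0)
  expect_equal(res$p, oracleTauExactP(x, y), tolerance = 1e-12)
})

test_that("pipeline recovers simulated concordant genes end-to-end", {
  cfg <- simulationConfig(n_proteins = 80, seed = 21)
  study <- simulateSpcExperiment(cfg)
  tx <- simulateTranscriptome(cfg, frac_concordant = 1, n_participants = 16,
                              delta_log2 = 2)
  e <- quantileNormalize(tx$expr)
  calls <- callGeneChanges(e, tx$samples, tx$probe_map)
  concTruth <- tx$truth[tx$truth$concordant, ]
  got <- calls[concTruth$gene_id, ]
  expect_gte(mean(got$significant &
                    got$direction == concTruth$direction), 0.95)
  # and the full concordance test sees them
  design <- validateDesign(study@sce)
  fit <- fitPairedCountModel(study@sce, design, "adult", "MPLA")
  matched <- matchMolecules(calls, fit, tx$gene_map)
  res <- concordanceTest(matched, background_n = 12893)
  expect_gte(res$n_concordant, 0.5 * sum(tx$truth$concordant))
  expect_lt(res$p, 0.05)
})

test_that("GO-term overlap fraction uses the secretome denominator", {
  expect_equal(goOverlapFraction(letters[1:10], letters[1:10])$fraction, 1)
  expect_equal(goOverlapFraction(letters[1:10], LETTERS[1:10])$fraction, 0)
  ov <- goOverlapFraction(paste0("t", 1:100), paste0("t", 88:120))
  expect_equal(ov$fraction, 0.13)
  expect_error(goOverlapFraction(character(), "a"), "empty")
})
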