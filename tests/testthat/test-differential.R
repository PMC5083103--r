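# The paired Poisson count model: hand-checkable cases, the exact
# conditional-binomial oracle, glm cross-check, and the label/scale
# invariances.

makePairedSce <- function(control, treated, nPairs = ncol(control),
                          steady = NULL) {
  # control/treated: proteins x subjects count matrices
  if (!is.null(steady)) {
    control <- rbind(control, steady)
    treated <- rbind(treated, steady)
  }
  prot <- paste0("P", seq_len(nrow(control)))
  rownames(control) <- rownames(treated) <- prot
  cts <- cbind(control, treated)
  colnames(cts) <- c(paste0("c_S", seq_len(nPairs)),
                     paste0("t_S", seq_len(nPairs)))
  sheet <- data.frame(
    sample_id = colnames(cts),
    age_group = "adult",
    treatment = rep(c("control", "Alum"), each = nPairs),
    subject_id = rep(paste0("S", seq_len(nPairs)), 2),
    stringsAsFactors = FALSE)
  SpectralCountExperiment(cts, sheet)
}

test_that("identical treated and control counts give beta = 0, Z = 0, p = 1", {
  m <- matrix(c(5, 9, 2, 5, 9, 2, 5, 9, 2), 3, 3)
  sce <- makePairedSce(m, m, steady = matrix(30, 2, 3))
  fit <- fitPairedCountModel(sce, validateDesign(sce), "adult", "Alum")
  expect_equal(unname(fit$log2FC[1:3]), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(fit$Z[1:3]), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(fit$p[1:3]), rep(1, 3), tolerance = 1e-9)
})

test_that("single-protein fit recovers the conditional-binomial estimate", {
  # pairs (control 2, treated 8) x 4 subjects with equal offsets: the
  # conditional MLE is logit(32/40) = log 4
  cts <- rbind(P1 = rep(c(2, 8), each = 4),
               # background protein equalizing per-sample totals at 100
               P2 = rep(c(98, 92), each = 4))
  colnames(cts) <- c(paste0("c_S", 1:4), paste0("t_S", 1:4))
  sheet <- data.frame(sample_id = colnames(cts), age_group = "adult",
                      treatment = rep(c("control", "Alum"), each = 4),
                      subject_id = rep(paste0("S", 1:4), 2),
                      stringsAsFactors = FALSE)
  sce <- SpectralCountExperiment(cts, sheet)
  fit <- fitPairedCountModel(sce, validateDesign(sce), "adult", "Alum")
  expect_equal(unname(fit["P1", "log2FC"] * log(2)), log(4), tolerance = 1e-6)
  # oracle: exact conditional binomial test of 32 treated of 40
  pExact <- binom.test(32, 40, 0.5)$p.value
  ratio <- fit["P1", "p"] / pExact
  expect_gt(ratio, 1 / 5)
  expect_lt(ratio, 5)
  # the moderated Z agrees in sign and calls the protein significant
  expect_gt(fit["P1", "Z"], 2)
})

test_that("estimates match a Poisson GLM with subject fixed effects", {
  set.seed(601)
  nPairs <- 5
  control <- matrix(rpois(3 * nPairs, 8), 3)
  treated <- matrix(rpois(3 * nPairs, c(8, 16, 24)), 3)
  sce <- makePairedSce(control, treated, steady = matrix(40, 2, nPairs))
  design <- validateDesign(sce)
  fit <- fitPairedCountModel(sce, design, "adult", "Alum")
  cts <- spcCounts(sce)
  offs <- colSums(cts)
  for (p in c("P1", "P2", "P3")) {
    df <- data.frame(y = cts[p, ],
                     subj = sub("^[ct]_", "", colnames(cts)),
                     trt = rep(c(0, 1), each = nPairs),
                     off = log(offs))
    g <- glm(y ~ subj + trt + offset(off), family = poisson, data = df)
    expect_equal(unname(fit[p, "log2FC"] * log(2)),
                 unname(coef(g)["trt"]), tolerance = 1e-6)
    expect_equal(unname(fit[p, "SE"]),
                 unname(sqrt(vcov(g)["trt", "trt"])), tolerance = 1e-4)
  }
})

test_that("swapping treated and control labels negates beta and Z exactly", {
  study <- smallStudy(seed = 62, n_proteins = 60)
  sce <- study@sce
  fit <- fitPairedCountModel(sce, validateDesign(sce), "adult", "MPLA")
  # swap roles by relabelling treatments in the sheet
  cd <- sampleInfo(sce)
  sel <- cd$treatment %in% c("control", "MPLA")
  cts <- spcCounts(sce)[, cd$sample_id[sel]]
  cd <- cd[sel, ]
  cd$treatment <- ifelse(cd$treatment == "control", "MPLA", "control")
  sceSwap <- SpectralCountExperiment(cts, cd)
  fitSwap <- fitPairedCountModel(sceSwap, validateDesign(sceSwap),
                                 "adult", "MPLA")
  expect_equal(fitSwap$log2FC, -fit$log2FC, tolerance = 1e-8)
  expect_equal(fitSwap$Z, -fit$Z, tolerance = 1e-8)
})

test_that("doubling every count leaves beta unchanged (offset correctness)", {
  set.seed(603)
  control <- matrix(rpois(40, 6) + 1, 8)
  treated <- matrix(rpois(40, 10) + 1, 8)
  sce1 <- makePairedSce(control, treated, steady = matrix(25, 2, 5))
  sce2 <- makePairedSce(2 * control, 2 * treated,
                        steady = matrix(50, 2, 5))
  f1 <- fitPairedCountModel(sce1, validateDesign(sce1), "adult", "Alum")
  f2 <- fitPairedCountModel(sce2, validateDesign(sce2), "adult", "Alum")
  expect_equal(f2$log2FC[1:8], f1$log2FC[1:8], tolerance = 1e-8)
})

test_that("all-zero proteins are flagged uninformative; one-sided zeros flagged boundary", {
  control <- rbind(c(0, 0, 0), c(4, 5, 6), c(3, 3, 3))
  treated <- rbind(c(0, 0, 0), c(0, 0, 0), c(3, 3, 4))
  sce <- makePairedSce(control, treated, steady = matrix(20, 2, 3))
  fit <- fitPairedCountModel(sce, validateDesign(sce), "adult", "Alum")
  expect_equal(unname(fit["P1", "flag"]), "uninformative")
  expect_equal(unname(fit["P1", "p"]), 1)
  expect_equal(unname(fit["P2", "flag"]), "boundary")
  expect_true(is.finite(fit["P2", "Z"]))
  expect_lt(fit["P2", "log2FC"], 0)
  expect_error(fitPairedCountModel(sce, validateDesign(sce), "adult",
                                   "missingTreatment"),
               "pair")
})

test_that("moderated Z ranking tracks the exact conditional-test ranking", {
  set.seed(604)
  study <- smallStudy(seed = 604, n_proteins = 120)
  sce <- study@sce
  design <- validateDesign(sce)
  fit <- fitPairedCountModel(sce, design, "adult", "Alum")
  cts <- spcCounts(sce)
  cts[is.na(cts)] <- 0
  pr <- design@pairs
  pr <- pr[pr$age_group == "adult" & pr$treatment == "Alum", ]
  offRatio <- colSums(cts)[pr$treated_sample] /
    (colSums(cts)[pr$treated_sample] + colSums(cts)[pr$control_sample])
  pExact <- vapply(rownames(cts), function(p) {
    y <- sum(cts[p, pr$treated_sample])
    n <- y + sum(cts[p, pr$control_sample])
    if (n == 0) return(1)
    binom.test(y, n, mean(offRatio))$p.value
  }, numeric(1))
  keep <- fit$flag == "ok"
  tau <- cor(abs(fit$Z[keep]), -log10(pExact[keep]), method = "kendall")
  expect_gte(tau, 0.8)
})

test_that("null and powered simulations are calibrated and sensitive", {
  # light versions of the calibration suites (the deeper runs live in the
  # acceptance tests)
  fracs <- vapply(1:10, function(s) {
    study <- simulateSpcExperiment(
      simulationConfig(n_proteins = 200, frac_responsive = 0, seed = s))
    fit <- fitPairedCountModel(study@sce, validateDesign(study@sce),
                               "adult", "MPLA")
    mean(fit$p < 0.05)
  }, numeric(1))
  expect_gt(mean(fracs), 0.02)
  expect_lt(mean(fracs), 0.08)
  study <- smallStudy(seed = 99, n_proteins = 250)
  fit <- fitPairedCountModel(study@sce, validateDesign(study@sce),
                             "adult", "MPLA")
  resp <- study@truth$accession[study@truth$treatment == "MPLA" &
                                  study@truth$responsive]
  called <- rownames(fit)[fit$significant]
  expect_gte(mean(resp %in% called), 0.8)
  if (length(called)) expect_lte(mean(!(called %in% resp)), 0.15)
})

test_that("age-specificity labels partition the protein universe", {
  study <- smallStudy(seed = 77, n_proteins = 150)
  design <- validateDesign(study@sce)
  nb <- fitPairedCountModel(study@sce, design, "newborn", "MPLA")
  ad <- fitPairedCountModel(study@sce, design, "adult", "MPLA")
  calls <- classifyAgeSpecificity(nb, ad)
  expect_equal(nrow(calls), 150)
  expect_setequal(unique(calls$label),
                  intersect(c("newborn_only", "adult_only", "both",
                              "neither"), calls$label))
  counts <- attr(calls, "counts")
  expect_equal(sum(counts), 150)
  # truth responds in both ages, so with ~94% per-age sensitivity most
  # responsive proteins land in "both"
  resp <- study@truth$accession[study@truth$treatment == "MPLA" &
                                  study@truth$responsive]
  respLabels <- calls$label[calls$accession %in% resp]
  expect_gte(mean(respLabels == "both"), 0.7)
  # no significant calls anywhere -> all neither
  nullStudy <- simulateSpcExperiment(
    simulationConfig(n_proteins = 60, frac_responsive = 0, seed = 5))
  d0 <- validateDesign(nullStudy@sce)
  n0 <- fitPairedCountModel(nullStudy@sce, d0, "newborn", "Alum")
  a0 <- fitPairedCountModel(nullStudy@sce, d0, "adult", "Alum")
  if (!any(n0$significant) && !any(a0$significant)) {
    expect_true(all(classifyAgeSpecificity(n0, a0)$label == "neither"))
  }
})
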