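# Paired count-model differential abundance.
#
# Model, per protein and per (age group, treatment) contrast: counts in the
# control and treated sample of each subject follow
#   y_{s,c} ~ Poisson(mu_{s,c}),  log mu = log(offset_{s,c}) + alpha_s +
#                                           beta * 1[c = treated]
# with the per-sample total spectral count (times the protein length, which
# cancels within a pair) as exposure offset and subject alpha_s as a fixed
# effect. Conditioning on each pair's total n_s = y_treated + y_control
# removes alpha_s exactly: y_treated | n_s ~ Binomial(n_s, p_s) with
# logit(p_s) = beta + log(offset_treated/offset_control). beta is estimated
# by Newton-Raphson on this conditional likelihood (the conditional MLE
# equals the fixed-effects profile MLE for paired Poisson data), its Wald
# variance is moderated by empirical-Bayes shrinkage toward the trimmed
# mean variance across proteins, and Z = beta / SE_moderated is referred to
# the normal distribution. Significance is called at BH FDR < 5%.

.fitPairedBeta <- function(Y, Nn, r, maxIter = 50, tol = 1e-10) {
  # Y, Nn: proteins x pairs treated counts and pair totals; r: pair log
  # offset ratios. Vectorized Newton across proteins.
  beta <- rep(0, nrow(Y))
  R <- matrix(r, nrow(Y), ncol(Y), byrow = TRUE)
  for (it in seq_len(maxIter)) {
    eta <- beta + R
    p <- 1 / (1 + exp(-eta))
    score <- rowSums(Y - Nn * p)
    info <- rowSums(Nn * p * (1 - p))
    step <- ifelse(info > 0, score / info, 0)
    step <- pmax(pmin(step, 5), -5)   # damp early oversteps
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- beta + R
  p <- 1 / (1 + exp(-eta))
  info <- rowSums(Nn * p * (1 - p))
  list(beta = beta, se = ifelse(info > 0, 1 / sqrt(info), NA_real_))
}

#' Fit the paired Poisson count model for one contrast
#'
#' Estimates, per protein, the treated-vs-control log fold change under the
#' paired count model described above, with per-sample total spectral
#' counts as exposure offsets, empirical-Bayes variance moderation, a
#' moderated Z statistic, two-sided normal p and BH FDR.
#'
#' Proteins with zero counts in every sample of the contrast are flagged
#' \code{"uninformative"} (Z = 0, p = 1). Proteins with all counts on one
#' side (complete separation; the unpenalized MLE diverges) are refit with a
#' Jeffreys-style continuity adjustment (+0.25 to each arm's count, +0.5 to
#' each pair total) and flagged \code{"boundary"}.
#'
#' @param x a \code{SpectralCountExperiment}; undetected (missing) cells
#'   count as zero spectra in the model.
#' @param design a \link{PairedDesign}.
#' @param age age group of the contrast.
#' @param treatment treatment of the contrast (vs the design's control).
#' @param moderationDf prior degrees of freedom of the variance shrinkage
#'   (default 4).
#' @param fdrThreshold significance threshold on BH FDR (default 0.05).
#' @param lengths optional named protein lengths; enters the exposure as a
#'   per-protein constant and therefore cancels within pairs (kept for
#'   interface completeness).
#' @return A \link{DifferentialResult}.
#' @export
fitPairedCountModel <- function(x, design, age, treatment,
                                moderationDf = 4, fdrThreshold = 0.05,
                                lengths = NULL) {
  stopifnot(is(x, "SpectralCountExperiment"), is(design, "PairedDesign"))
  pr <- design@pairs
  pr <- pr[pr$age_group == age & pr$treatment == treatment, , drop = FALSE]
  if (nrow(pr) < 2) {
    .stopf("contrast (%s, %s) has %d complete pair(s); need >= 2",
           age, treatment, nrow(pr))
  }
  cts <- spcCounts(x)
  cts[is.na(cts)] <- 0
  offsets <- colSums(cts)
  if (any(offsets[c(pr$treated_sample, pr$control_sample)] <= 0)) {
    .stopf("zero-total sample in contrast (%s, %s)", age, treatment)
  }
  Y <- cts[, pr$treated_sample, drop = FALSE]
  Ctl <- cts[, pr$control_sample, drop = FALSE]
  Nn <- Y + Ctl
  r <- log(offsets[pr$treated_sample] / offsets[pr$control_sample])
  uninformative <- rowSums(Nn) == 0
  allTreated <- !uninformative & rowSums(Ctl) == 0
  allControl <- !uninformative & rowSums(Y) == 0
  boundary <- allTreated | allControl
  fit <- .fitPairedBeta(Y, Nn, r)
  if (any(boundary)) {
    adjFit <- .fitPairedBeta(Y[boundary, , drop = FALSE] + 0.25,
                             Nn[boundary, , drop = FALSE] + 0.5, r)
    fit$beta[boundary] <- adjFit$beta
    fit$se[boundary] <- adjFit$se
  }
  beta <- fit$beta
  s2 <- fit$se^2
  beta[uninformative] <- 0
  ok <- !uninformative & is.finite(s2)
  if (!any(ok)) .stopf("no informative protein in contrast (%s, %s)",
                       age, treatment)
  v0 <- mean(s2[ok], trim = 0.2)
  dfResid <- max(1, nrow(pr) - 1)
  s2mod <- (moderationDf * v0 + dfResid * s2) / (moderationDf + dfResid)
  z <- ifelse(ok, beta / sqrt(s2mod), 0)
  p <- ifelse(ok, 2 * pnorm(-abs(z)), 1)
  fdr <- fdrAdjust(p)
  res <- DataFrame(
    accession = rownames(cts),
    log2FC = beta / log(2),
    SE = sqrt(ifelse(ok, s2, NA_real_)),
    SE_moderated = sqrt(ifelse(ok, s2mod, NA_real_)),
    Z = z,
    p = p,
    fdr = fdr,
    significant = fdr < fdrThreshold,
    direction = ifelse(beta >= 0, "up", "down"),
    flag = ifelse(uninformative, "uninformative",
                  ifelse(boundary, "boundary", "ok")),
    row.names = rownames(cts))
  metadata(res) <- list(age_group = age, treatment = treatment,
                        control = design@control,
                        n_pairs = nrow(pr), moderation_df = moderationDf,
                        fdr_threshold = fdrThreshold,
                        prior_variance = v0)
  new("DifferentialResult", res)
}

#' Fit the paired count model for every (age, treatment) contrast
#'
#' @param x a \code{SpectralCountExperiment}.
#' @param design a \link{PairedDesign}.
#' @param ... passed to \link{fitPairedCountModel}.
#' @return named list of \link{DifferentialResult} objects, names
#'   \code{"<age>.<treatment>"}.
#' @export
fitAllContrasts <- function(x, design, ...) {
  pr <- design@pairs
  combos <- unique(pr[, c("age_group", "treatment")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    fitPairedCountModel(x, design, combos$age_group[i],
                        combos$treatment[i], ...)
  })
  names(out) <- paste(combos$age_group, combos$treatment, sep = ".")
  out
}

#' Classify age specificity of significant proteins
#'
#' Joins a newborn and an adult contrast over the union of their protein
#' universes (a protein absent from one result counts as not significant
#' there) and labels each protein \code{newborn_only}, \code{adult_only},
#' \code{both} or \code{neither}.
#'
#' @param newborn,adult \link{DifferentialResult} objects for the same
#'   treatment in the two age groups.
#' @return data.frame with \code{accession}, \code{label}, plus an attribute
#'   \code{"counts"} (table of label counts).
#' @export
classifyAgeSpecificity <- function(newborn, adult) {
  prots <- union(rownames(newborn), rownames(adult))
  sigN <- prots %in% rownames(newborn)[newborn$significant]
  sigA <- prots %in% rownames(adult)[adult$significant]
  label <- ifelse(sigN & sigA, "both",
                  ifelse(sigN, "newborn_only",
                         ifelse(sigA, "adult_only", "neither")))
  out <- data.frame(accession = prots, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(label, levels = c("newborn_only",
                                                        "adult_only",
                                                        "both", "neither")))
  out
}
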