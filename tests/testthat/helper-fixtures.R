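# In-code fixtures shared across test files.

# A hand-built 4-protein, 2-subject, 2-treatment experiment with one
# missing cell and one literal zero.
makeTinySce <- function() {
  cts <- matrix(
    c(10L, 5L, 8L, 4L,
      2L,  1L, NA, 2L,
      0L,  3L, 6L, 1L,
      1L,  NA, NA, NA),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("P", 1:4),
                    c("s1_ctrl", "s1_trt", "s2_ctrl", "s2_trt")))
  sheet <- data.frame(
    sample_id = colnames(cts),
    age_group = "adult",
    treatment = rep(c("control", "Alum"), 2),
    subject_id = rep(c("S1", "S2"), each = 2),
    stringsAsFactors = FALSE)
  info <- data.frame(accession = rownames(cts),
                     gene_symbol = paste0("G", 1:4),
                     length = c(100L, 200L, 400L, 50L),
                     stringsAsFactors = FALSE)
  SpectralCountExperiment(cts, sheet, proteinData = info)
}

smallStudy <- function(seed = 11, n_proteins = 150, ...) {
  simulateSpcExperiment(simulationConfig(n_proteins = n_proteins,
                                         seed = seed, ...))
}
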