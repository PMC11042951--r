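# Small simulation configurations so module tests stay fast; the acceptance
# suite exercises the full default configuration.

tinyCohortConfig <- function(seed = 7L, ...) {
  simulationConfig(
    nGenes = 300L, nSignatureGenes = 40L, nStemTrain = 20L,
    nDiffTrain = 30L, nProlifGenes = 15L, nSenescGenes = 15L,
    nSubjects = 150L, seed = seed,
    tissues = list(
      tissueSpec("liver", nSamples = 60L, betaAge = -0.03),
      tissueSpec("kidney", nSamples = 60L, betaAge = -0.03,
                 nRegions = 2L),
      tissueSpec("spleen", nSamples = 60L, betaAge = 0)),
    ...)
}

# minimal valid sample table
makeSampleTable <- function(n = 6L, tissue = "liver") {
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    subject_id = sprintf("SUBJ%02d", seq_len(n)),
    tissue = tissue,
    region = paste0(tissue, "-R1"),
    age_bin = NA_character_,
    age_years = seq(25, by = 10, length.out = n),
    sex = rep(c("female", "male"), length.out = n),
    death = "0",
    stringsAsFactors = FALSE)
}

randomExpression <- function(nGenes = 20L, nSamples = 5L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rexp(nGenes * nSamples, rate = 0.1), nGenes, nSamples,
              dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                              sprintf("S%02d", seq_len(nSamples))))
  m
}
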