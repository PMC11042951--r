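#' Tissue specification for the cohort simulator
#'
#' Describes one tissue of the synthetic cohort: its sample count, the
#' ground-truth age effect on latent stemness, sex/region covariate effects,
#' and the loading on the subject-level shared factor that induces
#' cross-tissue correlation of stemness within an individual.
#'
#' @param name tissue label.
#' @param nSamples samples drawn for this tissue (>= 2); one sample per
#'   selected subject.
#' @param betaAge ground-truth change in latent stemness per year of age.
#' @param hasSex if `FALSE`, the tissue is sex-restricted (female-only, like
#'   uterus); subjects are then drawn from female subjects only and sex is a
#'   single observed level.
#' @param nRegions number of tissue-detail regions (>= 1).
#' @param sexEffect additive latent shift for female samples (0 when
#'   `hasSex = FALSE` has made sex constant).
#' @param regionEffects numeric additive latent shifts, one per region;
#'   default `0, 0.3, 0.6, ...`.
#' @param sharedFactorLoading loading of the subject-level shared factor
#'   (standard normal) on this tissue's latent stemness; 0 decouples the
#'   tissue from the rest of the organism (brain-like).
#' @param sexImbalance strength of sex-by-age confounding in subject
#'   selection: selection weight `exp(sexImbalance * (age - 50) / 25)` for
#'   female subjects, so positive values over-represent older females.
#'   Default 0 (sex independent of age).
#' @return a `tissueSpec` list.
#' @export
tissueSpec <- function(name, nSamples = 300L, betaAge = -0.02,
                       hasSex = TRUE, nRegions = 1L, sexEffect = 0.2,
                       regionEffects = NULL,
                       sharedFactorLoading = 0.5, sexImbalance = 0) {
  stopifnot(nSamples >= 2L, nRegions >= 1L)
  if (is.null(regionEffects)) regionEffects <- (seq_len(nRegions) - 1L) * 0.3
  stopifnot(length(regionEffects) == nRegions)
  structure(list(name = as.character(name), nSamples = as.integer(nSamples),
                 betaAge = betaAge, hasSex = isTRUE(hasSex),
                 nRegions = as.integer(nRegions), sexEffect = sexEffect,
                 regionEffects = regionEffects,
                 sharedFactorLoading = sharedFactorLoading,
                 sexImbalance = sexImbalance),
            class = "tissueSpec")
}

#' Default ten-tissue cohort layout
#'
#' Eight tissues losing stemness with age (`betaAge = -0.02`/year), a
#' female-only "uterus" gaining stemness (`+0.02`/year), and a null "muscle"
#' (`betaAge = 0`). "brain" carries zero shared-factor loading so its
#' stemness is decoupled from the rest of the organism, while every other
#' tissue loads 0.5 on the subject factor.
#'
#' @return list of [tissueSpec()] objects.
#' @export
defaultTissues <- function() {
  neg <- c("adipose", "artery", "colon", "heart", "lung", "nerve", "skin")
  specs <- lapply(neg, function(nm)
    tissueSpec(nm, nRegions = if (nm %in% c("artery", "colon", "skin")) 2L
                              else 1L))
  c(specs,
    list(tissueSpec("brain", nRegions = 2L, sharedFactorLoading = 0),
         tissueSpec("uterus", betaAge = 0.02, hasSex = FALSE,
                    sexEffect = 0),
         tissueSpec("muscle", betaAge = 0)))
}

#' Simulation configuration
#'
#' Bundles the generative parameters of the synthetic bulk-RNA-seq study.
#' Expression is log-normal: `TPM = exp(base_g + c_g * latent_i + noise)`,
#' where `base_g ~ N(baseMean, baseSd)` is a gene-specific baseline, `c_g`
#' couples a gene to the sample's latent stemness (signature genes:
#' `signatureCoupling`; proliferation genes and MKI67: `couplingProlif`;
#' senescence genes: `couplingSenesc`; all other genes 0), and the noise is
#' `N(0, noiseSd)` on the log scale — guaranteeing positive values.
#' Latent stemness is
#' `betaAge*(age-50) + sexEffect*1[female] + regionEffect +
#'  sharedFactorLoading*u_subject + N(0, latentSd)`.
#'
#' @param nGenes total genes (> nSignatureGenes).
#' @param nSignatureGenes genes elevated in pluripotent samples and coupled
#'   to latent stemness in the cohort.
#' @param nStemTrain pluripotent (stem-labeled) training samples.
#' @param nDiffTrain differentiated training samples (used for centering
#'   during signature training; not stem-labeled).
#' @param tissues list of [tissueSpec()]s.
#' @param seed integer seed governing all draws through per-component
#'   substreams, so adding a tissue does not perturb the others.
#' @param noiseSd log-scale expression noise SD (> 0).
#' @param baseMean,baseSd distribution of per-gene log-baselines.
#' @param signatureEffect log-scale up-shift of signature genes in stem
#'   training samples.
#' @param signatureCoupling log-scale shift of signature genes per unit of
#'   latent stemness in the cohort.
#' @param couplingProlif coupling of the proliferation gene set (and the
#'   MKI67 marker) to latent stemness, in `[-1, 1]`.
#' @param couplingSenesc coupling of the senescence gene set, in `[-1, 1]`
#'   (negative by default: senescence opposes stemness).
#' @param nProlifGenes,nSenescGenes gene-set sizes.
#' @param nSubjects size of the shared subject pool from which every tissue
#'   samples, creating same-subject overlap across tissues.
#' @param latentSd SD of the latent-stemness residual.
#' @return a validated `simulationConfig` list.
#' @export
simulationConfig <- function(nGenes = 2000L, nSignatureGenes = 100L,
                             nStemTrain = 50L, nDiffTrain = 100L,
                             tissues = defaultTissues(), seed = 1L,
                             noiseSd = 0.5, baseMean = 2, baseSd = 1,
                             signatureEffect = 1.5, signatureCoupling = 1,
                             couplingProlif = 0.5, couplingSenesc = -0.5,
                             nProlifGenes = 40L, nSenescGenes = 40L,
                             nSubjects = 800L, latentSd = 0.8) {
  stopifnot(nSignatureGenes < nGenes,
            nGenes >= 2L, nSignatureGenes >= 2L, nStemTrain >= 2L,
            nDiffTrain >= 2L, nSubjects >= 2L,
            noiseSd > 0, latentSd > 0,
            couplingProlif >= -1, couplingProlif <= 1,
            couplingSenesc >= -1, couplingSenesc <= 1,
            nSignatureGenes + nProlifGenes + nSenescGenes <= nGenes)
  stopifnot(all(vapply(tissues, inherits, TRUE, "tissueSpec")))
  nm <- vapply(tissues, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate tissue names")
  structure(list(nGenes = as.integer(nGenes),
                 nSignatureGenes = as.integer(nSignatureGenes),
                 nStemTrain = as.integer(nStemTrain),
                 nDiffTrain = as.integer(nDiffTrain),
                 tissues = tissues, seed = as.integer(seed),
                 noiseSd = noiseSd, baseMean = baseMean, baseSd = baseSd,
                 signatureEffect = signatureEffect,
                 signatureCoupling = signatureCoupling,
                 couplingProlif = couplingProlif,
                 couplingSenesc = couplingSenesc,
                 nProlifGenes = as.integer(nProlifGenes),
                 nSenescGenes = as.integer(nSenescGenes),
                 nSubjects = as.integer(nSubjects),
                 latentSd = latentSd),
            class = "simulationConfig")
}

# deterministic substream seeds derived from a master seed; keeps every
# component (gene universe, subject pool, training draw, each tissue) on an
# independent stream so configurations compose without perturbing each other.
# The gene universe always derives from the *config* seed while sampling
# draws derive from the replicate seed, so repeated cohorts drawn with
# different replicate seeds share one biology (same signature / gene-set
# membership) and remain scorable by one trained signature.
substreamSeed <- function(seed, component) {
  offs <- c(genes = 1L, subjects = 2L, training = 3L)
  k <- if (is.character(component)) offs[[component]] else 3L + component
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

# gene universe: ids, log-baselines, signature/proliferation/senescence
# membership and the latent-coupling vector
geneUniverse <- function(config) {
  set.seed(substreamSeed(config$seed, "genes"))
  ids <- sprintf("G%05d", seq_len(config$nGenes))
  base <- stats::rnorm(config$nGenes, config$baseMean, config$baseSd)
  pick <- sample.int(config$nGenes,
                     config$nSignatureGenes + config$nProlifGenes +
                       config$nSenescGenes)
  sig <- pick[seq_len(config$nSignatureGenes)]
  prolif <- pick[config$nSignatureGenes + seq_len(config$nProlifGenes)]
  senesc <- pick[config$nSignatureGenes + config$nProlifGenes +
                   seq_len(config$nSenescGenes)]
  ids[prolif[1L]] <- "MKI67"
  coupling <- numeric(config$nGenes)
  coupling[sig] <- config$signatureCoupling
  coupling[prolif] <- config$couplingProlif
  coupling[senesc] <- config$couplingSenesc
  list(ids = ids, base = base, coupling = coupling,
       signatureIdx = sig, prolifIdx = prolif, senescIdx = senesc)
}

ageBinLabels <- function() c("20-29", "30-39", "40-49",
                             "50-59", "60-69", "70-79")

# shared subject pool: ages uniform over the six decade bins, sex, Hardy
# death code, and the subject-level shared stemness factor
subjectPool <- function(config, seed = config$seed) {
  set.seed(substreamSeed(seed, "subjects"))
  n <- config$nSubjects
  bins <- sample(ageBinLabels(), n, replace = TRUE)
  data.frame(subject_id = sprintf("SUBJ%04d", seq_len(n)),
             age_bin = bins,
             age_years = ageBinToMidpoint(bins),
             sex = sample(c("female", "male"), n, replace = TRUE),
             death = as.character(sample(0:4, n, replace = TRUE)),
             factor = stats::rnorm(n),
             stringsAsFactors = FALSE)
}

#' Simulate a signature-training compendium
#'
#' Emits a pluripotent + differentiated training set: stem-labeled samples
#' have every signature gene shifted up by `signatureEffect` on the log
#' scale; differentiated samples sit at baseline. All values are
#' `exp(N(base_g + shift, noiseSd))`, hence finite and positive.
#' Reproducible bit-for-bit given the configuration seed.
#'
#' @param config a [simulationConfig()]; `config$seed` fixes the gene
#'   universe (which genes form the signature and the gene sets).
#' @param seed replicate seed for the sample draws (defaults to
#'   `config$seed`); varying it redraws samples under the same biology.
#' @return `SummarizedExperiment`: assay `"tpm"`, `colData$isStem`,
#'   `rowData$isSignature`, and the config in `metadata`.
#' @export
simulateTrainingCohort <- function(config = simulationConfig(),
                                   seed = config$seed) {
  uni <- geneUniverse(config)
  set.seed(substreamSeed(as.integer(seed), "training"))
  nStem <- config$nStemTrain
  nDiff <- config$nDiffTrain
  n <- nStem + nDiff
  shift <- numeric(config$nGenes)
  shift[uni$signatureIdx] <- config$signatureEffect
  mu <- uni$base + outer(shift, c(rep(1, nStem), rep(0, nDiff)))
  logx <- mu + matrix(stats::rnorm(config$nGenes * n, 0, config$noiseSd),
                      config$nGenes, n)
  x <- exp(logx)
  dimnames(x) <- list(uni$ids,
                      c(sprintf("STEM%03d", seq_len(nStem)),
                        sprintf("DIFF%03d", seq_len(nDiff))))
  isSig <- seq_len(config$nGenes) %in% uni$signatureIdx
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = x),
    colData = S4Vectors::DataFrame(
      isStem = c(rep(TRUE, nStem), rep(FALSE, nDiff)),
      row.names = colnames(x)),
    rowData = S4Vectors::DataFrame(isSignature = isSig,
                                   row.names = rownames(x)),
    metadata = list(config = config))
}

#' Simulate a multi-tissue aging cohort with known ground truth
#'
#' For each tissue, subjects are drawn (without replacement) from a shared
#' pool whose ages are uniform over the six GTEx decade bins. Each sample's
#' latent stemness is
#' `betaAge*(age-50) + sexEffect*1[female] + regionEffect +
#'  sharedFactorLoading*u_subject + N(0, latentSd)`,
#' and gene `g`'s abundance is `exp(base_g + c_g*latent + N(0, noiseSd))`
#' with the coupling vector `c_g` described in [simulationConfig()]. The
#' shared subject pool gives tissues overlapping donors (cross-tissue
#' structure); the MKI67 marker and the proliferation set co-vary positively
#' and the senescence set negatively with latent stemness under the default
#' couplings.
#'
#' @param config a [simulationConfig()]; `config$seed` fixes the gene
#'   universe (which genes form the signature and the gene sets).
#' @param seed replicate seed for the subject pool and sample draws
#'   (defaults to `config$seed`); varying it redraws a cohort under the
#'   same biology, so one trained signature applies across replicates.
#' @return `SummarizedExperiment`: assay `"tpm"`; `colData` columns
#'   `sample_id`, `subject_id`, `tissue`, `region`, `age_bin`, `age_years`,
#'   `sex`, `death`; `rowData` membership flags; `metadata$groundTruth` with
#'   per-tissue `betaAge`, gene-set ids, per-sample latent stemness and
#'   per-subject shared factor; `metadata$config`.
#' @export
simulateCohort <- function(config = simulationConfig(),
                           seed = config$seed) {
  seed <- as.integer(seed)
  uni <- geneUniverse(config)
  pool <- subjectPool(config, seed)
  blocks <- vector("list", length(config$tissues))
  for (k in seq_along(config$tissues)) {
    ts <- config$tissues[[k]]
    set.seed(substreamSeed(seed, k))
    cand <- if (ts$hasSex) pool else pool[pool$sex == "female", ]
    if (nrow(cand) < ts$nSamples)
      stop("tissue '", ts$name, "': subject pool too small (",
           nrow(cand), " candidates for ", ts$nSamples, " samples)")
    wsel <- rep(1, nrow(cand))
    if (ts$sexImbalance != 0) {
      fem <- cand$sex == "female"
      wsel[fem] <- exp(ts$sexImbalance * (cand$age_years[fem] - 50) / 25)
    }
    rows <- sample.int(nrow(cand), ts$nSamples, prob = wsel)
    subj <- cand[rows, , drop = FALSE]
    region <- sample.int(ts$nRegions, ts$nSamples, replace = TRUE)
    latent <- ts$betaAge * (subj$age_years - 50) +
      ts$sexEffect * as.numeric(subj$sex == "female") +
      ts$regionEffects[region] +
      ts$sharedFactorLoading * subj$factor +
      stats::rnorm(ts$nSamples, 0, config$latentSd)
    logx <- uni$base + outer(uni$coupling, latent) +
      matrix(stats::rnorm(config$nGenes * ts$nSamples, 0, config$noiseSd),
             config$nGenes, ts$nSamples)
    tab <- data.frame(
      sample_id = paste0(ts$name, "-", subj$subject_id),
      subject_id = subj$subject_id,
      tissue = ts$name,
      region = paste0(ts$name, "-R", region),
      age_bin = subj$age_bin,
      age_years = subj$age_years,
      sex = if (ts$hasSex) subj$sex else rep("female", ts$nSamples),
      death = subj$death,
      stringsAsFactors = FALSE)
    blocks[[k]] <- list(x = exp(logx), tab = tab, latent = latent)
  }
  x <- do.call(cbind, lapply(blocks, `[[`, "x"))
  tab <- do.call(rbind, lapply(blocks, `[[`, "tab"))
  latent <- unlist(lapply(blocks, `[[`, "latent"), use.names = FALSE)
  names(latent) <- tab$sample_id
  dimnames(x) <- list(uni$ids, tab$sample_id)
  idx <- seq_len(config$nGenes)
  gt <- list(
    betaAge = stats::setNames(
      vapply(config$tissues, `[[`, 0, "betaAge"),
      vapply(config$tissues, `[[`, "", "name")),
    signatureGenes = uni$ids[uni$signatureIdx],
    prolifGenes = uni$ids[uni$prolifIdx],
    senescGenes = uni$ids[uni$senescIdx],
    latent = latent,
    subjectFactor = stats::setNames(pool$factor, pool$subject_id))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = x),
    colData = S4Vectors::DataFrame(tab, row.names = tab$sample_id),
    rowData = S4Vectors::DataFrame(
      isSignature = idx %in% uni$signatureIdx,
      isProlif = idx %in% uni$prolifIdx,
      isSenesc = idx %in% uni$senescIdx,
      row.names = uni$ids),
    metadata = list(config = config, groundTruth = gt))
}

#' Sample table of a simulated cohort
#'
#' @param se `SummarizedExperiment` from [simulateCohort()].
#' @return plain data.frame of the per-sample covariates.
#' @export
sampleTable <- function(se) {
  as.data.frame(SummarizedExperiment::colData(se))
}

#' Ground truth of a simulated cohort
#'
#' @param se `SummarizedExperiment` from [simulateCohort()].
#' @return the `groundTruth` list stored at simulation time.
#' @export
groundTruth <- function(se) {
  S4Vectors::metadata(se)$groundTruth
}
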