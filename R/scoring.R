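#' Restrict a signature and expression matrix to their shared genes
#'
#' @param signature a [StemnessSignature-class].
#' @param x genes x samples expression matrix.
#' @return list with `signature` (reduced, signature gene order preserved),
#'   `x` (reduced matrix, same order), and `coverage` (shared / signature
#'   size). A warning is raised when coverage drops below 0.5; an empty
#'   intersection is an error.
#' @export
intersectSignature <- function(signature, x) {
  stopifnot(is(signature, "StemnessSignature"), is.matrix(x))
  shared <- signature@geneIds[signature@geneIds %in% rownames(x)]
  coverage <- length(shared) / length(signature@geneIds)
  if (length(shared) == 0L)
    stop("no genes shared between signature and expression matrix")
  if (coverage < 0.5)
    warning(sprintf("only %.1f%% of signature genes present in matrix",
                    100 * coverage))
  keep <- match(shared, signature@geneIds)
  sig <- signature
  sig@geneIds <- signature@geneIds[keep]
  sig@weights <- signature@weights[keep]
  if (length(signature@centers)) sig@centers <- signature@centers[keep]
  list(signature = sig, x = x[shared, , drop = FALSE], coverage = coverage)
}

#' Spearman raw stemness scores for each sample
#'
#' For every sample (column), the raw score is the Spearman rank correlation
#' between the signature weight vector and the sample's expression profile
#' over the genes shared by both (ties by average ranks). Samples whose
#' expression is constant across the shared genes have no defined rank
#' correlation; their raw score is `NA`, with a warning.
#'
#' @param signature a [StemnessSignature-class].
#' @param x genes x samples expression matrix.
#' @return named numeric vector of raw scores in `[-1, 1]` (or `NA`), with
#'   attribute `"nGenesUsed"` giving the shared-gene count.
#' @export
scoreSamples <- function(signature, x) {
  red <- intersectSignature(signature, x)
  xs <- red$x
  if (nrow(xs) < 3L)
    stop("need at least 3 shared genes for Spearman scoring, got ", nrow(xs))
  w <- red$signature@weights
  if (max(w) == min(w))
    stop("signature weights are constant over the shared genes; ",
         "rank correlation is undefined")
  xs0 <- xs
  dimnames(xs0) <- NULL  # named columns slow rank() down considerably
  raw <- suppressWarnings(
    drop(stats::cor(w, xs0, method = "spearman")))
  if (anyNA(raw)) {
    # cor() yields NA exactly for zero-variance profiles (w is non-constant)
    warning("zero expression variance over signature genes for sample(s): ",
            paste(colnames(xs)[is.na(raw)], collapse = ", "),
            "; raw score recorded as NA")
  }
  names(raw) <- colnames(xs)
  attr(raw, "nGenesUsed") <- nrow(xs)
  raw
}

#' Rescale raw scores to the unit interval
#'
#' Affine min-max map: `(raw - min) / (max - min)` over the non-missing raw
#' scores, so the least stem-like sample in the cohort scores exactly 0 and
#' the most stem-like exactly 1. The map is cohort-dependent by construction;
#' see [stemnessScores()] for the scope choices.
#'
#' @param raw numeric raw scores (may contain `NA`, which propagate).
#' @return numeric vector in `[0, 1]`, same names and length.
#' @export
rescaleUnit <- function(raw) {
  ok <- !is.na(raw)
  if (sum(ok) < 2L)
    stop("need at least 2 non-missing raw scores to rescale")
  rng <- range(raw[ok])
  if (rng[1L] == rng[2L])
    stop("all raw scores identical; rescaling is degenerate. ",
         "Score jointly with more (or more diverse) samples.")
  out <- (raw - rng[1L]) / (rng[2L] - rng[1L])
  out
}

#' Score a cohort against a stemness signature
#'
#' Computes the per-sample raw Spearman score ([scoreSamples()]) and the
#' `[0, 1]` stemness index ([rescaleUnit()]). The rescaling scope is a
#' first-class choice: `"all"` rescales over the whole cohort jointly (the
#' pan-tissue convention), `"per_group"` rescales within each level of
#' `groups` (the convention for independently scored validation datasets).
#' Raw scores are always returned so results can be re-scoped without
#' re-scoring.
#'
#' @param signature a [StemnessSignature-class].
#' @param x genes x samples matrix, or a `SummarizedExperiment` whose first
#'   assay is one.
#' @param rescaleScope `"all"` or `"per_group"`.
#' @param groups per-sample group labels (required for `"per_group"`).
#' @return data.frame with columns `sample_id`, `raw_score`, `stemness`,
#'   `n_genes_used`.
#' @export
setGeneric("stemnessScores",
  function(signature, x, rescaleScope = c("all", "per_group"),
           groups = NULL)
    standardGeneric("stemnessScores"))

#' @rdname stemnessScores
#' @export
setMethod("stemnessScores", signature(signature = "StemnessSignature",
                                      x = "matrix"),
  function(signature, x, rescaleScope = c("all", "per_group"),
           groups = NULL) {
    rescaleScope <- match.arg(rescaleScope)
    raw <- scoreSamples(signature, x)
    nGenes <- attr(raw, "nGenesUsed")
    stem <- rep(NA_real_, length(raw))
    if (rescaleScope == "all") {
      stem <- rescaleUnit(as.numeric(raw))
    } else {
      if (is.null(groups) || length(groups) != length(raw))
        stop("'groups' (one per sample) required for per_group rescaling")
      for (g in unique(groups)) {
        idx <- which(groups == g)
        stem[idx] <- rescaleUnit(as.numeric(raw[idx]))
      }
    }
    data.frame(sample_id = names(raw),
               raw_score = as.numeric(raw),
               stemness = stem,
               n_genes_used = nGenes,
               stringsAsFactors = FALSE)
  })

#' @rdname stemnessScores
#' @export
setMethod("stemnessScores", signature(signature = "StemnessSignature",
                                      x = "SummarizedExperiment"),
  function(signature, x, rescaleScope = c("all", "per_group"),
           groups = NULL) {
    stemnessScores(signature, SummarizedExperiment::assay(x),
                   rescaleScope = rescaleScope, groups = groups)
  })
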