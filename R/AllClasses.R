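#' @import methods
NULL

#' Stemness signature from one-class logistic regression
#'
#' Holds the per-gene weight vector produced by [fitOCLR()] /
#' [trainStemnessSignature()], together with the per-gene centering means used
#' during training and the fit metadata. Samples are scored against the weight
#' vector by Spearman correlation ([stemnessScores()]), so only the rank order
#' of the weights matters downstream.
#'
#' @slot geneIds character vector of gene identifiers (unique).
#' @slot weights numeric weight vector, one entry per gene.
#' @slot centers numeric per-gene means subtracted during training (training
#'   provenance; not applied when scoring, which is rank-based).
#' @slot lambda2 non-negative ridge penalty used in training.
#' @slot nTrain number of training samples the model was fitted on.
#' @slot converged logical; whether the gradient max-norm tolerance was met.
#' @slot finalObjective value of the penalized one-class log-likelihood at the
#'   returned weights.
#' @slot nIter number of ascent iterations performed.
#'
#' @aliases StemnessSignature-class
#' @exportClass StemnessSignature
setClass("StemnessSignature",
  representation(
    geneIds = "character",
    weights = "numeric",
    centers = "numeric",
    lambda2 = "numeric",
    nTrain = "integer",
    converged = "logical",
    finalObjective = "numeric",
    nIter = "integer"
  )
)

setValidity("StemnessSignature", function(object) {
  msg <- character()
  if (length(object@weights) != length(object@geneIds))
    msg <- c(msg, "length of 'weights' must match 'geneIds'")
  if (length(object@centers) &&
      length(object@centers) != length(object@geneIds))
    msg <- c(msg, "length of 'centers' must match 'geneIds' (or be empty)")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "duplicate gene ids in signature")
  if (any(!is.finite(object@weights)))
    msg <- c(msg, "non-finite weights")
  if (length(object@lambda2) != 1L || object@lambda2 < 0)
    msg <- c(msg, "'lambda2' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Construct a StemnessSignature
#'
#' @param geneIds character vector of gene identifiers.
#' @param weights numeric weights, one per gene.
#' @param centers optional per-gene training means (provenance).
#' @param lambda2 ridge penalty used.
#' @param nTrain number of training samples.
#' @param converged logical convergence flag.
#' @param finalObjective objective value at the returned weights.
#' @param nIter iterations used.
#' @return a [StemnessSignature-class] object.
#' @export
StemnessSignature <- function(geneIds, weights, centers = numeric(0),
                              lambda2 = 1, nTrain = NA_integer_,
                              converged = NA, finalObjective = NA_real_,
                              nIter = NA_integer_) {
  new("StemnessSignature",
    geneIds = as.character(geneIds), weights = as.numeric(weights),
    centers = as.numeric(centers), lambda2 = as.numeric(lambda2),
    nTrain = as.integer(nTrain), converged = as.logical(converged),
    finalObjective = as.numeric(finalObjective), nIter = as.integer(nIter))
}

#' @describeIn StemnessSignature gene identifiers of the signature.
#' @param object,x a `StemnessSignature`.
#' @export
setGeneric("signatureGenes", function(object) standardGeneric("signatureGenes"))

#' @rdname StemnessSignature-class
#' @export
setMethod("signatureGenes", "StemnessSignature", function(object) object@geneIds)

#' @describeIn StemnessSignature named numeric weight vector.
#' @export
setGeneric("signatureWeights",
           function(object) standardGeneric("signatureWeights"))

#' @rdname StemnessSignature-class
#' @export
setMethod("signatureWeights", "StemnessSignature", function(object) {
  stats::setNames(object@weights, object@geneIds)
})

#' @rdname StemnessSignature-class
#' @export
setMethod("length", "StemnessSignature", function(x) length(x@geneIds))

setMethod("show", "StemnessSignature", function(object) {
  cat("StemnessSignature with", length(object@geneIds), "genes\n")
  cat("  lambda2:", object@lambda2,
      " nTrain:", object@nTrain,
      " converged:", object@converged,
      " iterations:", object@nIter, "\n")
  cat("  objective:", format(object@finalObjective, digits = 6), "\n")
  w <- object@weights
  cat("  weights: min", format(min(w), digits = 4),
      " median", format(stats::median(w), digits = 4),
      " max", format(max(w), digits = 4), "\n")
})

#' Cross-tissue stemness correlation matrix
#'
#' Pairwise-complete Pearson correlations of per-subject mean stemness between
#' tissues, with the per-pair subject overlap counts and an optional
#' hierarchical-clustering leaf order.
#'
#' @slot r symmetric correlation matrix (NA where overlap < the mask
#'   threshold used at construction).
#' @slot nOverlap symmetric integer matrix of subjects shared by each pair.
#' @slot ordering character permutation of tissue names from average-linkage
#'   clustering on 1 - r (may be empty if not computed).
#'
#' @aliases TissueCorrelationMatrix-class
#' @exportClass TissueCorrelationMatrix
setClass("TissueCorrelationMatrix",
  representation(r = "matrix", nOverlap = "matrix", ordering = "character")
)

setValidity("TissueCorrelationMatrix", function(object) {
  msg <- character()
  r <- object@r
  n <- object@nOverlap
  if (!identical(dim(r), dim(n)))
    msg <- c(msg, "'r' and 'nOverlap' dimensions differ")
  if (nrow(r) != ncol(r)) msg <- c(msg, "'r' must be square")
  if (!identical(rownames(r), colnames(r)))
    msg <- c(msg, "row and column names of 'r' must agree")
  ok <- is.finite(r)
  if (any(abs(r[ok & t(ok)] - t(r)[ok & t(ok)]) > 1e-12))
    msg <- c(msg, "'r' not symmetric")
  d <- diag(r)
  if (any(is.finite(d) & abs(d - 1) > 1e-12))
    msg <- c(msg, "diagonal of 'r' must be 1 where defined")
  if (length(object@ordering) &&
      !setequal(object@ordering, rownames(r)))
    msg <- c(msg, "'ordering' must be a permutation of the tissue names")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TissueCorrelationMatrix", function(object) {
  k <- nrow(object@r)
  off <- object@r[upper.tri(object@r)]
  cat("TissueCorrelationMatrix over", k, "tissues\n")
  cat("  off-diagonal r: median", format(stats::median(off, na.rm = TRUE), digits = 3),
      " range [", format(min(off, na.rm = TRUE), digits = 3), ",",
      format(max(off, na.rm = TRUE), digits = 3), "]\n")
  cat("  masked pairs (insufficient overlap):", sum(is.na(off)), "\n")
  if (length(object@ordering))
    cat("  clustering order:", paste(object@ordering, collapse = ", "), "\n")
})

#' @describeIn TissueCorrelationMatrix the correlation matrix.
#' @param object a `TissueCorrelationMatrix`.
#' @export
setGeneric("correlationMatrix",
           function(object) standardGeneric("correlationMatrix"))

#' @rdname TissueCorrelationMatrix-class
#' @export
setMethod("correlationMatrix", "TissueCorrelationMatrix",
          function(object) object@r)

#' @describeIn TissueCorrelationMatrix the per-pair subject overlap counts.
#' @export
setGeneric("overlapMatrix", function(object) standardGeneric("overlapMatrix"))

#' @rdname TissueCorrelationMatrix-class
#' @export
setMethod("overlapMatrix", "TissueCorrelationMatrix",
          function(object) object@nOverlap)

#' @describeIn TissueCorrelationMatrix clustering leaf order (character).
#' @export
setGeneric("clusterOrdering",
           function(object) standardGeneric("clusterOrdering"))

#' @rdname TissueCorrelationMatrix-class
#' @export
setMethod("clusterOrdering", "TissueCorrelationMatrix",
          function(object) object@ordering)
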