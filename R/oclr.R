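#' Mean-center each gene across samples
#'
#' Subtracts the per-gene mean so every gene row averages zero over the
#' columns of `x`. Centering is computed over *all* columns supplied — for
#' signature training this must be the complete training compendium
#' (pluripotent plus differentiated samples), so that the stem-labeled subset
#' retains a non-zero mean on stem-elevated genes (see
#' [trainStemnessSignature()]).
#'
#' @param x numeric genes x samples matrix.
#' @return list with `centered` (matrix of same shape) and `means` (numeric
#'   per-gene means, for provenance).
#' @export
meanCenter <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (any(!is.finite(x))) stop("non-finite values in matrix")
  m <- rowMeans(x)
  list(centered = x - m, means = m)
}

# log(1 + exp(s)) without overflow
softplus <- function(s) {
  out <- numeric(length(s))
  pos <- s > 0
  out[pos] <- s[pos] + log1p(exp(-s[pos]))
  out[!pos] <- log1p(exp(s[!pos]))
  out
}

#' One-class logistic regression objective
#'
#' Penalized mean log-likelihood that all training samples belong to the
#' positive (stem) class:
#' \deqn{L(w) = \frac{1}{n}\sum_i \left[s_i - \log(1 + e^{s_i})\right]
#'       - \frac{\lambda_2}{2}\|w\|^2, \qquad s_i = w^\top x_i,}
#' i.e. the mean of \eqn{\log \sigma(s_i)} minus a ridge penalty. There is no
#' intercept: downstream scoring uses only the rank order of \eqn{w}. The
#' per-sample terms are evaluated through a softplus formulation, so the
#' objective stays finite for arbitrarily large \eqn{|s_i|}.
#'
#' @param w numeric weight vector (one per gene).
#' @param xCentered centered genes x samples training matrix.
#' @param lambda2 ridge penalty, >= 0.
#' @return the (scalar) objective value; larger is better.
#' @export
oclrObjective <- function(w, xCentered, lambda2 = 1) {
  checkOclrArgs(w, xCentered, lambda2)
  s <- drop(crossprod(xCentered, w))
  # s - softplus(s) == -softplus(-s)
  mean(-softplus(-s)) - lambda2 / 2 * sum(w^2)
}

#' Gradient of the one-class logistic objective
#'
#' \deqn{\nabla L(w) = \frac{1}{n} \sum_i x_i\,(1 - \sigma(s_i)) - \lambda_2 w}
#' with \eqn{\sigma} the logistic function.
#'
#' @inheritParams oclrObjective
#' @return numeric gradient vector of the same length as `w`.
#' @export
oclrGradient <- function(w, xCentered, lambda2 = 1) {
  checkOclrArgs(w, xCentered, lambda2)
  s <- drop(crossprod(xCentered, w))
  n <- ncol(xCentered)
  drop(xCentered %*% (1 - stats::plogis(s))) / n - lambda2 * w
}

checkOclrArgs <- function(w, xCentered, lambda2) {
  if (!is.matrix(xCentered) || !is.numeric(xCentered))
    stop("'xCentered' must be a numeric matrix")
  if (length(w) != nrow(xCentered))
    stop("length(w) must equal nrow(xCentered)")
  if (any(!is.finite(w)) || any(!is.finite(xCentered)) ||
      !is.finite(lambda2))
    stop("non-finite input to OCLR objective/gradient")
  invisible(TRUE)
}

# largest squared singular value of x via eigen on the smaller Gram matrix
spectralNormSq <- function(x) {
  g <- if (ncol(x) <= nrow(x)) crossprod(x) else tcrossprod(x)
  max(eigen(g, symmetric = TRUE, only.values = TRUE)$values, 0)
}

#' Fit the one-class logistic regression signature
#'
#' Maximizes [oclrObjective()] by deterministic fixed-step gradient ascent
#' from \eqn{w = 0}. The step size is \eqn{1/L} with
#' \eqn{L = \lambda_2 + \sigma_{\max}(X)^2 / (4n)} an upper bound on the
#' gradient's Lipschitz constant, which guarantees a monotonically
#' non-decreasing objective trace for this concave problem. Iteration stops
#' when the gradient max-norm falls below `tol` or after `maxIter` steps; the
#' `converged` slot records which. Training is exactly reproducible (no
#' random initialization) and invariant to the order of training samples.
#'
#' @param xCentered centered genes x samples training matrix (rownames =
#'   gene ids). An all-zero matrix yields the zero signature with a warning.
#' @param lambda2 ridge penalty (> 0 recommended; default 1).
#' @param tol convergence tolerance on the gradient max-norm.
#' @param maxIter iteration cap.
#' @param keepTrace if `TRUE`, attach the per-iteration objective values as
#'   attribute `"objectiveTrace"` of the result.
#' @return a [StemnessSignature-class] (centers slot left empty; filled by
#'   [trainStemnessSignature()]).
#' @export
fitOCLR <- function(xCentered, lambda2 = 1, tol = 1e-6, maxIter = 10000L,
                    keepTrace = FALSE) {
  stopifnot(is.matrix(xCentered), ncol(xCentered) >= 2L, lambda2 > 0)
  if (any(!is.finite(xCentered))) stop("non-finite training values")
  genes <- rownames(xCentered)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(xCentered)))
  p <- nrow(xCentered)
  n <- ncol(xCentered)
  if (all(xCentered == 0)) {
    warning("all-zero training matrix; returning zero signature")
    sig <- StemnessSignature(genes, rep(0, p), lambda2 = lambda2,
                             nTrain = n, converged = TRUE,
                             finalObjective = -log(2), nIter = 0L)
    if (keepTrace) attr(sig, "objectiveTrace") <- -log(2)
    return(sig)
  }
  L <- lambda2 + spectralNormSq(xCentered) / (4 * n)
  step <- 1 / L
  w <- rep(0, p)
  trace <- if (keepTrace) numeric(maxIter + 1L) else NULL
  obj <- oclrObjective(w, xCentered, lambda2)
  if (keepTrace) trace[1L] <- obj
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    g <- oclrGradient(w, xCentered, lambda2)
    if (max(abs(g)) < tol) {
      converged <- TRUE
      break
    }
    w <- w + step * g
    iter <- iter + 1L
    if (keepTrace) trace[iter + 1L] <- oclrObjective(w, xCentered, lambda2)
  }
  if (!converged && max(abs(oclrGradient(w, xCentered, lambda2))) < tol)
    converged <- TRUE
  if (!converged)
    warning("fitOCLR did not reach tol = ", tol, " in ", maxIter,
            " iterations")
  sig <- StemnessSignature(genes, w, lambda2 = lambda2, nTrain = n,
                           converged = converged,
                           finalObjective = oclrObjective(w, xCentered,
                                                          lambda2),
                           nIter = iter)
  if (keepTrace) attr(sig, "objectiveTrace") <- trace[seq_len(iter + 1L)]
  sig
}

#' Train a stemness signature from a labeled training compendium
#'
#' End-to-end training: (optionally) log2-transform TPM-like values, center
#' every gene across *all* training samples, then fit the one-class logistic
#' model on the stem-labeled columns only. Centering over the full
#' compendium is what gives the stem subset a non-zero mean on stem-elevated
#' genes; centering over the stem samples alone would make \eqn{w = 0} the
#' exact optimum of the concave objective and the signature vacuous.
#'
#' @param x genes x samples training matrix (TPM-like, non-negative), or a
#'   `SummarizedExperiment` whose first assay is such a matrix and whose
#'   `colData` has a logical `isStem` column.
#' @param isStem logical per-sample stem flag (ignored for the
#'   SummarizedExperiment method, which reads `colData(x)$isStem`).
#' @param lambda2,tol,maxIter passed to [fitOCLR()].
#' @param log2 transform expression to `log2(x + 1)` before centering
#'   (default `TRUE`). Scoring is rank-based, so this choice affects only
#'   training.
#' @return a [StemnessSignature-class] with the per-gene centering means in
#'   its `centers` slot.
#' @export
setGeneric("trainStemnessSignature",
  function(x, isStem, lambda2 = 1, tol = 1e-6, maxIter = 10000L,
           log2 = TRUE)
    standardGeneric("trainStemnessSignature"))

#' @rdname trainStemnessSignature
#' @export
setMethod("trainStemnessSignature", "matrix",
  function(x, isStem, lambda2 = 1, tol = 1e-6, maxIter = 10000L,
           log2 = TRUE) {
    stopifnot(is.logical(isStem), length(isStem) == ncol(x))
    if (sum(isStem) < 2L) stop("need at least 2 stem-labeled samples")
    if (any(x < 0)) stop("expression must be non-negative")
    xl <- if (log2) log2(x + 1) else x
    cen <- meanCenter(xl)
    sig <- fitOCLR(cen$centered[, isStem, drop = FALSE], lambda2 = lambda2,
                   tol = tol, maxIter = maxIter)
    sig@centers <- cen$means
    sig@nTrain <- sum(isStem)
    validObject(sig)
    sig
  })

#' @rdname trainStemnessSignature
#' @export
setMethod("trainStemnessSignature", "SummarizedExperiment",
  function(x, isStem, lambda2 = 1, tol = 1e-6, maxIter = 10000L,
           log2 = TRUE) {
    cd <- SummarizedExperiment::colData(x)
    if (!"isStem" %in% names(cd))
      stop("colData of the training object needs an 'isStem' column")
    trainStemnessSignature(SummarizedExperiment::assay(x),
                           as.logical(cd$isStem), lambda2 = lambda2,
                           tol = tol, maxIter = maxIter, log2 = log2)
  })
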