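#' Subject x tissue stemness matrix
#'
#' Aggregates per-sample stemness to one value per (subject, tissue): the
#' mean over a subject's samples in that tissue (relevant when a subject
#' contributed several samples of the same tissue), `NA` where the subject
#' has no sample of the tissue.
#'
#' @param scores score data.frame from [stemnessScores()].
#' @param table sample table with `sample_id`, `subject_id`, `tissue`.
#' @return numeric matrix, subjects in rows, tissues in columns, with `NA`
#'   for absent combinations.
#' @export
subjectTissueMatrix <- function(scores, table) {
  stopifnot(all(c("sample_id", "stemness") %in% names(scores)),
            all(c("sample_id", "subject_id", "tissue") %in% names(table)))
  df <- merge(scores[c("sample_id", "stemness")], table, by = "sample_id",
              sort = FALSE)
  subjects <- sort(unique(df$subject_id))
  tissues <- sort(unique(df$tissue))
  m <- matrix(NA_real_, length(subjects), length(tissues),
              dimnames = list(subjects, tissues))
  agg <- stats::aggregate(stemness ~ subject_id + tissue, data = df,
                          FUN = mean)
  m[cbind(match(agg$subject_id, subjects),
          match(agg$tissue, tissues))] <- agg$stemness
  m
}

#' Pairwise-complete cross-tissue correlation matrix
#'
#' Pearson correlation of per-subject mean stemness between every pair of
#' tissues, computed over the subjects observed in both (pairwise-complete,
#' not listwise). Pairs with fewer than `minOverlap` shared subjects are
#' masked (`NA`) but their overlap count is always reported. Sex-restricted
#' tissues — which cannot share subjects of both sexes — are typically
#' passed through `exclude`.
#'
#' @param m subject x tissue matrix from [subjectTissueMatrix()].
#' @param minOverlap minimum shared subjects per pair (>= 3; default 10).
#' @param exclude tissue names to remove before computing (e.g.
#'   `c("testis", "prostate", "vagina", "uterus", "ovary")`).
#' @return a [TissueCorrelationMatrix-class].
#' @export
pairwiseCorrelation <- function(m, minOverlap = 10L, exclude = character(0)) {
  stopifnot(is.matrix(m), minOverlap >= 3L)
  m <- m[, !colnames(m) %in% exclude, drop = FALSE]
  k <- ncol(m)
  if (k < 2L) stop("fewer than 2 tissues remain after exclusion")
  tn <- colnames(m)
  r <- matrix(NA_real_, k, k, dimnames = list(tn, tn))
  nO <- matrix(0L, k, k, dimnames = list(tn, tn))
  diag(r) <- 1
  diag(nO) <- colSums(!is.na(m))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      both <- !is.na(m[, i]) & !is.na(m[, j])
      nO[i, j] <- nO[j, i] <- sum(both)
      if (sum(both) >= minOverlap) {
        r[i, j] <- r[j, i] <- stats::cor(m[both, i], m[both, j])
      }
    }
  }
  new("TissueCorrelationMatrix", r = r, nOverlap = nO,
      ordering = character(0))
}

#' Hierarchical tissue ordering of a correlation matrix
#'
#' Average-linkage agglomerative clustering on the distance `1 - r`,
#' returning the dendrogram leaf order. Tissues are sorted lexicographically
#' before clustering so equal-distance merges resolve deterministically and
#' the result is invariant to the input tissue order. The correlation
#' matrix must be complete — raise data coverage or drop sparse tissues
#' first if entries are masked.
#'
#' @param x a [TissueCorrelationMatrix-class] or a complete symmetric
#'   correlation matrix with dimnames.
#' @return character vector: tissue names in leaf order. For a
#'   `TissueCorrelationMatrix` input, the object is returned with its
#'   `ordering` slot filled instead.
#' @export
setGeneric("clusterOrder", function(x) standardGeneric("clusterOrder"))

#' @rdname clusterOrder
#' @export
setMethod("clusterOrder", "matrix", function(x) {
  stopifnot(nrow(x) == ncol(x), !is.null(rownames(x)))
  if (any(is.na(x)))
    stop("correlation matrix has masked entries; lower minOverlap, add ",
         "data, or drop the sparse tissues before clustering")
  ord <- order(rownames(x))
  xs <- x[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(1 - xs), method = "average")
  rownames(xs)[hc$order]
})

#' @rdname clusterOrder
#' @export
setMethod("clusterOrder", "TissueCorrelationMatrix", function(x) {
  x@ordering <- clusterOrder(x@r)
  x
})
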