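#' Pearson correlation with exact t-based p-value
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite, each with
#'   non-zero variance (a constant vector is an error naming the offender).
#' @return list with elements `r`, `p`, `n`.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x))) stop("non-finite values in 'x'")
  if (any(!is.finite(y))) stop("non-finite values in 'y'")
  if (stats::sd(x) == 0) stop("zero variance in 'x'")
  if (stats::sd(y) == 0) stop("zero variance in 'y'")
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR control: after sorting the m p-values ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' original order. Output never falls below the input p-value.
#'
#' @param p numeric p-values, all in (0, 1].
#' @return adjusted values (FDR/q-values) in the input order.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-group Pearson correlations with FDR across groups
#'
#' The per-tissue correlation screen: within each group (tissue) holding at
#' least `minN` samples, the Pearson correlation between a numeric
#' per-sample variable and the stemness score, with BH adjustment applied
#' across the reported groups only (one correction per analysis family).
#' Groups below `minN` are not tested; their labels are returned in the
#' `"skipped"` attribute.
#'
#' @param scores score data.frame from [stemnessScores()] (needs
#'   `sample_id` and `stemness`).
#' @param table sample table with `sample_id` and the grouping column.
#' @param xVar either the name of a numeric column of `table` (e.g.
#'   `"age_years"`) or a named numeric vector keyed by sample id (e.g. a
#'   marker or gene-set signal).
#' @param groupVar name of the grouping column (default `"tissue"`).
#' @param minN minimum group size to report (default 50).
#' @return data.frame with columns `group`, `n`, `r`, `p`, `fdr`, sorted by
#'   group label; attribute `"skipped"` lists groups below `minN`.
#' @export
correlateWithinGroups <- function(scores, table, xVar,
                                  groupVar = "tissue", minN = 50L) {
  stopifnot(is.data.frame(scores), is.data.frame(table),
            all(c("sample_id", "stemness") %in% names(scores)),
            "sample_id" %in% names(table), groupVar %in% names(table))
  df <- merge(scores[c("sample_id", "stemness")], table,
              by = "sample_id", sort = FALSE)
  if (is.character(xVar) && length(xVar) == 1L) {
    if (!xVar %in% names(df)) stop("column '", xVar, "' not in table")
    df$.x <- as.numeric(df[[xVar]])
  } else {
    if (is.null(names(xVar))) stop("vector 'xVar' must be named by sample id")
    df$.x <- as.numeric(xVar[df$sample_id])
  }
  df <- df[is.finite(df$.x) & is.finite(df$stemness), , drop = FALSE]
  groups <- sort(unique(df[[groupVar]]))
  sizes <- vapply(groups, function(g) sum(df[[groupVar]] == g), 0L)
  keep <- groups[sizes >= minN]
  skipped <- groups[sizes < minN]
  if (length(keep) == 0L)
    stop("no group reaches minN = ", minN, " samples")
  rows <- lapply(keep, function(g) {
    sub <- df[df[[groupVar]] == g, ]
    pc <- pearsonCor(sub$.x, sub$stemness)
    data.frame(group = g, n = pc$n, r = pc$r, p = pc$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Mean-expression signal of a gene set
#'
#' Per-sample arithmetic mean of the TPM values of the set genes present in
#' the matrix — the construction used both for the proliferation index
#' (mean over the PCNA-correlated list) and the SenMayo senescence signal.
#'
#' @param x genes x samples matrix or `SummarizedExperiment`.
#' @param genes character vector of gene ids (a gene set).
#' @return named numeric per-sample signal. Warns when less than half of
#'   the set is present; errors when none is.
#' @export
setGeneric("geneSetSignal", function(x, genes)
  standardGeneric("geneSetSignal"))

#' @rdname geneSetSignal
#' @export
setMethod("geneSetSignal", "matrix", function(x, genes) {
  stopifnot(length(genes) >= 1L)
  present <- intersect(genes, rownames(x))
  if (length(present) == 0L)
    stop("none of the ", length(genes), " set genes present in the matrix")
  if (length(present) < 0.5 * length(unique(genes)))
    warning(sprintf("gene-set coverage only %d/%d",
                    length(present), length(unique(genes))))
  colMeans(x[present, , drop = FALSE])
})

#' @rdname geneSetSignal
#' @export
setMethod("geneSetSignal", "SummarizedExperiment", function(x, genes) {
  geneSetSignal(SummarizedExperiment::assay(x), genes)
})

#' Expression signal of a single marker gene
#'
#' @param x genes x samples matrix or `SummarizedExperiment`.
#' @param geneId the marker (e.g. `"MKI67"`). An absent gene is an error
#'   listing near-matching row names.
#' @return named numeric vector (the gene's expression row).
#' @export
setGeneric("markerSignal", function(x, geneId)
  standardGeneric("markerSignal"))

#' @rdname markerSignal
#' @export
setMethod("markerSignal", "matrix", function(x, geneId) {
  stopifnot(length(geneId) == 1L)
  if (!geneId %in% rownames(x)) {
    near <- utils::head(agrep(geneId, rownames(x), value = TRUE,
                              ignore.case = TRUE), 5L)
    stop("gene '", geneId, "' not found",
         if (length(near)) paste0("; near matches: ",
                                  paste(near, collapse = ", ")))
  }
  x[geneId, ]
})

#' @rdname markerSignal
#' @export
setMethod("markerSignal", "SummarizedExperiment", function(x, geneId) {
  markerSignal(SummarizedExperiment::assay(x), geneId)
})

#' Two- or multi-group comparison of scores
#'
#' Two groups: two-sided two-sample t-test (Welch by default; set
#' `pooled = TRUE` for the equal-variance Student form). Three or more
#' groups: Kruskal-Wallis rank test with tie correction. Degenerate input
#' (any group under 2 samples, or zero overall variance) is an error.
#'
#' @param values numeric per-sample scores.
#' @param groups group labels, same length.
#' @param pooled use the pooled-variance t-test for two groups.
#' @return list with `test` (`"t"` or `"kruskal-wallis"`), `statistic`,
#'   `p`, `df`, and the group labels.
#' @export
compareGroups <- function(values, groups, pooled = FALSE) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (stats::sd(values) == 0)
    stop("zero variance across all samples; comparison undefined")
  if (length(lv) == 2L) {
    tt <- stats::t.test(values[groups == lv[1L]],
                        values[groups == lv[2L]],
                        var.equal = pooled, alternative = "two.sided")
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), groups = lv)
  } else {
    kw <- stats::kruskal.test(values, factor(groups))
    list(test = "kruskal-wallis", statistic = unname(kw$statistic),
         p = kw$p.value, df = unname(kw$parameter), groups = lv)
  }
}

#' Derive a proliferation gene set from a marker
#'
#' Ranks all genes by their Pearson correlation with a proliferation marker
#' (PCNA in the original construction) across samples and returns the top
#' fraction — the recipe behind published proliferation indexes. The marker
#' itself is excluded from the returned set.
#'
#' @param x genes x samples matrix or `SummarizedExperiment`.
#' @param marker marker gene id present in `x`.
#' @param topFrac fraction of genes to keep (default 0.01).
#' @return character vector of gene ids, ordered by decreasing correlation.
#' @export
setGeneric("deriveProliferationSet",
  function(x, marker = "PCNA", topFrac = 0.01)
    standardGeneric("deriveProliferationSet"))

#' @rdname deriveProliferationSet
#' @export
setMethod("deriveProliferationSet", "matrix",
  function(x, marker = "PCNA", topFrac = 0.01) {
    stopifnot(topFrac > 0, topFrac <= 1, ncol(x) >= 3L)
    m <- markerSignal(x, marker)
    others <- setdiff(rownames(x), marker)
    keepVar <- others[apply(x[others, , drop = FALSE], 1L,
                            function(v) max(v) > min(v))]
    r <- drop(stats::cor(m, t(x[keepVar, , drop = FALSE])))
    k <- max(1L, ceiling(topFrac * nrow(x)))
    keepVar[order(r, decreasing = TRUE)][seq_len(min(k, length(keepVar)))]
  })

#' @rdname deriveProliferationSet
#' @export
setMethod("deriveProliferationSet", "SummarizedExperiment",
  function(x, marker = "PCNA", topFrac = 0.01) {
    deriveProliferationSet(SummarizedExperiment::assay(x), marker, topFrac)
  })
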