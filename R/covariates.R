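#' Build the per-tissue design matrix
#'
#' Constructs the covariate-adjusted design for one tissue: an intercept, age
#' in years (numeric, always first among predictors), and treatment-coded
#' dummies for each requested categorical covariate that shows at least two
#' observed levels in that tissue. Categoricals that are constant or entirely
#' missing are dropped and recorded (e.g. sex in a sex-restricted tissue, or
#' region where a tissue has a single detail). Rows missing a *retained*
#' covariate are removed (complete-case) with a message. The reference level
#' of each categorical is its most frequent level, recorded for
#' reproducibility.
#'
#' @param table sample table (canonical columns; see [readSampleTable()]).
#' @param tissue tissue label to subset to.
#' @param covariates categoricals to consider, subset of
#'   `c("sex", "death", "region")`.
#' @return list with `design` (numeric matrix incl. intercept), `sampleIds`,
#'   `dropped` (covariates removed), `references` (named character of
#'   reference levels), `nDroppedRows`.
#' @export
buildDesign <- function(table, tissue,
                        covariates = c("sex", "death", "region")) {
  stopifnot(is.data.frame(table),
            all(covariates %in% c("sex", "death", "region")))
  sub <- table[table$tissue == tissue, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no samples for tissue '", tissue, "'")
  if (any(!is.finite(sub$age_years)))
    stop("missing age for tissue '", tissue, "'")
  dropped <- character(0)
  refs <- character(0)
  keepCov <- character(0)
  for (cv in covariates) {
    v <- sub[[cv]]
    lev <- unique(v[!is.na(v)])
    if (length(lev) < 2L) {
      dropped <- c(dropped, cv)
    } else {
      keepCov <- c(keepCov, cv)
    }
  }
  cc <- rep(TRUE, nrow(sub))
  for (cv in keepCov) cc <- cc & !is.na(sub[[cv]])
  nDroppedRows <- sum(!cc)
  if (nDroppedRows > 0L)
    message("buildDesign(", tissue, "): dropped ", nDroppedRows,
            " incomplete row(s)")
  sub <- sub[cc, , drop = FALSE]
  dat <- data.frame(age = sub$age_years)
  for (cv in keepCov) {
    f <- factor(sub[[cv]])
    ref <- names(sort(table(f), decreasing = TRUE))[1L]
    f <- stats::relevel(f, ref = ref)
    refs[cv] <- ref
    dat[[cv]] <- f
  }
  design <- stats::model.matrix(~ ., data = dat)
  p <- ncol(design)
  if (nrow(design) < p + 2L)
    stop("tissue '", tissue, "' has too few samples (", nrow(design),
         ") for ", p, " design columns")
  qrd <- qr(design)
  if (qrd$rank < p) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1L):p]]
    stop("rank-deficient design for tissue '", tissue, "'; aliased: ",
         paste(aliased, collapse = ", "))
  }
  list(design = design, sampleIds = sub$sample_id, dropped = dropped,
       references = refs, nDroppedRows = nDroppedRows)
}

#' Ordinary least squares fit with t-based inference
#'
#' Plain OLS of a response on a design matrix: coefficients from the QR
#' solution, standard errors from the unbiased residual variance, and
#' two-sided p-values from the t distribution with n - p degrees of freedom.
#'
#' @param design numeric design matrix (full column rank, n > p).
#' @param y numeric response vector.
#' @return list with `coefficients`, `se`, `p` (all named), `sigma2`
#'   (residual variance), `df`, `fitted`.
#' @export
olsFit <- function(design, y) {
  stopifnot(is.matrix(design), length(y) == nrow(design))
  n <- nrow(design)
  p <- ncol(design)
  if (n <= p) stop("need more observations than design columns")
  qrd <- qr(design)
  if (qrd$rank < p) stop("singular design matrix")
  fit <- stats::lm.fit(design, y)
  beta <- fit$coefficients
  res <- fit$residuals
  df <- n - p
  sigma2 <- sum(res^2) / df
  xtxInv <- chol2inv(qr.R(qrd))
  se <- sqrt(pmax(sigma2 * diag(xtxInv), 0))
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(coefficients = beta, se = stats::setNames(se, names(beta)),
       p = stats::setNames(pval, names(beta)), sigma2 = sigma2, df = df,
       fitted = fit$fitted.values)
}

#' Age-effect summary of a fitted per-tissue model
#'
#' Extracts the age coefficient (stemness change per year) with its standard
#' error and p-value, and derives a fold-change style summary:
#' `log2fc = log2(yhat(ageHigh) / yhat(ageLow))` with every categorical at
#' its reference level (dummies = 0), defined only when both predictions are
#' positive; otherwise `NA` with the reason recorded.
#'
#' @param fit result of [olsFit()].
#' @param ages two ages (years) to compare; default `c(25, 75)`, the extreme
#'   decade midpoints.
#' @return list with `alpha`, `se`, `p`, `log2fc`, `log2fcReason`
#'   (`NA` when defined).
#' @export
ageEffect <- function(fit, ages = c(25, 75)) {
  beta <- fit$coefficients
  if (!"age" %in% names(beta)) stop("model has no 'age' coefficient")
  alpha <- unname(beta["age"])
  yhat <- unname(beta["(Intercept)"]) + alpha * ages
  if (all(yhat > 0)) {
    log2fc <- log2(yhat[2L] / yhat[1L])
    reason <- NA_character_
  } else {
    log2fc <- NA_real_
    reason <- sprintf("non-positive predicted stemness (%.3g at %g, %.3g at %g)",
                      yhat[1L], ages[1L], yhat[2L], ages[2L])
  }
  list(alpha = alpha, se = unname(fit$se["age"]), p = unname(fit$p["age"]),
       log2fc = log2fc, log2fcReason = reason)
}

#' Covariate-adjusted age effect per tissue
#'
#' Fits, for every tissue with enough samples, the linear model
#' `stemness ~ age + sex + death + region` (categoricals dropped
#' automatically when constant in a tissue; see [buildDesign()]) and
#' summarizes the age effect, with BH FDR across the fitted tissues.
#'
#' @param scores score data.frame from [stemnessScores()].
#' @param table sample table.
#' @param covariates categoricals to adjust for.
#' @param minN minimum per-tissue sample size to fit (default 50).
#' @param ages ages for the log2 fold-change summary.
#' @return data.frame with one row per fitted tissue: `tissue`, `n`,
#'   `alpha`, `se`, `p`, `fdr`, `log2fc`, `dropped_covariates`
#'   (comma-separated). Attribute `"skipped"` lists tissues below `minN`.
#' @export
fitAgeModels <- function(scores, table,
                         covariates = c("sex", "death", "region"),
                         minN = 50L, ages = c(25, 75)) {
  stopifnot(all(c("sample_id", "stemness") %in% names(scores)))
  y <- stats::setNames(scores$stemness, scores$sample_id)
  tissues <- sort(unique(table$tissue))
  sizes <- vapply(tissues, function(tt) sum(table$tissue == tt), 0L)
  keep <- tissues[sizes >= minN]
  skipped <- tissues[sizes < minN]
  if (length(keep) == 0L) stop("no tissue reaches minN = ", minN)
  rows <- lapply(keep, function(tt) {
    d <- buildDesign(table, tt, covariates = covariates)
    yy <- y[d$sampleIds]
    if (any(is.na(yy)))
      stop("missing stemness score for tissue '", tt, "'")
    fit <- olsFit(d$design, yy)
    eff <- ageEffect(fit, ages = ages)
    data.frame(tissue = tt, n = length(yy), alpha = eff$alpha,
               se = eff$se, p = eff$p, log2fc = eff$log2fc,
               dropped_covariates = paste(d$dropped, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p)
  out <- out[c("tissue", "n", "alpha", "se", "p", "fdr", "log2fc",
               "dropped_covariates")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
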