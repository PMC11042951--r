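#' Read a gene x sample expression matrix
#'
#' Reads TPM-like abundance tables in plain TSV (first column = gene id,
#' header row = sample ids) or GCT 1.2 (two header lines, `Name` and
#' `Description` columns). Values must be finite and non-negative. Duplicate
#' gene rows are collapsed by their mean with a warning; duplicate sample ids
#' are an error. Expression is accepted as-is — no renormalization is applied
#' anywhere in the pipeline, since scoring is rank-based within each sample.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"gct"`.
#' @return numeric matrix, genes in rows, samples in columns, with dimnames.
#' @export
readExpression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gct") {
    hdr <- readLines(path, n = 3L)
    if (!grepl("^#1\\.2", hdr[1L]))
      stop("malformed GCT header in ", path, ": expected '#1.2', got '",
           hdr[1L], "'")
    rawNames <- strsplit(hdr[3L], "\t", fixed = TRUE)[[1L]][-(1:2)]
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                            colClasses = "character")
    if (ncol(df) < 3L || !identical(tolower(names(df)[1:2]),
                                    c("name", "description")))
      stop("malformed GCT body: first two columns must be Name, Description")
    genes <- df[[1L]]
    df <- df[, -(1:2), drop = FALSE]
  } else {
    rawNames <- strsplit(readLines(path, n = 1L), "\t",
                         fixed = TRUE)[[1L]][-1L]
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2L)
      stop("malformed TSV: need a gene-id column plus at least one sample")
    genes <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
  }
  samples <- rawNames  # read.delim may silently uniquify duplicate headers
  names(df) <- samples
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & df[[j]] != "NA")
    if (length(bad))
      stop("non-numeric value '", df[[j]][bad[1L]], "' at row ", bad[1L],
           " (gene ", genes[bad[1L]], "), column '", samples[j], "'")
    vals[, j] <- v
  }
  rownames(vals) <- genes
  validateExpression(collapseDuplicateGenes(vals))
}

collapseDuplicateGenes <- function(x) {
  if (!anyDuplicated(rownames(x))) return(x)
  dups <- unique(rownames(x)[duplicated(rownames(x))])
  warning("collapsing ", length(dups), " duplicated gene id(s) by mean: ",
          paste(utils::head(dups, 5L), collapse = ", "),
          if (length(dups) > 5L) ", ...")
  grp <- factor(rownames(x), levels = unique(rownames(x)))
  out <- rowsum(x, grp) / as.vector(table(grp))
  rownames(out) <- levels(grp)
  out
}

validateExpression <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene and sample ids as dimnames")
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (any(!is.finite(x))) stop("expression values must be finite")
  if (any(x < 0)) stop("expression values must be non-negative")
  x
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()] for the TSV dialect; round-trips values to
#' full double precision.
#'
#' @param x numeric gene x sample matrix with dimnames.
#' @param path output path.
#' @param idColumn header of the gene-id column.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, idColumn = "gene_id") {
  validateExpression(x)
  df <- data.frame(rownames(x), format(x, digits = 17, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(idColumn, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map GTEx-style age decade bins to midpoint years
#'
#' The six GTEx age-range labels are approximated by their decade midpoints:
#' "20-29" -> 25, "30-39" -> 35, ..., "70-79" -> 75. Any other label is an
#' error — cohorts with literal ages should supply them as numbers instead.
#'
#' @param ageBin character vector of bin labels.
#' @return numeric vector of midpoint ages in years.
#' @export
ageBinToMidpoint <- function(ageBin) {
  mids <- c("20-29" = 25, "30-39" = 35, "40-49" = 45,
            "50-59" = 55, "60-69" = 65, "70-79" = 75)
  out <- mids[as.character(ageBin)]
  if (any(is.na(out)))
    stop("unknown age bin label(s): ",
         paste(unique(ageBin[is.na(out)]), collapse = ", "),
         " (supported: ", paste(names(mids), collapse = ", "), ")")
  unname(out)
}

#' Default GTEx sample-attribute column mapping
#'
#' Column names used by the GTEx sample/subject attribute tables; pass a
#' modified copy to [readSampleTable()] for other cohorts.
#'
#' @return named list mapping canonical fields to source column names.
#' @export
gtexColumnMap <- function() {
  list(sample_id = "SAMPID", subject_id = "SUBJID", tissue = "SMTS",
       region = "SMTSD", age = "AGE", sex = "SEX", death = "DTHHRDY")
}

#' Read a per-sample covariate table
#'
#' Builds the canonical sample table (sample_id, subject_id, tissue, region,
#' age_bin, age_years, sex, death) from a TSV with arbitrary column names via
#' a column map. Age may be given either as a decade bin (mapped through
#' [ageBinToMidpoint()]) or as a literal age in years. Missing optional
#' covariates (region, sex, death) are recorded as `NA`, never imputed; the
#' Hardy death code is kept as an opaque categorical.
#'
#' @param path TSV path with a header row.
#' @param columnMap named list as returned by [gtexColumnMap()]; entries for
#'   `sample_id`, `subject_id`, `tissue` are required, the rest optional.
#' @return data.frame with the canonical columns above.
#' @export
readSampleTable <- function(path, columnMap = gtexColumnMap()) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  for (f in c("sample_id", "subject_id", "tissue")) {
    cm <- columnMap[[f]]
    if (is.null(cm) || !cm %in% names(df))
      stop("required column for '", f, "' (", cm %||% "<unmapped>",
           ") not found in ", path)
  }
  pick <- function(f) {
    cm <- columnMap[[f]]
    v <- if (!is.null(cm) && cm %in% names(df)) df[[cm]] else
      rep(NA_character_, nrow(df))
    v[!is.na(v) & v == ""] <- NA_character_  # empty cells are absent values
    v
  }
  out <- data.frame(
    sample_id = pick("sample_id"),
    subject_id = pick("subject_id"),
    tissue = pick("tissue"),
    region = pick("region"),
    sex = pick("sex"),
    death = pick("death"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample id(s) in sample table: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]),
               collapse = ", "))
  age <- pick("age")
  isBin <- grepl("^[0-9]+-[0-9]+$", age)
  ageYears <- suppressWarnings(as.numeric(age))
  if (any(isBin)) ageYears[isBin] <- ageBinToMidpoint(age[isBin])
  bad <- which(!is.na(age) & is.na(ageYears))
  if (length(bad))
    stop("unparseable age value '", age[bad[1L]], "' for sample ",
         out$sample_id[bad[1L]])
  if (any(!is.na(ageYears) & ageYears <= 0))
    stop("age in years must be positive")
  out$age_bin <- ifelse(isBin, age, NA_character_)
  out$age_years <- ageYears
  out[c("sample_id", "subject_id", "tissue", "region",
        "age_bin", "age_years", "sex", "death")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' gene ids. Duplicate genes within a line are removed (first occurrence
#' kept); line order is preserved.
#'
#' @param path GMT path.
#' @return named list of character vectors; set descriptions are kept in the
#'   `"descriptions"` attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (any(lengths(sets) == 0L)) stop("empty gene set in ", path)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  stopifnot(length(names(sets)) == length(sets))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Drop samples from excluded tissue regions
#'
#' Removes records whose `region` (tissue detail) is in `exclude` — e.g.
#' cultured cell lines such as EBV-transformed lymphocytes and transformed
#' fibroblasts, which behave like stem-like outliers and would distort
#' tissue-level aging analyses.
#'
#' @param table sample table as from [readSampleTable()].
#' @param exclude character vector of region labels to drop.
#' @return the filtered sample table; the number removed is reported via
#'   `message()`, and an empty result triggers a warning.
#' @export
filterTissueDetails <- function(table, exclude) {
  stopifnot(is.data.frame(table), "region" %in% names(table))
  if (length(exclude) == 0L) return(table)
  drop <- !is.na(table$region) & table$region %in% exclude
  message("filterTissueDetails: removed ", sum(drop), " of ", nrow(table),
          " samples")
  out <- table[!drop, , drop = FALSE]
  if (nrow(out) == 0L) warning("all samples removed by region filter")
  rownames(out) <- NULL
  out
}

#' Write / read a stemness score table
#'
#' TSV round-trip for the score tables produced by [stemnessScores()]
#' (columns `sample_id`, `raw_score`, `stemness`, `n_genes_used`).
#'
#' @param scores score data.frame.
#' @param path file path.
#' @return `path` invisibly for the writer; the score data.frame for the
#'   reader.
#' @export
writeScores <- function(scores, path) {
  stopifnot(all(c("sample_id", "raw_score", "stemness") %in% names(scores)))
  df <- scores
  for (cn in c("raw_score", "stemness"))
    df[[cn]] <- format(df[[cn]], digits = 17, trim = TRUE,
                       scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (cn in c("raw_score", "stemness"))
    if (cn %in% names(df)) df[[cn]] <- as.numeric(df[[cn]])
  if ("n_genes_used" %in% names(df))
    df$n_genes_used <- as.integer(df$n_genes_used)
  df
}
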