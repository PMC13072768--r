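#' Read a genes x samples expression table
#'
#' Reads a tab-separated table whose first column (named \code{gene_id}) holds
#' gene identifiers and whose header row holds sample identifiers. Duplicate
#' gene ids, non-numeric cells and missing values are rejected with an error
#' naming the offending row or column.
#'
#' @param path file path to a TSV table.
#' @param space declared value space of the table.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpressionTable <- function(path,
                                space = c("log2", "raw_tpm", "zscored")) {
  space <- match.arg(space)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L)
    stop("expression table needs a gene_id column and at least one sample")
  gid <- df[[1L]]
  if (anyDuplicated(gid))
    stop("duplicate gene id(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) || anyNA(vals)) {
    if (!nrow(bad)) bad <- which(is.na(vals), arr.ind = TRUE)
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 gid[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  dimnames(num) <- list(gid, colnames(vals))
  ExpressionMatrix(num, space)
}

#' Write an ExpressionMatrix as a TSV table
#'
#' Inverse of \code{\link{readExpressionTable}}: first column \code{gene_id},
#' one column per sample, tab-separated, full precision (round trips are
#' bit-exact through the text representation).
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(m, path) {
  stopifnot(is(m, "ExpressionMatrix"))
  v <- exprValues(m)
  df <- data.frame(gene_id = rownames(v),
                   format(v, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("gene_id", colnames(v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2(TPM + 1) transform
#'
#' Maps every raw TPM value v to log2(v + 1), the model's working scale before
#' per-gene standardization.
#'
#' @param m an \linkS4class{ExpressionMatrix} in \code{raw_tpm} space.
#' @return An \linkS4class{ExpressionMatrix} in \code{log2} space.
#' @export
log2Transform <- function(m) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (exprSpace(m) != "raw_tpm")
    stop("log2Transform expects raw_tpm input, got ", exprSpace(m))
  v <- exprValues(m)
  if (any(v < 0)) stop("negative TPM value encountered")
  ExpressionMatrix(log2(v + 1), "log2")
}

#' Fit per-gene standardization constants
#'
#' Computes, per gene, the mean and population standard deviation (divide by
#' n) across samples of a log2-space matrix. Genes with zero variance get a
#' substituted sd of 1 (their z-scores are then 0), keeping the gene universe
#' stable across cross-validation folds.
#'
#' @param m an \linkS4class{ExpressionMatrix} in \code{log2} space with at
#'   least two samples.
#' @return A \linkS4class{NormalizationParams}.
#' @export
fitGeneNormalization <- function(m) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (exprSpace(m) != "log2")
    stop("fitGeneNormalization expects log2 input, got ", exprSpace(m))
  v <- exprValues(m)
  if (ncol(v) < 2L)
    stop("need at least two samples to fit normalization constants")
  mu <- rowMeans(v)
  s <- sqrt(rowMeans((v - mu)^2))
  degen <- rownames(v)[s == 0]
  s[s == 0] <- 1
  new("NormalizationParams", mean = stats::setNames(mu, rownames(v)),
      sd = stats::setNames(s, rownames(v)), degenerate = degen)
}

#' Apply fitted standardization constants
#'
#' Standardizes a log2-space matrix with previously fitted constants (never
#' refit on the matrix being transformed, so held-out data see only
#' training-fold statistics).
#'
#' @param m an \linkS4class{ExpressionMatrix} in \code{log2} space whose genes
#'   are all covered by \code{p}.
#' @param p a \linkS4class{NormalizationParams}.
#' @return An \linkS4class{ExpressionMatrix} in \code{zscored} space.
#' @export
applyGeneNormalization <- function(m, p) {
  stopifnot(is(m, "ExpressionMatrix"), is(p, "NormalizationParams"))
  if (exprSpace(m) != "log2")
    stop("applyGeneNormalization expects log2 input, got ", exprSpace(m))
  v <- exprValues(m)
  missing <- setdiff(rownames(v), names(p@mean))
  if (length(missing))
    stop("genes missing from normalization params: ",
         paste(missing, collapse = ", "))
  mu <- p@mean[rownames(v)]
  s <- p@sd[rownames(v)]
  ExpressionMatrix((v - mu) / s, "zscored")
}

#' Invert per-gene standardization
#'
#' Maps z-scores back to log2 space with the same constants:
#' v = z * sd + mean.
#'
#' @param m an \linkS4class{ExpressionMatrix} in \code{zscored} space.
#' @param p the \linkS4class{NormalizationParams} used to standardize it.
#' @return An \linkS4class{ExpressionMatrix} in \code{log2} space.
#' @export
invertGeneNormalization <- function(m, p) {
  stopifnot(is(m, "ExpressionMatrix"), is(p, "NormalizationParams"))
  if (exprSpace(m) != "zscored")
    stop("invertGeneNormalization expects zscored input")
  v <- exprValues(m)
  missing <- setdiff(rownames(v), names(p@mean))
  if (length(missing))
    stop("genes missing from normalization params: ",
         paste(missing, collapse = ", "))
  ExpressionMatrix(v * p@sd[rownames(v)] + p@mean[rownames(v)], "log2")
}

#' Assemble a paired perturbation dataset
#'
#' Aligns a baseline and a post-treatment matrix on their gene intersection
#' (sorted lexicographically, so embeddings and tests see one deterministic
#' order) and builds one record per pairing row. Vocabularies are recorded in
#' first-appearance order of the pairing table.
#'
#' @param baseline,treated \linkS4class{ExpressionMatrix} objects sharing a
#'   value space.
#' @param pairing data.frame with columns \code{baseline_sample},
#'   \code{treated_sample}, \code{cell_id}, \code{drug_id}.
#' @return A \linkS4class{PerturbationDataset}.
#' @export
assembleDataset <- function(baseline, treated, pairing) {
  stopifnot(is(baseline, "ExpressionMatrix"), is(treated, "ExpressionMatrix"))
  need <- c("baseline_sample", "treated_sample", "cell_id", "drug_id")
  if (!all(need %in% colnames(pairing)))
    stop("pairing must have columns ", paste(need, collapse = ", "))
  if (exprSpace(baseline) != exprSpace(treated))
    stop("baseline and treated matrices must share a value space")
  genes <- sort(intersect(geneIds(baseline), geneIds(treated)))
  if (!length(genes)) stop("empty gene intersection")
  bm <- exprValues(baseline)[genes, , drop = FALSE]
  tm <- exprValues(treated)[genes, , drop = FALSE]
  bs <- as.character(pairing$baseline_sample)
  ts <- as.character(pairing$treated_sample)
  missB <- setdiff(bs, colnames(bm))
  missT <- setdiff(ts, colnames(tm))
  if (length(missB) || length(missT))
    stop("pairing references absent sample(s): ",
         paste(c(missB, missT), collapse = ", "))
  cells <- as.character(pairing$cell_id)
  drugs <- as.character(pairing$drug_id)
  new("PerturbationDataset", geneIds = genes,
      x = t(bm[, bs, drop = FALSE]), y = t(tm[, ts, drop = FALSE]),
      cellIds = cells, drugIds = drugs,
      cellVocab = unique(cells), drugVocab = unique(drugs),
      space = exprSpace(baseline))
}

#' Read a pairing manifest TSV
#'
#' @param path TSV with columns baseline_sample, treated_sample, cell_id,
#'   drug_id.
#' @return data.frame.
#' @export
readPairingTable <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  need <- c("baseline_sample", "treated_sample", "cell_id", "drug_id")
  if (!all(need %in% colnames(df)))
    stop("pairing manifest must have columns ", paste(need, collapse = ", "))
  df
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then members. Members are de-duplicated; lines with fewer than three
#' fields or no members are rejected. Effective/ineffective category labels
#' are not part of GMT — attach them with \code{\link{readStateCategories}}.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set members), in file order.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file")
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("GMT line %d has no members", i))
    list(name = f[[1L]], members = members)
  })
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate gene-set names in GMT")
  stats::setNames(lapply(sets, `[[`, "members"), nm)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of member character vectors.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a state-category mapping from YAML
#'
#' The companion file maps each gene-set name to \code{"effective"} or
#' \code{"ineffective"}; categories live outside the GMT because GMT has no
#' category field.
#'
#' @param path YAML file of \code{set_name: category} entries.
#' @return Named character vector of categories.
#' @export
readStateCategories <- function(path) {
  y <- yaml::read_yaml(path)
  out <- vapply(y, as.character, character(1))
  if (!all(out %in% c("effective", "ineffective")))
    stop("categories must be 'effective' or 'ineffective'")
  out
}
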