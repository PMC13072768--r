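#' @import methods
#' @importFrom stats rnorm runif sd cor quantile
#' @importFrom utils read.delim write.table head
NULL

VALUE_SPACES <- c("raw_tpm", "log2", "zscored")

#' ExpressionMatrix: a genes x samples matrix with a declared value space
#'
#' Thin S4 container for a numeric genes-by-samples matrix whose rows are gene
#' identifiers and whose columns are sample identifiers, tagged with the value
#' space the numbers live in: \code{"raw_tpm"} (linear, non-negative),
#' \code{"log2"} (log2(TPM + 1)), or \code{"zscored"} (per-gene standardized
#' log2 values).
#'
#' @slot values numeric matrix, genes in rows, samples in columns; dimnames
#'   carry the identifiers.
#' @slot space one of \code{"raw_tpm"}, \code{"log2"}, \code{"zscored"}.
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", space = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must have gene (row) and sample (column) names")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate gene ids")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate sample ids")
  }
  if (length(object@space) != 1L || !object@space %in% VALUE_SPACES)
    msgs <- c(msgs, sprintf("space must be one of %s",
                            paste(VALUE_SPACES, collapse = ", ")))
  if (is.numeric(v) && length(v) && !all(is.finite(v)))
    msgs <- c(msgs, "values must be finite")
  if (is.numeric(v) && length(object@space) == 1L &&
      identical(object@space, "raw_tpm") && length(v) && any(v < 0))
    msgs <- c(msgs, "raw_tpm values must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with gene row names and sample column names.
#' @param space value space, one of \code{"raw_tpm"}, \code{"log2"},
#'   \code{"zscored"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, "raw_tpm")
#' @export
ExpressionMatrix <- function(values, space = c("log2", "raw_tpm", "zscored")) {
  space <- match.arg(space)
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, space = space)
}

#' @describeIn ExpressionMatrix gene identifiers (row order)
#' @param x,object an \code{ExpressionMatrix}
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @describeIn ExpressionMatrix sample identifiers (column order)
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @describeIn ExpressionMatrix the underlying numeric matrix
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @describeIn ExpressionMatrix the declared value space
#' @export
setGeneric("exprSpace", function(x) standardGeneric("exprSpace"))
#' @export
setMethod("exprSpace", "ExpressionMatrix", function(x) x@space)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [space: %s]\n",
              nrow(object@values), ncol(object@values), object@space))
})

setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' NormalizationParams: per-gene standardization constants
#'
#' Per-gene mean and standard deviation fitted on a training fold in log2
#' space. Zero-variance (degenerate) genes carry a substituted sd of 1 and are
#' flagged, so the gene universe is stable across folds.
#'
#' @slot mean named numeric vector, one entry per gene.
#' @slot sd named numeric vector, strictly positive, same genes.
#' @slot degenerate character vector of gene ids whose sd was substituted.
#' @export
setClass("NormalizationParams",
  representation(mean = "numeric", sd = "numeric", degenerate = "character"))

setValidity("NormalizationParams", function(object) {
  msgs <- character()
  if (is.null(names(object@mean)) || is.null(names(object@sd)))
    msgs <- c(msgs, "mean and sd must be named by gene id")
  else if (!identical(names(object@mean), names(object@sd)))
    msgs <- c(msgs, "mean and sd must cover the same genes in the same order")
  if (any(!is.finite(object@mean)) || any(!is.finite(object@sd)))
    msgs <- c(msgs, "normalization constants must be finite")
  if (any(object@sd <= 0)) msgs <- c(msgs, "sd must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "NormalizationParams", function(object) {
  cat(sprintf("NormalizationParams: %d genes (%d degenerate, sd set to 1)\n",
              length(object@mean), length(object@degenerate)))
})

#' PerturbationDataset: paired baseline/post-treatment records
#'
#' A set of perturbation records sharing one gene order. Each record holds a
#' cell-line id, a drug id, a baseline profile x and a post-treatment profile
#' y. Baselines and targets are stored as two aligned samples-by-genes
#' matrices for efficiency; \code{perturbationPairs} exposes the record view.
#'
#' @slot geneIds shared gene order for every record.
#' @slot x numeric matrix, records x genes (baseline profiles).
#' @slot y numeric matrix, records x genes (post-treatment profiles).
#' @slot cellIds character, cell id per record.
#' @slot drugIds character, drug id per record.
#' @slot cellVocab unique cell ids in first-appearance order.
#' @slot drugVocab unique drug ids in first-appearance order.
#' @slot space value space of x and y.
#' @export
setClass("PerturbationDataset",
  representation(geneIds = "character", x = "matrix", y = "matrix",
                 cellIds = "character", drugIds = "character",
                 cellVocab = "character", drugVocab = "character",
                 space = "character"))

setValidity("PerturbationDataset", function(object) {
  msgs <- character()
  n <- nrow(object@x)
  g <- length(object@geneIds)
  if (ncol(object@x) != g || ncol(object@y) != g)
    msgs <- c(msgs, "x and y must have one column per gene")
  if (nrow(object@y) != n || length(object@cellIds) != n ||
      length(object@drugIds) != n)
    msgs <- c(msgs, "x, y, cellIds, drugIds must agree on record count")
  if (anyDuplicated(object@geneIds)) msgs <- c(msgs, "duplicate gene ids")
  if (!all(object@cellIds %in% object@cellVocab))
    msgs <- c(msgs, "cell id outside vocabulary")
  if (!all(object@drugIds %in% object@drugVocab))
    msgs <- c(msgs, "drug id outside vocabulary")
  if (anyDuplicated(object@cellVocab) || anyDuplicated(object@drugVocab))
    msgs <- c(msgs, "vocabularies must be unique")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PerturbationDataset", function(object) {
  cat(sprintf(paste0("PerturbationDataset: %d records, %d genes, ",
                     "%d cell lines, %d drugs [space: %s]\n"),
              nrow(object@x), length(object@geneIds),
              length(object@cellVocab), length(object@drugVocab),
              object@space))
})

#' @describeIn PerturbationDataset number of records
#' @param object a \code{PerturbationDataset}
#' @export
setGeneric("nPairs", function(object) standardGeneric("nPairs"))
#' @export
setMethod("nPairs", "PerturbationDataset", function(object) nrow(object@x))

#' @describeIn PerturbationDataset list of per-record views, each with
#'   \code{cell_id}, \code{drug_id}, \code{x}, \code{y}
#' @export
setGeneric("perturbationPairs",
           function(object) standardGeneric("perturbationPairs"))
#' @export
setMethod("perturbationPairs", "PerturbationDataset", function(object) {
  lapply(seq_len(nrow(object@x)), function(i)
    list(cell_id = object@cellIds[i], drug_id = object@drugIds[i],
         x = stats::setNames(object@x[i, ], object@geneIds),
         y = stats::setNames(object@y[i, ], object@geneIds)))
})

#' @describeIn PerturbationDataset gene order shared by all records
#' @export
setMethod("geneIds", "PerturbationDataset", function(x) x@geneIds)

#' Subset a PerturbationDataset by record index
#' @param x a \code{PerturbationDataset}
#' @param i integer or logical record index
#' @param j,drop,... ignored
#' @export
setMethod("[", "PerturbationDataset", function(x, i, j, ..., drop = FALSE) {
  new("PerturbationDataset", geneIds = x@geneIds,
      x = x@x[i, , drop = FALSE], y = x@y[i, , drop = FALSE],
      cellIds = x@cellIds[i], drugIds = x@drugIds[i],
      cellVocab = x@cellVocab, drugVocab = x@drugVocab, space = x@space)
})

#' StateScoreTable: per-sample six-state scores and resistance calls
#'
#' Holds raw ssGSEA scores for the six post-treatment cellular states, their
#' per-state z-scores across the scored cohort, the mean effective and
#' ineffective scores, the resistance index RI (ineffective minus effective),
#' and the resulting effective/ineffective call (RI > 0 means ineffective).
#'
#' @slot sampleIds sample identifiers.
#' @slot stateNames the six state (gene-set) names.
#' @slot categories named character, \code{"effective"}/\code{"ineffective"}
#'   per state.
#' @slot raw samples x states matrix of raw ssGSEA scores.
#' @slot z samples x states matrix of per-state z-scores.
#' @slot effectiveScore,ineffectiveScore,ri numeric per sample.
#' @slot call character per sample, \code{"effective"} or
#'   \code{"ineffective"}.
#' @export
setClass("StateScoreTable",
  representation(sampleIds = "character", stateNames = "character",
                 categories = "character", raw = "matrix", z = "matrix",
                 effectiveScore = "numeric", ineffectiveScore = "numeric",
                 ri = "numeric", call = "character"))

setValidity("StateScoreTable", function(object) {
  msgs <- character()
  n <- length(object@sampleIds); s <- length(object@stateNames)
  if (!all(dim(object@raw) == c(n, s)) || !all(dim(object@z) == c(n, s)))
    msgs <- c(msgs, "score matrices must be samples x states")
  if (length(object@ri) != n || length(object@call) != n)
    msgs <- c(msgs, "per-sample vectors must match sample count")
  if (!all(object@categories %in% c("effective", "ineffective")))
    msgs <- c(msgs, "categories must be effective/ineffective")
  bad <- (object@ri > 0) != (object@call == "ineffective")
  if (any(bad)) msgs <- c(msgs, "call must equal ineffective iff ri > 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StateScoreTable", function(object) {
  cat(sprintf("StateScoreTable: %d samples x %d states; %d ineffective calls\n",
              length(object@sampleIds), length(object@stateNames),
              sum(object@call == "ineffective")))
})

#' @describeIn StateScoreTable assemble the table as a data.frame (raw scores,
#'   z-scores, effective/ineffective scores, RI, call)
#' @param object a \code{StateScoreTable}
#' @export
setGeneric("asStateFrame", function(object) standardGeneric("asStateFrame"))
#' @export
setMethod("asStateFrame", "StateScoreTable", function(object) {
  raw <- object@raw; z <- object@z
  colnames(raw) <- paste0("raw_", object@stateNames)
  colnames(z) <- paste0("z_", object@stateNames)
  data.frame(sample_id = object@sampleIds, raw, z,
             effective_score = object@effectiveScore,
             ineffective_score = object@ineffectiveScore,
             ri = object@ri, call = object@call,
             row.names = NULL, check.names = FALSE)
})

#' SyntheticCohort: a seeded simulated perturbation study with ground truth
#'
#' Paired baseline/post-treatment profiles for a grid of cell lines and drugs
#' with replicates, generated in log2(TPM+1)-like space under an additive
#' low-rank drug-effect model, together with every ground-truth quantity the
#' evaluation machinery estimates.
#'
#' @slot baseline,treated \linkS4class{ExpressionMatrix} objects (log2 space),
#'   one column per record.
#' @slot pairing data.frame with columns baseline_sample, treated_sample,
#'   cell_id, drug_id.
#' @slot delta 3-d array cells x drugs x genes of true expression shifts.
#' @slot geneMeans named numeric, per-gene baseline means.
#' @slot cellProfiles cells x genes matrix of noiseless cell baselines.
#' @slot geneSets list of planted gene sets (possibly empty).
#' @slot setCategories named character mapping set name to category.
#' @slot responseLabels data.frame cell_id, drug_id, label, log_gi50 (possibly
#'   empty).
#' @slot config the \code{simConfig} list used.
#' @export
setClass("SyntheticCohort",
  representation(baseline = "ExpressionMatrix", treated = "ExpressionMatrix",
                 pairing = "data.frame", delta = "array",
                 geneMeans = "numeric", cellProfiles = "matrix",
                 geneSets = "list", setCategories = "character",
                 responseLabels = "data.frame", config = "list"))

setMethod("show", "SyntheticCohort", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("SyntheticCohort: %d genes, %d cells x %d drugs x %d ",
                     "reps (seed %d)\n"),
              cfg$nGenes, cfg$nCells, cfg$nDrugs, cfg$nReps, cfg$seed))
  if (length(object@geneSets))
    cat(sprintf("  planted state programs: %d sets\n", length(object@geneSets)))
})
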