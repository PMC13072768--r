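#' Save a trained model (or bundle) as a checkpoint
#'
#' Serializes every parameter group of the generator and discriminator plus
#' the normalization constants to one RDS file, and writes a sidecar JSON
#' manifest (same path with extension \code{.json}) enumerating the
#' architecture tags, gene count, vocabularies and training configuration.
#'
#' @param model a \code{TrainedModel} or \code{ModelBundle}.
#' @param path checkpoint file path (e.g. \code{model.rds}).
#' @return \code{path}, invisibly.
#' @export
writeModelCheckpoint <- function(model, path) {
  saveRDS(model, path)
  g <- model$generator
  manifest <- list(
    combination = model$combination,
    generator = g$architecture,
    discriminator = model$discriminator$architecture,
    n_genes = g$nGenes,
    embedding_dim = g$embDim,
    cell_vocab = g$cellVocab,
    drug_vocab = g$drugVocab,
    config = if (!is.null(model$config)) unclass(model$config))
  manifestPath <- sub("\\.[^.]*$", ".json", path)
  if (identical(manifestPath, path)) manifestPath <- paste0(path, ".json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         null = "null")
  }
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by \code{\link{writeModelCheckpoint}}.
#' @return the saved \code{TrainedModel} / \code{ModelBundle}.
#' @export
readModelCheckpoint <- function(path) readRDS(path)
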