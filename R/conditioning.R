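#' Initialize a learnable embedding table
#'
#' One embedding vector per vocabulary entry, drawn i.i.d. Normal(0, 0.02^2)
#' from a per-position seed stream (entry i of any vocabulary gets the same
#' vector under the same seed), plus a shared affine projection from the
#' embedding dimension to the gene dimension (weights Normal(0, 0.02^2), zero
#' bias). The small scale keeps the conditioned input close to the raw
#' baseline at initialization.
#'
#' @param vocab character vector of entity ids (cell lines or drugs).
#' @param dim embedding dimensionality (default 128).
#' @param nGenes length of the expression vectors the projection maps to.
#' @param seed integer seed; the table is deterministic given
#'   \code{(vocab, dim, nGenes, seed)}.
#' @return A list with \code{vocab}, \code{dim}, \code{vectors} (|vocab| x dim
#'   matrix, rows named by entity) and \code{projection} (\code{W}, \code{b}).
#' @export
initEmbeddingTable <- function(vocab, dim = 128L, nGenes, seed = 1L) {
  vocab <- as.character(vocab)
  if (!length(vocab)) stop("empty vocabulary")
  if (anyDuplicated(vocab)) stop("duplicate vocabulary entries")
  if (dim < 1L) stop("dim must be >= 1")
  vectors <- matrix(0, length(vocab), dim,
                    dimnames = list(vocab, NULL))
  for (i in seq_along(vocab)) {
    set.seed(deriveSeed(seed, i))
    vectors[i, ] <- rnorm(dim, 0, 0.02)
  }
  set.seed(deriveSeed(seed, -1L))
  projection <- list(W = matrix(rnorm(dim * nGenes, 0, 0.02), dim, nGenes),
                     b = numeric(nGenes))
  list(vocab = vocab, dim = dim, vectors = vectors, projection = projection)
}

# look up embedding rows for a batch of ids, with a vocabulary error
embLookup <- function(table, ids) {
  idx <- match(ids, table$vocab)
  if (anyNA(idx))
    stop("unknown id(s): ", paste(unique(ids[is.na(idx)]), collapse = ", "))
  table$vectors[idx, , drop = FALSE]
}

# project embeddings to gene space (batch rows)
embProject <- function(table, emb) addBias(emb %*% table$projection$W,
                                           table$projection$b)

#' Condition an input profile by element-wise addition
#'
#' Adds the gene-space-projected cell and drug vectors to the baseline
#' profile. Output length equals input length — conditioning never inflates
#' the input dimensionality (the motivation for addition over concatenation).
#'
#' @param x numeric baseline vector (length n_genes).
#' @param cellVec,drugVec projected conditioning vectors, same length.
#' @return \code{x + cellVec + drugVec}.
#' @export
conditionInput <- function(x, cellVec, drugVec) {
  if (length(cellVec) != length(x) || length(drugVec) != length(x))
    stop("conditioning vectors must match the input length")
  x + cellVec + drugVec
}

#' Initialize a FiLM modulation network
#'
#' A one-hidden-layer network mapping the concatenated (cell, drug)
#' embeddings to the feature-wise modulation parameters: 2*embDim inputs, a
#' ReLU hidden layer, and a linear layer producing 2*hidden outputs that split
#' into the gamma offset and beta. The output layer is zero-initialized so
#' the network yields identity modulation (gamma = 1, beta = 0) at the start
#' of training.
#'
#' @param embDim embedding dimensionality per entity (default 128).
#' @param hidden generator hidden width the parameters modulate (default 256).
#' @param modHidden hidden units in the modulation network (default 128).
#' @param seed integer seed.
#' @return A list with layers \code{l1}, \code{l2} and sizes.
#' @export
initModulationNetwork <- function(embDim = 128L, hidden = 256L,
                                  modHidden = 128L, seed = 1L) {
  set.seed(deriveSeed(seed, 11L))
  list(l1 = newLinear(2L * embDim, modHidden),
       l2 = newLinear(modHidden, 2L * hidden, zero = TRUE),
       embDim = embDim, hidden = hidden, modHidden = modHidden)
}

# batch FiLM parameter forward pass with cache for backprop
filmParamsBatch <- function(net, cellEmb, drugEmb) {
  m0 <- cbind(cellEmb, drugEmb)
  a1 <- linFwd(m0, net$l1)
  m1 <- relu(a1)
  out <- linFwd(m1, net$l2)
  H <- net$hidden
  list(gamma = 1 + out[, seq_len(H), drop = FALSE],
       beta = out[, H + seq_len(H), drop = FALSE],
       cache = list(m0 = m0, m1 = m1))
}

filmParamsBwd <- function(net, cache, dGamma, dBeta) {
  dOut <- cbind(dGamma, dBeta)
  b2 <- linBwd(dOut, cache$m1, net$l2)
  dM1 <- b2$dX * (cache$m1 > 0)
  b1 <- linBwd(dM1, cache$m0, net$l1)
  ed <- ncol(cache$m0) / 2L
  list(grads = list(l1 = list(W = b1$dW, b = b1$db),
                    l2 = list(W = b2$dW, b = b2$db)),
       dCellEmb = b1$dX[, seq_len(ed), drop = FALSE],
       dDrugEmb = b1$dX[, ed + seq_len(ed), drop = FALSE])
}

#' Compute FiLM parameters for one cell-drug pair
#'
#' Concatenates the raw (un-projected) cell and drug embeddings, runs them
#' through the modulation network, and returns the feature-wise parameters:
#' gamma is one plus the first half of the network output (so a
#' zero-initialized network modulates with the identity), beta is the second
#' half.
#'
#' @param net a modulation network from \code{\link{initModulationNetwork}}.
#' @param cellEmb,drugEmb numeric embedding vectors of length \code{embDim}.
#' @return list with numeric vectors \code{gamma} and \code{beta} of length
#'   \code{hidden}.
#' @export
filmParams <- function(net, cellEmb, drugEmb) {
  if (length(cellEmb) != net$embDim || length(drugEmb) != net$embDim)
    stop("embedding length does not match the modulation network input")
  fp <- filmParamsBatch(net, matrix(cellEmb, 1L), matrix(drugEmb, 1L))
  list(gamma = drop(fp$gamma), beta = drop(fp$beta))
}

#' Apply feature-wise linear modulation
#'
#' @param h hidden feature vector.
#' @param p list with \code{gamma} and \code{beta} (as from
#'   \code{\link{filmParams}}).
#' @return \code{gamma * h + beta}.
#' @export
applyFilm <- function(h, p) {
  if (length(p$gamma) != length(h) || length(p$beta) != length(h))
    stop("FiLM parameter length does not match the hidden vector")
  p$gamma * h + p$beta
}
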