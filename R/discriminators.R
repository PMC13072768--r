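#' Initialize a conditional discriminator
#'
#' Builds the parameter set for one of the two discriminator architectures:
#' \describe{
#'   \item{mlp}{three fully connected layers (256, 128, 64 units) with
#'     LeakyReLU activations (negative slope 0.2) and one output neuron. The
#'     final layer is zero-initialized, so the untrained discriminator emits
#'     logit 0 (probability one half) for any input.}
#'   \item{cnn1d}{two 1-D convolutions over the gene axis (kernel 7, stride
#'     2; 16 then 32 channels) with LeakyReLU, global average pooling, and an
#'     affine head to one logit.}
#' }
#' Conditioning mirrors the generator: gene-space-projected cell and drug
#' embeddings (the discriminator's own tables) are added element-wise to the
#' expression vector before the network proper.
#'
#' @param nGenes number of genes.
#' @param cellVocab,drugVocab character vocabularies.
#' @param architecture \code{"mlp"} or \code{"cnn1d"}.
#' @param embDim embedding dimensionality (128).
#' @param seed integer seed.
#' @return A discriminator object (list with meta fields and trainable
#'   \code{params}).
#' @export
initDiscriminator <- function(nGenes, cellVocab, drugVocab,
                              architecture = c("mlp", "cnn1d"),
                              embDim = 128L, seed = 1L) {
  architecture <- match.arg(architecture)
  ct <- initEmbeddingTable(cellVocab, embDim, nGenes, deriveSeed(seed, 505L))
  dt <- initEmbeddingTable(drugVocab, embDim, nGenes, deriveSeed(seed, 606L))
  params <- list(cellVec = ct$vectors, cellProj = ct$projection,
                 drugVec = dt$vectors, drugProj = dt$projection)
  d <- list(architecture = architecture, nGenes = nGenes, embDim = embDim,
            cellVocab = ct$vocab, drugVocab = dt$vocab, slope = 0.2)
  set.seed(deriveSeed(seed, 707L))
  if (architecture == "mlp") {
    params$l1 <- newLinear(nGenes, 256L)
    params$l2 <- newLinear(256L, 128L)
    params$l3 <- newLinear(128L, 64L)
    params$out <- newLinear(64L, 1L, zero = TRUE)
  } else {
    kernel <- 7L; stride <- 2L; c1 <- 16L; c2 <- 32L
    if (nGenes < kernel) stop("cnn1d needs n_genes >= kernel size")
    d$kernel <- kernel; d$stride <- stride; d$channels <- c(c1, c2)
    params$conv1 <- newLinear(kernel, c1, sd = sqrt(2 / kernel))
    params$conv2 <- newLinear(kernel * c1, c2, sd = sqrt(2 / (kernel * c1)))
    params$head <- newLinear(c2, 1L, zero = TRUE)
    d$len1 <- (nGenes - kernel) %/% stride + 1L
    d$len2 <- (d$len1 - kernel) %/% stride + 1L
    if (d$len2 < 1L) stop("input too short for two conv layers")
  }
  d$params <- params
  d
}

# im2col index matrix: rows = output positions, cols = kernel taps
convIndex <- function(len, kernel, stride) {
  nOut <- (len - kernel) %/% stride + 1L
  outer((seq_len(nOut) - 1L) * stride, seq_len(kernel), `+`)
}

# conv over rows of X (B x L), one input channel -> (B*nOut) x kernel patches
im2colSingle <- function(X, idx) {
  B <- nrow(X); nOut <- nrow(idx); kernel <- ncol(idx)
  patches <- matrix(0, B * nOut, kernel)
  for (k in seq_len(kernel)) {
    patches[, k] <- as.vector(t(X[, idx[, k], drop = FALSE]))
  }
  patches
}

# multi-channel im2col: X is (B*L) x C token-major rows (b-major, pos-minor)
im2colMulti <- function(X, B, L, idx, C) {
  nOut <- nrow(idx); kernel <- ncol(idx)
  patches <- matrix(0, B * nOut, kernel * C)
  for (k in seq_len(kernel)) {
    rowPick <- as.vector(vapply(seq_len(B), function(b)
      (b - 1L) * L + idx[, k], numeric(nOut)))
    patches[, ((k - 1L) * C + 1L):(k * C)] <- X[rowPick, , drop = FALSE]
  }
  patches
}

discIdx <- function(d, cellIds, drugIds) {
  ci <- match(cellIds, d$cellVocab)
  di <- match(drugIds, d$drugVocab)
  if (anyNA(ci))
    stop("unknown cell id(s): ",
         paste(unique(cellIds[is.na(ci)]), collapse = ", "))
  if (anyNA(di))
    stop("unknown drug id(s): ",
         paste(unique(drugIds[is.na(di)]), collapse = ", "))
  list(ci = ci, di = di)
}

mlpDiscFwd <- function(d, Y, ci, di) {
  p <- d$params; s <- d$slope
  cf <- condFwd(p, Y, ci, di)
  z1 <- linFwd(cf$x1, p$l1); a1 <- leakyRelu(z1, s)
  z2 <- linFwd(a1, p$l2); a2 <- leakyRelu(z2, s)
  z3 <- linFwd(a2, p$l3); a3 <- leakyRelu(z3, s)
  logit <- unname(drop(linFwd(a3, p$out)))
  list(logit = logit,
       cache = list(cf = cf, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                    z3 = z3, a3 = a3))
}

# dLogit: numeric vector (per batch row). Returns grads and dY (gradient wrt
# the expression input, needed for the generator update).
mlpDiscBwd <- function(d, fw, dLogit) {
  p <- d$params; c <- fw$cache; s <- d$slope
  dOut <- matrix(dLogit, ncol = 1L)
  bO <- linBwd(dOut, c$a3, p$out)
  dZ3 <- bO$dX * leakyReluGrad(c$z3, s)
  b3 <- linBwd(dZ3, c$a2, p$l3)
  dZ2 <- b3$dX * leakyReluGrad(c$z2, s)
  b2 <- linBwd(dZ2, c$a1, p$l2)
  dZ1 <- b2$dX * leakyReluGrad(c$z1, s)
  b1 <- linBwd(dZ1, c$cf$x1, p$l1)
  cb <- condBwd(p, c$cf, b1$dX, fw$ci, fw$di,
                nrow(p$cellVec), nrow(p$drugVec))
  list(grads = c(cb, list(l1 = list(W = b1$dW, b = b1$db),
                          l2 = list(W = b2$dW, b = b2$db),
                          l3 = list(W = b3$dW, b = b3$db),
                          out = list(W = bO$dW, b = bO$db))),
       dY = b1$dX)
}

cnnDiscFwd <- function(d, Y, ci, di) {
  p <- d$params; s <- d$slope
  B <- nrow(Y)
  cf <- condFwd(p, Y, ci, di)
  idx1 <- convIndex(d$nGenes, d$kernel, d$stride)
  pat1 <- im2colSingle(cf$x1, idx1)                      # (B*len1) x kernel
  z1 <- linFwd(pat1, p$conv1)                            # (B*len1) x c1
  a1 <- leakyRelu(z1, s)
  idx2 <- convIndex(d$len1, d$kernel, d$stride)
  pat2 <- im2colMulti(a1, B, d$len1, idx2, d$channels[1L]) # (B*len2) x (k*c1)
  z2 <- linFwd(pat2, p$conv2)                            # (B*len2) x c2
  a2 <- leakyRelu(z2, s)
  # global average pool over positions per sample
  grp <- rep(seq_len(B), each = d$len2)
  pooled <- rowsum(a2, grp) / d$len2                     # B x c2
  logit <- unname(drop(linFwd(pooled, p$head)))
  list(logit = logit,
       cache = list(cf = cf, pat1 = pat1, z1 = z1, a1 = a1,
                    pat2 = pat2, z2 = z2, pooled = pooled,
                    idx1 = idx1, idx2 = idx2, B = B))
}

cnnDiscBwd <- function(d, fw, dLogit) {
  p <- d$params; c <- fw$cache; s <- d$slope
  B <- c$B
  bH <- linBwd(matrix(dLogit, ncol = 1L), c$pooled, p$head)
  dA2 <- bH$dX[rep(seq_len(B), each = d$len2), , drop = FALSE] / d$len2
  dZ2 <- dA2 * leakyReluGrad(c$z2, s)
  b2 <- linBwd(dZ2, c$pat2, p$conv2)
  # scatter dPat2 back onto a1 rows
  dA1 <- matrix(0, nrow(c$a1), ncol(c$a1))
  C1 <- d$channels[1L]; nOut2 <- nrow(c$idx2)
  for (k in seq_len(d$kernel)) {
    rowPick <- as.vector(vapply(seq_len(B), function(b)
      (b - 1L) * d$len1 + c$idx2[, k], numeric(nOut2)))
    contrib <- b2$dX[, ((k - 1L) * C1 + 1L):(k * C1), drop = FALSE]
    agg <- rowsum(contrib, rowPick)
    dA1[as.integer(rownames(agg)), ] <-
      dA1[as.integer(rownames(agg)), , drop = FALSE] + agg
  }
  dZ1 <- dA1 * leakyReluGrad(c$z1, s)
  b1 <- linBwd(dZ1, c$pat1, p$conv1)
  # scatter dPat1 back onto the conditioned input
  dX1 <- matrix(0, B, d$nGenes)
  nOut1 <- nrow(c$idx1)
  for (k in seq_len(d$kernel)) {
    contrib <- t(matrix(b1$dX[, k], nrow = nOut1))       # B x nOut1
    cols <- c$idx1[, k]                                  # distinct within k
    dX1[, cols] <- dX1[, cols, drop = FALSE] + contrib
  }
  cb <- condBwd(p, c$cf, dX1, fw$ci, fw$di,
                nrow(p$cellVec), nrow(p$drugVec))
  list(grads = c(cb, list(conv1 = list(W = b1$dW, b = b1$db),
                          conv2 = list(W = b2$dW, b = b2$db),
                          head = list(W = bH$dW, b = bH$db))),
       dY = dX1)
}

discForward <- function(d, Y, cellIds, drugIds) {
  idx <- discIdx(d, cellIds, drugIds)
  fw <- switch(d$architecture,
               mlp = mlpDiscFwd(d, Y, idx$ci, idx$di),
               cnn1d = cnnDiscFwd(d, Y, idx$ci, idx$di))
  fw$ci <- idx$ci; fw$di <- idx$di
  fw
}

discBackward <- function(d, fw, dLogit) {
  switch(d$architecture,
         mlp = mlpDiscBwd(d, fw, dLogit),
         cnn1d = cnnDiscBwd(d, fw, dLogit))
}

#' MLP discriminator forward pass
#'
#' Scores one expression vector under a (cell, drug) condition; the returned
#' scalar is a logit, with \code{sigmoid(logit)} the probability the
#' discriminator assigns to "real".
#'
#' @param d a discriminator from \code{\link{initDiscriminator}} with
#'   \code{architecture = "mlp"}.
#' @param y numeric expression vector of length \code{nGenes}.
#' @param cellId,drugId entity ids in the discriminator's vocabularies.
#' @return scalar logit.
#' @export
mlpDiscriminatorForward <- function(d, y, cellId, drugId) {
  if (d$architecture != "mlp") stop("discriminator is not mlp")
  if (length(y) != d$nGenes) stop("input length must equal nGenes")
  discForward(d, matrix(y, 1L), cellId, drugId)$logit
}

#' 1D-CNN discriminator forward pass
#'
#' Convolution over the gene axis (kernel 7, stride 2, two layers of 16 and
#' 32 channels), global average pooling and an affine head; returns one logit
#' for any input length at least the kernel size.
#'
#' @inheritParams mlpDiscriminatorForward
#' @export
cnn1dDiscriminatorForward <- function(d, y, cellId, drugId) {
  if (d$architecture != "cnn1d") stop("discriminator is not cnn1d")
  if (length(y) != d$nGenes) stop("input length must equal nGenes")
  discForward(d, matrix(y, 1L), cellId, drugId)$logit
}
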