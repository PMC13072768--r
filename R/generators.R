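#' Initialize a conditional generator
#'
#' Builds the parameter set for one of the three generator architectures:
#' \describe{
#'   \item{residual}{input projection n_genes -> 256, FiLM modulation of the
#'     hidden features by a (cell, drug) modulation network, a residual block
#'     of two 256 -> 256 ReLU layers, and a zero-initialized output head
#'     n_genes wide whose result is added to the baseline (so the untrained
#'     generator is exactly the identity map).}
#'   \item{cae}{conditional autoencoder: encoder n_genes -> 256 -> 64,
#'     decoder 64 -> 256 -> n_genes, additive conditioning at the input, no
#'     residual skip.}
#'   \item{transformer}{input chunked into 64-gene tokens, a linear token
#'     projection, two self-attention blocks (4 heads, model dim 64) with
#'     skip connections and a ReLU feed-forward, then a linear un-chunking;
#'     additive conditioning at the input, no residual skip. Inputs whose
#'     length is not a token multiple are zero-padded and the padded
#'     positions dropped from the output.}
#' }
#' Cell and drug identities enter every architecture by element-wise addition
#' of gene-space-projected 128-d embeddings to the baseline profile; the
#' residual architecture additionally modulates its hidden layer with FiLM
#' parameters derived from the raw embeddings.
#'
#' @param nGenes number of genes.
#' @param cellVocab,drugVocab character vocabularies.
#' @param architecture \code{"residual"}, \code{"cae"} or
#'   \code{"transformer"}.
#' @param hidden hidden width of the residual path and cAE encoder (256).
#' @param embDim embedding dimensionality (128).
#' @param bottleneck cAE bottleneck width (64).
#' @param tokenSize,nHeads,nBlocks transformer geometry (64, 4, 2).
#' @param seed integer seed; initialization is deterministic given it.
#' @return A generator object (list with \code{architecture}, meta fields and
#'   the trainable \code{params}).
#' @export
initGenerator <- function(nGenes, cellVocab, drugVocab,
                          architecture = c("residual", "cae", "transformer"),
                          hidden = 256L, embDim = 128L, bottleneck = 64L,
                          tokenSize = 64L, nHeads = 4L, nBlocks = 2L,
                          seed = 1L) {
  architecture <- match.arg(architecture)
  ct <- initEmbeddingTable(cellVocab, embDim, nGenes, deriveSeed(seed, 101L))
  dt <- initEmbeddingTable(drugVocab, embDim, nGenes, deriveSeed(seed, 202L))
  params <- list(cellVec = ct$vectors, cellProj = ct$projection,
                 drugVec = dt$vectors, drugProj = dt$projection)
  g <- list(architecture = architecture, nGenes = nGenes, hidden = hidden,
            embDim = embDim, cellVocab = ct$vocab, drugVocab = dt$vocab)
  set.seed(deriveSeed(seed, 303L))
  if (architecture == "residual") {
    mod <- initModulationNetwork(embDim, hidden, 128L, deriveSeed(seed, 404L))
    params$mod <- list(l1 = mod$l1, l2 = mod$l2)
    params$inProj <- newLinear(nGenes, hidden)
    params$res1 <- newLinear(hidden, hidden)
    params$res2 <- newLinear(hidden, hidden)
    params$outHead <- newLinear(hidden, nGenes, zero = TRUE)
    g$modHidden <- 128L
  } else if (architecture == "cae") {
    params$enc1 <- newLinear(nGenes, hidden)
    params$enc2 <- newLinear(hidden, bottleneck)
    params$dec1 <- newLinear(bottleneck, hidden)
    params$dec2 <- newLinear(hidden, nGenes, sd = sqrt(1 / hidden))
    g$bottleneck <- bottleneck
  } else {
    if (nGenes < tokenSize)
      stop("transformer needs n_genes >= token size")
    dModel <- tokenSize
    if (dModel %% nHeads != 0L) stop("model dim must divide into heads")
    g$tokenSize <- tokenSize; g$dModel <- dModel
    g$nHeads <- nHeads; g$nBlocks <- nBlocks
    g$nTokens <- as.integer(ceiling(nGenes / tokenSize))
    params$tokenProj <- newLinear(tokenSize, dModel)
    params$blocks <- lapply(seq_len(nBlocks), function(i) {
      list(Wq = newLinear(dModel, dModel, sd = sqrt(1 / dModel)),
           Wk = newLinear(dModel, dModel, sd = sqrt(1 / dModel)),
           Wv = newLinear(dModel, dModel, sd = sqrt(1 / dModel)),
           Wo = newLinear(dModel, dModel, zero = TRUE),
           ff1 = newLinear(dModel, 4L * dModel),
           ff2 = newLinear(4L * dModel, dModel, zero = TRUE))
    })
    params$unchunk <- newLinear(dModel, tokenSize)
  }
  g$params <- params
  g
}

genIdx <- function(g, cellIds, drugIds) {
  ci <- match(cellIds, g$cellVocab)
  di <- match(drugIds, g$drugVocab)
  if (anyNA(ci))
    stop("unknown cell id(s): ",
         paste(unique(cellIds[is.na(ci)]), collapse = ", "))
  if (anyNA(di))
    stop("unknown drug id(s): ",
         paste(unique(drugIds[is.na(di)]), collapse = ", "))
  list(ci = ci, di = di)
}

# additive input conditioning shared by all generator architectures
condFwd <- function(p, X, ci, di) {
  CE <- p$cellVec[ci, , drop = FALSE]
  DE <- p$drugVec[di, , drop = FALSE]
  cp <- addBias(CE %*% p$cellProj$W, p$cellProj$b)
  dp <- addBias(DE %*% p$drugProj$W, p$drugProj$b)
  list(x1 = X + cp + dp, CE = CE, DE = DE)
}

# gradient of the additive conditioning path; dX1 is the gradient wrt x1.
# dCEextra/dDEextra let the FiLM path contribute to the embedding gradient.
condBwd <- function(p, cache, dX1, ci, di, nCell, nDrug,
                    dCEextra = NULL, dDEextra = NULL) {
  dWc <- crossprod(cache$CE, dX1)
  dWd <- crossprod(cache$DE, dX1)
  db <- colSums(dX1)
  dCE <- tcrossprod(dX1, p$cellProj$W)
  dDE <- tcrossprod(dX1, p$drugProj$W)
  if (!is.null(dCEextra)) dCE <- dCE + dCEextra
  if (!is.null(dDEextra)) dDE <- dDE + dDEextra
  scatter <- function(dE, idx, n) {
    out <- matrix(0, n, ncol(dE))
    agg <- rowsum(dE, idx)
    out[as.integer(rownames(agg)), ] <- agg
    out
  }
  list(cellVec = scatter(dCE, ci, nCell),
       cellProj = list(W = dWc, b = db),
       drugVec = scatter(dDE, di, nDrug),
       drugProj = list(W = dWd, b = db))
}

# ---- residual generator ----------------------------------------------------

resFwd <- function(g, X, ci, di) {
  p <- g$params
  cf <- condFwd(p, X, ci, di)
  h0 <- linFwd(cf$x1, p$inProj)
  net <- list(l1 = p$mod$l1, l2 = p$mod$l2, hidden = g$hidden)
  fp <- filmParamsBatch(net, cf$CE, cf$DE)
  hf <- fp$gamma * h0 + fp$beta
  z1 <- linFwd(hf, p$res1); a1 <- relu(z1)
  z2 <- linFwd(a1, p$res2); a2 <- relu(z2)
  hb <- hf + a2
  delta <- linFwd(hb, p$outHead)
  list(yhat = X + delta,
       cache = list(cf = cf, h0 = h0, fp = fp, hf = hf,
                    a1 = a1, a2 = a2, hb = hb))
}

resBwd <- function(g, fw, dY) {
  p <- g$params; c <- fw$cache
  bOut <- linBwd(dY, c$hb, p$outHead)
  dHb <- bOut$dX
  dA2 <- dHb * (c$a2 > 0)
  b2 <- linBwd(dA2, c$a1, p$res2)
  dA1 <- b2$dX * (c$a1 > 0)
  b1 <- linBwd(dA1, c$hf, p$res1)
  dHf <- dHb + b1$dX
  dGamma <- dHf * c$h0
  dBeta <- dHf
  dH0 <- dHf * c$fp$gamma
  net <- list(l1 = p$mod$l1, l2 = p$mod$l2, hidden = g$hidden)
  fb <- filmParamsBwd(net, c$fp$cache, dGamma, dBeta)
  bIn <- linBwd(dH0, c$cf$x1, p$inProj)
  cb <- condBwd(p, c$cf, bIn$dX, fw$ci, fw$di,
                nrow(p$cellVec), nrow(p$drugVec),
                dCEextra = fb$dCellEmb, dDEextra = fb$dDrugEmb)
  c(cb, list(mod = fb$grads,
             inProj = list(W = bIn$dW, b = bIn$db),
             res1 = list(W = b1$dW, b = b1$db),
             res2 = list(W = b2$dW, b = b2$db),
             outHead = list(W = bOut$dW, b = bOut$db)))
}

# ---- conditional autoencoder ----------------------------------------------

caeFwd <- function(g, X, ci, di, conditioned = TRUE) {
  p <- g$params
  if (conditioned) {
    cf <- condFwd(p, X, ci, di)
  } else {
    cf <- list(x1 = X, CE = NULL, DE = NULL)
  }
  z1 <- linFwd(cf$x1, p$enc1); e1 <- relu(z1)
  z2 <- linFwd(e1, p$enc2); e2 <- relu(z2)
  z3 <- linFwd(e2, p$dec1); d1 <- relu(z3)
  yhat <- linFwd(d1, p$dec2)
  list(yhat = yhat,
       cache = list(cf = cf, e1 = e1, e2 = e2, d1 = d1,
                    conditioned = conditioned))
}

caeBwd <- function(g, fw, dY) {
  p <- g$params; c <- fw$cache
  b4 <- linBwd(dY, c$d1, p$dec2)
  dD1 <- b4$dX * (c$d1 > 0)
  b3 <- linBwd(dD1, c$e2, p$dec1)
  dE2 <- b3$dX * (c$e2 > 0)
  b2 <- linBwd(dE2, c$e1, p$enc2)
  dE1 <- b2$dX * (c$e1 > 0)
  b1 <- linBwd(dE1, c$cf$x1, p$enc1)
  core <- list(enc1 = list(W = b1$dW, b = b1$db),
               enc2 = list(W = b2$dW, b = b2$db),
               dec1 = list(W = b3$dW, b = b3$db),
               dec2 = list(W = b4$dW, b = b4$db))
  if (!c$conditioned) return(core)
  cb <- condBwd(p, c$cf, b1$dX, fw$ci, fw$di,
                nrow(p$cellVec), nrow(p$drugVec))
  c(cb, core)
}

# ---- transformer -----------------------------------------------------------

# reshape B x (T*ts) into (B*T) x ts token rows (b-major, token-minor)
toTokens <- function(Xp, ts) t(matrix(t(Xp), nrow = ts))

fromTokens <- function(M, B, ts) {
  t(matrix(t(M), nrow = nrow(M) / B * ts))
}

transFwd <- function(g, X, ci, di) {
  p <- g$params
  B <- nrow(X); ts <- g$tokenSize; Tn <- g$nTokens
  dm <- g$dModel; nh <- g$nHeads; dh <- dm %/% nh
  cf <- condFwd(p, X, ci, di)
  pad <- Tn * ts - g$nGenes
  Xp <- if (pad > 0) cbind(cf$x1, matrix(0, B, pad)) else cf$x1
  M <- toTokens(Xp, ts)
  H <- linFwd(M, p$tokenProj)
  blocks <- vector("list", g$nBlocks)
  for (bl in seq_len(g$nBlocks)) {
    bp <- p$blocks[[bl]]
    Hin <- H
    Q <- linFwd(H, bp$Wq); K <- linFwd(H, bp$Wk); V <- linFwd(H, bp$Wv)
    O <- matrix(0, nrow(H), dm)
    A <- vector("list", B)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      Ab <- vector("list", nh)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dh)
        S <- S - apply(S, 1L, max)
        E <- exp(S)
        Ah <- E / rowSums(E)
        O[rows, cols] <- Ah %*% V[rows, cols, drop = FALSE]
        Ab[[h]] <- Ah
      }
      A[[b]] <- Ab
    }
    attnOut <- linFwd(O, bp$Wo)
    H1 <- Hin + attnOut
    F1 <- relu(linFwd(H1, bp$ff1))
    H <- H1 + linFwd(F1, bp$ff2)
    blocks[[bl]] <- list(Hin = Hin, Q = Q, K = K, V = V, O = O, A = A,
                         H1 = H1, F1 = F1)
  }
  U <- linFwd(H, p$unchunk)
  Yp <- fromTokens(U, B, ts)
  list(yhat = Yp[, seq_len(g$nGenes), drop = FALSE],
       cache = list(cf = cf, M = M, blocks = blocks, H = H, B = B,
                    pad = pad))
}

transBwd <- function(g, fw, dY) {
  p <- g$params; cc <- fw$cache
  B <- cc$B; ts <- g$tokenSize; Tn <- g$nTokens
  dm <- g$dModel; nh <- g$nHeads; dh <- dm %/% nh
  dYp <- if (cc$pad > 0) cbind(dY, matrix(0, B, cc$pad)) else dY
  dU <- toTokens(dYp, ts)
  bU <- linBwd(dU, cc$H, p$unchunk)
  dH <- bU$dX
  gBlocks <- vector("list", g$nBlocks)
  for (bl in rev(seq_len(g$nBlocks))) {
    bp <- p$blocks[[bl]]; c <- cc$blocks[[bl]]
    # FF with skip: H_out = H1 + ff2(relu(ff1(H1)))
    bF2 <- linBwd(dH, c$F1, bp$ff2)
    preF1 <- linFwd(c$H1, bp$ff1)
    dPre <- bF2$dX * (preF1 > 0)
    bF1 <- linBwd(dPre, c$H1, bp$ff1)
    dH1 <- dH + bF1$dX
    # attention with skip: H1 = Hin + Wo(O)
    bWo <- linBwd(dH1, c$O, bp$Wo)
    dO <- bWo$dX
    dQ <- matrix(0, nrow(dO), dm)
    dK <- matrix(0, nrow(dO), dm)
    dV <- matrix(0, nrow(dO), dm)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * Tn + 1L):(b * Tn)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        Ah <- c$A[[b]][[h]]
        dOb <- dO[rows, cols, drop = FALSE]
        dV[rows, cols] <- crossprod(Ah, dOb)
        dA <- tcrossprod(dOb, c$V[rows, cols, drop = FALSE])
        dS <- Ah * (dA - rowSums(dA * Ah))
        dQ[rows, cols] <- dS %*% c$K[rows, cols, drop = FALSE] / sqrt(dh)
        dK[rows, cols] <- crossprod(dS, c$Q[rows, cols, drop = FALSE]) /
          sqrt(dh)
      }
    }
    bQ <- linBwd(dQ, c$Hin, bp$Wq)
    bK <- linBwd(dK, c$Hin, bp$Wk)
    bV <- linBwd(dV, c$Hin, bp$Wv)
    dH <- dH1 + bQ$dX + bK$dX + bV$dX
    gBlocks[[bl]] <- list(Wq = list(W = bQ$dW, b = bQ$db),
                          Wk = list(W = bK$dW, b = bK$db),
                          Wv = list(W = bV$dW, b = bV$db),
                          Wo = list(W = bWo$dW, b = bWo$db),
                          ff1 = list(W = bF1$dW, b = bF1$db),
                          ff2 = list(W = bF2$dW, b = bF2$db))
  }
  bTok <- linBwd(dH, cc$M, p$tokenProj)
  dXp <- fromTokens(bTok$dX, B, ts)
  dX1 <- dXp[, seq_len(g$nGenes), drop = FALSE]
  cb <- condBwd(p, cc$cf, dX1, fw$ci, fw$di,
                nrow(p$cellVec), nrow(p$drugVec))
  c(cb, list(tokenProj = list(W = bTok$dW, b = bTok$db),
             blocks = gBlocks,
             unchunk = list(W = bU$dW, b = bU$db)))
}

# ---- shared dispatch -------------------------------------------------------

genForward <- function(g, X, cellIds, drugIds) {
  idx <- genIdx(g, cellIds, drugIds)
  fw <- switch(g$architecture,
               residual = resFwd(g, X, idx$ci, idx$di),
               cae = caeFwd(g, X, idx$ci, idx$di),
               transformer = transFwd(g, X, idx$ci, idx$di))
  fw$ci <- idx$ci; fw$di <- idx$di
  fw
}

genBackward <- function(g, fw, dY) {
  switch(g$architecture,
         residual = resBwd(g, fw, dY),
         cae = caeBwd(g, fw, dY),
         transformer = transBwd(g, fw, dY))
}

#' Residual generator forward pass
#'
#' Predicts the post-treatment profile for one baseline vector via the
#' residual formulation: yhat = x + Delta x, where Delta x is produced by the
#' conditioned, FiLM-modulated residual network. With a zero output head the
#' prediction is exactly the baseline.
#'
#' @param g a generator from \code{\link{initGenerator}} with
#'   \code{architecture = "residual"}.
#' @param x numeric baseline vector (z-scored), length \code{nGenes}.
#' @param cellId,drugId entity ids present in the generator's vocabularies.
#' @return numeric predicted post-treatment vector, same length as \code{x}.
#' @export
residualGeneratorForward <- function(g, x, cellId, drugId) {
  if (g$architecture != "residual") stop("generator is not residual")
  if (length(x) != g$nGenes) stop("input length must equal nGenes")
  drop(genForward(g, matrix(x, 1L), cellId, drugId)$yhat)
}

#' Variant generator forward pass (cAE or transformer)
#'
#' Same signature as \code{\link{residualGeneratorForward}}; the prediction is
#' direct (no residual skip).
#'
#' @inheritParams residualGeneratorForward
#' @export
variantGeneratorForward <- function(g, x, cellId, drugId) {
  if (!g$architecture %in% c("cae", "transformer"))
    stop("generator is not a cae/transformer variant")
  if (length(x) != g$nGenes) stop("input length must equal nGenes")
  drop(genForward(g, matrix(x, 1L), cellId, drugId)$yhat)
}
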