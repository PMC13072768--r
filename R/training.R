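#' Generator loss: MSE plus weighted adversarial term
#'
#' L_G = MSE(pred, target) + lambda * mean(-log D(pred)), with natural
#' logarithms. The discriminator probabilities must lie strictly inside
#' (0, 1); the training loop itself works on logits through a numerically
#' stable softplus form and never materializes probabilities.
#'
#' @param pred,target numeric vectors or matrices of equal shape.
#' @param dProbOnPred discriminator probability (or probabilities) assigned
#'   to the prediction, in (0, 1).
#' @param lambdaAdv non-negative adversarial weight.
#' @return scalar loss.
#' @export
generatorLoss <- function(pred, target, dProbOnPred, lambdaAdv) {
  if (length(pred) != length(target)) stop("pred/target length mismatch")
  if (lambdaAdv < 0) stop("lambdaAdv must be non-negative")
  if (any(dProbOnPred <= 0 | dProbOnPred >= 1))
    stop("discriminator probabilities must lie strictly in (0, 1)")
  mean((pred - target)^2) + lambdaAdv * mean(-log(dProbOnPred))
}

#' Discriminator loss: binary cross-entropy on real and generated profiles
#'
#' L_D = mean(-log D(y_real)) + mean(-log(1 - D(y_fake))), natural logs.
#' At uniform probabilities 0.5 this equals 2 log 2 exactly.
#'
#' @param dProbReal,dProbFake probabilities in (0, 1), one per batch element.
#' @return scalar loss.
#' @export
discriminatorLoss <- function(dProbReal, dProbFake) {
  if (any(dProbReal <= 0 | dProbReal >= 1) ||
      any(dProbFake <= 0 | dProbFake >= 1))
    stop("discriminator probabilities must lie strictly in (0, 1)")
  mean(-log(dProbReal)) + mean(-log(1 - dProbFake))
}

COMBINATIONS <- c("res+mlp", "res+cnn", "cae+mlp", "cae+cnn",
                  "trans+mlp", "trans+cnn")

# generator parameter groups subject to weight decay: the expression-path
# layers; conditioning parameters (embeddings, projections, modulation net)
# are exempt
GEN_DECAY_GROUPS <- c("inProj", "res1", "res2", "outHead",
                      "enc1", "enc2", "dec1", "dec2",
                      "tokenProj", "blocks", "unchunk")

# conditioning parameter groups (eligible for a learning-rate multiplier)
GEN_COND_GROUPS <- c("cellVec", "drugVec", "cellProj", "drugProj", "mod")

#' Build a generator-discriminator bundle
#'
#' Instantiates one of the six generator-discriminator combinations of the
#' model zoo: residual / cAE / transformer generators crossed with MLP /
#' 1D-CNN discriminators.
#'
#' @param nGenes number of genes.
#' @param cellVocab,drugVocab character vocabularies.
#' @param combination one of \code{"res+mlp"}, \code{"res+cnn"},
#'   \code{"cae+mlp"}, \code{"cae+cnn"}, \code{"trans+mlp"},
#'   \code{"trans+cnn"}.
#' @param seed integer seed.
#' @param ... passed to \code{\link{initGenerator}}.
#' @return list with \code{generator}, \code{discriminator},
#'   \code{combination}.
#' @export
newModelBundle <- function(nGenes, cellVocab, drugVocab,
                           combination = "res+mlp", seed = 1L, ...) {
  combination <- match.arg(combination, COMBINATIONS)
  parts <- strsplit(combination, "+", fixed = TRUE)[[1L]]
  genArch <- switch(parts[1L], res = "residual", cae = "cae",
                    trans = "transformer")
  discArch <- switch(parts[2L], mlp = "mlp", cnn = "cnn1d")
  structure(list(
    generator = initGenerator(nGenes, cellVocab, drugVocab, genArch,
                              seed = seed, ...),
    discriminator = initDiscriminator(nGenes, cellVocab, drugVocab, discArch,
                                      seed = deriveSeed(seed, 9L)),
    combination = combination), class = "ModelBundle")
}

#' Training configuration
#'
#' @param learningRate Adam learning rate (default 0.001).
#' @param lambdaAdv adversarial weight lambda (default 0.1; 0 gives pure
#'   regression).
#' @param epochs training epochs (default 200).
#' @param batchSize minibatch size (default 32).
#' @param seed integer seed controlling initialization-free randomness (data
#'   order); training is bit-reproducible given (data, bundle, cfg).
#' @param weightDecay decoupled (AdamW-style) weight decay applied to the
#'   generator's expression-path layers only (default 0.01); the embedding
#'   tables, their projections and the modulation network are exempt, since
#'   they carry the cell/drug identity signal that must be amplified, not
#'   shrunk, during training.
#' @param inputNoise sd of Gaussian jitter added to the baseline input of
#'   the generator during training steps only (default 0.6, z-score units).
#'   Fresh noise is drawn every step, so the learned shift cannot memorize
#'   individual training records and must rely on features that are stable
#'   across replicates: the cell-intrinsic baseline structure and the
#'   cell/drug embeddings. For the residual architecture the identity skip
#'   uses the clean baseline, so the jitter regularizes only the shift
#'   network. Evaluation always uses clean inputs.
#' @param condLrMult learning-rate multiplier for the conditioning
#'   parameters (embedding tables, projections, modulation network) relative
#'   to \code{learningRate} (default 3). The conditioning path starts at
#'   the 0.02 initialization scale and carries the only drug-identity
#'   signal; letting it adapt faster than the expression-path layers
#'   measurably improves held-out recovery of per-condition effects.
#' @param emaDecay exponential-moving-average decay for the generator
#'   weights (default 0, disabled; cosine annealing already provides the
#'   smoothing in practice). The EMA generator, not the raw
#'   final iterate, is returned for prediction: it averages away the
#'   parameter wobble induced by minibatching and the input jitter.
#' @param lrSchedule \code{"cosine"} (default) anneals the learning rate
#'   from \code{learningRate} to \code{learningRate / 20} over the epochs
#'   with a half-cosine, damping the gradient noise injected by the input
#'   jitter as training converges; \code{"constant"} disables annealing.
#' @param patience optional early-stop patience on validation MSE (epochs
#'   without improvement); \code{NULL} disables early stopping.
#' @return list of class \code{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 0.001, lambdaAdv = 0.1, epochs = 200L,
                        batchSize = 32L, seed = 1L, weightDecay = 0.01,
                        inputNoise = 0.6, condLrMult = 3, emaDecay = 0,
                        lrSchedule = c("cosine", "constant"),
                        patience = NULL) {
  lrSchedule <- match.arg(lrSchedule)
  if (emaDecay < 0 || emaDecay >= 1) stop("emaDecay must be in [0, 1)")
  if (learningRate <= 0) stop("learningRate must be positive")
  if (lambdaAdv < 0) stop("lambdaAdv must be non-negative")
  if (weightDecay < 0) stop("weightDecay must be non-negative")
  if (inputNoise < 0) stop("inputNoise must be non-negative")
  structure(list(learningRate = learningRate, lambdaAdv = lambdaAdv,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 seed = as.integer(seed), weightDecay = weightDecay,
                 inputNoise = inputNoise, condLrMult = condLrMult,
                 emaDecay = emaDecay,
                 lrSchedule = lrSchedule,
                 patience = patience,
                 optimizer = "adam"), class = "TrainConfig")
}

#' Alternating adversarial training
#'
#' Per minibatch: one discriminator step minimizing the binary cross-entropy
#' over real versus generated profiles, then one generator step minimizing
#' MSE plus lambda times the non-saturating adversarial term, both with Adam.
#' Generated profiles are treated as constants during the discriminator step;
#' the generator step backpropagates through the freshly updated
#' discriminator without touching its weights. Training aborts with a
#' diagnostic if any loss turns non-finite. With \code{lambdaAdv = 0} the
#' discriminator is skipped entirely and training is pure regression.
#'
#' @param dataset a \linkS4class{PerturbationDataset} (z-scored values).
#' @param bundle a \code{ModelBundle}.
#' @param cfg a \code{TrainConfig}.
#' @param valDataset optional held-out \linkS4class{PerturbationDataset} for
#'   per-epoch validation MSE monitoring (never trained on).
#' @return A \code{TrainedModel}: list with \code{generator},
#'   \code{discriminator}, \code{combination}, \code{config}, \code{history}
#'   (one row per epoch run: gLoss, dLoss, valMse), and slots for the
#'   normalization parameters used (filled by
#'   \code{\link{runCrossValidation}}).
#' @export
trainAdversarial <- function(dataset, bundle, cfg, valDataset = NULL) {
  stopifnot(is(dataset, "PerturbationDataset"))
  n <- nPairs(dataset)
  if (n < 1L) stop("empty dataset")
  g <- bundle$generator
  d <- bundle$discriminator
  lambda <- cfg$lambdaAdv
  useD <- lambda > 0
  X <- dataset@x; Y <- dataset@y
  cells <- dataset@cellIds; drugs <- dataset@drugIds
  gState <- adamInit(g$params)
  dState <- if (useD) adamInit(d$params)
  useEma <- !is.null(cfg$emaDecay) && cfg$emaDecay > 0
  ema <- if (useEma) rapply(g$params, function(x) x * 0, how = "replace")
  emaT <- 0L
  hist <- vector("list", cfg$epochs)
  set.seed(cfg$seed)
  bestVal <- Inf; since <- 0L
  epochsRun <- 0L
  for (ep in seq_len(cfg$epochs)) {
    lrNow <- if (identical(cfg$lrSchedule, "constant") || cfg$epochs <= 1L)
      cfg$learningRate
    else cfg$learningRate *
      (0.05 + 0.95 * (1 + cos(pi * (ep - 1) / (cfg$epochs - 1))) / 2)
    ord <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batchSize)
    gAcc <- 0; dAcc <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batchSize - 1L, n)]
      B <- length(idx)
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      cb <- cells[idx]; db <- drugs[idx]
      Xn <- Xb
      if (cfg$inputNoise > 0) {
        Xn <- Xb + matrix(rnorm(length(Xb), 0, cfg$inputNoise), nrow(Xb))
      }
      fwG <- genForward(g, Xn, cb, db)
      yhat <- fwG$yhat
      # the jitter regularizes the learned shift, not the identity path:
      # for the residual architecture the skip re-uses the clean baseline
      if (cfg$inputNoise > 0 && g$architecture == "residual")
        yhat <- yhat - Xn + Xb
      if (useD) {
        # real and generated profiles scored as one concatenated batch
        fwD <- discForward(d, rbind(Yb, yhat), c(cb, cb), c(db, db))
        lr_ <- fwD$logit[seq_len(B)]
        lf_ <- fwD$logit[B + seq_len(B)]
        dLoss <- mean(softplus(-lr_)) + mean(softplus(lf_))
        if (!is.finite(dLoss))
          stop(sprintf("non-finite discriminator loss (epoch %d)", ep))
        dLogit <- c(sigmoid(lr_) - 1, sigmoid(lf_)) / B
        gd <- discBackward(d, fwD, dLogit)$grads
        upd <- adamStep(d$params, gd, dState, lrNow)
        d$params <- upd$params; dState <- upd$state
        dAcc <- dAcc + dLoss
      }
      mse <- mean((yhat - Yb)^2)
      dYhat <- 2 * (yhat - Yb) / (B * ncol(Yb))
      gLoss <- mse
      if (useD) {
        fwF2 <- discForward(d, yhat, cb, db)
        gLoss <- gLoss + lambda * mean(softplus(-fwF2$logit))
        dAdv <- lambda * (sigmoid(fwF2$logit) - 1) / B
        dYhat <- dYhat + discBackward(d, fwF2, dAdv)$dY
      }
      if (!is.finite(gLoss))
        stop(sprintf("non-finite generator loss (epoch %d)", ep))
      gGrads <- genBackward(g, fwG, dYhat)
      upd <- adamStep(g$params, gGrads, gState, lrNow,
                      weightDecay = cfg$weightDecay,
                      decayGroups = GEN_DECAY_GROUPS,
                      lrMult = cfg$condLrMult %||% 1,
                      lrMultGroups = GEN_COND_GROUPS)
      g$params <- upd$params; gState <- upd$state
      if (useEma) {
        dEma <- cfg$emaDecay
        ema <- gradAdd(rapply(ema, function(x) dEma * x, how = "replace"),
                       rapply(g$params, function(x) (1 - dEma) * x,
                              how = "replace"))
        emaT <- emaT + 1L
      }
      gAcc <- gAcc + gLoss
    }
    valMse <- NA_real_
    if (!is.null(valDataset) && nPairs(valDataset) > 0L) {
      gv <- g
      if (useEma && emaT > 0L)
        gv$params <- rapply(ema, function(x) x / (1 - cfg$emaDecay^emaT),
                            how = "replace")
      pv <- genForward(gv, valDataset@x, valDataset@cellIds,
                       valDataset@drugIds)$yhat
      valMse <- mean((pv - valDataset@y)^2)
    }
    hist[[ep]] <- data.frame(epoch = ep, gLoss = gAcc / length(starts),
                             dLoss = if (useD) dAcc / length(starts)
                                     else NA_real_,
                             valMse = valMse)
    epochsRun <- ep
    if (!is.null(cfg$patience) && is.finite(valMse)) {
      if (valMse < bestVal - 1e-12) { bestVal <- valMse; since <- 0L }
      else { since <- since + 1L; if (since >= cfg$patience) break }
    }
  }
  history <- if (epochsRun > 0L) do.call(rbind, hist[seq_len(epochsRun)])
             else data.frame(epoch = integer(), gLoss = numeric(),
                             dLoss = numeric(), valMse = numeric())
  if (useEma && emaT > 0L)
    g$params <- rapply(ema, function(x) x / (1 - cfg$emaDecay^emaT),
                       how = "replace")
  structure(list(generator = g, discriminator = d,
                 combination = bundle$combination, config = cfg,
                 history = history, normX = NULL, normY = NULL),
            class = "TrainedModel")
}

#' Predict post-treatment profiles with a (trained) generator
#'
#' @param model a \code{TrainedModel} or \code{ModelBundle}.
#' @param X numeric matrix of baseline profiles, records in rows (z-scored,
#'   same gene order as training), or a single numeric vector.
#' @param cellIds,drugIds ids per record.
#' @return matrix of predicted profiles, records in rows.
#' @export
predictPerturbation <- function(model, X, cellIds, drugIds) {
  g <- model$generator
  if (is.null(dim(X))) X <- matrix(X, 1L)
  genForward(g, X, cellIds, drugIds)$yhat
}

#' Seeded k-fold split with a carved validation fraction
#'
#' Shuffles the records with the given seed and assigns folds round-robin, so
#' fold sizes differ by at most one. Within each fold's training split, 10
#' percent of the records (at least one) are carved out as a validation set
#' for epoch monitoring.
#'
#' @param dataset a \linkS4class{PerturbationDataset} (or a record count).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param valFraction fraction of each training split held out for
#'   validation (default 0.1).
#' @return list of class \code{FoldAssignment}: \code{k},
#'   \code{assignment} (fold index per record), \code{val} (list of
#'   validation index vectors per fold), \code{valFraction}.
#' @export
kfoldSplit <- function(dataset, k = 5L, seed = 1L, valFraction = 0.1) {
  n <- if (is(dataset, "PerturbationDataset")) nPairs(dataset)
       else as.integer(dataset)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of records")
  set.seed(seed)
  ord <- sample.int(n)
  assignment <- integer(n)
  assignment[ord] <- rep_len(seq_len(k), n)
  val <- lapply(seq_len(k), function(f) {
    train <- which(assignment != f)
    set.seed(deriveSeed(seed, 1000L + f))
    sort(sample(train, max(1L, round(valFraction * length(train)))))
  })
  structure(list(k = k, assignment = assignment, val = val,
                 valFraction = valFraction), class = "FoldAssignment")
}

#' Leakage-free k-fold cross-validation of a model combination
#'
#' For every fold, per-gene standardization constants are fitted on the
#' training records only, then applied unchanged to the validation and test
#' records. With \code{normalization = "pooled"} (default) one set of
#' constants is fitted on the union of the training baselines and training
#' post-treatment profiles, so baseline and target live in the same z-space
#' and the residual formulation predicts a pure per-condition shift;
#' \code{"independent"} fits separate constants for the input and output
#' matrices. The model is trained on the standardized training records and
#' evaluated on the standardized test records with regression (MSE, pooled
#' R2) and zero-threshold direction-classification metrics (ACC, macro
#' precision/recall/F1).
#'
#' @param baseline,treated \linkS4class{ExpressionMatrix} objects in
#'   \code{raw_tpm} (log2-transformed on the fly) or \code{log2} space.
#' @param pairing pairing data.frame (see \code{\link{assembleDataset}}).
#' @param combination model-zoo tag (see \code{\link{newModelBundle}}).
#' @param cfg a \code{TrainConfig}.
#' @param k folds (default 5).
#' @param normalization \code{"pooled"} (one constant set per fold) or
#'   \code{"independent"} (separate input/output constants).
#' @param keepModels keep per-fold \code{TrainedModel}s (with their
#'   normalization constants) in the result.
#' @return list with \code{perFold} (one row per fold: mse, r2, acc, prec,
#'   rec, f1), \code{summary} (mean and sd per metric), \code{pooled}
#'   (metrics over all test predictions pooled across folds), \code{folds},
#'   and optionally \code{models}.
#' @export
runCrossValidation <- function(baseline, treated, pairing,
                               combination = "res+mlp", cfg = trainConfig(),
                               k = 5L,
                               normalization = c("pooled", "independent"),
                               keepModels = FALSE) {
  normalization <- match.arg(normalization)
  if (exprSpace(baseline) == "raw_tpm") baseline <- log2Transform(baseline)
  if (exprSpace(treated) == "raw_tpm") treated <- log2Transform(treated)
  ds <- assembleDataset(baseline, treated, pairing)
  folds <- kfoldSplit(ds, k, cfg$seed)
  genes <- geneIds(ds)
  perFold <- vector("list", k)
  models <- vector("list", k)
  poolPred <- vector("list", k); poolTrue <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- which(folds$assignment == f)
    valIdx <- folds$val[[f]]
    # the carved validation records are only excluded from training when
    # they actually drive a decision (early stopping); otherwise they are
    # monitoring-only and remain part of the training split
    trainIdx <- if (is.null(cfg$patience))
      which(folds$assignment != f)
    else setdiff(which(folds$assignment != f), valIdx)
    asEM <- function(M, idx) ExpressionMatrix(
      t(M[idx, , drop = FALSE]), "log2")
    if (normalization == "pooled") {
      pool <- rbind(ds@x[trainIdx, , drop = FALSE],
                    ds@y[trainIdx, , drop = FALSE])
      rownames(pool) <- sprintf("s%05d", seq_len(nrow(pool)))
      normX <- fitGeneNormalization(ExpressionMatrix(t(pool), "log2"))
      normY <- normX
    } else {
      normX <- fitGeneNormalization(asEM(ds@x, trainIdx))
      normY <- fitGeneNormalization(asEM(ds@y, trainIdx))
    }
    zx <- t((t(ds@x) - normX@mean[genes]) / normX@sd[genes])
    zy <- t((t(ds@y) - normY@mean[genes]) / normY@sd[genes])
    dsz <- new("PerturbationDataset", geneIds = genes, x = zx, y = zy,
               cellIds = ds@cellIds, drugIds = ds@drugIds,
               cellVocab = ds@cellVocab, drugVocab = ds@drugVocab,
               space = "zscored")
    bundle <- newModelBundle(length(genes), ds@cellVocab, ds@drugVocab,
                             combination, seed = deriveSeed(cfg$seed, f))
    fit <- trainAdversarial(dsz[trainIdx], bundle, cfg,
                            valDataset = dsz[valIdx])
    fit$normX <- normX; fit$normY <- normY
    pred <- predictPerturbation(fit, dsz@x[testIdx, , drop = FALSE],
                                ds@cellIds[testIdx], ds@drugIds[testIdx])
    truth <- zy[testIdx, , drop = FALSE]
    rm <- regressionMetrics(pred, truth)
    dm <- directionMetrics(pred, truth)
    perFold[[f]] <- data.frame(fold = f, mse = rm$mse, r2 = rm$r2,
                               acc = dm$acc, prec = dm$prec, rec = dm$rec,
                               f1 = dm$f1)
    poolPred[[f]] <- pred; poolTrue[[f]] <- truth
    if (keepModels) models[[f]] <- fit
  }
  perFold <- do.call(rbind, perFold)
  mets <- c("mse", "r2", "acc", "prec", "rec", "f1")
  summ <- data.frame(metric = mets,
                     mean = vapply(mets, function(m) mean(perFold[[m]]),
                                   numeric(1)),
                     sd = vapply(mets, function(m) stats::sd(perFold[[m]]),
                                 numeric(1)), row.names = NULL)
  pp <- do.call(rbind, poolPred); pt <- do.call(rbind, poolTrue)
  pooled <- c(regressionMetrics(pp, pt), directionMetrics(pp, pt))
  out <- list(perFold = perFold, summary = summ, pooled = pooled,
              folds = folds, dataset = ds)
  if (keepModels) out$models <- models
  out
}
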