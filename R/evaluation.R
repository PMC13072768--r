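#' Regression metrics: MSE and pooled R-squared
#'
#' MSE is the mean squared entrywise error; R2 is 1 - SSres/SStot pooled over
#' every gene-by-sample entry (a single scalar per model, not a per-gene
#' average).
#'
#' @param pred,true numeric vectors or matrices of equal shape with at least
#'   two entries.
#' @return list with \code{mse} and \code{r2}.
#' @export
regressionMetrics <- function(pred, true) {
  if (length(pred) != length(true)) stop("shape mismatch")
  if (length(true) < 2L) stop("need at least two entries")
  sstot <- sum((true - mean(true))^2)
  if (sstot == 0) stop("R2 undefined for a constant true matrix")
  list(mse = mean((pred - true)^2),
       r2 = 1 - sum((pred - true)^2) / sstot)
}

#' Zero-threshold direction classification metrics
#'
#' Standardized values are binarized at zero (v > 0 is up-regulation, v <= 0
#' is down-regulation); a prediction is correct when the direction matches
#' the true post-treatment direction. Precision, recall and F1 are
#' macro-averaged over the two classes; a class absent from the truth
#' contributes its defined components only.
#'
#' @param pred,true z-scored numeric vectors or matrices of equal shape.
#' @return list with \code{acc}, \code{prec}, \code{rec}, \code{f1}.
#' @export
directionMetrics <- function(pred, true) {
  if (length(pred) != length(true)) stop("shape mismatch")
  pu <- pred > 0; tu <- true > 0
  acc <- mean(pu == tu)
  perClass <- function(p, t) {
    tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
          else 2 * prec * rec / (prec + rec)
    c(prec = prec, rec = rec, f1 = f1)
  }
  up <- perClass(pu, tu); down <- perClass(!pu, !tu)
  m <- rbind(up, down)
  list(acc = acc,
       prec = mean(m[, "prec"], na.rm = TRUE),
       rec = mean(m[, "rec"], na.rm = TRUE),
       f1 = mean(m[, "f1"], na.rm = TRUE))
}

#' Gene-wise Pearson correlation between predicted and observed expression
#'
#' For every gene, pairs the predicted with the observed value across all
#' samples and computes Pearson's r. Genes constant in either matrix are
#' returned as NA and flagged as undefined rather than silently dropped.
#'
#' @param pred,true genes x samples matrices with at least three samples.
#' @return named numeric vector of per-gene correlations (NA where
#'   undefined), with attribute \code{undefined} listing the flagged genes.
#' @export
genewisePearson <- function(pred, true) {
  if (!all(dim(pred) == dim(true))) stop("shape mismatch")
  if (ncol(pred) < 3L) stop("need at least three samples per gene")
  n <- ncol(pred)
  cp <- pred - rowMeans(pred); ct <- true - rowMeans(true)
  sp <- sqrt(rowSums(cp^2)); st <- sqrt(rowSums(ct^2))
  r <- rowSums(cp * ct) / (sp * st)
  r[sp == 0 | st == 0] <- NA_real_
  if (!is.null(rownames(pred))) names(r) <- rownames(pred)
  undef <- if (!is.null(rownames(pred))) rownames(pred)[is.na(r)]
           else which(is.na(r))
  attr(r, "undefined") <- undef
  r
}

#' Profile similarity: cosine, Pearson, Spearman
#'
#' @param pred,true numeric vectors of equal length at least 3. Spearman uses
#'   average ranks for ties.
#' @return list with \code{cosine}, \code{pearson}, \code{spearman}.
#' @export
profileSimilarity <- function(pred, true) {
  if (length(pred) != length(true)) stop("length mismatch")
  if (length(pred) < 3L) stop("need length >= 3")
  np <- sqrt(sum(pred^2)); nt <- sqrt(sum(true^2))
  if (np == 0 || nt == 0) stop("cosine undefined for a zero-norm vector")
  list(cosine = sum(pred * true) / (np * nt),
       pearson = stats::cor(pred, true),
       spearman = stats::cor(pred, true, method = "spearman"))
}

#' RMSE and MAE restricted to differentially expressed genes
#'
#' DEGs are called from the \emph{true} post-treatment profile against the
#' baseline: genes whose absolute z-space shift exceeds the threshold. RMSE
#' and MAE of the prediction against the true post-treatment profile are then
#' computed on that gene subset only. An empty DEG set is reported with a
#' warning flag rather than an error.
#'
#' @param pred,truePost,baseline numeric vectors on matched gene orders
#'   (z space).
#' @param threshold absolute-shift DEG threshold (default 1.0).
#' @return list with \code{rmse}, \code{mae}, \code{degs} (indices or names)
#'   and \code{empty} flag.
#' @export
degSubsetError <- function(pred, truePost, baseline, threshold = 1.0) {
  if (length(pred) != length(truePost) ||
      length(baseline) != length(truePost)) stop("length mismatch")
  deg <- which(abs(truePost - baseline) > threshold)
  if (!length(deg)) {
    warning("no genes pass the DEG threshold")
    return(list(rmse = NA_real_, mae = NA_real_, degs = integer(), empty = TRUE))
  }
  err <- pred[deg] - truePost[deg]
  nm <- if (!is.null(names(truePost))) names(truePost)[deg] else deg
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)), degs = nm,
       empty = FALSE)
}

#' Match a patient profile to its most similar cell line
#'
#' Computes Pearson correlation between the patient baseline and every cell
#' line baseline over the shared genes and returns the argmax; exact ties go
#' to the lexicographically smallest cell id.
#'
#' @param patientBaseline named numeric vector (log2 space).
#' @param cellBaselines genes x cells matrix with cell ids as column names.
#' @return list with \code{cell_id} and \code{similarity}.
#' @export
matchPatientToCellLine <- function(patientBaseline, cellBaselines) {
  shared <- intersect(names(patientBaseline), rownames(cellBaselines))
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  p <- patientBaseline[shared]
  r <- apply(cellBaselines[shared, , drop = FALSE], 2L,
             function(cc) stats::cor(p, cc))
  ord <- order(-r, colnames(cellBaselines))
  list(cell_id = colnames(cellBaselines)[ord[1L]], similarity = r[[ord[1L]]])
}

#' Nearest-neighbour perturbation transfer baseline
#'
#' Adds the matched cell line's drug-induced expression shift, in linear
#' (TPM) space, to the patient's linear-space baseline. Genes whose
#' prediction falls below zero are biologically implausible and are excluded
#' from the evaluated set (and listed).
#'
#' @param patientBaselineLinear named numeric vector, linear space.
#' @param matchedDeltaLinear numeric vector of linear-space shifts, same gene
#'   order.
#' @return list with \code{prediction} (full vector), \code{excluded} (gene
#'   names or indices with negative predictions) and \code{evaluated}
#'   (logical keep mask).
#' @export
nnPerturbationBaseline <- function(patientBaselineLinear, matchedDeltaLinear) {
  if (length(patientBaselineLinear) != length(matchedDeltaLinear))
    stop("length mismatch")
  pred <- patientBaselineLinear + matchedDeltaLinear
  neg <- pred < 0
  nm <- names(patientBaselineLinear)
  list(prediction = pred,
       excluded = if (!is.null(nm)) nm[neg] else which(neg),
       evaluated = !neg)
}

#' Per-gene, per-drug linear regression baseline
#'
#' Fits, for every gene within every drug stratum, the univariate least
#' squares line y_g = a x_g + b from training records, and evaluates the
#' predictions on test records. Strata with constant x get slope 0 and
#' intercept mean(y).
#'
#' @param trainDs,testDs \linkS4class{PerturbationDataset}s sharing gene
#'   order and drug vocabulary (z-scored values).
#' @return list with the metric report (\code{mse}, \code{r2}, \code{acc},
#'   \code{prec}, \code{rec}, \code{f1}) and \code{pred}.
#' @export
linearBaseline <- function(trainDs, testDs) {
  stopifnot(identical(trainDs@geneIds, testDs@geneIds))
  pred <- matrix(NA_real_, nPairs(testDs), length(testDs@geneIds))
  for (drug in unique(testDs@drugIds)) {
    tr <- which(trainDs@drugIds == drug)
    te <- which(testDs@drugIds == drug)
    if (!length(te)) next
    if (length(tr) < 2L)
      stop("need at least 2 training records per drug stratum")
    Xtr <- trainDs@x[tr, , drop = FALSE]; Ytr <- trainDs@y[tr, , drop = FALSE]
    mx <- colMeans(Xtr); my <- colMeans(Ytr)
    vx <- colMeans(Xtr^2) - mx^2
    cxy <- colMeans(Xtr * Ytr) - mx * my
    a <- ifelse(vx > 0, cxy / vx, 0)
    b <- my - a * mx
    Xte <- testDs@x[te, , drop = FALSE]
    pred[te, ] <- sweep(Xte, 2L, a, `*`) + rep(b, each = length(te))
  }
  truth <- testDs@y
  c(regressionMetrics(pred, truth), directionMetrics(pred, truth),
    list(pred = pred))
}

#' Autoencoder baseline
#'
#' The cAE architecture trained to reconstruct post-treatment profiles from
#' baseline inputs with MSE only: no adversarial term, no conditioning, no
#' residual skip.
#'
#' @param trainDs,testDs \linkS4class{PerturbationDataset}s (z-scored).
#' @param cfg a \code{TrainConfig} (its \code{lambdaAdv} is ignored; the loss
#'   is pure MSE).
#' @return list with the metric report, \code{pred} and the fitted
#'   \code{generator}.
#' @export
autoencoderBaseline <- function(trainDs, testDs, cfg = trainConfig()) {
  g <- initGenerator(length(trainDs@geneIds), trainDs@cellVocab,
                     trainDs@drugVocab, "cae", seed = cfg$seed)
  X <- trainDs@x; Y <- trainDs@y
  n <- nrow(X)
  core <- c("enc1", "enc2", "dec1", "dec2")
  state <- adamInit(g$params[core])
  set.seed(cfg$seed)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = cfg$batchSize)) {
      idx <- ord[s:min(s + cfg$batchSize - 1L, n)]
      B <- length(idx)
      fw <- caeFwd(g, X[idx, , drop = FALSE], NULL, NULL, conditioned = FALSE)
      dY <- 2 * (fw$yhat - Y[idx, , drop = FALSE]) / (B * ncol(Y))
      grads <- caeBwd(g, fw, dY)
      # only core layers receive gradients without conditioning
      upd <- adamStep(g$params[names(grads)], grads, state, cfg$learningRate)
      g$params[names(grads)] <- upd$params; state <- upd$state
    }
  }
  pred <- caeFwd(g, testDs@x, NULL, NULL, conditioned = FALSE)$yhat
  truth <- testDs@y
  c(regressionMetrics(pred, truth), directionMetrics(pred, truth),
    list(pred = pred, generator = g))
}

#' Permutation test of prediction error
#'
#' Shuffles the target profiles across records (gene axis fixed), recomputes
#' the prediction error for each permutation, and reports the add-one
#' p-value p = (1 + #permuted errors <= observed) / (1 + nPerm). A model
#' that captures the baseline-to-target pairing attains small p; a model
#' whose predictions are unrelated to the targets attains a uniform p.
#'
#' @param model a \code{TrainedModel} or \code{ModelBundle}.
#' @param dataset a \linkS4class{PerturbationDataset} with at least two
#'   records (z-scored).
#' @param nPerm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list with \code{observed}, \code{permuted} (numeric vector of
#'   length nPerm) and \code{p}.
#' @export
permutationTest <- function(model, dataset, nPerm = 99L, seed = 1L) {
  if (nPerm < 1L) stop("nPerm must be at least 1")
  n <- nPairs(dataset)
  if (n < 2L) stop("need at least two records to permute")
  pred <- predictPerturbation(model, dataset@x, dataset@cellIds,
                              dataset@drugIds)
  observed <- mean((pred - dataset@y)^2)
  set.seed(seed)
  permuted <- vapply(seq_len(nPerm), function(i) {
    perm <- sample.int(n)
    mean((pred - dataset@y[perm, , drop = FALSE])^2)
  }, numeric(1))
  list(observed = observed, permuted = permuted,
       p = (1 + sum(permuted <= observed)) / (1 + nPerm))
}
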