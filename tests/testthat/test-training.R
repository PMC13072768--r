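# small synthetic dataset builders shared by the training tests
tinyDataset <- function(nGenes = 50L, nCells = 4L, nDrugs = 2L, nReps = 3L,
                        noiseSd = 0, seed = 11L) {
  cfg <- simConfig(nGenes = nGenes, nCells = nCells, nDrugs = nDrugs,
                   nReps = nReps, k = 2L, noiseSd = noiseSd,
                   baselineNoiseSd = 0.1, seed = seed)
  cohort <- generateCohort(cfg)
  ds <- assembleDataset(cohort@baseline, cohort@treated, cohort@pairing)
  pool <- rbind(ds@x, ds@y)
  rownames(pool) <- sprintf("s%04d", seq_len(nrow(pool)))
  np <- fitGeneNormalization(ExpressionMatrix(t(pool), "log2"))
  zx <- t((t(ds@x) - np@mean) / np@sd)
  zy <- t((t(ds@y) - np@mean) / np@sd)
  new("PerturbationDataset", geneIds = geneIds(ds), x = zx, y = zy,
      cellIds = ds@cellIds, drugIds = ds@drugIds,
      cellVocab = ds@cellVocab, drugVocab = ds@drugVocab, space = "zscored")
}

test_that("generator loss closed forms", {
  expect_equal(generatorLoss(c(1, 2), c(1, 2), 1 - 1e-12, 0.1), 0,
               tolerance = 1e-10)
  set.seed(3)
  p <- rnorm(10); t <- rnorm(10)
  expect_identical(generatorLoss(p, t, 0.3, 0), mean((p - t)^2))
  # diff (1, -1), d_prob 0.5, lambda 1 -> 1 + ln 2
  expect_equal(generatorLoss(c(1, 0), c(0, 1), 0.5, 1), 1 + log(2),
               tolerance = 1e-12)
  expect_error(generatorLoss(p, t, 1.0, 0.1), "strictly in")
  expect_error(generatorLoss(p, t, 0, 0.1), "strictly in")
})

test_that("discriminator loss closed forms and batch averaging", {
  expect_equal(discriminatorLoss(1 - 1e-13, 1e-13), 0, tolerance = 1e-10)
  expect_equal(discriminatorLoss(0.5, 0.5), 2 * log(2), tolerance = 1e-12)
  got <- discriminatorLoss(c(0.9, 0.8), c(0.1, 0.3))
  hand <- mean(c(-log(0.9), -log(0.8))) + mean(c(-log(0.9), -log(0.7)))
  expect_equal(got, hand, tolerance = 1e-12)
  expect_error(discriminatorLoss(1, 0.5), "strictly in")
})

test_that("kfoldSplit partitions records into balanced, seeded folds", {
  ds <- tinyDataset(nGenes = 20L, nReps = 2L)     # 16 records
  f <- kfoldSplit(ds, k = 5L, seed = 3L)
  expect_length(f$assignment, 16L)
  sizes <- tabulate(f$assignment, 5L)
  expect_true(max(sizes) - min(sizes) <= 1L)
  expect_setequal(unlist(lapply(1:5, function(k) which(f$assignment == k))),
                  1:16)
  expect_identical(f, kfoldSplit(ds, k = 5L, seed = 3L))
  expect_false(identical(f$assignment, kfoldSplit(ds, 5L, 4L)$assignment))
  # validation indices live inside the training split
  for (k in 1:5)
    expect_true(all(f$assignment[f$val[[k]]] != k))
  expect_error(kfoldSplit(ds, k = 17L), "exceeds")
  # k = 5, n = 10: test folds of size 2
  expect_equal(tabulate(kfoldSplit(10L, 5L, 1L)$assignment, 5L),
               rep(2L, 5L))
})

test_that("zero-epoch training returns untouched parameters and empty history", {
  ds <- tinyDataset(nGenes = 20L)
  b <- newModelBundle(20L, ds@cellVocab, ds@drugVocab, "res+mlp",
                      seed = 2L, hidden = 8L, embDim = 4L)
  fit <- trainAdversarial(ds, b, trainConfig(epochs = 0L, seed = 1L))
  expect_equal(nrow(fit$history), 0L)
  expect_identical(fit$generator$params, b$generator$params)
  expect_identical(fit$discriminator$params, b$discriminator$params)
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- tinyDataset(nGenes = 30L)
  cfg <- trainConfig(epochs = 4L, batchSize = 8L, seed = 7L)
  b <- newModelBundle(30L, ds@cellVocab, ds@drugVocab, "res+mlp",
                      seed = 2L, hidden = 8L, embDim = 4L)
  f1 <- trainAdversarial(ds, b, cfg, valDataset = ds[1:4])
  f2 <- trainAdversarial(ds, b, cfg, valDataset = ds[1:4])
  expect_identical(f1$history, f2$history)
  expect_identical(f1$generator$params, f2$generator$params)
})

test_that("pure regression on a noiseless linear cohort converges", {
  # sigma = 0: validation MSE decreasing over the first 10 epochs, small end
  ds <- tinyDataset(nGenes = 50L, nCells = 4L, nDrugs = 2L, noiseSd = 0,
                    seed = 13L)
  val <- seq(1L, nPairs(ds), by = 6L)
  train <- setdiff(seq_len(nPairs(ds)), val)
  b <- newModelBundle(50L, ds@cellVocab, ds@drugVocab, "res+mlp", seed = 5L)
  cfg <- trainConfig(learningRate = 0.003, epochs = 150L, lambdaAdv = 0,
                     batchSize = 8L, inputNoise = 0.3, seed = 5L)
  fit <- trainAdversarial(ds[train], b, cfg, valDataset = ds[val])
  v <- fit$history$valMse
  # early validation error trends down (minibatch jitter makes strict
  # per-epoch monotonicity too brittle to assert); the fit ends near the
  # least-squares-achievable error of zero
  expect_lt(v[10], v[1])
  expect_lt(mean(v[11:20]), mean(v[1:10]))
  expect_lt(v[length(v)], 0.05)
})

test_that("at lambda 0 the generator gradient is the pure MSE gradient", {
  set.seed(17)
  G <- 20L
  g <- initGenerator(G, "c", "d", "residual", hidden = 4L, embDim = 3L,
                     seed = 2L)
  bump <- function(p) if (is.list(p)) lapply(p, bump)
          else p + rnorm(length(p), 0, 0.05)
  g$params <- bump(g$params)
  X <- matrix(rnorm(2 * G), 2L); Y <- matrix(rnorm(2 * G), 2L)
  fw <- perturbGAN:::genForward(g, X, c("c", "c"), c("d", "d"))
  ana <- perturbGAN:::genBackward(g, fw, 2 * (fw$yhat - Y) / length(Y))
  num <- perturbGAN:::numericGrad(function(params) {
    g2 <- g; g2$params <- params
    fw2 <- perturbGAN:::genForward(g2, X, c("c", "c"), c("d", "d"))
    generatorLoss(fw2$yhat, Y, 0.5, 0)        # lambda 0: loss IS the MSE
  }, g$params, eps = 1e-5)
  err <- max(abs(unlist(ana[names(g$params)]) - unlist(num)))
  expect_lt(err, 1e-6)
})

test_that("cross-validation is leakage-free and reports the full schema", {
  cfg <- simConfig(nGenes = 40L, nCells = 3L, nDrugs = 2L, nReps = 2L,
                   k = 2L, seed = 19L)
  cohort <- generateCohort(cfg)
  out <- runCrossValidation(cohort@baseline, cohort@treated, cohort@pairing,
                            "res+mlp",
                            trainConfig(epochs = 2L, batchSize = 6L,
                                        seed = 1L),
                            k = 3L, keepModels = TRUE)
  expect_identical(colnames(out$perFold),
                   c("fold", "mse", "r2", "acc", "prec", "rec", "f1"))
  expect_equal(nrow(out$perFold), 3L)
  expect_identical(out$summary$metric, c("mse", "r2", "acc", "prec",
                                         "rec", "f1"))
  # leakage probe: train-fold per-gene means are 0 under the fold's params,
  # test-fold means generally deviate
  ds <- out$dataset
  f <- out$folds
  for (k in 1:2) {
    m <- out$models[[k]]
    trainIdx <- which(f$assignment != k)   # no patience: carve trains too
    testIdx <- which(f$assignment == k)
    pool <- rbind(ds@x[trainIdx, ], ds@y[trainIdx, ])
    zTrain <- t((t(pool) - m$normX@mean) / m$normX@sd)
    expect_true(all(abs(colMeans(zTrain)) < 1e-9))
    zTest <- t((t(ds@x[testIdx, , drop = FALSE]) - m$normX@mean) /
               m$normX@sd)
    expect_gt(max(abs(colMeans(zTest))), 1e-3)
  }
  # normalization constants are a pure function of the training split
  reFit <- fitGeneNormalization(ExpressionMatrix({
    pool <- rbind(ds@x[which(f$assignment != 1L), ],
                  ds@y[which(f$assignment != 1L), ])
    rownames(pool) <- sprintf("s%04d", seq_len(nrow(pool)))
    t(pool)
  }, "log2"))
  expect_equal(reFit@mean, out$models[[1L]]$normX@mean)
})

test_that("model checkpoints round-trip with a JSON manifest", {
  ds <- tinyDataset(nGenes = 20L)
  b <- newModelBundle(20L, ds@cellVocab, ds@drugVocab, "res+mlp",
                      seed = 2L, hidden = 8L, embDim = 4L)
  fit <- trainAdversarial(ds, b, trainConfig(epochs = 1L, batchSize = 8L,
                                             seed = 1L))
  path <- withr::local_tempfile(fileext = ".rds")
  writeModelCheckpoint(fit, path)
  back <- readModelCheckpoint(path)
  expect_identical(back$generator$params, fit$generator$params)
  manifest <- jsonlite::read_json(sub("\\.rds$", ".json", path))
  expect_identical(manifest$combination, "res+mlp")
  expect_identical(manifest$n_genes, 20L)
  x <- ds@x[1, ]
  expect_identical(predictPerturbation(back, x, ds@cellIds[1], ds@drugIds[1]),
                   predictPerturbation(fit, x, ds@cellIds[1], ds@drugIds[1]))
})
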