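test_that("regression metrics: definitions and hand-computed case", {
  t <- c(1, 2, 3)
  expect_equal(regressionMetrics(t, t), list(mse = 0, r2 = 1))
  expect_equal(regressionMetrics(rep(mean(t), 3), t)$r2, 0)
  got <- regressionMetrics(c(1, 2, 5), t)
  expect_equal(got$mse, 4 / 3)
  expect_equal(got$r2, -1)
  expect_error(regressionMetrics(c(1, 2), c(5, 5)), "constant")
})

test_that("direction metrics: binarization rule and macro averaging", {
  # 0.5 up; -0.2 down; 0.0 down (zero is down-regulation)
  v <- c(0.5, -0.2, 0)
  expect_equal(directionMetrics(v, v)$acc, 1)
  expect_true((0 > 0) == FALSE)
  p <- c(1, 1, 1, 1, -1, -1, -1, -1, -1, 1)
  t <- c(1, 1, 1, -1, 1, -1, -1, -1, -1, -1)
  got <- directionMetrics(p, t)
  # counts: TPup 3, FPup 2, FNup 1, TPdown 4 (FPdown 1, FNdown 2)
  precUp <- 3 / 5; recUp <- 3 / 4
  precDn <- 4 / 5; recDn <- 4 / 6
  expect_equal(got$acc, 7 / 10)
  expect_equal(got$prec, mean(c(precUp, precDn)))
  expect_equal(got$rec, mean(c(recUp, recDn)))
  f1Up <- 2 * precUp * recUp / (precUp + recUp)
  f1Dn <- 2 * precDn * recDn / (precDn + recDn)
  expect_equal(got$f1, mean(c(f1Up, f1Dn)))
})

test_that("direction metrics equal the brute-force confusion oracle", {
  set.seed(41)
  for (i in 1:50) {
    p <- matrix(rnorm(40), 8)
    t <- matrix(rnorm(40), 8)
    expect_equal(directionMetrics(p, t), bruteDirectionMetrics(p, t),
                 tolerance = 1e-12)
  }
})

test_that("gene-wise Pearson handles exact cases and flags constants", {
  set.seed(43)
  t <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("g", 1:4), NULL))
  r <- genewisePearson(t, t)
  expect_equal(unname(r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unname(genewisePearson(-t, t)), rep(-1, 4),
               ignore_attr = TRUE)
  # 4-sample toy gene against the closed form
  pg <- c(1, 3, 2, 5); tg <- c(2, 2.5, 1, 6)
  hand <- sum((pg - mean(pg)) * (tg - mean(tg))) /
    sqrt(sum((pg - mean(pg))^2) * sum((tg - mean(tg))^2))
  got <- genewisePearson(rbind(g1 = pg, g2 = pg), rbind(g1 = tg, g2 = tg))
  expect_equal(got[["g1"]], hand, tolerance = 1e-9)
  tc <- t; tc[2, ] <- 7
  rc <- genewisePearson(t, tc)
  expect_true(is.na(rc[[2]]))
  expect_identical(attr(rc, "undefined"), "g2")
  expect_error(genewisePearson(t[, 1:2], t[, 1:2]), "three")
})

test_that("profile similarity: invariances and tie-aware Spearman", {
  set.seed(47)
  v <- abs(rnorm(8)) + 0.1
  s <- profileSimilarity(v, v)
  expect_equal(unlist(s), c(cosine = 1, pearson = 1, spearman = 1))
  s2 <- profileSimilarity(2 * v, v)
  expect_equal(unlist(s2), c(cosine = 1, pearson = 1, spearman = 1),
               tolerance = 1e-12)
  # tie handling against an explicit average-rank computation
  p <- c(1, 2, 2, 3, 5); t <- c(2, 1, 4, 4, 5)
  rankP <- rank(p); rankT <- rank(t)   # average ranks for ties
  expect_equal(profileSimilarity(p, t)$spearman, cor(rankP, rankT),
               tolerance = 1e-12)
  expect_error(profileSimilarity(rep(0, 5), t), "zero-norm")
})

test_that("DEG-subset errors follow the threshold rule", {
  base <- c(0, 0, 0, 0, 0)
  post <- c(2, 0.5, -1.5, 0.2, -0.1)
  pred <- c(1.5, 0.4, -1.0, 0.3, 0)
  names(base) <- names(post) <- names(pred) <- paste0("g", 1:5)
  out <- degSubsetError(pred, post, base, threshold = 1.0)
  expect_identical(out$degs, c("g1", "g3"))
  expect_equal(out$rmse, sqrt(mean(c(0.5, 0.5)^2)))
  expect_equal(out$mae, 0.5)
  expect_false(out$empty)
  expect_equal(degSubsetError(post, post, base)$rmse, 0)
  expect_warning(out2 <- degSubsetError(pred, post, base, threshold = Inf),
                 "no genes")
  expect_true(out2$empty)
})

test_that("patient matching maximizes Pearson with lexicographic ties", {
  genes <- paste0("g", 1:4)
  patient <- setNames(c(1, 2, 3, 4), genes)
  cells <- cbind(B = c(1.1, 2.2, 2.9, 4.2), A = c(4, 1, 2, 2))
  rownames(cells) <- genes
  got <- matchPatientToCellLine(patient, cells)
  expect_identical(got$cell_id, "B")
  expect_equal(got$similarity, cor(patient, cells[, "B"]))
  # exact copy gives similarity 1
  exact <- matchPatientToCellLine(setNames(cells[, "A"], genes), cells)
  expect_identical(exact$cell_id, "A")
  expect_equal(exact$similarity, 1)
  # exact tie -> lexicographically smallest id
  twin <- cbind(Z = c(1, 2, 3, 4), A = c(1, 2, 3, 4))
  rownames(twin) <- genes
  expect_identical(matchPatientToCellLine(patient, twin)$cell_id, "A")
})

test_that("nearest-neighbour baseline excludes negative linear predictions", {
  base <- setNames(c(5, 10, 2, 8, 1, 4), paste0("g", 1:6))
  delta <- c(-7, 3, -1, -9, 2, -4.5)
  out <- nnPerturbationBaseline(base, delta)
  expect_equal(unname(out$prediction), base + delta, ignore_attr = TRUE)
  expect_identical(out$excluded, c("g1", "g4", "g6"))
  expect_equal(sum(out$evaluated), 3L)
  # zero shift: prediction is the baseline, nothing excluded
  out0 <- nnPerturbationBaseline(base, rep(0, 6))
  expect_length(out0$excluded, 0L)
  # hand RMSE on the evaluated subset
  target <- base + delta + c(0, 0.5, 0, 0, -0.5, 0)
  keep <- out$evaluated
  rmse <- sqrt(mean((out$prediction[keep] - target[keep])^2))
  expect_equal(rmse, sqrt(mean(c(0.5, 0, -0.5)^2)))
})

test_that("linear baseline interpolates two points and fits y = x exactly", {
  mk <- function(x, y, drugs, cells = rep("cA", nrow(x))) {
    new("PerturbationDataset", geneIds = paste0("g", seq_len(ncol(x))),
        x = x, y = y, cellIds = cells, drugIds = drugs,
        cellVocab = unique(cells), drugVocab = unique(drugs),
        space = "zscored")
  }
  set.seed(53)
  X <- matrix(rnorm(20), 4, 5); Y <- X
  tr <- mk(X, Y, rep("d1", 4))
  te <- mk(matrix(rnorm(10), 2, 5), matrix(rnorm(10), 2, 5), rep("d1", 2))
  te@y <- te@x
  out <- linearBaseline(tr, te)
  expect_equal(out$mse, 0, tolerance = 1e-20)
  expect_equal(out$r2, 1)
  # two training points per gene: exact interpolation
  X2 <- matrix(c(0, 1, 0, 2), 2, 2); Y2 <- matrix(c(1, 3, 5, 1), 2, 2)
  tr2 <- mk(X2, Y2, rep("d1", 2))
  out2 <- linearBaseline(tr2, tr2)
  expect_equal(out2$mse, 0, tolerance = 1e-20)
  # constant x within a stratum: slope 0, intercept mean(y)
  X3 <- matrix(2, 3, 1); Y3 <- matrix(c(1, 2, 6), 3, 1)
  tr3 <- mk(X3, Y3, rep("d1", 3))
  pr <- linearBaseline(tr3, tr3)$pred
  expect_equal(as.vector(pr), rep(3, 3))
})

test_that("autoencoder baseline is deterministic and can overfit one pair", {
  set.seed(59)
  X <- matrix(rnorm(40), 1, 40); Y <- matrix(rnorm(40), 1, 40)
  ds <- new("PerturbationDataset", geneIds = paste0("g", 1:40),
            x = rbind(X, X), y = rbind(Y, Y),
            cellIds = c("cA", "cA"), drugIds = c("d1", "d1"),
            cellVocab = "cA", drugVocab = "d1", space = "zscored")
  cfg <- trainConfig(epochs = 400L, batchSize = 2L, seed = 3L,
                     learningRate = 0.005)
  out <- autoencoderBaseline(ds, ds, cfg)
  expect_lt(out$mse, 0.05)
  out2 <- autoencoderBaseline(ds, ds, cfg)
  expect_identical(out$pred, out2$pred)
})

test_that("permutation test attains its minimum p for a perfect model on y = x", {
  set.seed(61)
  X <- matrix(rnorm(200), 10, 20)
  ds <- new("PerturbationDataset", geneIds = paste0("g", 1:20),
            x = X, y = X, cellIds = rep("cA", 10), drugIds = rep("d1", 10),
            cellVocab = "cA", drugVocab = "d1", space = "zscored")
  b <- newModelBundle(20L, "cA", "d1", "res+mlp", seed = 1L, hidden = 4L,
                      embDim = 2L)   # untrained residual = identity
  out <- permutationTest(b, ds, nPerm = 49L, seed = 9L)
  expect_equal(out$observed, 0)
  expect_true(all(out$permuted >= out$observed))
  expect_equal(out$p, 1 / 50)
  expect_error(permutationTest(b, ds[1], nPerm = 9L), "two records")
  expect_error(permutationTest(b, ds, nPerm = 0L), "at least 1")
})

test_that("similarity metrics are invariant to positive rescaling (property)", {
  set.seed(67)
  for (i in 1:25) {
    a <- rnorm(12); b <- rnorm(12)
    s <- profileSimilarity(a, b)
    s2 <- profileSimilarity(a * runif(1, 0.1, 10), b)
    expect_equal(unlist(s), unlist(s2), tolerance = 1e-10)
  }
})
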