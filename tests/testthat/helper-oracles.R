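# Independent brute-force oracles used to cross-check the implementation.
# Written deliberately in the most literal style possible, step by step, so
# they share no code path with the package internals.

# ssGSEA running-sum oracle: walk the ranked gene list position by position,
# maintaining both ECDFs explicitly, and add up the differences.
bruteSsgsea <- function(profile, members, alpha = 0.25) {
  genes <- names(profile)
  ord <- order(-profile, genes)
  ranked <- genes[ord]
  N <- length(ranked)
  inSet <- ranked %in% members
  weights <- rep(0, N)
  for (i in seq_len(N)) {
    if (inSet[i]) weights[i] <- (N - i + 1)^alpha
  }
  totalIn <- sum(weights)
  totalOut <- sum(!inSet)
  score <- 0
  pin <- 0; pout <- 0
  for (i in seq_len(N)) {
    if (inSet[i]) pin <- pin + weights[i] / totalIn
    else pout <- pout + 1 / totalOut
    score <- score + (pin - pout)
  }
  score
}

# direction-classification oracle: build the 2x2 confusion matrix by
# explicit counting, then macro-average the per-class metrics.
bruteDirectionMetrics <- function(pred, true) {
  p <- as.vector(pred) > 0
  t <- as.vector(true) > 0
  acc <- sum(p == t) / length(p)
  classStats <- function(positive) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(p)) {
      pi <- if (positive) p[i] else !p[i]
      ti <- if (positive) t[i] else !t[i]
      if (pi && ti) tp <- tp + 1
      if (pi && !ti) fp <- fp + 1
      if (!pi && ti) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA
    c(prec, rec, f1)
  }
  up <- classStats(TRUE); down <- classStats(FALSE)
  list(acc = acc,
       prec = mean(c(up[1], down[1]), na.rm = TRUE),
       rec = mean(c(up[2], down[2]), na.rm = TRUE),
       f1 = mean(c(up[3], down[3]), na.rm = TRUE))
}

# tiny named expression matrix builder
tinyExprMatrix <- function(values, genes = NULL, samples = NULL,
                           space = "log2") {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  ExpressionMatrix(values, space)
}
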