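#' Single-sample GSEA enrichment score
#'
#' Barbie-style weighted running-sum score for one expression profile and one
#' gene set. Genes are ranked by descending expression (ties broken by
#' ascending gene id); member genes are weighted by their rank magnitude
#' raised to \code{alpha}, non-members by the uniform ECDF. The score is the
#' sum of the per-position differences between the weighted in-set ECDF and
#' the out-of-set ECDF (sum of running-sum increments, not the maximum
#' deviation). Because the weights depend on ranks only, the score is
#' invariant under any strictly increasing transform of the profile.
#'
#' @param profile named numeric expression vector (any monotone scale).
#' @param members character vector of gene-set member ids; must hit at least
#'   one gene of the profile and leave at least one non-member.
#' @param alpha weight exponent (default 0.25).
#' @return scalar enrichment score.
#' @export
ssgseaScore <- function(profile, members, alpha = 0.25) {
  genes <- names(profile)
  if (is.null(genes)) stop("profile must be a named vector")
  inSet <- genes %in% members
  m <- sum(inSet)
  if (m == 0L) stop("gene set hits no genes in the profile")
  if (m == length(genes)) stop("gene set covers every gene in the profile")
  ord <- order(-profile, genes)
  inOrd <- inSet[ord]
  N <- length(genes)
  rankMag <- (N:1)^alpha
  win <- rankMag * inOrd
  pIn <- cumsum(win) / sum(win)
  pOut <- cumsum(!inOrd) / (N - m)
  sum(pIn - pOut)
}

#' Score every sample against a collection of state gene sets
#'
#' @param profiles an \linkS4class{ExpressionMatrix} (any monotone value
#'   space; scores are rank-based within sample).
#' @param sets named list of member character vectors (typically the six
#'   post-treatment state signatures).
#' @param alpha weight exponent passed to \code{\link{ssgseaScore}}.
#' @return samples x states numeric matrix of raw enrichment scores.
#' @export
scoreStates <- function(profiles, sets, alpha = 0.25) {
  stopifnot(is(profiles, "ExpressionMatrix"))
  v <- exprValues(profiles)
  out <- matrix(NA_real_, ncol(v), length(sets),
                dimnames = list(colnames(v), names(sets)))
  for (j in seq_along(sets)) {
    for (i in seq_len(ncol(v))) {
      out[i, j] <- ssgseaScore(stats::setNames(v[, i], rownames(v)),
                               sets[[j]], alpha)
    }
  }
  out
}

#' Z-score raw state scores across samples
#'
#' Standardizes each state (column) across the scored cohort with the
#' population standard deviation. Degenerate (constant) states become zero
#' columns and are flagged via the \code{degenerate} attribute. The cohort
#' passed in one call IS the z-scoring population: resistance calls depend
#' on its composition, which is the caller's responsibility.
#'
#' @param raw samples x states numeric matrix with at least two samples.
#' @return z-scored matrix with attribute \code{degenerate} (state names).
#' @export
zscoreStateScores <- function(raw) {
  if (nrow(raw) < 2L) stop("need at least two samples to z-score")
  mu <- colMeans(raw)
  s <- sqrt(colMeans(sweep(raw, 2L, mu)^2))
  degen <- colnames(raw)[s == 0]
  s[s == 0] <- 1
  z <- sweep(sweep(raw, 2L, mu), 2L, s, `/`)
  attr(z, "degenerate") <- degen
  z
}

#' Effective/ineffective scores and the resistance index
#'
#' The effective score is the mean z-score over the effective-category
#' states, the ineffective score the mean over the ineffective-category
#' states, and the resistance index their difference RI = ineffective -
#' effective. Swapping the two categories negates RI exactly.
#'
#' @param z numeric vector of per-state z-scores for one sample, named by
#'   state.
#' @param categories named character vector mapping each state to
#'   \code{"effective"} or \code{"ineffective"}; both categories must be
#'   non-empty.
#' @return list with \code{effective_score}, \code{ineffective_score},
#'   \code{ri}.
#' @export
resistanceIndex <- function(z, categories) {
  categories <- categories[names(z)]
  eff <- names(z)[categories == "effective"]
  ineff <- names(z)[categories == "ineffective"]
  if (!length(eff) || !length(ineff))
    stop("both categories must contain at least one state")
  es <- mean(z[eff]); is <- mean(z[ineff])
  list(effective_score = es, ineffective_score = is, ri = is - es)
}

#' Classify a response from its resistance index
#'
#' RI greater than zero is called ineffective; RI equal to or less than zero
#' is called effective (zero sits on the effective side).
#'
#' @param ri finite numeric resistance index (vectorized).
#' @return character vector of \code{"effective"}/\code{"ineffective"}.
#' @export
classifyResponse <- function(ri) {
  if (any(!is.finite(ri))) stop("ri must be finite")
  ifelse(ri > 0, "ineffective", "effective")
}

#' Drug-sensitivity label from logGI50
#'
#' A drug is effective for a cell line when its logGI50 is strictly less
#' than the threshold (default -8); a value at or above the threshold is
#' ineffective.
#'
#' @param logGi50 finite numeric (vectorized).
#' @param threshold sensitivity cutoff (default -8).
#' @return character vector of labels.
#' @export
gi50Label <- function(logGi50, threshold = -8) {
  if (any(!is.finite(logGi50))) stop("logGI50 must be finite")
  ifelse(logGi50 < threshold, "effective", "ineffective")
}

#' Agreement between RI-based calls and logGI50 labels
#'
#' @param calls,labels character vectors of \code{"effective"}/
#'   \code{"ineffective"}, matched by position or by shared names.
#' @return list with \code{agreement} (fraction equal) and \code{table}
#'   (2x2 contingency of call x label).
#' @export
concordanceWithGi50 <- function(calls, labels) {
  if (!is.null(names(calls)) && !is.null(names(labels))) {
    shared <- intersect(names(calls), names(labels))
    if (!length(shared)) stop("no overlapping samples")
    calls <- calls[shared]; labels <- labels[shared]
  }
  if (length(calls) != length(labels)) stop("length mismatch")
  lev <- c("effective", "ineffective")
  list(agreement = mean(calls == labels),
       table = table(call = factor(calls, lev), label = factor(labels, lev)))
}

#' Full state-scoring pipeline
#'
#' ssGSEA-scores every sample against the six state signatures, z-scores per
#' state across the cohort, computes effective/ineffective scores and the
#' resistance index per sample, and calls each sample effective (RI <= 0) or
#' ineffective (RI > 0).
#'
#' @param profiles an \linkS4class{ExpressionMatrix} of post-treatment
#'   profiles.
#' @param sets named list of state gene sets.
#' @param categories named character vector of per-state categories.
#' @param alpha ssGSEA weight exponent (default 0.25).
#' @return A \linkS4class{StateScoreTable}.
#' @export
scoreStateTable <- function(profiles, sets, categories, alpha = 0.25) {
  missing <- setdiff(names(sets), names(categories))
  if (length(missing))
    stop("no category for set(s): ", paste(missing, collapse = ", "))
  raw <- scoreStates(profiles, sets, alpha)
  z <- zscoreStateScores(raw)
  per <- lapply(seq_len(nrow(z)), function(i)
    resistanceIndex(z[i, ], categories))
  es <- vapply(per, `[[`, numeric(1), "effective_score")
  is <- vapply(per, `[[`, numeric(1), "ineffective_score")
  ri <- vapply(per, `[[`, numeric(1), "ri")
  new("StateScoreTable", sampleIds = rownames(raw),
      stateNames = colnames(raw),
      categories = categories[colnames(raw)],
      raw = raw, z = matrix(z, nrow(z), ncol(z), dimnames = dimnames(raw)),
      effectiveScore = es, ineffectiveScore = is, ri = ri,
      call = classifyResponse(ri))
}

#' Write a StateScoreTable as TSV
#'
#' @param tab a \linkS4class{StateScoreTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStateScoreTable <- function(tab, path) {
  write.table(asStateFrame(tab), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
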