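#' Simulation configuration for a synthetic perturbation cohort
#'
#' The generator emulates the statistical structure the framework assumes:
#' per-cell baseline profiles in log2(TPM+1)-like space, an additive low-rank
#' drug effect modulated per cell line, replicate samples, Gaussian noise,
#' and (optionally) a nonlinear baseline-dependent effect component.
#'
#' @param nGenes,nCells,nDrugs,nReps cohort dimensions (defaults 2000, 8, 5,
#'   4 replicates per cell x drug).
#' @param k latent rank of the drug-effect model (default 3).
#' @param effectScale standard deviation of the per-gene drug-effect loadings
#'   (log2 units, default 0.7).
#' @param cellSpread spread of the per-cell sensitivity factor s_c = 1 +
#'   cellSpread * N(0,1) (default 0.3).
#' @param noiseSd post-treatment measurement noise sd (log2 units, 0.3).
#' @param baselineNoiseSd per-sample baseline noise sd (0.3).
#' @param cellFactorSd sd of per-cell, per-gene baseline offsets (0.5).
#' @param geneMeanRange uniform range of per-gene baseline means in log2
#'   units (default c(3, 12), i.e. roughly 7 to 4000 TPM).
#' @param nonlinear scale of a quadratic baseline-dependent effect component
#'   (default 0, purely additive).
#' @param seed integer master seed; every substream (baselines, effects,
#'   noise, planting, patients) derives from it.
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(nGenes = 2000L, nCells = 8L, nDrugs = 5L, nReps = 4L,
                      k = 3L, effectScale = 0.7, cellSpread = 0.3,
                      noiseSd = 0.3, baselineNoiseSd = 0.3,
                      cellFactorSd = 0.5, geneMeanRange = c(3, 12),
                      nonlinear = 0, seed = 1L) {
  stopifnot(nGenes >= 1L, nCells >= 1L, nDrugs >= 1L, nReps >= 1L,
            noiseSd >= 0, k >= 1L)
  if (k > min(nGenes, nDrugs)) stop("k must be <= min(nGenes, nDrugs)")
  structure(list(nGenes = as.integer(nGenes), nCells = as.integer(nCells),
                 nDrugs = as.integer(nDrugs), nReps = as.integer(nReps),
                 k = as.integer(k), effectScale = effectScale,
                 cellSpread = cellSpread, noiseSd = noiseSd,
                 baselineNoiseSd = baselineNoiseSd,
                 cellFactorSd = cellFactorSd, geneMeanRange = geneMeanRange,
                 nonlinear = nonlinear, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Generate a synthetic perturbation cohort with known ground truth
#'
#' Baseline profiles are per-gene means plus per-cell offsets plus
#' per-sample noise; post-treatment profiles add the true shift
#' Delta(c,d,g) = s_c * (u_d V)_g (a rank-k drug effect modulated by a
#' per-cell sensitivity), an optional centred quadratic term in the
#' baseline, and Gaussian noise. Everything any evaluation estimates — the
#' shift array, labels, source identities — is stored exactly. Deterministic
#' given the seed.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return A \linkS4class{SyntheticCohort}.
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  G <- cfg$nGenes; C <- cfg$nCells; D <- cfg$nDrugs; R <- cfg$nReps
  genes <- sprintf("g%05d", seq_len(G))
  cells <- sprintf("cell%02d", seq_len(C))
  drugs <- sprintf("drug%02d", seq_len(D))
  set.seed(deriveSeed(cfg$seed, 1L))
  geneMeans <- stats::setNames(runif(G, cfg$geneMeanRange[1L],
                                     cfg$geneMeanRange[2L]), genes)
  set.seed(deriveSeed(cfg$seed, 2L))
  cellProfiles <- matrix(rnorm(C * G, 0, cfg$cellFactorSd), C, G,
                         dimnames = list(cells, genes))
  cellProfiles <- sweep(cellProfiles, 2L, geneMeans, `+`)
  set.seed(deriveSeed(cfg$seed, 3L))
  # unit-norm drug loadings pin the realized effect variance at
  # effectScale^2 * E[s^2] for every seed (the closed-form signal variance
  # the noise-floor oracles rely on); with free Gaussian loadings the
  # handful of u_d draws would make Var(delta) swing by a factor of two
  # between realizations
  U <- matrix(rnorm(D * cfg$k), D, cfg$k)
  U <- U / sqrt(rowSums(U^2))
  set.seed(deriveSeed(cfg$seed, 4L))
  V <- matrix(rnorm(cfg$k * G, 0, cfg$effectScale), cfg$k, G)
  set.seed(deriveSeed(cfg$seed, 5L))
  sCell <- 1 + cfg$cellSpread * rnorm(C)
  UV <- U %*% V                                   # drugs x genes
  delta <- array(0, dim = c(C, D, G), dimnames = list(cells, drugs, genes))
  for (ci in seq_len(C)) delta[ci, , ] <- sCell[ci] * UV
  n <- C * D * R
  grid <- expand.grid(rep = seq_len(R), drug = seq_len(D), cell = seq_len(C))
  set.seed(deriveSeed(cfg$seed, 6L))
  baseNoise <- matrix(rnorm(n * G, 0, cfg$baselineNoiseSd), n, G)
  set.seed(deriveSeed(cfg$seed, 7L))
  postNoise <- matrix(rnorm(n * G, 0, cfg$noiseSd), n, G)
  base <- cellProfiles[grid$cell, , drop = FALSE] + baseNoise
  shift <- matrix(0, n, G)
  for (i in seq_len(n)) shift[i, ] <- delta[grid$cell[i], grid$drug[i], ]
  if (cfg$nonlinear != 0) {
    vtot <- cfg$cellFactorSd^2 + cfg$baselineNoiseSd^2
    centred <- sweep(base, 2L, geneMeans)
    shift <- shift + cfg$nonlinear * (centred^2 - vtot)
  }
  post <- base + shift + postNoise
  baseIds <- sprintf("%s_%s_r%d_base", cells[grid$cell], drugs[grid$drug],
                     grid$rep)
  postIds <- sub("_base$", "_post", baseIds)
  pairing <- data.frame(baseline_sample = baseIds, treated_sample = postIds,
                        cell_id = cells[grid$cell], drug_id = drugs[grid$drug],
                        stringsAsFactors = FALSE)
  bm <- t(base); colnames(bm) <- baseIds; rownames(bm) <- genes
  tm <- t(post); colnames(tm) <- postIds; rownames(tm) <- genes
  new("SyntheticCohort",
      baseline = ExpressionMatrix(bm, "log2"),
      treated = ExpressionMatrix(tm, "log2"),
      pairing = pairing, delta = delta, geneMeans = geneMeans,
      cellProfiles = cellProfiles, geneSets = list(),
      setCategories = character(), responseLabels = data.frame(),
      config = unclass(cfg))
}

STATE_NAMES <- c("programmed_cell_death", "senescence", "cell_cycle_arrest",
                 "drug_resistance", "immune_escape", "malignant_progression")

#' Default category mapping for the six post-treatment states
#'
#' Programmed cell death, senescence and cell-cycle arrest are treated as
#' effective (stress-associated growth suppression); drug resistance, immune
#' escape and malignant progression as ineffective.
#'
#' @return named character vector of categories.
#' @export
defaultStateCategories <- function() {
  stats::setNames(rep(c("effective", "ineffective"), each = 3L), STATE_NAMES)
}

#' Plant six state gene programs and effectiveness labels into a cohort
#'
#' Picks six disjoint member sets from the gene universe, assigns each
#' (cell, drug) combination a ground-truth effective/ineffective label, and
#' up-shifts the members of the matching category's sets in that
#' combination's post-treatment profiles: effective responders activate the
#' effective programs, ineffective responders the ineffective ones. A
#' synthetic logGI50 per combination is drawn so that label == (logGI50 <
#' -8) holds exactly.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param effect added expression shift on planted members, log2 units
#'   (default 3 * noiseSd of the cohort).
#' @param setSize members per set (default 20; must not exceed nGenes / 6).
#' @return the cohort with modified treated profiles, planted
#'   \code{geneSets}, \code{setCategories} and \code{responseLabels}.
#' @export
plantStatePrograms <- function(cohort, effect = NULL, setSize = 20L) {
  stopifnot(is(cohort, "SyntheticCohort"))
  cfg <- cohort@config
  if (is.null(effect)) effect <- 3 * cfg$noiseSd
  if (setSize > cfg$nGenes / 6) stop("set size exceeds nGenes/6")
  genes <- names(cohort@geneMeans)
  set.seed(deriveSeed(cfg$seed, 8L))
  picked <- sample(genes, 6L * setSize)
  sets <- split(picked, rep(STATE_NAMES, each = setSize))[STATE_NAMES]
  categories <- defaultStateCategories()
  combos <- unique(cohort@pairing[, c("cell_id", "drug_id")])
  set.seed(deriveSeed(cfg$seed, 9L))
  labels <- sample(c("effective", "ineffective"), nrow(combos),
                   replace = TRUE)
  set.seed(deriveSeed(cfg$seed, 10L))
  gi50 <- ifelse(labels == "effective", runif(nrow(combos), -10, -8.2),
                 runif(nrow(combos), -7.8, -5))
  tm <- exprValues(cohort@treated)
  effGenes <- unlist(sets[names(categories)[categories == "effective"]],
                     use.names = FALSE)
  ineffGenes <- unlist(sets[names(categories)[categories == "ineffective"]],
                       use.names = FALSE)
  key <- paste(cohort@pairing$cell_id, cohort@pairing$drug_id)
  comboKey <- paste(combos$cell_id, combos$drug_id)
  for (i in seq_len(nrow(combos))) {
    cols <- cohort@pairing$treated_sample[key == comboKey[i]]
    target <- if (labels[i] == "effective") effGenes else ineffGenes
    tm[target, cols] <- tm[target, cols] + effect
  }
  cohort@treated <- ExpressionMatrix(tm, "log2")
  cohort@geneSets <- sets
  cohort@setCategories <- categories
  cohort@responseLabels <- data.frame(cell_id = combos$cell_id,
                                      drug_id = combos$drug_id,
                                      label = labels, log_gi50 = gi50,
                                      stringsAsFactors = FALSE)
  cohort
}

#' Generate patient-like bulk profiles from a cohort
#'
#' Each patient baseline is a convex mixture of one source cell line's
#' noiseless baseline and the cohort mean profile, plus noise; the patient's
#' post-treatment profile applies the source cell line's true shift for a
#' randomly chosen drug (plus the cohort's measurement noise). Source cell
#' line and drug are recorded as ground truth for matching tests.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param nPatients number of patients (default 20).
#' @param mix weight of the source cell line in the baseline mixture, in
#'   [0, 1] (default 0.8).
#' @param noise per-gene baseline noise sd (default 0.1).
#' @return list with \code{baseline} and \code{post}
#'   (\linkS4class{ExpressionMatrix}, genes x patients), \code{source}
#'   (cell id per patient) and \code{drug} (drug id per patient).
#' @export
generatePatientProfiles <- function(cohort, nPatients = 20L, mix = 0.8,
                                    noise = 0.1) {
  stopifnot(is(cohort, "SyntheticCohort"))
  if (mix < 0 || mix > 1) stop("mix must lie in [0, 1]")
  cfg <- cohort@config
  G <- cfg$nGenes
  cells <- rownames(cohort@cellProfiles)
  drugs <- dimnames(cohort@delta)[[2L]]
  meanProfile <- colMeans(cohort@cellProfiles)
  set.seed(deriveSeed(cfg$seed, 11L))
  src <- sample(cells, nPatients, replace = TRUE)
  drug <- sample(drugs, nPatients, replace = TRUE)
  baseNoise <- matrix(rnorm(nPatients * G, 0, noise), nPatients, G)
  postNoise <- matrix(rnorm(nPatients * G, 0, cfg$noiseSd), nPatients, G)
  base <- mix * cohort@cellProfiles[src, , drop = FALSE] +
    (1 - mix) * rep(meanProfile, each = nPatients) + baseNoise
  shift <- t(vapply(seq_len(nPatients), function(i)
    cohort@delta[src[i], drug[i], ], numeric(G)))
  post <- base + shift + postNoise
  ids <- sprintf("patient%02d", seq_len(nPatients))
  bm <- t(base); colnames(bm) <- ids
  pm <- t(post); colnames(pm) <- ids
  rownames(bm) <- rownames(pm) <- names(cohort@geneMeans)
  list(baseline = ExpressionMatrix(bm, "log2"),
       post = ExpressionMatrix(pm, "log2"),
       source = stats::setNames(src, ids), drug = stats::setNames(drug, ids))
}

#' Linear-space (TPM) view of a log2 matrix
#'
#' Inverts log2(TPM + 1); values are floored at zero in log2 space first, so
#' the linear view is non-negative everywhere.
#'
#' @param m an \linkS4class{ExpressionMatrix} in \code{log2} space.
#' @return An \linkS4class{ExpressionMatrix} in \code{raw_tpm} space.
#' @export
linearView <- function(m) {
  stopifnot(is(m, "ExpressionMatrix"))
  if (exprSpace(m) != "log2") stop("linearView expects log2 input")
  ExpressionMatrix(2^pmax(exprValues(m), 0) - 1, "raw_tpm")
}

#' Write a cohort to the plain-text input files the tool consumes
#'
#' Writes baseline.tsv, treated.tsv, pairing.tsv, states.gmt,
#' categories.yaml and gi50.tsv (the latter three only if state programs
#' were planted) into a directory.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCohortFiles <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionTable(cohort@baseline, file.path(dir, "baseline.tsv"))
  writeExpressionTable(cohort@treated, file.path(dir, "treated.tsv"))
  write.table(cohort@pairing, file.path(dir, "pairing.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(cohort@geneSets)) {
    writeGmt(cohort@geneSets, file.path(dir, "states.gmt"))
    yaml::write_yaml(as.list(cohort@setCategories),
                     file.path(dir, "categories.yaml"))
    write.table(cohort@responseLabels[, c("cell_id", "drug_id", "log_gi50")],
                file.path(dir, "gi50.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(dir)
}
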