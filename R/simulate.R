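#' Configuration for the planted-truth simulator
#'
#' Defaults define the package's reference study conditions: 120 drugs
#' assayed on 200 endpoints (latent rank 4, 20% of cells unobserved,
#' logistic-squashed to hit-fraction scale), 400 genes scored against 40
#' phenotypes (latent rank 4, z-score-like scale), a sparse planted
#' endpoint-gene interaction scaled so the association logits have standard
#' deviation `signalScale = 2`, association density 10%, and 8 targets of 5
#' drugs each.
#'
#' @param nDrugs,nEndpoints,nGenes,nPhenotypes dimensions.
#' @param latentRankD,latentRankG latent ranks of the two feature spaces.
#' @param wSparsity fraction of nonzero entries in the planted interaction
#'   matrix W (endpoints x genes).
#' @param signalScale target standard deviation of the association logits;
#'   0 gives a global null.
#' @param missingFractionD fraction of endpoint cells masked, in [0, 1).
#' @param noiseSdD Gaussian noise added to the endpoint matrix before
#'   squashing.
#' @param yDensity target Bernoulli density of the association matrix; the
#'   intercept is calibrated by bisection to hit it.
#' @param nTargets,drugsPerTarget planted target map dimensions.
#' @param seed master seed; every sub-matrix draws from a sub-stream
#'   derived from it.
#' @return Named list of class `simConfig`.
#' @export
simConfig <- function(nDrugs = 120L, nEndpoints = 200L, nGenes = 400L,
                      nPhenotypes = 40L, latentRankD = 4L, latentRankG = 4L,
                      wSparsity = 0.05, signalScale = 2, missingFractionD = 0.2,
                      noiseSdD = 0.25, yDensity = 0.1, nTargets = 8L,
                      drugsPerTarget = 5L, seed = 1L) {
  cfg <- list(nDrugs = nDrugs, nEndpoints = nEndpoints, nGenes = nGenes,
              nPhenotypes = nPhenotypes, latentRankD = latentRankD,
              latentRankG = latentRankG, wSparsity = wSparsity,
              signalScale = signalScale, missingFractionD = missingFractionD,
              noiseSdD = noiseSdD, yDensity = yDensity, nTargets = nTargets,
              drugsPerTarget = drugsPerTarget, seed = seed)
  if (latentRankD > min(nDrugs, nEndpoints) ||
      latentRankG > min(nGenes, nPhenotypes))
    stop("latent ranks cannot exceed the matrix dimensions")
  if (missingFractionD < 0 || missingFractionD >= 1)
    stop("missingFractionD must lie in [0, 1)")
  if (wSparsity <= 0 || wSparsity > 1) stop("wSparsity must lie in (0, 1]")
  if (signalScale < 0) stop("signalScale must be >= 0")
  if (yDensity <= 0 || yDensity >= 1) stop("yDensity must lie in (0, 1)")
  class(cfg) <- "simConfig"
  cfg
}

.calibrateIntercept <- function(logits, target) {
  f <- function(b) mean(stats::plogis(logits + b)) - target
  lo <- -50; hi <- 50
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate synthetic inputs from a planted ground-truth model
#'
#' Emulates the statistical structure of the real study inputs: a low-rank
#' endpoint matrix with missingness (hit-fraction scale via a logistic
#' squash), a low-rank signed gene-phenotype score matrix, a sparse planted
#' endpoint-gene interaction W, and associations drawn as
#' `Y ~ Bernoulli(sigmoid(D_complete W G + intercept))` with the intercept
#' bisected to the requested density — so drugs with similar molecular
#' profiles are more likely to share phenotypes, the premise the affinity
#' model exploits. Targets are groups of drugs sharing a latent endpoint
#' component, each with a planted gene set read off the interaction of that
#' component's endpoints.
#'
#' @param config a [simConfig()] list.
#' @return List with `endpoints` ([EndpointMatrix-class]), `genes`
#'   ([GeneScoreMatrix-class]), `assoc` ([AssociationMatrix-class]),
#'   `targets` (named list), and `truth` (latent factors `A`, planted `W`,
#'   `dComplete`, `logits`, `intercept`, `targetGenes`).
#' @export
simulateData <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  cfg <- config
  drugs <- sprintf("drug%03d", seq_len(cfg$nDrugs))
  endpoints <- sprintf("ep%03d", seq_len(cfg$nEndpoints))
  genes <- sprintf("gene%04d", seq_len(cfg$nGenes))
  phenos <- sprintf("pheno%02d", seq_len(cfg$nPhenotypes))

  set.seed(cfg$seed)
  a <- matrix(stats::rnorm(cfg$nDrugs * cfg$latentRankD), cfg$nDrugs)
  b <- matrix(stats::rnorm(cfg$nEndpoints * cfg$latentRankD), cfg$nEndpoints)
  dRaw <- tcrossprod(a, b) / sqrt(cfg$latentRankD) +
    matrix(stats::rnorm(cfg$nDrugs * cfg$nEndpoints, sd = cfg$noiseSdD),
           cfg$nDrugs)
  dComplete <- stats::plogis(dRaw)
  dimnames(dComplete) <- list(drugs, endpoints)

  set.seed(cfg$seed + 1L)
  ug <- matrix(stats::rnorm(cfg$nGenes * cfg$latentRankG), cfg$nGenes)
  vg <- matrix(stats::rnorm(cfg$nPhenotypes * cfg$latentRankG), cfg$nPhenotypes)
  g <- tcrossprod(ug, vg)
  g <- g / stats::sd(g) * 2  # z-score-like spread
  dimnames(g) <- list(genes, phenos)

  set.seed(cfg$seed + 2L)
  w <- matrix(0, cfg$nEndpoints, cfg$nGenes, dimnames = list(endpoints, genes))
  nnz <- max(1L, round(cfg$wSparsity * length(w)))
  nz <- sample.int(length(w), nnz)
  w[nz] <- sample(c(-1, 1), nnz, replace = TRUE)
  logits0 <- dComplete %*% w %*% g
  if (cfg$signalScale > 0 && stats::sd(logits0) > 0) {
    w <- w * cfg$signalScale / stats::sd(logits0)
    logits <- logits0 * cfg$signalScale / stats::sd(logits0)
  } else {
    w[] <- 0
    logits <- logits0 * 0
  }
  intercept <- .calibrateIntercept(logits, cfg$yDensity)

  set.seed(cfg$seed + 3L)
  yv <- matrix(stats::rbinom(length(logits), 1L,
                             stats::plogis(logits + intercept)),
               cfg$nDrugs, dimnames = list(drugs, phenos))

  set.seed(cfg$seed + 4L)
  mask <- matrix(stats::runif(length(dComplete)) >= cfg$missingFractionD,
                 cfg$nDrugs, dimnames = dimnames(dComplete))
  for (i in which(rowSums(mask) == 0))
    mask[i, sample.int(cfg$nEndpoints, 1L)] <- TRUE
  dVals <- dComplete
  dVals[!mask] <- NA_real_

  set.seed(cfg$seed + 5L)
  targets <- list(); targetGenes <- list()
  if (cfg$nTargets > 0L) {
    for (t in seq_len(cfg$nTargets)) {
      comp <- ((t - 1L) %% cfg$latentRankD) + 1L
      block <- (t - 1L) %/% cfg$latentRankD
      ranked <- order(a[, comp], decreasing = TRUE)
      pick <- ranked[block * cfg$drugsPerTarget + seq_len(cfg$drugsPerTarget)]
      if (anyNA(drugs[pick]))
        stop("nTargets * drugsPerTarget exceeds the drug pool per component")
      id <- sprintf("target%02d", t)
      targets[[id]] <- drugs[pick]
      topEp <- order(abs(b[, comp]), decreasing = TRUE)[
        seq_len(max(1L, round(0.1 * cfg$nEndpoints)))]
      geneScore <- colSums(abs(w[topEp, , drop = FALSE]))
      targetGenes[[id]] <- genes[order(geneScore, decreasing = TRUE)[1:20]]
    }
  }

  list(endpoints = EndpointMatrix(dVals, mask),
       genes = GeneScoreMatrix(g),
       assoc = AssociationMatrix(yv, polarity = "side_effects"),
       targets = targets,
       truth = list(A = a, W = w, dComplete = dComplete, logits = logits,
                    intercept = intercept, targetGenes = targetGenes,
                    config = cfg))
}

#' Recovery metrics of a fitted model against the planted truth
#'
#' Quantifies how much of the planted interaction structure a fitted model
#' recovered: (i) the correlation and sign agreement between the planted
#' gene-space effects (`D_complete W` summed into drug-gene effects) and
#' the model's disease-genome scores, (ii) precision/recall of the
#' per-drug significant gene sets against the union of planted target gene
#' supports, and (iii) AUC of the model's predicted probabilities against
#' the truth's Bernoulli logits thresholded at their median.
#'
#' @param truth the `truth` element of [simulateData()].
#' @param model a fitted [AffinityModel-class].
#' @param genomeResult optional [DiseaseGenomeResult-class]; enables the
#'   precision/recall report.
#' @param alpha significance level for [significantGenes()] (default 0.05).
#' @return List with `geneSpaceCorrelation`, `signAgreement`, `aucVsTruth`,
#'   and (when `genomeResult` is given) `precision`, `recall`.
#' @export
truthMetrics <- function(truth, model, genomeResult = NULL, alpha = 0.05) {
  planted <- truth$dComplete %*% truth$W  # drugs x genes planted effect
  fitted <- diseaseGenome(model)
  common <- intersect(colnames(planted), colnames(fitted))
  planted <- planted[rownames(fitted), common]
  fittedM <- fitted[, common]
  geneCor <- if (stats::sd(fittedM) == 0) NA_real_
  else stats::cor(as.vector(planted), as.vector(fittedM))
  nzF <- fittedM != 0
  signAgr <- if (any(nzF))
    mean(sign(fittedM[nzF]) == sign(planted[nzF])) else NA_real_
  p <- predictAssociation(model)
  labels <- as.numeric(truth$logits[rownames(p), colnames(p)] >
                         stats::median(truth$logits))
  aucTruth <- rocAuc(as.vector(p), labels)$auc
  out <- list(geneSpaceCorrelation = geneCor, signAgreement = signAgr,
              aucVsTruth = aucTruth)
  if (!is.null(genomeResult)) {
    sig <- significantGenes(genomeResult, alpha = alpha)
    support <- unique(unlist(truth$targetGenes, use.names = FALSE))
    found <- unique(unlist(sig, use.names = FALSE))
    out$precision <- if (length(found)) mean(found %in% support) else NA_real_
    out$recall <- if (length(support)) mean(support %in% found) else NA_real_
  }
  out
}
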