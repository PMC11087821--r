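#' Jaccard index and distance of two sets
#'
#' `|A n B| / |A u B|`; when both sets are empty the index is undefined and
#' `NA` is returned. The distance is `1 - index`.
#'
#' @param a,b vectors treated as sets (or logical vectors of equal length,
#'   interpreted as membership indicators).
#' @return Numeric in `[0, 1]`, or `NA` for two empty sets.
#' @export
jaccardIndex <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    if (length(a) != length(b)) stop("logical profiles must have equal length")
    u <- sum(a | b)
    if (u == 0L) return(NA_real_)
    return(sum(a & b) / u)
  }
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' @rdname jaccardIndex
#' @export
jaccardDistance <- function(a, b) 1 - jaccardIndex(a, b)

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney U statistic normalised by
#' `n_pos * n_neg`, with tied scores contributing 1/2; ROC points sweep the
#' unique score thresholds from high to low.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 (or logical) true labels; both classes must be
#'   present.
#' @return List with `auc` and `roc`, a data.frame of `(fpr, tpr)` points
#'   including (0,0) and (1,1).
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels == 1 & scores >= t) / nPos, 0)
  fpr <- vapply(thr, function(t) sum(labels == 0 & scores >= t) / nNeg, 0)
  list(auc = auc,
       roc = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
}

.spearman <- function(x, y) suppressWarnings(stats::cor(x, y, method = "spearman"))

.pairAssociation <- function(records, nPerm, seed) {
  cc <- stats::complete.cases(records[, c("jaccard", "correlation")])
  rec <- records[cc, , drop = FALSE]
  obs <- .spearman(rec$jaccard, rec$correlation)
  lmFit <- stats::lm(jaccard ~ correlation + nShared, data = rec)
  set.seed(seed)
  permStats <- vapply(seq_len(nPerm), function(b)
    .spearman(rec$jaccard, sample(rec$correlation)), 0)
  permP <- (1 + sum(abs(permStats) >= abs(obs))) / (nPerm + 1)
  list(spearman = obs, permutationP = permP, linearModel = summary(lmFit),
       nPairsUsed = nrow(rec))
}

#' Drug-pair similarity across data sources
#'
#' The premise check: do drugs with more similar molecular (endpoint)
#' profiles share more phenotype associations? For every drug pair it
#' records the Jaccard index of the two association rows, the Spearman
#' correlation of their endpoint scores over the endpoints both drugs were
#' assayed for, and the count of shared endpoints. The association between
#' the two similarities is summarised by (i) their Spearman correlation
#' across pairs, (ii) a least-squares fit of the Jaccard index on the
#' endpoint correlation plus the shared-endpoint count, and (iii) an
#' empirical permutation p-value from shuffling which pair each endpoint
#' correlation belongs to.
#'
#' @param d an [EndpointMatrix-class].
#' @param y an aligned [AssociationMatrix-class].
#' @param minSharedEndpoints pairs sharing fewer observed endpoints are
#'   excluded (default 3).
#' @param nPerm permutations for the pairing shuffle (default 1000).
#' @param seed RNG seed.
#' @return List with `records` (one row per retained pair), `spearman`,
#'   `permutationP`, `linearModel`, `nPairsUsed`, `nExcluded`.
#' @export
drugPairSimilarity <- function(d, y, minSharedEndpoints = 3L, nPerm = 1000L,
                               seed = 1L) {
  stopifnot(is(d, "EndpointMatrix"), is(y, "AssociationMatrix"))
  if (!identical(drugIds(d), drugIds(y)))
    stop("endpoint and association matrices must be drug-aligned")
  dv <- values(d); mk <- observedMask(d); yv <- values(y) == 1
  n <- nrow(dv)
  if (n < 2L) stop("need at least two drugs")
  nPair <- n * (n - 1L) / 2L
  ia <- ib <- integer(nPair); jac <- rho <- rep(NA_real_, nPair)
  nsh <- integer(nPair)
  idx <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      idx <- idx + 1L
      ia[idx] <- i; ib[idx] <- j
      shared <- mk[i, ] & mk[j, ]
      nsh[idx] <- sum(shared)
      if (nsh[idx] < minSharedEndpoints) next
      jac[idx] <- jaccardIndex(yv[i, ], yv[j, ])
      rho[idx] <- .spearman(dv[i, shared], dv[j, shared])
    }
  }
  keep <- nsh >= minSharedEndpoints
  if (!any(keep)) stop("no pair passed the shared-endpoint filter")
  records <- data.frame(id_a = rownames(dv)[ia[keep]],
                        id_b = rownames(dv)[ib[keep]],
                        jaccard = jac[keep], correlation = rho[keep],
                        nShared = nsh[keep])
  c(list(records = records, nExcluded = sum(!keep)),
    .pairAssociation(records, nPerm, seed))
}

#' Phenotype-pair similarity across data sources
#'
#' Mirror of [drugPairSimilarity()] with the roles swapped: for each pair
#' of phenotypes, the Jaccard index of their drug sets (association
#' columns) against the Spearman correlation of their gene association
#' profiles. Gene-score columns are complete, so no shared-feature filter
#' applies.
#'
#' @param g a [GeneScoreMatrix-class].
#' @param y an aligned [AssociationMatrix-class].
#' @param nPerm,seed as in [drugPairSimilarity()].
#' @return As [drugPairSimilarity()], without `nExcluded`.
#' @export
phenotypePairSimilarity <- function(g, y, nPerm = 1000L, seed = 1L) {
  stopifnot(is(g, "GeneScoreMatrix"), is(y, "AssociationMatrix"))
  if (!identical(phenotypeIds(g), phenotypeIds(y)))
    stop("gene-score and association matrices must be phenotype-aligned")
  gv <- values(g); yv <- values(y) == 1
  m <- ncol(gv)
  if (m < 2L) stop("need at least two phenotypes")
  nPair <- m * (m - 1L) / 2L
  ia <- ib <- integer(nPair); jac <- rho <- rep(NA_real_, nPair)
  idx <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in seq((i + 1L), m)) {
      idx <- idx + 1L
      ia[idx] <- i; ib[idx] <- j
      jac[idx] <- jaccardIndex(yv[, i], yv[, j])
      rho[idx] <- .spearman(gv[, i], gv[, j])
    }
  }
  records <- data.frame(id_a = colnames(gv)[ia], id_b = colnames(gv)[ib],
                        jaccard = jac, correlation = rho, nShared = nrow(gv))
  c(list(records = records), .pairAssociation(records, nPerm, seed))
}

#' Nearest-neighbour baseline prediction
#'
#' Predicts a held-out drug's associations as the association row of its
#' Euclidean nearest neighbour in endpoint factor space among the training
#' drugs. Distance ties are broken by drug-id order.
#'
#' @param trainFactors training drug factors (rows named by drug id).
#' @param trainY training association rows aligned with `trainFactors`.
#' @param queryFactors factor rows of the drugs to predict.
#' @return Matrix of predicted 0/1 rows, one per query drug.
#' @export
nearestNeighborBaseline <- function(trainFactors, trainY, queryFactors) {
  if (!nrow(trainFactors)) stop("need at least one training drug")
  ord <- order(rownames(trainFactors))
  trainFactors <- trainFactors[ord, , drop = FALSE]
  trainY <- trainY[ord, , drop = FALSE]
  out <- matrix(0, nrow(queryFactors), ncol(trainY),
                dimnames = list(rownames(queryFactors), colnames(trainY)))
  for (q in seq_len(nrow(queryFactors))) {
    d2 <- rowSums(sweep(trainFactors, 2L, queryFactors[q, ])^2)
    out[q, ] <- trainY[which.min(d2), ]
  }
  out
}

#' Drug-held-out cross-validated evaluation
#'
#' Approximates leave-one-drug-out evaluation by `nFolds`-fold
#' cross-validation over drugs: per fold the model is fitted on the
#' in-fold drugs (drug factors always from the full-matrix decomposition)
#' and the held-out drugs are predicted. Per drug it reports the Jaccard
#' distance between the binarised predicted set and the true set, and the
#' same for the nearest-neighbour baseline; model-vs-baseline distances are
#' compared by a paired one-sided rank-sum (Wilcoxon signed-rank) test that
#' the model's are lower. Probabilities are pooled over all (drug,
#' phenotype) pairs for the ROC/AUC.
#'
#' @param dDecomp a [Decomposition-class] of the endpoint matrix.
#' @param g a [GeneScoreMatrix-class].
#' @param y an aligned [AssociationMatrix-class].
#' @param rD,rP,l1Strength model configuration (ranks and lasso penalty).
#' @param nFolds number of drug folds (default 20, i.e. 5% of drugs held
#'   out per fold).
#' @param binarizeThreshold probability cutoff turning predictions into
#'   sets (default 0.5; used by the `"threshold"` rule).
#' @param binarize how continuous predictions become sets for the Jaccard
#'   comparison: `"threshold"` (default) cuts at `binarizeThreshold`;
#'   `"topk"` takes each drug's top-k phenotypes by probability, with k the
#'   size of the baseline neighbour's association set, so the two
#'   predictions are size-matched (at sparse association densities the
#'   threshold rule yields near-empty sets, which degenerates the
#'   comparison).
#' @param seed RNG seed for the fold assignment.
#' @return List with `perDrug` (data.frame of per-drug distances),
#'   `rankSumP`, `auc`, `roc`, `probabilities`.
#' @export
cvEvaluate <- function(dDecomp, g, y, rD, rP, l1Strength, nFolds = 20L,
                       binarizeThreshold = 0.5,
                       binarize = c("threshold", "topk"), seed = 1L) {
  binarize <- match.arg(binarize)
  stopifnot(is(dDecomp, "Decomposition"), is(g, "GeneScoreMatrix"),
            is(y, "AssociationMatrix"))
  yv <- values(y)
  n <- nrow(yv)
  if (nFolds > n) stop("nFolds cannot exceed the number of drugs")
  if (rD > length(dDecomp@d)) stop("rD exceeds the endpoint decomposition rank")
  fFull <- drugFactors(dDecomp)[, seq_len(rD), drop = FALSE]
  if (!identical(rownames(fFull), rownames(yv)))
    stop("decomposition and association drugs disagree")
  gd <- decomposeGeneMatrix(g, rP)
  set.seed(seed)
  foldOf <- sample(rep(seq_len(nFolds), length.out = n))
  prob <- matrix(NA_real_, n, ncol(yv), dimnames = dimnames(yv))
  baseline <- matrix(NA_real_, n, ncol(yv), dimnames = dimnames(yv))
  for (k in seq_len(nFolds)) {
    inIdx <- which(foldOf != k); outIdx <- which(foldOf == k)
    yIn <- yv[inIdx, , drop = FALSE]
    if (all(yIn == 0) || all(yIn == 1)) {
      foldOf <- sample(rep(seq_len(nFolds), length.out = n))
      inIdx <- which(foldOf != k); outIdx <- which(foldOf == k)
      yIn <- yv[inIdx, , drop = FALSE]
      if (all(yIn == 0) || all(yIn == 1))
        stop("degenerate training labels after fold re-draw")
    }
    fitK <- fitAffinity(fFull[inIdx, , drop = FALSE], gd,
                        AssociationMatrix(yIn, polarity(y)),
                        l1Strength = l1Strength)
    prob[outIdx, ] <- predictAssociation(fitK, fFull[outIdx, , drop = FALSE])
    baseline[outIdx, ] <- nearestNeighborBaseline(
      fFull[inIdx, , drop = FALSE], yIn, fFull[outIdx, , drop = FALSE])
  }
  trueSet <- yv == 1
  if (binarize == "threshold") {
    predSet <- prob >= binarizeThreshold
  } else {
    predSet <- matrix(FALSE, n, ncol(yv), dimnames = dimnames(yv))
    for (i in seq_len(n)) {
      k <- sum(baseline[i, ] == 1)
      if (k > 0L) predSet[i, order(prob[i, ], decreasing = TRUE)[seq_len(k)]] <- TRUE
    }
  }
  perDrug <- data.frame(
    drug = rownames(yv),
    jaccardDistanceModel = vapply(seq_len(n), function(i)
      jaccardDistance(predSet[i, ], trueSet[i, ]), 0),
    jaccardDistanceBaseline = vapply(seq_len(n), function(i)
      jaccardDistance(baseline[i, ] == 1, trueSet[i, ]), 0))
  ok <- stats::complete.cases(perDrug)
  rankSumP <- stats::wilcox.test(perDrug$jaccardDistanceModel[ok],
                                 perDrug$jaccardDistanceBaseline[ok],
                                 paired = TRUE, alternative = "less",
                                 exact = FALSE)$p.value
  ra <- rocAuc(as.vector(prob), as.vector(yv))
  list(perDrug = perDrug, rankSumP = rankSumP, auc = ra$auc, roc = ra$roc,
       probabilities = prob)
}

#' Compare pairwise similarity between drugs that share an attribute
#'
#' Given per-drug feature vectors (endpoint profiles, phenome effect rows,
#' null-projection rows, ...) and a predicate saying which drug pairs share
#' an attribute (e.g. a recorded target), computes pairwise Spearman
#' correlations and compares the sharing vs non-sharing correlation
#' distributions by a two-sided rank-sum test.
#'
#' @param vectors numeric matrix, one row per drug, rows named by drug id.
#' @param sharedPairs two-column character matrix (or data.frame) of drug
#'   id pairs that share the attribute; all other pairs form the comparison
#'   group.
#' @return List with `sharedCorrelations`, `otherCorrelations`, `p`
#'   (two-sided rank-sum), `statistic`.
#' @export
similarityByGroup <- function(vectors, sharedPairs) {
  ids <- rownames(vectors)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  sharedKey <- unique(key(as.character(sharedPairs[, 1L]),
                          as.character(sharedPairs[, 2L])))
  shared <- numeric(0); other <- numeric(0)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq((i + 1L), length(ids))) {
      rho <- .spearman(vectors[i, ], vectors[j, ])
      if (key(ids[i], ids[j]) %in% sharedKey) shared <- c(shared, rho)
      else other <- c(other, rho)
    }
  }
  if (!length(shared) || !length(other))
    stop("both sharing and non-sharing pair groups must be non-empty")
  wt <- stats::wilcox.test(shared, other, alternative = "two.sided",
                           exact = FALSE)
  list(sharedCorrelations = shared, otherCorrelations = other,
       p = wt$p.value, statistic = unname(wt$statistic))
}
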