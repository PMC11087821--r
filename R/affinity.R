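#' Truncated SVD of the gene score matrix
#'
#' Decomposes the gene-major matrix `G` (genes x phenotypes) as
#' `G = U_P diag(S_P) V_P'` with `U_P` on the gene side and `V_P` on the
#' phenotype side; the phenotype-side factors `V_P` enter the bilinear model
#' and `U_P`, `S_P` define the disease-genome projection. Requesting a rank
#' beyond the numerical rank truncates with a warning.
#'
#' @param g a [GeneScoreMatrix-class].
#' @param rP target rank, `<= min(n_genes, n_phenotypes)`.
#' @return A [Decomposition-class] with gene ids on `u` rows and phenotype
#'   ids on `v` rows.
#' @export
decomposeGeneMatrix <- function(g, rP) {
  stopifnot(is(g, "GeneScoreMatrix"))
  v <- g@values
  if (rP < 1L || rP > min(dim(v))) stop("rP must lie in [1, min(dim)]")
  sv <- svd(v, nu = rP, nv = rP)
  d <- sv$d[seq_len(rP)]
  tolRank <- sum(sv$d > max(dim(v)) * .Machine$double.eps * sv$d[1L])
  if (rP > tolRank) {
    warning(sprintf("requested rank %d exceeds numerical rank %d; truncating",
                    rP, tolRank))
    d <- d[seq_len(tolRank)]
  }
  r <- length(d)
  u <- sv$u[, seq_len(r), drop = FALSE]
  vv <- sv$v[, seq_len(r), drop = FALSE]
  rownames(u) <- rownames(v); rownames(vv) <- colnames(v)
  new("Decomposition", u = u, d = d, v = vv, lambda = 0)
}

#' Kronecker design over (drug, phenotype) pairs
#'
#' Builds the expanded design matrix of the vectorised bilinear model: the
#' row for pair (drug i, phenotype j) is the outer product
#' `V_P[j, ] %x% drugFactors[i, ]`, and pairs are ordered column-major over
#' Y with the drug index varying fastest, so that
#' `design %*% as.vector(W_DP)` equals
#' `as.vector(drugFactors %*% W_DP %*% t(V_P))` exactly (vec identity).
#'
#' @param drugFactors numeric matrix (drugs x r_D).
#' @param vP numeric matrix (phenotypes x r_P), the phenotype-side factors.
#' @param pairSubset optional integer matrix with columns `(drug, phenotype)`
#'   selecting a subset of pairs (rows keep the given order).
#' @return Numeric matrix with `r_D * r_P` columns.
#' @export
buildDesign <- function(drugFactors, vP, pairSubset = NULL) {
  rD <- ncol(drugFactors); rP <- ncol(vP)
  if (is.null(pairSubset)) {
    n <- nrow(drugFactors); m <- nrow(vP)
    pairSubset <- cbind(rep(seq_len(n), times = m),
                        rep(seq_len(m), each = n))
  }
  if (ncol(pairSubset) != 2L) stop("pairSubset must have two columns (drug, phenotype)")
  a <- drugFactors[pairSubset[, 1L], , drop = FALSE]
  b <- vP[pairSubset[, 2L], , drop = FALSE]
  # row-wise outer products, flattened column-major over (r_D, r_P)
  x <- a[, rep(seq_len(rD), times = rP), drop = FALSE] *
    b[, rep(seq_len(rP), each = rD), drop = FALSE]
  colnames(x) <- paste0("w", rep(seq_len(rD), times = rP), "_",
                        rep(seq_len(rP), each = rD))
  x
}

#' Fit the bilinear association model by lasso logistic regression
#'
#' Learns the reduced-rank interaction matrix `W_DP` of the model
#' `logit P(Y = 1) = intercept + (U_D S_D) W_DP V_P'` by L1-penalised
#' logistic regression of `vec(Y)` on the Kronecker design from
#' [buildDesign()]; the coefficient vector is reshaped column-major into
#' `W_DP`. The penalty is glmnet's `lambda` (applied to the mean log-loss),
#' so duplicating every (drug, phenotype) pair leaves the fit unchanged.
#'
#' @param drugFactors numeric matrix (drugs x r_D) with drug ids on rows,
#'   from [drugFactors()].
#' @param geneDecomp a [Decomposition-class] of the gene score matrix at
#'   rank r_P, from [decomposeGeneMatrix()].
#' @param y an [AssociationMatrix-class]; drug rows must match
#'   `drugFactors`, phenotype columns must match the decomposition.
#' @param l1Strength lasso penalty, > 0.
#' @param intercept include an intercept (default TRUE; association
#'   matrices are sparse, so the base rate should not be forced through
#'   `W_DP`).
#' @param thresh glmnet convergence threshold.
#' @return An [AffinityModel-class].
#' @examples
#' \donttest{
#' sim <- simulateData(simConfig(nDrugs = 40, nEndpoints = 60, nGenes = 80,
#'                               nPhenotypes = 12, seed = 7))
#' dec <- softImpute(sim$endpoints, rank = 4, lambda = 0.1)
#' gd <- decomposeGeneMatrix(sim$genes, rP = 4)
#' fit <- fitAffinity(drugFactors(dec), gd, sim$assoc, l1Strength = 0.005)
#' fit
#' }
#' @export
fitAffinity <- function(drugFactors, geneDecomp, y, l1Strength,
                        intercept = TRUE, thresh = 1e-10) {
  stopifnot(is(geneDecomp, "Decomposition"), is(y, "AssociationMatrix"))
  if (l1Strength <= 0) stop("l1Strength must be > 0")
  yv <- values(y)
  if (nrow(drugFactors) != nrow(yv))
    stop("drug rows of factors and associations disagree")
  if (!identical(rownames(drugFactors), rownames(yv)))
    stop("drug id order of factors and associations disagree")
  vP <- geneDecomp@v
  if (nrow(vP) != ncol(yv))
    stop("phenotype count of gene decomposition and associations disagree")
  yvec <- as.vector(yv)
  if (all(yvec == 0) || all(yvec == 1))
    stop("degenerate association matrix: labels are all 0 or all 1")
  x <- buildDesign(drugFactors, vP)
  pad <- ncol(x) == 1L  # glmnet needs >= 2 columns; pad rank-1 designs
  if (pad) x <- cbind(x, pad = 0)
  fit <- glmnet::glmnet(x, yvec, family = "binomial", alpha = 1,
                        lambda = l1Strength, standardize = FALSE,
                        intercept = intercept, thresh = thresh,
                        maxit = 1e6)
  if (fit$jerr != 0)
    warning(sprintf("glmnet reported a convergence issue (jerr = %d)", fit$jerr))
  beta <- as.numeric(fit$beta[, 1L])
  if (pad) beta <- beta[1L]
  wdp <- matrix(beta, ncol(drugFactors), ncol(vP))
  new("AffinityModel", wdp = wdp,
      intercept = if (intercept) as.numeric(fit$a0[1L]) else 0,
      drugFactors = drugFactors, geneDecomp = geneDecomp,
      l1Strength = l1Strength, polarity = polarity(y),
      phenotypeIds = phenotypeIds(y), usedIntercept = intercept)
}

#' Predict association probabilities
#'
#' Applies the fitted bilinear map: `sigmoid(intercept + F W_DP V_P')` for
#' the given drug factor rows. Held-out or new drugs are scored with their
#' rows of the SoftImpute decomposition fitted on the full endpoint matrix
#' (the endpoint data are unsupervised input; only association rows are ever
#' held out).
#'
#' @param model an [AffinityModel-class].
#' @param newFactors optional numeric matrix (drugs x r_D); defaults to the
#'   training factors.
#' @return Matrix of probabilities in (0, 1), drugs x phenotypes.
#' @export
predictAssociation <- function(model, newFactors = NULL) {
  stopifnot(is(model, "AffinityModel"))
  f <- if (is.null(newFactors)) model@drugFactors else newFactors
  if (ncol(f) != nrow(model@wdp))
    stop("factor row length must equal the model's r_D")
  eta <- model@intercept + f %*% model@wdp %*% t(model@geneDecomp@v)
  p <- stats::plogis(eta)
  dimnames(p) <- list(rownames(f), model@phenotypeIds)
  p
}

#' Tune ranks and penalty by drug-held-out cross-validation
#'
#' Grid search over (r_D, r_P, l1Strength). Drugs (not pairs) are
#' partitioned into folds; for each fold the model is fitted on the in-fold
#' drugs and the held-out drugs' predicted probabilities are scored against
#' their association rows by pooled AUC. Drug factors always come from the
#' decomposition of the full endpoint matrix, truncated per candidate r_D.
#' The configuration maximising the mean held-out AUC wins. Folds whose
#' held-out labels are single-class have no AUC and are skipped with a
#' warning.
#'
#' @param dDecomp a [Decomposition-class] of the endpoint matrix at rank
#'   `>= max(rdGrid)`.
#' @param g a [GeneScoreMatrix-class].
#' @param y an [AssociationMatrix-class] aligned with the decomposition's
#'   drugs.
#' @param rdGrid,rpGrid,l1Grid candidate values.
#' @param nFolds number of drug folds (default 10, holding out 10% of drugs
#'   per fold).
#' @param seed RNG seed for the fold assignment.
#' @return List with `rD`, `rP`, `l1Strength`, and `aucTable`.
#' @export
tuneAffinity <- function(dDecomp, g, y, rdGrid, rpGrid, l1Grid,
                         nFolds = 10L, seed = 1L) {
  stopifnot(is(dDecomp, "Decomposition"), is(g, "GeneScoreMatrix"),
            is(y, "AssociationMatrix"))
  if (!length(rdGrid) || !length(rpGrid) || !length(l1Grid))
    stop("empty hyperparameter grid")
  if (max(rdGrid) > length(dDecomp@d))
    stop("rdGrid exceeds the endpoint decomposition rank")
  fFull <- drugFactors(dDecomp)
  yv <- values(y)
  n <- nrow(yv)
  set.seed(seed)
  foldOf <- sample(rep(seq_len(nFolds), length.out = n))
  grid <- expand.grid(rD = rdGrid, rP = rpGrid, l1 = l1Grid)
  grid$meanAuc <- NA_real_
  gDecomps <- lapply(stats::setNames(rpGrid, rpGrid), function(r)
    decomposeGeneMatrix(g, r))
  for (i in seq_len(nrow(grid))) {
    gd <- gDecomps[[as.character(grid$rP[i])]]
    f <- fFull[, seq_len(grid$rD[i]), drop = FALSE]
    aucs <- rep(NA_real_, nFolds)
    for (k in seq_len(nFolds)) {
      inIdx <- which(foldOf != k); outIdx <- which(foldOf == k)
      yTrain <- AssociationMatrix(yv[inIdx, , drop = FALSE], polarity(y))
      fitK <- fitAffinity(f[inIdx, , drop = FALSE], gd, yTrain,
                          l1Strength = grid$l1[i])
      p <- predictAssociation(fitK, f[outIdx, , drop = FALSE])
      lab <- as.vector(yv[outIdx, , drop = FALSE])
      if (length(unique(lab)) < 2L) {
        warning(sprintf("fold %d held-out labels are single-class; skipped", k))
        next
      }
      aucs[k] <- rocAuc(as.vector(p), lab)$auc
    }
    grid$meanAuc[i] <- mean(aucs, na.rm = TRUE)
  }
  best <- grid[which.max(grid$meanAuc), ]
  list(rD = best$rD, rP = best$rP, l1Strength = best$l1, aucTable = grid)
}
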