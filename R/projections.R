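#' Drug phenome effect matrix
#'
#' Multiplies the transformed endpoint data `U_D S_D` by the learned
#' interaction matrix: `U_D S_D W_DP` maps each drug onto a compressed
#' summary of its effect over the phenotype factor space.
#'
#' @param model an [AffinityModel-class].
#' @return Numeric matrix (drugs x r_P) with drug ids on rows.
#' @export
phenomeEffect <- function(model) {
  stopifnot(is(model, "AffinityModel"))
  e <- model@drugFactors %*% model@wdp
  colnames(e) <- paste0("p", seq_len(ncol(e)))
  e
}

#' Drug disease-genome matrix
#'
#' Decompresses the phenome effect onto gene space using the inverse of the
#' gene matrix decomposition: `(U_D S_D W_DP) diag(S_P)^-1 U_P'`, yielding
#' each drug's inferred effect on every disease-associated gene. Because
#' `U_P' U_P = I` under truncation (but not the reverse), this is the
#' minimum-norm gene-space preimage of the phenome effect.
#'
#' @param model an [AffinityModel-class].
#' @return Numeric matrix (drugs x genes).
#' @export
diseaseGenome <- function(model) {
  stopifnot(is(model, "AffinityModel"))
  gd <- model@geneDecomp
  if (any(gd@d <= 0)) stop("gene decomposition has a non-positive singular value")
  s <- phenomeEffect(model) %*% (t(gd@u) / gd@d)
  colnames(s) <- rownames(gd@u)
  s
}

#' Score a drug against a disease's genetic profile
#'
#' Plain dot product between a drug's disease-genome row and a disease's
#' gene association column: `sum_g drugGeneEffect_g * geneDiseaseEffect_g`,
#' the model's estimate of the chance the drug affects that disease.
#'
#' @param drugGeneRow numeric vector over genes.
#' @param genePhenoColumn numeric vector over the same genes.
#' @return Single numeric score.
#' @export
drugDiseaseScore <- function(drugGeneRow, genePhenoColumn) {
  if (length(drugGeneRow) != length(genePhenoColumn))
    stop("gene vectors must have equal length")
  sum(drugGeneRow * genePhenoColumn)
}

.permuteY <- function(yv, mode) {
  switch(mode,
         entries = matrix(sample(as.vector(yv)), nrow(yv), ncol(yv),
                          dimnames = dimnames(yv)),
         rows = yv[sample(nrow(yv)), , drop = FALSE],
         columns = {
           out <- apply(yv, 2L, sample)
           dimnames(out) <- dimnames(yv)
           out
         },
         stop("unknown permutation mode"))
}

#' Permutation null ensemble of disease-genome matrices
#'
#' For each permutation the association labels are shuffled (by default a
#' global shuffle of `vec(Y)`, which preserves the number of 1s while
#' breaking all drug and phenotype structure), the model is refitted with
#' the same configuration and the *same* endpoint and gene inputs, and the
#' refitted model is projected onto gene space. The resulting null
#' drug-gene matrices quantify how strong drug-gene connections get when
#' only the input data, not the supervision, carries signal.
#'
#' @param model a fitted [AffinityModel-class] (supplies the factors, the
#'   gene decomposition, the penalty and the intercept setting).
#' @param y the training [AssociationMatrix-class].
#' @param nPerm number of permutations (the reference analysis uses 10000;
#'   desk-scale runs use far fewer).
#' @param seed RNG seed; the ensemble is reproducible bit-for-bit.
#' @param mode `"entries"` (default), `"rows"` or `"columns"`.
#' @return List with `matrices` (list of drug x gene null score matrices),
#'   `nValid`, `nFailed`, `mode`, `seed`. Permutations whose refit fails are
#'   recorded and excluded, with a warning when exclusions exceed 1%.
#' @export
nullEnsemble <- function(model, y, nPerm = 100L, seed = 1L,
                         mode = c("entries", "rows", "columns")) {
  stopifnot(is(model, "AffinityModel"), is(y, "AssociationMatrix"))
  mode <- match.arg(mode)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  yv <- values(y)
  set.seed(seed)
  matrices <- vector("list", nPerm)
  failed <- 0L
  for (b in seq_len(nPerm)) {
    yp <- .permuteY(yv, mode)
    res <- tryCatch({
      fitP <- fitAffinity(model@drugFactors, model@geneDecomp,
                          AssociationMatrix(yp, polarity(y)),
                          l1Strength = model@l1Strength,
                          intercept = model@usedIntercept)
      diseaseGenome(fitP)
    }, error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else matrices[[b]] <- res
  }
  matrices <- Filter(Negate(is.null), matrices)
  if (failed > 0.01 * nPerm)
    warning(sprintf("%d of %d permutations failed to refit and were excluded",
                    failed, nPerm))
  list(matrices = matrices, nValid = length(matrices), nFailed = failed,
       mode = mode, seed = seed)
}

#' Empirical two-sided permutation p-values
#'
#' For each drug-gene entry, tests whether the true effect is more extreme
#' than the null distribution of the same entry across permutations:
#' `p = (1 + #|null| >= |true|) / (nValid + 1)`. The add-one correction
#' keeps p strictly positive, as required by the downstream FDR adjustment.
#'
#' @param trueScores drug x gene matrix from [diseaseGenome()].
#' @param null a null ensemble from [nullEnsemble()].
#' @return Matrix of p-values in `[1/(nValid+1), 1]`, same shape as
#'   `trueScores`.
#' @export
empiricalPvalues <- function(trueScores, null) {
  if (!length(null$matrices)) stop("null ensemble holds no valid permutation")
  count <- matrix(0L, nrow(trueScores), ncol(trueScores))
  at <- abs(trueScores)
  for (m in null$matrices) {
    if (!identical(dim(m), dim(trueScores)))
      stop("null matrix shape does not match trueScores")
    count <- count + (abs(m) >= at)
  }
  p <- (1 + count) / (null$nValid + 1)
  dimnames(p) <- dimnames(trueScores)
  p
}

#' Benjamini-Yekutieli step-up adjustment
#'
#' FDR control under arbitrary dependence: the BH step-up inflated by the
#' harmonic factor `c(m) = sum_{i=1}^m 1/i`. Sorted p-values are scaled by
#' `m * c(m) / rank`, made monotone by a downward running minimum from the
#' largest, capped at 1, and returned in the original order. Appropriate
#' here because the drug-gene hypotheses within a drug are strongly
#' dependent (they share the fitted model).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, elementwise `>= p` and `<= 1`.
#' @export
byAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1L) return(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q <- p[o] * m * cm / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Disease-genome significance by permutation
#'
#' End-to-end wrapper: projects the fitted model onto gene space, builds
#' the permutation null with [nullEnsemble()], computes per-entry empirical
#' p-values, and BY-adjusts them per drug across that drug's genes.
#'
#' @param model a fitted [AffinityModel-class].
#' @param y the training [AssociationMatrix-class].
#' @param nPerm,seed,mode passed to [nullEnsemble()].
#' @return A [DiseaseGenomeResult-class].
#' @export
diseaseGenomeTest <- function(model, y, nPerm = 100L, seed = 1L,
                              mode = c("entries", "rows", "columns")) {
  mode <- match.arg(mode)
  trueScores <- diseaseGenome(model)
  null <- nullEnsemble(model, y, nPerm = nPerm, seed = seed, mode = mode)
  p <- empiricalPvalues(trueScores, null)
  q <- t(apply(p, 1L, byAdjust))
  dimnames(q) <- dimnames(p)
  new("DiseaseGenomeResult", scores = trueScores, pvalues = p, qvalues = q,
      nPerm = as.integer(null$nValid))
}

#' Per-drug significant disease-gene sets
#'
#' Genes whose BY-adjusted q-value falls below `alpha`, per drug (the
#' adjustment is per drug across its genes).
#'
#' @param result a [DiseaseGenomeResult-class].
#' @param alpha significance level in (0, 1), default 0.05.
#' @return Named list: drug id -> character vector of gene ids.
#' @export
significantGenes <- function(result, alpha = 0.05) {
  stopifnot(is(result, "DiseaseGenomeResult"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  q <- result@qvalues
  out <- lapply(seq_len(nrow(q)), function(i) colnames(q)[q[i, ] < alpha])
  names(out) <- rownames(q)
  out
}
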