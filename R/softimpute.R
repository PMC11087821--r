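#' Soft-thresholded iterative SVD of a matrix with missing entries
#'
#' Low-rank decomposition of the endpoint matrix in the presence of missing
#' data (the SoftImpute algorithm): missing cells are initialised (to 0 by
#' default, the scores being centred hit fractions, or to the column mean),
#' then the filled matrix is repeatedly decomposed by SVD, its singular
#' values shrunk by `lambda` and truncated to `rank`, and the missing cells
#' refilled from the low-rank reconstruction, until the relative Frobenius
#' change of the reconstruction drops below `tol`. Components shrunk to zero
#' are dropped, so the returned rank can be below the requested one; always
#' use the returned rank downstream.
#'
#' The goal is the reduced-rank representation of the drugs, not imputation:
#' the drug coordinates `U %*% diag(S)` from [drugFactors()] feed the
#' affinity model.
#'
#' The iterate tracks the penalised objective
#' `0.5 * sum((observed - reconstruction)^2) + lambda * sum(S)`, which is
#' non-increasing across iterations; it is returned in the `"objective"`
#' attribute.
#'
#' @param m an [EndpointMatrix-class] (or a plain numeric matrix with `NA`
#'   for missing cells).
#' @param rank maximum rank of the decomposition.
#' @param lambda soft-threshold (nuclear-norm) penalty, >= 0.
#' @param tol convergence tolerance on the relative Frobenius change of the
#'   reconstruction (default 1e-5).
#' @param maxIter iteration cap (default 500); hitting it raises a warning
#'   carrying the last relative change, and the result is still returned.
#' @param init `"zero"` (default) or `"mean"` initialisation of missing
#'   cells.
#' @return A [Decomposition-class]; attribute `"objective"` holds the
#'   per-iteration objective values and `"iterations"` the count.
#' @references Mazumder, Hastie & Tibshirani (2010) Spectral regularization
#'   algorithms for learning large incomplete matrices. JMLR 11.
#' @examples
#' set.seed(1)
#' u <- rnorm(6); v <- rnorm(6)
#' m <- 5 * tcrossprod(u / sqrt(sum(u^2)), v / sqrt(sum(v^2)))
#' dimnames(m) <- list(paste0("d", 1:6), paste0("e", 1:6))
#' dec <- softImpute(EndpointMatrix(m), rank = 1, lambda = 0)
#' dec@d  # ~ 5
#' @export
softImpute <- function(m, rank, lambda, tol = 1e-5, maxIter = 500L,
                       init = c("zero", "mean")) {
  init <- match.arg(init)
  if (is(m, "EndpointMatrix")) {
    vals <- values(m); obs <- observedMask(m)
  } else {
    vals <- as.matrix(m); obs <- !is.na(vals)
  }
  if (rank < 1L || rank > min(dim(vals)))
    stop("rank must lie in [1, min(dim)]")
  if (lambda < 0) stop("lambda must be >= 0")
  if (any(colSums(obs) == 0))
    stop(sprintf("endpoint(s) with no observed value: %s",
                 paste(colnames(vals)[colSums(obs) == 0], collapse = ", ")))
  x <- vals
  x[!obs] <- switch(init, zero = 0,
                    mean = rep(colMeans(vals, na.rm = TRUE),
                               each = nrow(vals))[!obs])
  recon <- matrix(0, nrow(x), ncol(x))
  objective <- numeric(0)
  relChange <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sv <- svd(x, nu = min(dim(x)), nv = min(dim(x)))
    ds <- pmax(sv$d - lambda, 0)
    keep <- which(ds > 0)
    keep <- keep[seq_len(min(rank, length(keep)))]
    if (!length(keep))
      stop("lambda shrinks every singular value to zero; decrease lambda")
    u <- sv$u[, keep, drop = FALSE]
    d <- ds[keep]
    v <- sv$v[, keep, drop = FALSE]
    newRecon <- u %*% (d * t(v))
    objective <- c(objective,
                   0.5 * sum((vals[obs] - newRecon[obs])^2) + lambda * sum(d))
    relChange <- sqrt(sum((newRecon - recon)^2)) /
      max(sqrt(sum(recon^2)), .Machine$double.eps)
    recon <- newRecon
    x[!obs] <- recon[!obs]
    if (relChange < tol || iter >= maxIter) break
  }
  if (relChange >= tol)
    warning(sprintf("softImpute did not converge in %d iterations (relative change %.3g)",
                    maxIter, relChange))
  rownames(u) <- rownames(vals); rownames(v) <- colnames(vals)
  out <- new("Decomposition", u = u, d = d, v = v, lambda = lambda)
  attr(out, "objective") <- objective
  attr(out, "iterations") <- iter
  out
}

#' Drug coordinates in endpoint factor space
#'
#' Projects each drug onto the reduced endpoint space as `U %*% diag(S)`;
#' these coordinates are the drug-side features of the affinity model and of
#' the nearest-neighbour baseline.
#'
#' @param dec a [Decomposition-class] of the endpoint matrix.
#' @return Numeric matrix (drugs x rank) with drug ids on rows.
#' @export
drugFactors <- function(dec) {
  stopifnot(is(dec, "Decomposition"))
  f <- dec@u %*% diag(dec@d, length(dec@d))
  rownames(f) <- rownames(dec@u)
  colnames(f) <- paste0("f", seq_along(dec@d))
  f
}

#' Choose SoftImpute rank and lambda by entry-holdout cross-validation
#'
#' Repeatedly hides a fraction of the observed cells (uniformly over
#' observed cells, not per drug), fits every (rank, lambda) combination on
#' the remainder, and scores the mean squared error of reconstructing the
#' hidden cells. Returns the combination with the lowest mean MSE together
#' with the full error table. A holdout that would leave some drug with no
#' observed cell is re-drawn (up to 100 attempts).
#'
#' @param m an [EndpointMatrix-class].
#' @param ranks integer vector of candidate ranks.
#' @param lambdas numeric vector of candidate soft-thresholds.
#' @param holdoutFraction fraction of observed cells to hide, in (0, 0.5);
#'   default 0.05.
#' @param nRepeats number of independent holdout draws (default 3).
#' @param seed RNG seed; the selection is reproducible given the seed.
#' @param ... further arguments passed to [softImpute()].
#' @return List with `rank`, `lambda`, and `mseTable` (a data.frame with one
#'   row per rank x lambda x repeat).
#' @export
cvSelect <- function(m, ranks, lambdas, holdoutFraction = 0.05, nRepeats = 3L,
                     seed = 1L, ...) {
  stopifnot(is(m, "EndpointMatrix"))
  if (!length(ranks) || !length(lambdas)) stop("empty candidate grid")
  if (holdoutFraction <= 0 || holdoutFraction >= 0.5)
    stop("holdoutFraction must lie in (0, 0.5)")
  vals <- values(m); obs <- observedMask(m)
  obsIdx <- which(obs)
  nHold <- max(1L, round(holdoutFraction * length(obsIdx)))
  set.seed(seed)
  rows <- expand.grid(rank = ranks, lambda = lambdas, repeatIdx = seq_len(nRepeats))
  rows$mse <- NA_real_
  for (rep in seq_len(nRepeats)) {
    hold <- NULL
    for (attempt in 1:100) {
      cand <- sample(obsIdx, nHold)
      trainMask <- obs; trainMask[cand] <- FALSE
      if (all(rowSums(trainMask) > 0)) { hold <- cand; break }
    }
    if (is.null(hold))
      stop("could not draw a holdout leaving every drug observed; lower holdoutFraction")
    trainVals <- vals; trainVals[hold] <- NA_real_
    trainMask <- obs; trainMask[hold] <- FALSE
    train <- EndpointMatrix(trainVals, trainMask)
    for (i in which(rows$repeatIdx == rep)) {
      dec <- softImpute(train, rank = rows$rank[i], lambda = rows$lambda[i], ...)
      recon <- dec@u %*% (dec@d * t(dec@v))
      rows$mse[i] <- mean((recon[hold] - vals[hold])^2)
    }
  }
  agg <- stats::aggregate(mse ~ rank + lambda, data = rows, FUN = mean)
  best <- agg[which.min(agg$mse), ]
  list(rank = best$rank, lambda = best$lambda, mseTable = rows)
}
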