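#' Signed gene-phenotype z-score from a combined p-value
#'
#' Converts an S-MultiXcan-style association p-value into a signed z-score:
#' the magnitude is the absolute standard-normal quantile of the p-value and
#' the sign is the consensus direction of regulation across tissues, i.e.
#' `|qnorm(p)| * sign`. The magnitude is 0 at p = 0.5 and grows toward both
#' tails of p, so only the supplied consensus sign carries direction.
#'
#' @param p numeric vector of p-values in (0, 1]. Values below `floor` are
#'   clipped (with a warning) to keep the quantile finite; values at the
#'   upper end are clipped to the largest double below 1 for the same
#'   reason (the magnitude is symmetric in p about 0.5, so p = 1 maps to
#'   the same magnitude as p = 1e-16).
#' @param consensusSign numeric vector of +1 / -1, recycled against `p`.
#' @param floor clipping floor for extreme p-values (default 1e-300).
#' @return Numeric vector of signed z-scores.
#' @examples
#' computeGeneZscore(0.05, -1)   # ~ -1.6449
#' computeGeneZscore(0.5, +1)    # 0
#' @seealso [consensusSign()], [varianceFilter()]
#' @export
computeGeneZscore <- function(p, consensusSign, floor = 1e-300) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (!all(consensusSign %in% c(-1, 1)))
    stop("consensusSign entries must be +1 or -1")
  if (any(p < floor)) {
    warning(sprintf("%d p-value(s) below the floor %g were clipped",
                    sum(p < floor), floor))
    p <- pmax(p, floor)
  }
  p <- pmin(p, 1 - 1e-16)  # 1 - 1e-300 is not representable; keep qnorm finite
  abs(stats::qnorm(p)) * consensusSign
}

#' Majority direction of regulation across tissues
#'
#' The per-tissue S-PrediXcan signs of a gene-phenotype association are
#' collapsed to a single consensus by majority vote. Ties are broken toward
#' +1 by default, or toward the sign of the most significant tissue when
#' per-tissue p-values are supplied and `tie = "most_significant"`.
#'
#' @param signs numeric vector of +1 / -1, one per tissue with a sign on
#'   record (tissues without a result are simply absent).
#' @param tie `"positive"` (default) or `"most_significant"`.
#' @param tissuePvalues per-tissue p-values aligned with `signs`; required
#'   for the `"most_significant"` tie-break.
#' @return +1 or -1.
#' @export
consensusSign <- function(signs, tie = c("positive", "most_significant"),
                          tissuePvalues = NULL) {
  tie <- match.arg(tie)
  if (!length(signs)) stop("at least one tissue sign is required")
  if (!all(signs %in% c(-1, 1))) stop("tissue signs must be +1 or -1")
  s <- sum(signs)
  if (s != 0) return(sign(s))
  if (tie == "positive") return(1)
  if (is.null(tissuePvalues) || length(tissuePvalues) != length(signs))
    stop("tissuePvalues aligned with signs are required for the 'most_significant' tie-break")
  signs[which.min(tissuePvalues)]
}

#' Build a GeneScoreMatrix from p-values and tissue signs
#'
#' Convenience wrapper combining [computeGeneZscore()] and [consensusSign()]:
#' given a genes x phenotypes matrix of combined p-values and, per cell, the
#' list of tissue signs, it produces the signed z-score matrix.
#'
#' @param pvalues genes x phenotypes numeric matrix of p-values in (0, 1].
#' @param signMatrix genes x phenotypes matrix of pre-computed consensus
#'   signs (+1/-1), e.g. from applying [consensusSign()] per cell.
#' @param floor passed to [computeGeneZscore()].
#' @return A [GeneScoreMatrix-class].
#' @export
geneScoresFromPvalues <- function(pvalues, signMatrix, floor = 1e-300) {
  if (!identical(dim(pvalues), dim(signMatrix)))
    stop("pvalues and signMatrix must share a shape")
  z <- matrix(computeGeneZscore(as.vector(pvalues), as.vector(signMatrix),
                                floor = floor),
              nrow(pvalues), ncol(pvalues), dimnames = dimnames(pvalues))
  GeneScoreMatrix(z)
}

#' Keep the genes most variably associated with phenotype
#'
#' Retains the `ceiling(keepFraction * n_genes)` genes with the largest
#' across-phenotype standard deviation, preserving the input row order of
#' the survivors. Ties in standard deviation are broken by input order
#' (stable sort), so the result is deterministic.
#'
#' @param g a [GeneScoreMatrix-class].
#' @param keepFraction fraction of genes to keep, in (0, 1]; default 0.5.
#' @return A [GeneScoreMatrix-class] with the filtered rows.
#' @export
varianceFilter <- function(g, keepFraction = 0.5) {
  stopifnot(is(g, "GeneScoreMatrix"))
  if (!is.numeric(keepFraction) || keepFraction <= 0 || keepFraction > 1)
    stop("keepFraction must lie in (0, 1]")
  v <- g@values
  nKeep <- ceiling(keepFraction * nrow(v))
  sds <- apply(v, 1L, stats::sd)
  keep <- sort(order(-sds)[seq_len(nKeep)])  # order() is stable: ties by row order
  GeneScoreMatrix(v[keep, , drop = FALSE])
}

#' Align drugs and phenotypes across the three input matrices
#'
#' Intersects and reorders shared identifiers so that the endpoint,
#' gene-score and association matrices agree: drugs are put in the endpoint
#' matrix's order restricted to drugs present in both D and Y, and
#' phenotypes in the gene-score matrix's order restricted to phenotypes
#' present in both G and Y. Drugs present in D but absent from Y are kept in
#' the returned endpoint matrix only when `keepUnlabelled = TRUE` (they can
#' be predicted for but not trained on).
#'
#' @param d an [EndpointMatrix-class].
#' @param g a [GeneScoreMatrix-class].
#' @param y an [AssociationMatrix-class].
#' @param keepUnlabelled keep D-only drugs at the end of the endpoint matrix.
#' @return A list with elements `d`, `g`, `y`, aligned.
#' @export
alignInputs <- function(d, g, y, keepUnlabelled = FALSE) {
  drugs <- intersect(drugIds(d), drugIds(y))
  phenos <- intersect(phenotypeIds(g), phenotypeIds(y))
  if (!length(drugs)) stop("no drugs shared between endpoint and association matrices")
  if (!length(phenos)) stop("no phenotypes shared between gene-score and association matrices")
  dOrder <- drugs[order(match(drugs, drugIds(d)))]
  pOrder <- phenos[order(match(phenos, phenotypeIds(g)))]
  dKeep <- dOrder
  if (keepUnlabelled) dKeep <- c(dOrder, setdiff(drugIds(d), drugIds(y)))
  list(
    d = EndpointMatrix(values(d)[dKeep, , drop = FALSE],
                       observedMask(d)[dKeep, , drop = FALSE]),
    g = GeneScoreMatrix(values(g)[, pOrder, drop = FALSE]),
    y = AssociationMatrix(values(y)[dOrder, pOrder, drop = FALSE],
                          polarity = polarity(y))
  )
}
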