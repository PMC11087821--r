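#' @import methods
NULL

.checkIds <- function(ids, what) {
  if (is.null(ids) || any(is.na(ids)) || !length(ids))
    return(sprintf("%s must be non-empty and NA-free", what))
  if (anyDuplicated(ids))
    return(sprintf("duplicated %s: %s", what,
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  NULL
}

#' EndpointMatrix: drug-by-endpoint hit-fraction scores with missingness
#'
#' Container for the drug molecular profile matrix D: real-valued
#' assay-endpoint scores (e.g. ToxCast Level 5 hit fractions) for each drug,
#' together with an observation mask, since most drugs are assayed for only a
#' subset of endpoints. Row and column identities live in `dimnames`.
#'
#' @slot values numeric matrix, drugs x endpoints; unobserved cells hold `NA`.
#' @slot mask logical matrix of the same shape; `TRUE` marks observed cells.
#'
#' @aliases EndpointMatrix
#' @exportClass EndpointMatrix
setClass("EndpointMatrix",
  representation(values = "matrix", mask = "matrix"),
  validity = function(object) {
    v <- object@values; m <- object@mask
    if (!is.numeric(v)) return("values must be numeric")
    if (!is.logical(m)) return("mask must be logical")
    if (!identical(dim(v), dim(m))) return("mask shape must equal values shape")
    msg <- c(.checkIds(rownames(v), "drug ids"),
             .checkIds(colnames(v), "endpoint ids"))
    if (length(msg)) return(msg[[1L]])
    if (any(rowSums(m) == 0))
      return(sprintf("drug(s) with no observed endpoint: %s",
                     paste(rownames(v)[rowSums(m) == 0], collapse = ", ")))
    if (any(!is.na(v[!m])) && any(!is.na(v) & !m))
      return("unobserved cells must hold NA")
    if (anyNA(v[m])) return("observed cells must be non-missing")
    TRUE
  })

#' Construct an EndpointMatrix
#'
#' @param values numeric matrix (drugs x endpoints) with `NA` for untested
#'   cells; must carry unique row and column names.
#' @param mask optional logical matrix of observed cells; defaults to
#'   `!is.na(values)`.
#' @return An [EndpointMatrix-class] object.
#' @examples
#' v <- matrix(c(0.1, NA, 0.7, 0.2, 0.5, NA), 2, 3,
#'             dimnames = list(c("d1", "d2"), c("e1", "e2", "e3")))
#' EndpointMatrix(v)
#' @export
EndpointMatrix <- function(values, mask = !is.na(values)) {
  storage.mode(values) <- "double"
  values[!mask] <- NA_real_
  dimnames(mask) <- dimnames(values)
  new("EndpointMatrix", values = values, mask = mask)
}

#' GeneScoreMatrix: signed gene-by-phenotype association z-scores
#'
#' Container for the complete matrix P of signed z-scores measuring the
#' association between genetically regulated expression of each gene and each
#' phenotype (PhenomeXcan-style S-MultiXcan statistics carrying the consensus
#' per-tissue direction of regulation).
#'
#' @slot values numeric matrix, genes x phenotypes, finite, no missing cells.
#'
#' @aliases GeneScoreMatrix
#' @exportClass GeneScoreMatrix
setClass("GeneScoreMatrix",
  representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    msg <- c(.checkIds(rownames(v), "gene ids"),
             .checkIds(colnames(v), "phenotype ids"))
    if (length(msg)) return(msg[[1L]])
    if (any(!is.finite(v))) return("gene scores must be finite and complete")
    TRUE
  })

#' Construct a GeneScoreMatrix
#'
#' @param values finite numeric matrix (genes x phenotypes) with unique
#'   row and column names.
#' @return A [GeneScoreMatrix-class] object.
#' @export
GeneScoreMatrix <- function(values) {
  storage.mode(values) <- "double"
  new("GeneScoreMatrix", values = values)
}

#' AssociationMatrix: binary known drug-phenotype associations
#'
#' Container for the supervision matrix Y: a 1 marks a recorded association
#' between a drug and a phenotype (SIDER-style side effects or indications),
#' a 0 an association not on record. Two polarities exist because side
#' effects and indications are modelled separately.
#'
#' @slot values numeric matrix of 0/1, drugs x phenotypes.
#' @slot polarity single string, `"side_effects"` or `"indications"`.
#'
#' @aliases AssociationMatrix
#' @exportClass AssociationMatrix
setClass("AssociationMatrix",
  representation(values = "matrix", polarity = "character"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    msg <- c(.checkIds(rownames(v), "drug ids"),
             .checkIds(colnames(v), "phenotype ids"))
    if (length(msg)) return(msg[[1L]])
    if (anyNA(v) || !all(v %in% c(0, 1)))
      return("association entries must all be 0 or 1")
    if (length(object@polarity) != 1L ||
        !object@polarity %in% c("side_effects", "indications"))
      return("polarity must be 'side_effects' or 'indications'")
    TRUE
  })

#' Construct an AssociationMatrix
#'
#' @param values numeric 0/1 matrix (drugs x phenotypes) with unique row and
#'   column names.
#' @param polarity `"side_effects"` (default) or `"indications"`.
#' @return An [AssociationMatrix-class] object.
#' @export
AssociationMatrix <- function(values, polarity = c("side_effects", "indications")) {
  storage.mode(values) <- "double"
  new("AssociationMatrix", values = values, polarity = match.arg(polarity))
}

#' Decomposition: truncated (soft-thresholded) SVD factors
#'
#' Holds the factors of a reduced-rank decomposition `M ~ U diag(S) V'` as
#' produced by [softImpute()] or [decomposeGeneMatrix()]. Columns of `U` and
#' `V` are orthonormal and singular values are positive and non-increasing;
#' components shrunk to zero are dropped, so the stored rank can be below the
#' requested one.
#'
#' @slot u numeric matrix with orthonormal columns (rows x r).
#' @slot d numeric vector of positive, non-increasing singular values.
#' @slot v numeric matrix with orthonormal columns (cols x r).
#' @slot lambda the soft-threshold parameter used (0 for a plain SVD).
#'
#' @aliases Decomposition
#' @exportClass Decomposition
setClass("Decomposition",
  representation(u = "matrix", d = "numeric", v = "matrix", lambda = "numeric"),
  validity = function(object) {
    r <- length(object@d)
    if (r == 0L) return("decomposition has rank zero")
    if (ncol(object@u) != r || ncol(object@v) != r)
      return("u, d, v ranks disagree")
    if (any(object@d <= 0)) return("singular values must be positive")
    if (is.unsorted(rev(object@d))) return("singular values must be non-increasing")
    if (max(abs(crossprod(object@u) - diag(r))) > 1e-8)
      return("u columns are not orthonormal (tolerance 1e-8)")
    if (max(abs(crossprod(object@v) - diag(r))) > 1e-8)
      return("v columns are not orthonormal (tolerance 1e-8)")
    if (length(object@lambda) != 1L || object@lambda < 0)
      return("lambda must be a single value >= 0")
    TRUE
  })

#' AffinityModel: a fitted bilinear drug-phenotype interaction model
#'
#' The result of [fitAffinity()]: the reduced-rank interaction matrix
#' `W_DP` (r_D x r_P) such that
#' `logit P(Y[i, j] = 1) = intercept + (U_D S_D)[i, ] W_DP V_P[j, ]'`,
#' together with the drug factor matrix `U_D S_D` and the gene-matrix
#' decomposition `G = U_P S_P V_P'` that define the prediction map and the
#' phenome / disease-genome projections.
#'
#' @slot wdp numeric matrix (r_D x r_P), typically sparse through the lasso.
#' @slot intercept single numeric, the fitted intercept (0 if disabled).
#' @slot drugFactors numeric matrix (drugs x r_D), rows named by drug id.
#' @slot geneDecomp [Decomposition-class] of the gene score matrix.
#' @slot l1Strength the lasso penalty the model was fitted at.
#' @slot polarity polarity label of the training associations.
#' @slot phenotypeIds phenotype identifiers, matching rows of `V_P`.
#'
#' @aliases AffinityModel
#' @exportClass AffinityModel
setClass("AffinityModel",
  representation(wdp = "matrix", intercept = "numeric",
                 drugFactors = "matrix", geneDecomp = "Decomposition",
                 l1Strength = "numeric", polarity = "character",
                 phenotypeIds = "character", usedIntercept = "logical"),
  validity = function(object) {
    rD <- nrow(object@wdp); rP <- ncol(object@wdp)
    if (ncol(object@drugFactors) != rD)
      return("drugFactors column count must equal nrow(wdp)")
    if (length(object@geneDecomp@d) != rP)
      return("gene decomposition rank must equal ncol(wdp)")
    if (length(object@intercept) != 1L) return("intercept must be scalar")
    if (nrow(object@geneDecomp@v) != length(object@phenotypeIds))
      return("phenotypeIds length must match gene decomposition v rows")
    if (is.null(rownames(object@drugFactors)))
      return("drugFactors rows must be named by drug id")
    TRUE
  })

#' DiseaseGenomeResult: drug-gene effects with permutation significance
#'
#' Drug-by-gene effect scores from the disease-genome projection, with
#' per-entry empirical permutation p-values and Benjamini-Yekutieli adjusted
#' q-values (adjusted per drug across its genes).
#'
#' @slot scores numeric matrix, drugs x genes.
#' @slot pvalues empirical two-sided permutation p-values, same shape.
#' @slot qvalues BY-adjusted q-values, same shape.
#' @slot nPerm number of valid permutations behind the p-values.
#'
#' @aliases DiseaseGenomeResult
#' @exportClass DiseaseGenomeResult
setClass("DiseaseGenomeResult",
  representation(scores = "matrix", pvalues = "matrix", qvalues = "matrix",
                 nPerm = "integer"),
  validity = function(object) {
    if (!identical(dim(object@scores), dim(object@pvalues)) ||
        !identical(dim(object@scores), dim(object@qvalues)))
      return("scores, pvalues and qvalues must share a shape")
    n <- object@nPerm
    if (length(n) != 1L || n < 1L) return("nPerm must be a positive integer")
    p <- object@pvalues; q <- object@qvalues
    if (any(p < 1 / (n + 1) - 1e-12) || any(p > 1))
      return("pvalues must lie in [1/(nPerm+1), 1]")
    if (any(q < p - 1e-12) || any(q > 1 + 1e-12))
      return("qvalues must satisfy p <= q <= 1")
    TRUE
  })

#' DrugNetwork: drug-drug graph from disease-gene overlap
#'
#' Undirected graph whose nodes are drugs and whose edges connect pairs
#' sharing significantly more disease genes than the weighted-sampling null
#' expects. Edge attributes carry the overlap size and empirical p-value.
#'
#' @slot graph an `igraph` object over all drugs with non-empty gene sets.
#' @slot edges data.frame with columns `drug_a`, `drug_b`, `overlap`, `p`.
#' @slot pThreshold the edge-significance cutoff the network was built at.
#'
#' @aliases DrugNetwork
#' @exportClass DrugNetwork
setClass("DrugNetwork",
  representation(graph = "ANY", edges = "data.frame", pThreshold = "numeric"),
  validity = function(object) {
    if (!igraph::is_igraph(object@graph)) return("graph must be an igraph")
    need <- c("drug_a", "drug_b", "overlap", "p")
    if (!all(need %in% names(object@edges)))
      return("edges must have columns drug_a, drug_b, overlap, p")
    TRUE
  })
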