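#' Matrix values of a draphnet container
#'
#' @param x an [EndpointMatrix-class], [GeneScoreMatrix-class] or
#'   [AssociationMatrix-class].
#' @return The underlying numeric matrix (with `NA` in unobserved endpoint
#'   cells).
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Observation mask of an endpoint matrix
#'
#' @param x an [EndpointMatrix-class].
#' @return Logical matrix; `TRUE` where the drug was assayed for the endpoint.
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' Drug identifiers
#' @param x a draphnet container carrying drugs on rows.
#' @return Character vector of drug ids in storage order.
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' Phenotype identifiers
#' @param x a draphnet container carrying phenotypes.
#' @return Character vector of phenotype ids in storage order.
#' @export
setGeneric("phenotypeIds", function(x) standardGeneric("phenotypeIds"))

#' Gene identifiers
#' @param x a draphnet container carrying genes.
#' @return Character vector of gene ids in storage order.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Polarity of an association source
#' @param x an [AssociationMatrix-class] or [AffinityModel-class].
#' @return `"side_effects"` or `"indications"`.
#' @export
setGeneric("polarity", function(x) standardGeneric("polarity"))

setMethod("values", "EndpointMatrix", function(x) x@values)
setMethod("values", "GeneScoreMatrix", function(x) x@values)
setMethod("values", "AssociationMatrix", function(x) x@values)
setMethod("observedMask", "EndpointMatrix", function(x) x@mask)

setMethod("drugIds", "EndpointMatrix", function(x) rownames(x@values))
setMethod("drugIds", "AssociationMatrix", function(x) rownames(x@values))
setMethod("drugIds", "AffinityModel", function(x) rownames(x@drugFactors))
setMethod("drugIds", "DiseaseGenomeResult", function(x) rownames(x@scores))

setMethod("phenotypeIds", "GeneScoreMatrix", function(x) colnames(x@values))
setMethod("phenotypeIds", "AssociationMatrix", function(x) colnames(x@values))
setMethod("phenotypeIds", "AffinityModel", function(x) x@phenotypeIds)

setMethod("geneIds", "GeneScoreMatrix", function(x) rownames(x@values))
setMethod("geneIds", "AffinityModel", function(x) rownames(x@geneDecomp@u))
setMethod("geneIds", "DiseaseGenomeResult", function(x) colnames(x@scores))

setMethod("polarity", "AssociationMatrix", function(x) x@polarity)
setMethod("polarity", "AffinityModel", function(x) x@polarity)

#' @describeIn interactionMatrix accessor for the fitted reduced-rank
#'   interaction matrix.
#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' Reduced-rank interaction matrix of a fitted model
#'
#' @name interactionMatrix
#' @param x an [AffinityModel-class].
#' @return The r_D x r_P matrix `W_DP`.
setMethod("interactionMatrix", "AffinityModel", function(x) x@wdp)

setMethod("show", "EndpointMatrix", function(object) {
  m <- object@mask
  cat(sprintf("EndpointMatrix: %d drugs x %d endpoints (%.1f%% observed)\n",
              nrow(m), ncol(m), 100 * mean(m)))
})

setMethod("show", "GeneScoreMatrix", function(object) {
  v <- object@values
  cat(sprintf("GeneScoreMatrix: %d genes x %d phenotypes (|z| range %.3g..%.3g)\n",
              nrow(v), ncol(v), min(abs(v)), max(abs(v))))
})

setMethod("show", "AssociationMatrix", function(object) {
  v <- object@values
  cat(sprintf("AssociationMatrix (%s): %d drugs x %d phenotypes, density %.3f\n",
              object@polarity, nrow(v), ncol(v), mean(v)))
})

setMethod("show", "Decomposition", function(object) {
  cat(sprintf("Decomposition: %d x %d, rank %d, lambda %.4g, d = [%.4g .. %.4g]\n",
              nrow(object@u), nrow(object@v), length(object@d), object@lambda,
              object@d[1L], object@d[length(object@d)]))
})

setMethod("show", "AffinityModel", function(object) {
  cat(sprintf(paste0("AffinityModel (%s): %d drugs, %d phenotypes, %d genes; ",
                     "r_D = %d, r_P = %d, l1 = %.4g, %d/%d nonzero in W_DP\n"),
              object@polarity, nrow(object@drugFactors),
              length(object@phenotypeIds), nrow(object@geneDecomp@u),
              nrow(object@wdp), ncol(object@wdp), object@l1Strength,
              sum(object@wdp != 0), length(object@wdp)))
})

setMethod("show", "DiseaseGenomeResult", function(object) {
  cat(sprintf(paste0("DiseaseGenomeResult: %d drugs x %d genes, %d permutations; ",
                     "%d entries with q < 0.05\n"),
              nrow(object@scores), ncol(object@scores), object@nPerm,
              sum(object@qvalues < 0.05)))
})

setMethod("show", "DrugNetwork", function(object) {
  cat(sprintf("DrugNetwork: %d drugs, %d significant edges (p < %.3g)\n",
              igraph::vcount(object@graph), nrow(object@edges),
              object@pThreshold))
})
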