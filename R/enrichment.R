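#' Build drug-gene sets with per-gene drug counts
#'
#' Packages per-drug significant disease-gene sets together with the gene
#' weights used by the overlap null: each gene's weight is the number of
#' drugs it is significantly associated with.
#'
#' @param sets named list: drug id -> character vector of gene ids (e.g.
#'   from [significantGenes()]).
#' @return List with `sets` (drugs with non-empty sets) and `geneWeight`
#'   (named integer vector over the gene universe).
#' @export
drugGeneSets <- function(sets) {
  sets <- lapply(sets, unique)
  nonEmpty <- sets[lengths(sets) > 0]
  w <- table(unlist(nonEmpty, use.names = FALSE))
  geneWeight <- stats::setNames(as.integer(w), names(w))
  list(sets = nonEmpty, geneWeight = geneWeight)
}

#' Hypergeometric enrichment of disease genes among a target's drugs
#'
#' For each target shared by at least three drugs, and each disease gene
#' associated with one or more of the drugs having that target, tests
#' whether the target's drugs are enriched for drugs associated with that
#' gene: upper-tail hypergeometric `P(X >= k)` with population
#' `N = nDrugsTotal` drugs, `K` drugs associated with the gene, `n` drugs
#' with the target, and observed overlap `k`. P-values are BH-adjusted
#' within each target across its tested genes.
#'
#' @param targets named list: target id -> drug ids. Targets with fewer
#'   than three drugs are dropped.
#' @param sets a [drugGeneSets()] result (or a plain named list of gene
#'   sets, which is wrapped).
#' @param nDrugsTotal population size: all drugs in the model.
#' @return data.frame with columns `target`, `gene`, `k`, `n`, `K`, `N`,
#'   `p`, `q`.
#' @export
targetGeneEnrichment <- function(targets, sets, nDrugsTotal) {
  if (!is.null(sets$sets)) { gw <- sets$geneWeight; sets <- sets$sets }
  else { gw <- drugGeneSets(sets)$geneWeight; sets <- sets[lengths(sets) > 0] }
  targets <- lapply(targets, intersect, y = names(sets))
  targets <- targets[lengths(targets) >= 3L]
  rows <- list()
  for (t in names(targets)) {
    tDrugs <- targets[[t]]
    n <- length(tDrugs)
    genes <- sort(unique(unlist(sets[tDrugs], use.names = FALSE)))
    if (!length(genes)) next
    k <- vapply(genes, function(g)
      sum(vapply(sets[tDrugs], function(s) g %in% s, TRUE)), 0L)
    K <- as.integer(gw[genes])
    if (any(k > pmin(n, K)))
      stop("internal consistency error: overlap exceeds min(n, K)")
    p <- stats::phyper(k - 1L, K, nDrugsTotal - K, n, lower.tail = FALSE)
    rows[[t]] <- data.frame(target = t, gene = genes, k = k, n = n, K = K,
                            N = nDrugsTotal, p = p,
                            q = stats::p.adjust(p, method = "BH"),
                            row.names = NULL)
  }
  if (!length(rows))
    return(data.frame(target = character(), gene = character(), k = integer(),
                      n = integer(), K = integer(), N = integer(),
                      p = numeric(), q = numeric()))
  do.call(rbind, rows)
}

#' Permuted-target calibration of enrichment significance
#'
#' Checks that targets carry more disease-gene signal than chance: drugs
#' are reassigned to targets at random (preserving each target's drug
#' count), the enrichment is recomputed, and for every true target and each
#' permuted version the p-value of its most significant gene is recorded.
#'
#' @param targets named list: target id -> drug ids.
#' @param sets a [drugGeneSets()] result or plain named list of gene sets.
#' @param nDrugsTotal population size for the hypergeometric test.
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @param drugUniverse pool the permuted assignments draw from; defaults to
#'   all drugs with a non-empty gene set.
#' @return List with `trueMinP` (named vector per target) and `nullMinP`
#'   (targets x nPerm matrix).
#' @export
permutedTargetCalibration <- function(targets, sets, nDrugsTotal, nPerm = 100L,
                                      seed = 1L, drugUniverse = NULL) {
  dgs <- if (!is.null(sets$sets)) sets else drugGeneSets(sets)
  if (is.null(drugUniverse)) drugUniverse <- names(dgs$sets)
  keep <- names(targets)[vapply(targets, function(d)
    length(intersect(d, names(dgs$sets))) >= 3L, TRUE)]
  targets <- targets[keep]
  minP <- function(tab) {
    out <- stats::setNames(rep(NA_real_, length(targets)), names(targets))
    if (nrow(tab)) {
      agg <- tapply(tab$p, tab$target, min)
      out[names(agg)] <- agg
    }
    out
  }
  trueMinP <- minP(targetGeneEnrichment(targets, dgs, nDrugsTotal))
  set.seed(seed)
  nullMinP <- matrix(NA_real_, length(targets), nPerm,
                     dimnames = list(names(targets), NULL))
  sizes <- lengths(lapply(targets, intersect, y = names(dgs$sets)))
  for (b in seq_len(nPerm)) {
    permTargets <- lapply(sizes, function(sz) sample(drugUniverse, sz))
    nullMinP[, b] <- minP(targetGeneEnrichment(permTargets, dgs, nDrugsTotal))
  }
  list(trueMinP = trueMinP, nullMinP = nullMinP)
}
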