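.stringSeed <- function(globalSeed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 1000000007
  as.integer((globalSeed %% 65521) * 32749 + h %% 30000000)  # < 2^31
}

#' Overlap significance of two drugs' disease-gene sets
#'
#' Monte-Carlo test of whether two drugs share more disease genes than
#' expected: a random gene set of size `|A|` is drawn (without replacement,
#' by successive draws with renormalisation) with probability proportional
#' to each gene's weight — how many drugs it is significantly associated
#' with — and its overlap with the fixed set B is compared to the observed
#' overlap. `p = (1 + #{sim overlap >= true overlap}) / (nSim + 1)`.
#' A zero observed overlap yields p = 1 without simulation (every simulated
#' overlap is >= 0).
#'
#' @param genesA character vector; the resampled drug's gene set.
#' @param genesB character vector; held fixed.
#' @param geneWeight named positive weights over the gene universe.
#' @param nSim number of simulations (default 1000).
#' @param seed RNG seed.
#' @return List with `overlap` and `p`.
#' @export
pairOverlapTest <- function(genesA, genesB, geneWeight, nSim = 1000L, seed = 1L) {
  universe <- names(geneWeight)
  if (any(geneWeight <= 0)) stop("gene weights must be positive")
  if (!all(genesA %in% universe) || !all(genesB %in% universe))
    stop("gene sets must be subsets of the weighted universe")
  if (length(genesA) > length(universe))
    stop("set A larger than the gene universe")
  ovTrue <- length(intersect(genesA, genesB))
  if (ovTrue == 0L) return(list(overlap = 0L, p = 1))
  set.seed(seed)
  inB <- universe %in% genesB
  hits <- 0L
  for (s in seq_len(nSim)) {
    draw <- sample.int(length(universe), length(genesA), prob = geneWeight)
    if (sum(inB[draw]) >= ovTrue) hits <- hits + 1L
  }
  list(overlap = ovTrue, p = (1 + hits) / (nSim + 1))
}

#' Drug-drug network from significant disease-gene overlap
#'
#' Connects pairs of drugs sharing more disease genes than the
#' weighted-sampling null expects. Every pair with a non-zero overlap is
#' tested with [pairOverlapTest()], resampling the drug with the smaller
#' gene set; pairs with zero overlap are never tested (their p is 1 by
#' construction). Per-pair RNG seeds are derived deterministically from the
#' global seed and the sorted id pair, so the network is invariant to drug
#' input order and safe to parallelise.
#'
#' @param sets a [drugGeneSets()] result, or a plain named list of per-drug
#'   gene sets.
#' @param pThreshold edge significance cutoff (nominal; default 0.05).
#' @param nSim simulations per pair (default 1000).
#' @param seed global seed.
#' @return A [DrugNetwork-class] over all drugs with non-empty sets.
#' @export
buildNetwork <- function(sets, pThreshold = 0.05, nSim = 1000L, seed = 1L) {
  dgs <- if (!is.null(sets$sets)) sets else drugGeneSets(sets)
  drugs <- sort(names(dgs$sets))
  if (length(drugs) < 2L) stop("need at least two drugs with non-empty gene sets")
  rows <- list()
  for (i in seq_along(drugs)[-length(drugs)]) {
    for (j in seq((i + 1L), length(drugs))) {
      a <- drugs[i]; b <- drugs[j]
      sa <- dgs$sets[[a]]; sb <- dgs$sets[[b]]
      ov <- length(intersect(sa, sb))
      if (ov == 0L) next
      if (length(sa) <= length(sb)) { resample <- sa; fixed <- sb }
      else { resample <- sb; fixed <- sa }
      res <- pairOverlapTest(resample, fixed, dgs$geneWeight, nSim = nSim,
                             seed = .stringSeed(seed, paste(a, b, sep = "|")))
      rows[[paste(a, b)]] <- data.frame(drug_a = a, drug_b = b,
                                        overlap = res$overlap, p = res$p)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows)
  else data.frame(drug_a = character(), drug_b = character(),
                  overlap = integer(), p = numeric())
  rownames(edges) <- NULL
  sig <- edges[edges$p < pThreshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sig, directed = FALSE,
                                     vertices = data.frame(name = drugs))
  new("DrugNetwork", graph = g, edges = sig, pThreshold = pThreshold)
}

#' Maximal drug cliques in the overlap network
#'
#' Retrieves all maximal fully connected cliques of at least `minSize`
#' drugs; these cliques are the network's categorisation units. Each clique
#' is sorted by drug id and the list is sorted lexicographically.
#'
#' @param network a [DrugNetwork-class].
#' @param minSize minimum clique size (default 3).
#' @return List of character vectors of drug ids.
#' @export
findCliques <- function(network, minSize = 3L) {
  stopifnot(is(network, "DrugNetwork"))
  cl <- igraph::max_cliques(network@graph, min = minSize)
  cl <- lapply(cl, function(x) sort(names(x)))
  cl[order(vapply(cl, paste, "", collapse = "\r"))]
}

#' Genes worth displaying in the drug-gene bipartite view
#'
#' The visualisation filter: keep genes significantly associated with at
#' least one target (enrichment q below `qThreshold`, default 0.01) and
#' associated with fewer than `maxDrugsPerGene` drugs in total (strict
#' inequality).
#'
#' @param sets a [drugGeneSets()] result or plain named list of gene sets.
#' @param enrichmentTable output of [targetGeneEnrichment()].
#' @param maxDrugsPerGene strict upper bound on per-gene drug count
#'   (default 15).
#' @param qThreshold target-association significance cutoff (default 0.01).
#' @return Character vector of gene ids.
#' @export
vizGeneFilter <- function(sets, enrichmentTable, maxDrugsPerGene = 15L,
                          qThreshold = 0.01) {
  dgs <- if (!is.null(sets$sets)) sets else drugGeneSets(sets)
  sig <- unique(enrichmentTable$gene[enrichmentTable$q < qThreshold])
  counts <- dgs$geneWeight[sig]
  sort(sig[!is.na(counts) & counts < maxDrugsPerGene])
}

#' Export a drug network
#'
#' Writes the edge list as TSV (`drug_a`, `drug_b`, `overlap`, `p`), the
#' graph as GraphML, and the cliques as one clique per line (tab-separated
#' drug ids).
#'
#' @param network a [DrugNetwork-class].
#' @param dir output directory (created if needed).
#' @param minCliqueSize passed to [findCliques()].
#' @return The directory path, invisibly.
#' @export
exportNetwork <- function(network, dir, minCliqueSize = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(network@edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  igraph::write_graph(network@graph, file.path(dir, "network.graphml"),
                      format = "graphml")
  cl <- findCliques(network, minSize = minCliqueSize)
  writeLines(vapply(cl, paste, "", collapse = "\t"),
             file.path(dir, "cliques.tsv"))
  invisible(dir)
}
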