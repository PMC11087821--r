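# Small named matrices and simulated instances shared across test files.

namedMatrix <- function(x, nr, prefixRow = "r", prefixCol = "c") {
  m <- matrix(x, nrow = nr)
  dimnames(m) <- list(paste0(prefixRow, seq_len(nrow(m))),
                      paste0(prefixCol, seq_len(ncol(m))))
  m
}

randomEndpointMatrix <- function(nDrugs, nEndpoints, missing = 0.2, seed = 1) {
  set.seed(seed)
  v <- namedMatrix(runif(nDrugs * nEndpoints), nDrugs, "drug", "ep")
  mask <- matrix(runif(length(v)) >= missing, nDrugs)
  for (i in which(rowSums(mask) == 0)) mask[i, 1] <- TRUE
  v[!mask] <- NA_real_
  EndpointMatrix(v, mask)
}

# A small fitted model on simulated data; cached per session because several
# test files exercise projections of the same object.
smallFit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulateData(simConfig(nDrugs = 40, nEndpoints = 60, nGenes = 80,
                                    nPhenotypes = 12, seed = 11))
      dec <- softImpute(sim$endpoints, rank = 4, lambda = 0.1)
      gd <- decomposeGeneMatrix(sim$genes, 4)
      model <- fitAffinity(drugFactors(dec), gd, sim$assoc, l1Strength = 0.01)
      cache <<- list(sim = sim, dec = dec, gd = gd, model = model)
    }
    cache
  }
})

# The reference-scale simulation (generator defaults) with its endpoint
# decomposition; cached because several test files reuse it.
defaultSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulateData(simConfig())
      dec <- softImpute(sim$endpoints, rank = 4, lambda = 0.1)
      cache <<- list(sim = sim, dec = dec)
    }
    cache
  }
})

# Brute-force oracles -------------------------------------------------------

# Upper-tail hypergeometric P(X >= k) by enumerating all C(N, n) draws.
enumHyperTail <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K)) >= k)
}

# All maximal cliques of size >= minSize by exhaustive subset search.
bruteMaximalCliques <- function(adj, minSize = 3) {
  nv <- nrow(adj)
  subsets <- lapply(seq_len(2^nv - 1), function(code)
    which(bitwAnd(code, 2^(seq_len(nv) - 1)) > 0))
  isClique <- function(s) all(adj[s, s][upper.tri(diag(length(s)))] == 1)
  cliques <- Filter(function(s) length(s) >= 2 && isClique(s), subsets)
  maximal <- Filter(function(s) {
    !any(vapply(cliques, function(t)
      length(t) > length(s) && all(s %in% t), TRUE))
  }, cliques)
  maximal <- Filter(function(s) length(s) >= minSize, maximal)
  maximal <- lapply(maximal, function(s) sort(rownames(adj)[s]))
  maximal[order(vapply(maximal, paste, "", collapse = "\r"))]
}
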