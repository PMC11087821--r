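.defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    simulate = list(enabled = TRUE),
    inputs = list(endpoints = NULL, genes = NULL, assoc = NULL, targets = NULL),
    prep = list(keepFraction = 1),
    decompose = list(rank = 4L, lambda = 0.1),
    model = list(rD = 4L, rP = 4L, l1Strength = 0.005),
    evaluate = list(enabled = TRUE, nFolds = 10L, binarizeThreshold = 0.5),
    permute = list(enabled = TRUE, nPerm = 49L, alpha = 0.05, mode = "entries"),
    network = list(enabled = TRUE, pThreshold = 0.05, nSim = 200L)
  )
}

.mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: simulate (or read) the inputs,
#' variance-filter the gene scores, decompose the endpoint matrix, fit the
#' affinity model, evaluate by drug-held-out cross-validation, project to
#' phenome and disease-genome space, build the permutation null with
#' significance calls, and derive the drug-drug network with its cliques.
#' Every artifact is a deterministic function of the configuration: a rerun
#' with an identical config produces byte-identical outputs. The fully
#' resolved configuration (all defaults filled in) is written alongside the
#' artifacts as `resolved_config.json`.
#'
#' @param config a named list overriding the defaults, or a path to a YAML
#'   file holding such a list. Sections: `seed`, `simulate` (`enabled` plus
#'   any [simConfig()] argument), `inputs` (paths to `endpoints`, `genes`,
#'   `assoc` TSVs and an optional `targets` map when not simulating),
#'   `prep` (`keepFraction`), `decompose` (`rank`, `lambda`, or a `cv` list
#'   with `ranks`/`lambdas`), `model` (`rD`, `rP`, `l1Strength`),
#'   `evaluate`, `permute`, `network` (each with `enabled` and their stage
#'   parameters).
#' @param outDir artifact directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- .mergeConfig(.defaultPipelineConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(cfg, file.path(outDir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- inputs ---
  if (isTRUE(cfg$simulate$enabled)) {
    simArgs <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
    if (is.null(simArgs$seed)) simArgs$seed <- cfg$seed
    sim <- simulateData(do.call(simConfig, simArgs))
    d <- sim$endpoints; g <- sim$genes; y <- sim$assoc; targets <- sim$targets
  } else {
    for (need in c("endpoints", "genes", "assoc"))
      if (is.null(cfg$inputs[[need]]) || !file.exists(cfg$inputs[[need]]))
        stop(sprintf("missing input path for '%s': %s", need,
                     if (is.null(cfg$inputs[[need]])) "(unset)"
                     else cfg$inputs[[need]]))
    d <- readMatrix(cfg$inputs$endpoints, "endpoints")
    g <- readMatrix(cfg$inputs$genes, "genescores")
    y <- readMatrix(cfg$inputs$assoc, "association")
    targets <- if (!is.null(cfg$inputs$targets)) readTargetMap(cfg$inputs$targets)
    else list()
    aligned <- alignInputs(d, g, y)
    d <- aligned$d; g <- aligned$g; y <- aligned$y
  }

  # --- prep ---
  if (cfg$prep$keepFraction < 1) g <- varianceFilter(g, cfg$prep$keepFraction)
  writeMatrix(d, file.path(outDir, "endpoints.tsv"))
  writeMatrix(g, file.path(outDir, "genescores.tsv"))
  writeMatrix(y, file.path(outDir, "associations.tsv"))

  # --- decompose ---
  if (!is.null(cfg$decompose$cv)) {
    sel <- cvSelect(d, ranks = cfg$decompose$cv$ranks,
                    lambdas = cfg$decompose$cv$lambdas,
                    holdoutFraction = cfg$decompose$cv$holdoutFraction %||% 0.05,
                    nRepeats = cfg$decompose$cv$nRepeats %||% 3L,
                    seed = cfg$seed)
    cfg$decompose$rank <- sel$rank; cfg$decompose$lambda <- sel$lambda
  }
  dec <- softImpute(d, rank = cfg$decompose$rank, lambda = cfg$decompose$lambda)
  fac <- drugFactors(dec)
  utils::write.table(data.frame(id = rownames(fac), fac, check.names = FALSE),
                     file.path(outDir, "drug_factors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- fit ---
  rD <- min(cfg$model$rD, ncol(fac))
  gd <- decomposeGeneMatrix(g, cfg$model$rP)
  model <- fitAffinity(fac[, seq_len(rD), drop = FALSE], gd, y,
                       l1Strength = cfg$model$l1Strength)
  utils::write.table(model@wdp, file.path(outDir, "wdp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  # --- evaluate ---
  evalReport <- NULL
  if (isTRUE(cfg$evaluate$enabled)) {
    evalReport <- cvEvaluate(dec, g, y, rD = rD, rP = cfg$model$rP,
                             l1Strength = cfg$model$l1Strength,
                             nFolds = cfg$evaluate$nFolds,
                             binarizeThreshold = cfg$evaluate$binarizeThreshold,
                             seed = cfg$seed)
    utils::write.table(evalReport$perDrug, file.path(outDir, "cv_per_drug.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(evalReport$roc, file.path(outDir, "roc_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(auc = evalReport$auc,
                              rankSumP = evalReport$rankSumP),
                         file.path(outDir, "cv_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- project ---
  phen <- phenomeEffect(model)
  genome <- diseaseGenome(model)
  utils::write.table(data.frame(id = rownames(phen), phen, check.names = FALSE),
                     file.path(outDir, "phenome_effect.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = rownames(genome), genome,
                                check.names = FALSE),
                     file.path(outDir, "disease_genome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- permute + network ---
  genomeResult <- NULL; network <- NULL; enrichment <- NULL
  if (isTRUE(cfg$permute$enabled)) {
    genomeResult <- diseaseGenomeTest(model, y, nPerm = cfg$permute$nPerm,
                                      seed = cfg$seed, mode = cfg$permute$mode)
    utils::write.table(data.frame(id = rownames(genomeResult@qvalues),
                                  genomeResult@qvalues, check.names = FALSE),
                       file.path(outDir, "disease_genome_q.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sets <- significantGenes(genomeResult, alpha = cfg$permute$alpha)
    dgs <- drugGeneSets(sets)
    if (length(targets)) {
      enrichment <- targetGeneEnrichment(targets, dgs, nrow(values(y)))
      utils::write.table(enrichment, file.path(outDir, "target_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (isTRUE(cfg$network$enabled) && length(dgs$sets) >= 2L) {
      network <- buildNetwork(dgs, pThreshold = cfg$network$pThreshold,
                              nSim = cfg$network$nSim, seed = cfg$seed)
      exportNetwork(network, file.path(outDir, "network"))
    }
  }

  invisible(list(config = cfg, endpoints = d, genes = g, assoc = y,
                 targets = targets, decomposition = dec, model = model,
                 evaluation = evalReport, genomeResult = genomeResult,
                 enrichment = enrichment, network = network))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
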